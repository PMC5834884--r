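#' Simulate complete spatial randomness (CSR) in 3D
#'
#' Draws a homogeneous Poisson point process: the number of points is
#' Poisson(lambda * V) and coordinates are i.i.d. uniform in the window.
#' This is the null model against which observed synapse centroid patterns
#' are compared.
#'
#' @param intensity Points per um^3 (> 0).
#' @param window A [window3d()] (nm).
#' @param seed Integer seed; the same seed reproduces the same pattern.
#' @return A [point_pattern()].
#' @examples
#' p <- simulate_csr_pattern(0.5, window3d(1e4, 1e4, 1e4), seed = 1)
#' intensity_um3(p)
#' @export
simulate_csr_pattern <- function(intensity, window, seed) {
  stopifnot(inherits(window, "window3d"))
  if (!is.numeric(intensity) || length(intensity) != 1 || intensity <= 0) {
    stop("simulate_csr_pattern: intensity must be a single positive number")
  }
  set.seed(seed)
  n <- stats::rpois(1, intensity * window_volume_um3(window))
  runifbox(n, window)
}

# n i.i.d. uniform points in the window (binomial process), as point_pattern
runifbox <- function(n, window) {
  pts <- cbind(
    stats::runif(n, 0, window$extents[1]),
    stats::runif(n, 0, window$extents[2]),
    stats::runif(n, 0, window$extents[3])
  )
  pts <- sweep(pts, 2, window$origin, "+")
  point_pattern(pts, window)
}

#' Simulate a hard-core point pattern by random sequential adsorption
#'
#' Synapses are extended objects and cannot overlap, so their centroids keep
#' a minimum separation. This generator places `round(intensity * volume)`
#' points one at a time, rejecting any candidate closer than
#' `2 * hardcore_radius` to an accepted point (random sequential adsorption,
#' RSA). With `hardcore_radius = 0` it reduces to a binomial (fixed-n CSR)
#' process.
#'
#' @param intensity Target points per um^3 of available volume.
#' @param hardcore_radius Hard-core radius in nm (>= 0); minimum pairwise
#'   distance is twice this value.
#' @param window A [window3d()].
#' @param seed Integer seed.
#' @param max_attempts Total candidate budget before the sampler declares
#'   saturation (default `500 * target`).
#' @param avoid Optional data frame of forbidden axis-aligned ellipsoids
#'   (columns `cx, cy, cz, ax, ay, az`, nm); candidates inside any of them
#'   are rejected and the target count is computed on the remaining volume.
#' @return A [point_pattern()] with attribute `hardcore_radius`.
#' @export
simulate_hardcore_pattern <- function(intensity, hardcore_radius, window,
                                      seed, max_attempts = NULL,
                                      avoid = NULL) {
  stopifnot(inherits(window, "window3d"))
  if (!is.numeric(intensity) || length(intensity) != 1 || intensity <= 0) {
    stop("simulate_hardcore_pattern: intensity must be positive")
  }
  if (hardcore_radius < 0) {
    stop("simulate_hardcore_pattern: hardcore_radius must be >= 0")
  }
  avail_um3 <- window_volume_um3(window)
  if (!is.null(avoid) && nrow(avoid) > 0) {
    avail_um3 <- avail_um3 -
      sum(4 / 3 * pi * avoid$ax * avoid$ay * avoid$az) / .NM3_PER_UM3
  }
  target <- round(intensity * avail_um3)
  set.seed(seed)
  pts <- rsa_fill(target, hardcore_radius, window, max_attempts, avoid)
  out <- point_pattern(pts, window)
  attr(out, "hardcore_radius") <- hardcore_radius
  out
}

# sequential RSA core; assumes RNG already seeded
rsa_fill <- function(target, hardcore_radius, window, max_attempts = NULL,
                     avoid = NULL) {
  if (is.null(max_attempts)) max_attempts <- max(1000L, 500L * target)
  if (target == 0) return(matrix(numeric(0), 0, 3))
  dmin2 <- (2 * hardcore_radius)^2
  acc <- matrix(NA_real_, target, 3)
  k <- 0L
  attempts <- 0L
  lo <- window$origin
  ext <- window$extents
  has_avoid <- !is.null(avoid) && nrow(avoid) > 0
  # propose candidates in batches to amortise R-level overhead
  while (k < target) {
    batch <- min(max(64L, 2L * (target - k)), max_attempts - attempts)
    if (batch <= 0L) {
      stop(sprintf(
        paste0("simulate_hardcore_pattern: RSA saturated after %d attempts; ",
               "achieved %d of %d points"), attempts, k, target))
    }
    cand <- cbind(lo[1] + stats::runif(batch) * ext[1],
                  lo[2] + stats::runif(batch) * ext[2],
                  lo[3] + stats::runif(batch) * ext[3])
    attempts <- attempts + batch
    if (has_avoid) {
      keep <- !points_in_ellipsoids(cand, avoid)
      cand <- cand[keep, , drop = FALSE]
    }
    for (i in seq_len(nrow(cand))) {
      if (k >= target) break
      p <- cand[i, ]
      if (k > 0L && dmin2 > 0) {
        a <- acc[seq_len(k), , drop = FALSE]
        d2 <- (a[, 1] - p[1])^2 + (a[, 2] - p[2])^2 + (a[, 3] - p[3])^2
        if (min(d2) < dmin2) next
      }
      k <- k + 1L
      acc[k, ] <- p
    }
  }
  acc
}

# logical vector: row of pts inside any ellipsoid of `ell`
points_in_ellipsoids <- function(pts, ell) {
  inside <- rep(FALSE, nrow(pts))
  for (j in seq_len(nrow(ell))) {
    u <- ((pts[, 1] - ell$cx[j]) / ell$ax[j])^2 +
      ((pts[, 2] - ell$cy[j]) / ell$ay[j])^2 +
      ((pts[, 3] - ell$cz[j]) / ell$az[j])^2
    inside <- inside | (u <= 1)
  }
  inside
}

#' Synthesize a synaptic apposition surface as a spherical cap
#'
#' The SAS curvature index used throughout this package is
#' `1 - projected_area / area`. For a spherical cap of half-angle `theta`
#' this index equals `(1 - cos(theta)) / 2`, and the cap area is
#' `2 * pi * R^2 * (1 - cos(theta))`, so a cap is the simplest surface family
#' whose area and curvature can be dialled independently: curvature 0 is a
#' flat disc, curvature 0.5 a hemisphere.
#'
#' @param area Target surface area in nm^2 (> 0).
#' @param curvature Target curvature index in `[0, 1)`.
#' @param resolution Approximate number of triangles (default 480).
#' @param seed Integer seed for the random 3D orientation.
#' @param calibrate If `TRUE` (default) the mesh is isotropically rescaled so
#'   its triangulated area equals `area` exactly; otherwise the triangulated
#'   area is within the mesh-resolution tolerance (about 1% at the default
#'   resolution) of the request.
#' @return A [sas_mesh()] centred at the origin.
#' @examples
#' m <- synthesize_sas_mesh(117800, 0.049, seed = 1)
#' mesh_area(m)
#' sas_curvature(m)
#' @export
synthesize_sas_mesh <- function(area, curvature, resolution = 480, seed = 1,
                                calibrate = TRUE) {
  if (!is.numeric(area) || area <= 0) {
    stop("synthesize_sas_mesh: area must be positive")
  }
  if (curvature < 0 || curvature >= 1) {
    stop("synthesize_sas_mesh: curvature must be in [0, 1)")
  }
  nr <- max(2L, round(sqrt(resolution / 8)))
  ns <- max(6L, round(resolution / (2 * nr - 1)))
  theta <- acos(1 - 2 * curvature)
  # ring construction: apex plus nr rings of ns vertices
  if (curvature < 1e-12) {
    r_out <- sqrt(area / pi)
    ring_r <- r_out * seq_len(nr) / nr
    ring_z <- rep(0, nr)
    apex_z <- 0
  } else {
    R <- sqrt(area / (4 * pi * curvature))
    phi <- theta * seq_len(nr) / nr
    ring_r <- R * sin(phi)
    ring_z <- R * cos(phi)
    apex_z <- R
  }
  ang <- 2 * pi * (seq_len(ns) - 1) / ns
  verts <- rbind(
    c(0, 0, apex_z),
    do.call(rbind, lapply(seq_len(nr), function(i) {
      cbind(ring_r[i] * cos(ang), ring_r[i] * sin(ang), ring_z[i])
    }))
  )
  idx <- function(ring, j) as.integer(1 + (ring - 1) * ns + (j - 1) %% ns + 1)
  fan <- t(vapply(seq_len(ns), function(j) {
    c(1L, idx(1L, j), idx(1L, j + 1L))
  }, integer(3)))
  quads <- NULL
  if (nr > 1L) {
    quads <- do.call(rbind, lapply(seq_len(nr - 1L), function(i) {
      do.call(rbind, lapply(seq_len(ns), function(j) {
        rbind(
          c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
          c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
        )
      }))
    }))
  }
  faces <- rbind(fan, quads)
  verts[, 3] <- verts[, 3] - mean(verts[, 3])
  set.seed(seed)
  rot <- random_rotation()
  verts <- verts %*% t(rot)
  m <- sas_mesh(verts, faces)
  if (calibrate) {
    s <- sqrt(area / mesh_area(m))
    m <- sas_mesh(verts * s, faces)
  }
  m
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_res)
  d <- sign(diag(qr.R(qr_res)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Place non-overlapping fixation-artifact ellipsoids
#'
#' Fixation artifacts (swollen neuronal/glial processes) occupy part of a
#' stack and must be discounted from the counting volume. The generator
#' models them as axis-aligned ellipsoids occupying exactly
#' `fraction` of the window volume. Placement partitions the window into
#' slabs along x, one ellipsoid inscribed (with jitter) per slab, which
#' guarantees non-overlap for any fraction up to ~0.45.
#'
#' @param window A [window3d()].
#' @param fraction Total artifact volume as a fraction of window volume
#'   (`0 <= fraction < 0.45`).
#' @param seed Integer seed.
#' @return Data frame with columns `cx, cy, cz, ax, ay, az` (nm) and
#'   attribute `volume_nm3` (analytic total, exactly `fraction * V`).
#' @export
artifact_masks <- function(window, fraction, seed) {
  stopifnot(inherits(window, "window3d"))
  if (fraction < 0 || fraction >= 0.45) {
    stop("artifact_masks: fraction must be in [0, 0.45)")
  }
  empty <- data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                      ax = numeric(0), ay = numeric(0), az = numeric(0))
  attr(empty, "volume_nm3") <- 0
  if (fraction == 0) return(empty)
  set.seed(seed)
  k <- sample(2:4, 1)
  w_rel <- stats::runif(k, 0.7, 1.3)
  w_rel <- w_rel / sum(w_rel)
  widths <- w_rel * window$extents[1]
  x0 <- window$origin[1] + c(0, cumsum(widths))[seq_len(k)]
  margin <- 0.97
  # per-slab fill is the global fraction; lambda^3 * (pi/6) * margin^3 = fraction
  q <- fraction / (pi / 6 * margin^3)   # = lambda_x * lambda_y * lambda_z
  rows <- lapply(seq_len(k), function(j) {
    ly <- stats::runif(1, q^(1 / 3), 1)
    lz <- stats::runif(1, max(q / ly, q^(1 / 3) * 0.9), 1)
    lx <- q / (ly * lz)
    half <- c(widths[j], window$extents[2], window$extents[3]) / 2
    a <- c(lx, ly, lz) * half * margin
    ctr <- c(x0[j] + half[1],
             window$origin[2] + half[2],
             window$origin[3] + half[3])
    slack <- half * margin - a
    ctr <- ctr + stats::runif(3, -1, 1) * slack
    data.frame(cx = ctr[1], cy = ctr[2], cz = ctr[3],
               ax = a[1], ay = a[2], az = a[3])
  })
  out <- do.call(rbind, rows)
  attr(out, "volume_nm3") <- sum(4 / 3 * pi * out$ax * out$ay * out$az)
  out
}

#' Volume of an ellipsoid clipped to a box
#'
#' Analytic when the ellipsoid lies wholly inside the box, otherwise a
#' vectorised midpoint slicing quadrature (relative error below ~0.5%).
#'
#' @param ell One-row data frame (or list) with `cx, cy, cz, ax, ay, az`.
#' @param lo,hi Numeric length-3 box corners (nm).
#' @param n Quadrature nodes per axis (default 256).
#' @return Volume in nm^3.
#' @export
ellipsoid_box_volume <- function(ell, lo, hi, n = 256) {
  ctr <- c(ell$cx, ell$cy, ell$cz)
  ax <- c(ell$ax, ell$ay, ell$az)
  if (all(ctr - ax >= lo) && all(ctr + ax <= hi)) {
    return(4 / 3 * pi * prod(ax))
  }
  if (any(ctr - ax >= hi) || any(ctr + ax <= lo)) return(0)
  zz <- ctr[3] + ax[3] * (seq_len(n) - 0.5) / n * 2 - ax[3]
  dz <- 2 * ax[3] / n
  keep_z <- zz >= lo[3] & zz <= hi[3]
  if (!any(keep_z)) return(0)
  zz <- zz[keep_z]
  yy <- ctr[2] + ax[2] * ((seq_len(n) - 0.5) / n * 2 - 1)
  dy <- 2 * ax[2] / n
  keep_y <- yy >= lo[2] & yy <= hi[2]
  if (!any(keep_y)) return(0)
  yy <- yy[keep_y]
  u2 <- ((zz - ctr[3]) / ax[3])^2
  v2 <- ((yy - ctr[2]) / ax[2])^2
  s <- outer(u2, v2, "+")
  w <- ax[1] * sqrt(pmax(0, 1 - s))          # x half-width
  xlo <- pmax(ctr[1] - w, lo[1])
  xhi <- pmin(ctr[1] + w, hi[1])
  sum(pmax(0, xhi - xlo)) * dy * dz
}

#' Render a synthetic semithin section label image
#'
#' Produces a 2D label field emulating a toluidine-blue semithin section:
#' spatially coherent blobs of neuronal somata, glial somata and blood
#' vessels on a neuropil background, with per-label pixel counts matching
#' the requested area fractions exactly (to the nearest pixel). Labels are
#' assigned by thresholding independent smoothed Gaussian random fields at
#' the exact empirical quantiles, so the ground truth is exact by
#' construction.
#'
#' @param fractions Numeric length-3: percentages of the image area occupied
#'   by neurons, glia and blood vessels (must sum to < 100).
#' @param image_size Pixels per side, length 1 or 2 (default 512).
#' @param seed Integer seed.
#' @param pixel_size_um Physical pixel size in um (default 0.25).
#' @return A [semithin_image()] whose `truth` attribute stores the exact
#'   rendered fractions (in %) for neurons, glia, vessels and neuropil.
#' @examples
#' img <- render_semithin(c(7.17, 0.50, 3.28), image_size = 128, seed = 1)
#' attr(img, "truth")
#' @export
render_semithin <- function(fractions, image_size = 512, seed = 1,
                            pixel_size_um = 0.25) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3 || any(fractions < 0)) {
    stop("render_semithin: fractions must be 3 non-negative percentages")
  }
  if (sum(fractions) >= 100) {
    stop("render_semithin: fractions must sum to < 100")
  }
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  set.seed(seed)
  npix <- prod(image_size)
  counts <- round(fractions / 100 * npix)
  labels <- matrix(0L, image_size[1], image_size[2])
  remaining <- rep(TRUE, npix)
  sigma <- c(max(2, image_size[1] / 16),   # neurons: large somata
             max(1, image_size[1] / 48),   # glia: small somata
             max(2, image_size[1] / 24))   # vessels: medium profiles
  for (lab in 1:3) {
    if (counts[lab] == 0) next
    field <- smooth_field(image_size, sigma[lab])
    pool <- which(remaining)
    pick <- pool[order(field[pool], decreasing = TRUE)[seq_len(counts[lab])]]
    labels[pick] <- lab
    remaining[pick] <- FALSE
  }
  truth <- c(counts, npix - sum(counts)) / npix * 100
  names(truth) <- c("neurons", "glia", "vessels", "neuropil")
  semithin_image(labels, pixel_size_um, truth = truth)
}

# periodic Gaussian-smoothed white noise field via FFT
smooth_field <- function(size, sigma) {
  noise <- matrix(stats::rnorm(prod(size)), size[1], size[2])
  gx <- stats::dnorm(pmin(0:(size[1] - 1), size[1]:1), sd = sigma)
  gy <- stats::dnorm(pmin(0:(size[2] - 1), size[2]:1), sd = sigma)
  kern <- outer(gx, gy)
  Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE))
}

#' Semithin section label image
#'
#' @param labels Integer matrix; 0 = neuropil background, 1 = neuron,
#'   2 = glia, 3 = blood vessel.
#' @param pixel_size_um Physical pixel size in um.
#' @param truth Optional named numeric of ground-truth fractions (%).
#' @return Object of class `semithin_image`.
#' @export
semithin_image <- function(labels, pixel_size_um, truth = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(!(labels %in% 0:3))) {
    stop("semithin_image: labels must be in {0, 1, 2, 3}")
  }
  structure(labels, class = "semithin_image",
            pixel_size_um = pixel_size_um, truth = truth)
}

#' @export
print.semithin_image <- function(x, ...) {
  cat(sprintf("semithin label image: %d x %d px at %.3g um/px\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um")))
  invisible(unclass(x))
}
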