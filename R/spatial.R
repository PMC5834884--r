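#' Nearest-neighbour distances of a 3D point pattern
#'
#' @param pattern A [point_pattern()] with at least two points.
#' @return Numeric vector of per-point nearest-neighbour distances (nm)
#'   with attribute `mean`.
#' @examples
#' p <- simulate_csr_pattern(0.5, window3d(1e4, 1e4, 1e4), seed = 1)
#' mean(nn_distances(p))
#' @export
nn_distances <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  n <- npoints(pattern)
  if (n < 2) stop("nn_distances: need at least 2 points")
  d <- pairdist_matrix(pattern$points)
  nnd <- d[cbind(seq_len(n), max.col(-d, ties.method = "first"))]
  attr(nnd, "mean") <- mean(nnd)
  nnd
}

# default r grid: 512 points from 0 to a quarter of the shortest side
default_r_grid <- function(window, n = 512) {
  seq(0, min(window$extents) / 4, length.out = n)
}

# truncate an r grid at rmax, warning if anything is dropped
truncate_r <- function(r, rmax, what) {
  if (max(r) > rmax) {
    warning(sprintf("%s: r grid truncated at %.4g nm", what, rmax))
    r <- r[r <= rmax]
  }
  r
}

#' Spatial summary-function estimate container
#'
#' @param fun `"G"`, `"F"` or `"K"`.
#' @param r Distance grid (nm).
#' @param est Estimated function values.
#' @param theo Theoretical CSR values on the same grid.
#' @param lo,hi Optional pointwise simulation envelope.
#' @param n_sim Number of CSR simulations behind the envelope.
#' @param correction Edge-correction label.
#' @return Object of class `spatial_function_estimate` (a data frame with
#'   attributes).
#' @export
spatial_function_estimate <- function(fun, r, est, theo, lo = NULL,
                                      hi = NULL, n_sim = 0,
                                      correction = "none") {
  df <- data.frame(r = r, est = est, theo = theo)
  if (!is.null(lo)) df$lo <- lo
  if (!is.null(hi)) df$hi <- hi
  structure(df, class = c("spatial_function_estimate", "data.frame"),
            fun = fun, n_sim = n_sim, correction = correction)
}

#' @export
print.spatial_function_estimate <- function(x, ...) {
  cat(sprintf("%s-function estimate (%s correction), %d r values%s\n",
              attr(x, "fun"), attr(x, "correction"), nrow(x),
              if (attr(x, "n_sim") > 0) {
                sprintf(", %d-simulation CSR envelope", attr(x, "n_sim"))
              } else ""))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' @export
plot.spatial_function_estimate <- function(x, ...) {
  fun <- attr(x, "fun")
  ylim <- range(c(x$est, x$theo, x$lo, x$hi), na.rm = TRUE)
  graphics::plot(x$r, x$est, type = "l", xlab = "r (nm)",
                 ylab = sprintf("%s(r)", fun), ylim = ylim, ...)
  if (!is.null(x$lo)) {
    graphics::polygon(c(x$r, rev(x$r)), c(x$lo, rev(x$hi)),
                      col = grDevices::adjustcolor("grey", 0.5), border = NA)
    graphics::lines(x$r, x$est)
  }
  graphics::lines(x$r, x$theo, lty = 2, col = "red")
  invisible(x)
}

# Kaplan-Meier estimator of a distance CDF under boundary censoring:
# d = distances, b = censoring (boundary) distances, r = evaluation grid
km_cdf <- function(d, b, r) {
  t <- pmin(d, b)
  e <- d <= b
  o <- order(t)
  t <- t[o]
  e <- e[o]
  n <- length(t)
  at_risk <- n - seq_len(n) + 1
  S <- cumprod(ifelse(e, 1 - 1 / at_risk, 1))
  idx <- findInterval(r, t)
  out <- numeric(length(r))
  pos <- idx > 0
  out[pos] <- 1 - S[idx[pos]]
  out
}

# reduced-sample (border) estimator of a distance CDF
rs_cdf <- function(d, b, r) {
  sb <- sort(b)
  den <- length(b) - findInterval(r, sb, left.open = TRUE)
  num <- vapply(r, function(ri) sum(d <= ri & b >= ri), numeric(1))
  ifelse(den > 0, num / den, NA_real_)
}

# uncorrected empirical CDF
raw_cdf <- function(d, r) {
  findInterval(r, sort(d)) / length(d)
}

#' Nearest-neighbour distance distribution function G
#'
#' Empirical CDF of nearest-neighbour distances with boundary-censoring
#' edge correction, against the CSR reference
#' `G(r) = 1 - exp(-lambda * (4/3) * pi * r^3)`.
#'
#' @param pattern A [point_pattern()], n >= 2.
#' @param r Distance grid (nm); default [default_r_grid()]. Values beyond
#'   half the shortest window side are dropped with a warning.
#' @param correction `"km"` (Kaplan-Meier, default; monotone by
#'   construction), `"rs"` (reduced-sample/border) or `"none"`.
#' @return A [spatial_function_estimate()].
#' @export
g_function <- function(pattern, r = NULL, correction = c("km", "rs", "none")) {
  stopifnot(inherits(pattern, "point_pattern"))
  correction <- match.arg(correction)
  n <- npoints(pattern)
  if (n < 2) stop("g_function: need at least 2 points")
  if (is.null(r)) r <- default_r_grid(pattern$window)
  r <- truncate_r(r, min(pattern$window$extents) / 2, "g_function")
  d <- as.numeric(nn_distances(pattern))
  b <- boundary_distance(pattern$points, pattern$window)
  est <- switch(correction,
                km = km_cdf(d, b, r),
                rs = rs_cdf(d, b, r),
                none = raw_cdf(d, r))
  lam <- n / window_volume_nm3(pattern$window)
  theo <- 1 - exp(-lam * 4 / 3 * pi * r^3)
  spatial_function_estimate("G", r, est, theo, correction = correction)
}

# regular grid of m test points (systematic, seeded random offset)
test_point_grid <- function(window, m, seed = NULL) {
  h <- (window_volume_nm3(window) / m)^(1 / 3)
  nk <- pmax(1L, round(window$extents / h))
  if (!is.null(seed)) set.seed(seed)
  off <- stats::runif(3)
  g <- lapply(1:3, function(k) {
    window$origin[k] + (seq_len(nk[k]) - 1 + off[k]) * window$extents[k] / nk[k]
  })
  as.matrix(expand.grid(x = g[[1]], y = g[[2]], z = g[[3]]))
}

# distance from each row of `from` to the nearest row of `to`.
# Single BLAS product on augmented coordinates: the column maximising
# 2 f.t - |t|^2 minimises the squared distance.
nearest_distance <- function(from, to) {
  s <- cbind(2 * from, 1) %*% t(cbind(to, -rowSums(to^2)))
  j <- max.col(s, ties.method = "first")
  d2 <- rowSums(from^2) - s[cbind(seq_len(nrow(from)), j)]
  sqrt(pmax(0, d2))
}

#' Empty-space function F
#'
#' CDF of the distance from test locations to the nearest point of the
#' pattern, estimated from a systematic grid of test points with
#' boundary-censoring edge correction. Under CSR, F equals G analytically.
#'
#' @inheritParams g_function
#' @param n_test_points Approximate number of grid test locations
#'   (default 4096).
#' @param seed Seed for the random offset of the test grid.
#' @return A [spatial_function_estimate()].
#' @export
f_function <- function(pattern, r = NULL, n_test_points = 4096,
                       correction = c("km", "rs", "none"), seed = 1) {
  stopifnot(inherits(pattern, "point_pattern"))
  correction <- match.arg(correction)
  if (npoints(pattern) < 1) stop("f_function: need at least 1 point")
  if (n_test_points < 1) stop("f_function: need at least 1 test point")
  if (is.null(r)) r <- default_r_grid(pattern$window)
  r <- truncate_r(r, min(pattern$window$extents) / 2, "f_function")
  tp <- test_point_grid(pattern$window, n_test_points, seed)
  d <- nearest_distance(tp, pattern$points)
  b <- boundary_distance(tp, pattern$window)
  est <- switch(correction,
                km = km_cdf(d, b, r),
                rs = rs_cdf(d, b, r),
                none = raw_cdf(d, r))
  lam <- npoints(pattern) / window_volume_nm3(pattern$window)
  theo <- 1 - exp(-lam * 4 / 3 * pi * r^3)
  spatial_function_estimate("F", r, est, theo, correction = correction)
}

#' Ripley's K function in 3D
#'
#' Second-moment function with translation edge correction, against the
#' CSR reference `K(r) = (4/3) * pi * r^3`.
#'
#' @inheritParams g_function
#' @param correction `"translation"` (default) or `"none"`.
#' @return A [spatial_function_estimate()].
#' @export
k_function <- function(pattern, r = NULL,
                       correction = c("translation", "none")) {
  stopifnot(inherits(pattern, "point_pattern"))
  correction <- match.arg(correction)
  n <- npoints(pattern)
  if (n < 2) stop("k_function: need at least 2 points")
  if (is.null(r)) r <- default_r_grid(pattern$window)
  r <- truncate_r(r, min(pattern$window$extents) / 2, "k_function")
  x <- pattern$points
  ext <- pattern$window$extents
  V <- window_volume_nm3(pattern$window)
  # unordered pairs via dist(); displacement components likewise
  dd <- as.numeric(stats::dist(x))
  if (correction == "translation") {
    w <- V / ((ext[1] - as.numeric(stats::dist(x[, 1]))) *
                (ext[2] - as.numeric(stats::dist(x[, 2]))) *
                (ext[3] - as.numeric(stats::dist(x[, 3]))))
  } else {
    w <- rep(1, length(dd))
  }
  o <- order(dd)
  cum <- cumsum(2 * w[o])           # ordered-pair sum
  idx <- findInterval(r, dd[o])
  est <- numeric(length(r))
  pos <- idx > 0
  est[pos] <- cum[idx[pos]] * V / (n * (n - 1))
  theo <- 4 / 3 * pi * r^3
  spatial_function_estimate("K", r, est, theo, correction = correction)
}

#' Pointwise CSR simulation envelopes
#'
#' Simulates `n_sim` CSR (binomial, conditioned on the observed n) patterns
#' in the observed window, evaluates the chosen summary function(s) on each,
#' and attaches the pointwise min/max envelope to the observed estimate.
#' The verdict is the fraction of r-grid points at which the observed
#' estimate exits the envelope; under CSR, pointwise exits occur at rate
#' `2 / (n_sim + 1)` per grid point.
#'
#' @param pattern A [point_pattern()].
#' @param fun Character vector from `c("G", "F", "K")`; several functions
#'   share the same simulated patterns.
#' @param n_sim Number of CSR simulations (default 100).
#' @param seed Integer seed.
#' @param r Distance grid (nm); default [default_r_grid()].
#' @param correction Correction for G/F (K always uses translation).
#' @param n_test_points Test points for F.
#' @return If one function requested, a [spatial_function_estimate()] with
#'   `lo`/`hi` and attributes `prop_outside` and `verdict`
#'   (`"consistent with CSR"` / `"departs from CSR"`); if several, a named
#'   list of them.
#' @export
csr_envelope <- function(pattern, fun = "G", n_sim = 100, seed = 1,
                         r = NULL, correction = "km",
                         n_test_points = 4096) {
  stopifnot(inherits(pattern, "point_pattern"))
  fun <- match.arg(fun, c("G", "F", "K"), several.ok = TRUE)
  if (n_sim < 1) stop("csr_envelope: n_sim must be >= 1")
  if (is.null(r)) r <- default_r_grid(pattern$window)
  r <- truncate_r(r, min(pattern$window$extents) / 2, "csr_envelope")
  n <- npoints(pattern)
  eval_one <- function(pat, f, s) {
    switch(f,
           G = g_function(pat, r, correction = correction)$est,
           F = f_function(pat, r, n_test_points = n_test_points,
                          correction = correction, seed = s)$est,
           K = k_function(pat, r)$est)
  }
  obs <- lapply(stats::setNames(fun, fun), function(f) {
    switch(f,
           G = g_function(pattern, r, correction = correction),
           F = f_function(pattern, r, n_test_points = n_test_points,
                          correction = correction, seed = seed),
           K = k_function(pattern, r))
  })
  sims <- lapply(stats::setNames(fun, fun),
                 function(f) matrix(NA_real_, n_sim, length(r)))
  for (i in seq_len(n_sim)) {
    set.seed(derive_seed(seed, i))
    simpat <- runifbox(n, pattern$window)
    for (f in fun) {
      sims[[f]][i, ] <- eval_one(simpat, f, derive_seed(seed, i))
    }
  }
  out <- lapply(stats::setNames(fun, fun), function(f) {
    lo <- apply(sims[[f]], 2, min)
    hi <- apply(sims[[f]], 2, max)
    e <- obs[[f]]
    est <- spatial_function_estimate(f, r, e$est, e$theo, lo = lo, hi = hi,
                                     n_sim = n_sim,
                                     correction = attr(e, "correction"))
    outside <- mean(e$est < lo - 1e-12 | e$est > hi + 1e-12, na.rm = TRUE)
    attr(est, "prop_outside") <- outside
    attr(est, "verdict") <- if (outside <= 2 * 2 / (n_sim + 1)) {
      "consistent with CSR"
    } else "departs from CSR"
    est
  })
  if (length(fun) == 1) out[[1]] else out
}

#' Dead-space radius of a G estimate
#'
#' Synapses are extended objects, so G(r) is exactly zero below the minimum
#' centroid separation: the "dead space". Returns the largest r at which
#' the estimate is still zero (up to grid resolution), or 0 (with attribute
#' `note`) when the first grid point is already positive.
#'
#' @param g_estimate A G-function [spatial_function_estimate()].
#' @return Radius in nm.
#' @export
dead_space_radius <- function(g_estimate) {
  stopifnot(inherits(g_estimate, "spatial_function_estimate"))
  if (attr(g_estimate, "fun") != "G") {
    stop("dead_space_radius: needs a G-function estimate")
  }
  est <- g_estimate$est
  r <- g_estimate$r
  pos <- which(est > 0)
  first_pos <- if (length(pos) > 0) pos[1] else length(r) + 1
  if (first_pos <= 2) {   # r[1] is 0 by convention; est positive right away
    out <- 0
    attr(out, "note") <- "G positive at the first non-zero grid point"
    return(out)
  }
  r[first_pos - 1]
}
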