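# Independent brute-force oracles used to validate the fast estimators.
# These deliberately re-derive each quantity from its definition with plain
# loops; they must never call the implementation they check.

# Kaplan-Meier CDF of censored distances, by explicit product over event
# times
naive_km_cdf <- function(d, b, r) {
  t <- pmin(d, b)
  e <- d <= b
  vapply(r, function(ri) {
    ts <- sort(unique(t[e & t <= ri]))
    s <- 1
    for (tt in ts) {
      s <- s * (1 - sum(e & t == tt) / sum(t >= tt))
    }
    1 - s
  }, numeric(1))
}

# reduced-sample (border) CDF
naive_rs_cdf <- function(d, b, r) {
  vapply(r, function(ri) {
    den <- sum(b >= ri)
    if (den == 0) NA_real_ else sum(d <= ri & b >= ri) / den
  }, numeric(1))
}

# nearest-neighbour distances by double loop
naive_nn <- function(pts) {
  n <- nrow(pts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      dij <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (dij < best) best <- dij
    }
    out[i] <- best
  }
  out
}

# translation-corrected Ripley K by double loop
naive_k <- function(pts, window, r) {
  n <- nrow(pts)
  ext <- window$extents
  V <- prod(ext)
  acc <- numeric(length(r))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dl <- abs(pts[i, ] - pts[j, ])
      dij <- sqrt(sum(dl^2))
      w <- V / prod(ext - dl)
      acc <- acc + w * (dij <= r)
    }
  }
  acc * V / (n * (n - 1))
}

# shortest distance to the window boundary, per point
naive_bdist <- function(pts, window) {
  lo <- window$origin
  hi <- window$origin + window$extents
  apply(pts, 1, function(p) min(p - lo, hi - p))
}

# counting-frame adjudication re-derived from interval overlap logic
naive_frame_decision <- function(ext_row, frame) {
  a <- ext_row[1:3]
  b <- ext_row[4:6]
  w <- frame$window
  wlo <- w$origin
  whi <- w$origin + w$extents
  if (any(a <= wlo) || any(b >= whi)) return("incomplete")
  # closed-box overlap with the frame (touching an inclusion face counts)
  olo <- pmax(a, frame$lo)
  ohi <- pmin(b, frame$hi)
  if (any(olo > ohi)) return("outside")
  # touching any exclusion face or its extension plane
  if (any(b >= frame$hi)) return("exclusion")
  "counted"
}

# exact Mann-Whitney two-sided p by full enumeration of group assignments
enum_mw_p <- function(a, b) {
  n <- length(a)
  m <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx) sum(rk[idx]) - n * (n + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# two-sample KS D by scanning both empirical CDFs at every data point
scan_ks_d <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  d <- 0
  for (x in xs) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}

# union area of projected triangles by rasterisation
raster_union_area <- function(p2d, faces, n = 800) {
  xr <- range(p2d[, 1])
  yr <- range(p2d[, 2])
  xs <- seq(xr[1], xr[2], length.out = n)
  ys <- seq(yr[1], yr[2], length.out = n)
  cell <- (xs[2] - xs[1]) * (ys[2] - ys[1])
  gx <- rep(xs, times = n)
  gy <- rep(ys, each = n)
  covered <- rep(FALSE, n * n)
  for (t in seq_len(nrow(faces))) {
    v <- p2d[faces[t, ], ]
    d1 <- (gx - v[2, 1]) * (v[1, 2] - v[2, 2]) -
      (v[1, 1] - v[2, 1]) * (gy - v[2, 2])
    d2 <- (gx - v[3, 1]) * (v[2, 2] - v[3, 2]) -
      (v[2, 1] - v[3, 1]) * (gy - v[3, 2])
    d3 <- (gx - v[1, 1]) * (v[3, 2] - v[1, 2]) -
      (v[3, 1] - v[1, 1]) * (gy - v[1, 2])
    neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
    pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
    covered <- covered | !(neg & pos)
  }
  sum(covered) * cell
}

# Thomas-like clustered pattern: CSR parents with tight Gaussian offspring
make_clustered_pattern <- function(n_parents, n_offspring, sd_nm, window,
                                   seed) {
  set.seed(seed)
  ext <- window$extents
  par <- cbind(runif(n_parents, 0, ext[1]), runif(n_parents, 0, ext[2]),
               runif(n_parents, 0, ext[3]))
  pts <- do.call(rbind, lapply(seq_len(n_parents), function(i) {
    sweep(matrix(rnorm(3 * n_offspring, sd = sd_nm), ncol = 3), 2,
          par[i, ], "+")
  }))
  pts <- sweep(pts, 2, window$origin, "+")
  keep <- pts[, 1] >= window$origin[1] &
    pts[, 1] <= window$origin[1] + ext[1] &
    pts[, 2] >= window$origin[2] & pts[, 2] <= window$origin[2] + ext[2] &
    pts[, 3] >= window$origin[3] & pts[, 3] <= window$origin[3] + ext[3]
  point_pattern(pts[keep, , drop = FALSE], window)
}

# tiny meshes used across tests
unit_square_mesh <- function() {
  sas_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
           rbind(c(1, 2, 3), c(1, 3, 4)))
}

tetrahedron_mesh <- function() {  # closed surface: no boundary
  sas_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

# strip of triangles folded back over itself: projections overlap
folded_strip_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(0, 1, 0),
             c(1, 0, 0), c(1, 1, 0),
             c(2, 0, 0.4), c(2, 1, 0.4),
             c(1.2, 0, 0.8), c(1.2, 1, 0.8),
             c(0.2, 0, 1.0), c(0.2, 1, 1.0))
  f <- rbind(c(1, 3, 4), c(1, 4, 2),
             c(3, 5, 6), c(3, 6, 4),
             c(5, 7, 8), c(5, 8, 6),
             c(7, 9, 10), c(7, 10, 8))
  sas_mesh(v, f)
}
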