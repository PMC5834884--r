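test_that("nearest-neighbour distances match closed form under CSR", {
  w <- window3d(500, 500, 500)
  p2 <- point_pattern(rbind(c(100, 100, 100), c(100, 100, 600 - 500)),
                      w)
  expect_error(nn_distances(point_pattern(c(1, 1, 1), w)), "at least 2")
  two <- point_pattern(rbind(c(0, 0, 0), c(500, 0, 0)), w)
  d <- nn_distances(two)
  expect_equal(as.numeric(d), c(500, 500))
  expect_equal(attr(d, "mean"), 500)
  # CSR closed form: Gamma(4/3) (4 pi lambda / 3)^(-1/3). The raw mean is
  # biased upward near the window boundary (the true nearest neighbour may
  # lie outside), so compare the edge-corrected mean obtained by
  # integrating the KM-corrected survival of G.
  lam <- 0.5
  expect_mean <- gamma(4 / 3) * (4 * pi * lam / 3)^(-1 / 3) * 1e3
  big <- window3d(12e3, 12e3, 12e3)
  means <- vapply(1:8, function(s) {
    p <- simulate_csr_pattern(lam, big, seed = s)
    g <- g_function(p, r = seq(0, 3000, length.out = 1000))
    sum(1 - g$est) * diff(g$r[1:2])
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expect_mean), 4 * se + 5)
})

test_that("G function: dead space, bounds, monotonicity", {
  w <- window3d(8e3, 8e3, 8e3)
  hp <- simulate_hardcore_pattern(0.5, 250, w, seed = 4)
  g <- g_function(hp)
  expect_equal(g$est[1], 0)   # r = 0
  expect_true(all(g$est[g$r < 500] == 0))   # dead space below 2 r_hc
  ds <- dead_space_radius(g)
  expect_gte(ds, 500 - diff(g$r[1:2]))
  expect_lt(ds, 700)
  # km estimates live in [0,1] and never decrease
  for (s in 1:4) {
    p <- simulate_csr_pattern(0.3, w, seed = s)
    gg <- g_function(p)
    expect_true(all(gg$est >= 0 & gg$est <= 1))
    expect_true(all(diff(gg$est) >= -1e-12))
  }
  # CSR dead space shrinks toward zero as n grows
  gd <- g_function(simulate_csr_pattern(2, w, seed = 9))
  expect_lt(as.numeric(dead_space_radius(gd)), as.numeric(ds))
  expect_warning(g_function(hp, r = seq(0, 1e4, length.out = 50)),
                 "truncated")
})

test_that("F function: sparse limit, CSR equality with G, regularity", {
  w <- window3d(6e3, 6e3, 6e3)
  single <- point_pattern(matrix(c(3e3, 3e3, 3e3), 1), w)
  fe <- f_function(single, r = seq(0, 500, length.out = 26), seed = 1)
  expect_true(all(fe$est[fe$r < 300] < 0.05))
  # under CSR, F and G share the Poisson closed form
  p <- simulate_csr_pattern(0.8, w, seed = 12)
  fe2 <- f_function(p, seed = 2)
  expect_lt(max(abs(fe2$est - fe2$theo)), 0.06)
  expect_true(all(diff(fe2$est) >= -1e-12))
  # a hard-core (more regular) pattern empties space faster than CSR
  fhs <- vapply(1:6, function(s) {
    hp <- simulate_hardcore_pattern(0.8, 300, w, seed = s)
    fh <- f_function(hp, seed = s)
    mean(fh$est - fh$theo)
  }, numeric(1))
  expect_gt(mean(fhs), 0)
  expect_error(f_function(p, n_test_points = 0), "test point")
})

test_that("K function matches CSR and dips for hard-core patterns", {
  w <- window3d(8e3, 8e3, 8e3)
  p <- simulate_csr_pattern(0.5, w, seed = 21)
  k <- k_function(p)
  expect_equal(k$est[1], 0)
  expect_true(all(diff(k$est) >= 0))
  mid <- which.min(abs(k$r - 1500))
  expect_equal(k$est[mid], k$theo[mid], tolerance = 0.15)
  hp <- simulate_hardcore_pattern(0.5, 300, w, seed = 22)
  kh <- k_function(hp)
  small <- kh$r > 100 & kh$r < 600
  expect_true(all(kh$est[small] <= kh$theo[small]))
})

test_that("estimators agree exactly with naive oracles on small patterns", {
  set.seed(33)
  w <- window3d(2000, 1700, 1400)
  for (n in c(12, 50)) {
    pts <- cbind(runif(n, 0, 2000), runif(n, 0, 1700), runif(n, 0, 1400))
    p <- point_pattern(pts, w)
    r <- seq(0, 350, length.out = 41)
    d <- naive_nn(pts)
    b <- naive_bdist(pts, w)
    expect_equal(as.numeric(nn_distances(p)), d, tolerance = 1e-12)
    expect_equal(g_function(p, r, correction = "km")$est,
                 naive_km_cdf(d, b, r), tolerance = 1e-12)
    expect_equal(g_function(p, r, correction = "rs")$est,
                 naive_rs_cdf(d, b, r), tolerance = 1e-12)
    expect_equal(k_function(p, r)$est, naive_k(pts, w, r),
                 tolerance = 1e-9)
    # F via the same censored-CDF oracle on the test grid
    tp <- synapse3d:::test_point_grid(w, 400, seed = 5)
    dtp <- apply(tp, 1, function(q) min(sqrt(colSums((t(pts) - q)^2))))
    btp <- naive_bdist(tp, w)
    expect_equal(f_function(p, r, n_test_points = 400, seed = 5)$est,
                 naive_km_cdf(dtp, btp, r), tolerance = 1e-12)
  }
})

test_that("CSR envelopes accept CSR and reject clustering", {
  w <- window3d(7e3, 7e3, 7e3)
  p <- simulate_csr_pattern(0.6, w, seed = 44)
  env <- csr_envelope(p, fun = c("G", "K"), n_sim = 50, seed = 45)
  expect_lte(attr(env$G, "prop_outside"), 0.1)
  expect_equal(attr(env$G, "verdict"), "consistent with CSR")
  expect_true(all(env$G$lo <= env$G$hi))
  cl <- make_clustered_pattern(12, 18, 120, w, seed = 46)
  envc <- csr_envelope(cl, fun = "G", n_sim = 50, seed = 47)
  expect_equal(attr(envc, "verdict"), "departs from CSR")
  expect_gt(attr(envc, "prop_outside"), 0.1)
})

test_that("dead-space radius reports zero with a note when G starts high", {
  w <- window3d(3e3, 3e3, 3e3)
  cl <- make_clustered_pattern(10, 30, 30, w, seed = 3)
  g <- g_function(cl, r = seq(0, 700, length.out = 100))
  ds <- dead_space_radius(g)
  if (as.numeric(ds) == 0) expect_false(is.null(attr(ds, "note")))
  expect_error(dead_space_radius(k_function(simulate_csr_pattern(
    1, w, 1))), "G-function")
})
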