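test_that("neuropil complement reproduces the reported fractions", {
  expect_equal(neuropil_complement(7.17, 0.50, 3.28), 89.05)
  expect_equal(neuropil_complement(5.86, 0.35, 3.71), 90.08)
  expect_equal(neuropil_complement(0, 0, 0), 100)
  expect_error(neuropil_complement(60, 30, 15), "sum")
  expect_error(neuropil_complement(-1, 0, 0), ">= 0")
})

test_that("shrinkage factor is the after/before area ratio", {
  expect_equal(as.numeric(shrinkage_factor(100, 93.3)), 0.933)
  expect_equal(as.numeric(shrinkage_factor(50, 50)), 1)
  expect_equal(as.numeric(shrinkage_factor(100, 90)), 0.9)
  expect_error(shrinkage_factor(0, 10), "positive")
  expect_warning(shrinkage_factor(90, 100), "expansion")
})

test_that("shrinkage correction reproduces the printed stack volumes", {
  field_um2 <- (2048 * 0.005) * (1536 * 0.005)
  v_min <- correct_measurement(149 * 0.02 * field_um2, 0.933, 3)
  v_max <- correct_measurement(472 * 0.02 * field_um2, 0.933, 3)
  expect_equal(v_min, 260.2, tolerance = 0.001)
  expect_equal(v_max, 824.4, tolerance = 0.001)
  # identity at p2 = 1; simple area case
  expect_equal(correct_measurement(123.4, 1, 3), 123.4)
  expect_equal(correct_measurement(100, 0.933, 2), 100 / 0.933)
  # correcting a volume equals correcting each linear dimension
  p2 <- 0.9
  expect_equal(correct_measurement(7^3, p2, 3),
               correct_measurement(7, p2, 1)^3)
  # densities transform inversely to volumes
  n <- 42
  v <- 100
  expect_equal(correct_measurement(n / v, p2, -3),
               n / correct_measurement(v, p2, 3))
})

test_that("Cavalieri point counts converge to exact pixel fractions", {
  # half-neuron image: left half label 1
  m <- matrix(0L, 200, 200)
  m[1:100, ] <- 1L
  img <- semithin_image(m, pixel_size_um = 1)
  vf <- cavalieri_point_count(img, grid_spec(25, seed = 1))
  expect_equal(unname(vf["neurons"]), 50, tolerance = 0.1)
  expect_equal(sum(vf), 100)
  # uniform background: everything neuropil
  img0 <- semithin_image(matrix(0L, 50, 50), pixel_size_um = 1)
  vf0 <- cavalieri_point_count(img0, grid_spec(25, seed = 2))
  expect_equal(unname(vf0["neuropil"]), 100)
  expect_true(all(vf0[c("neurons", "glia", "vessels")] == 0))
  # 1 mm^2 at 400 um^2 per point -> 2500 test points
  big <- semithin_image(matrix(0L, 500, 500), pixel_size_um = 2)
  vfb <- cavalieri_point_count(big, grid_spec(400, seed = 3))
  expect_equal(attr(vfb, "n_points"), 2500)
  # grid coarser than the image errors
  tiny <- semithin_image(matrix(0L, 10, 10), pixel_size_um = 1)
  expect_error(cavalieri_point_count(tiny, grid_spec(1e6, seed = 1)),
               "grid")
})

test_that("denser grids reduce Cavalieri error on a rendered section", {
  img <- render_semithin(c(12, 3, 5), image_size = 300, seed = 9,
                         pixel_size_um = 1)
  truth <- attr(img, "truth")
  errs <- vapply(c(400, 100, 16), function(pa) {
    est <- cavalieri_point_count(img, grid_spec(pa, seed = 4))
    mean(abs(est[1:3] - truth[1:3]))
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.5)
})

test_that("artifact discounting subtracts and validates", {
  expect_equal(as.numeric(discount_artifacts(500, 0.33 * 500)), 335)
  expect_equal(as.numeric(discount_artifacts(471.3, 0)), 471.3)
  expect_equal(attr(discount_artifacts(500, 165), "artifact_fraction"), 0.33)
  expect_error(discount_artifacts(100, 100), "artifact_volume")
  expect_error(discount_artifacts(0, 0), "frame_volume")
})

test_that("artifact Cavalieri tally agrees with the analytic volume", {
  w <- window3d(3000, 3000, 2000)
  a <- artifact_masks(w, 0.2, seed = 6)
  analytic <- attr(a, "volume_nm3")
  # voxel tally oracle at 25 nm spacing
  st <- list(window = w, extents = matrix(numeric(0), 0, 6), artifacts = a)
  arr <- rasterize_stack(st, voxel_nm = c(25, 25, 25))
  tally <- sum(arr == 2L) * 25^3
  expect_equal(tally / analytic, 1, tolerance = 0.02)
  # clipped-quadrature volume agrees with the voxel tally inside a frame
  fr <- counting_frame(w, margin = 0.2)
  clip <- sum(vapply(seq_len(nrow(a)), function(j) {
    ellipsoid_box_volume(a[j, ], fr$lo, fr$hi)
  }, numeric(1)))
  sub <- arr[floor(0.2 * dim(arr)[1]):ceiling(0.8 * dim(arr)[1]),
             floor(0.2 * dim(arr)[2]):ceiling(0.8 * dim(arr)[2]),
             floor(0.2 * dim(arr)[3]):ceiling(0.8 * dim(arr)[3])]
  expect_equal(sum(sub == 2L) * 25^3 / max(clip, 1), 1, tolerance = 0.05)
})

test_that("thickness summaries reproduce the percent reduction", {
  mk <- function(mean_mm) matrix(mean_mm, nrow = 3, ncol = 3)
  records <- list(c1 = mk(2.66), c2 = mk(2.66), a1 = mk(1.74),
                  a2 = mk(1.74))
  groups <- c(c1 = "control", c2 = "control", a1 = "disease",
              a2 = "disease")
  ts <- thickness_summary(records, groups)
  expect_equal(ts$reduction_pct, 35L)
  expect_equal(ts$per_group$mean_mm, c(2.66, 1.74))
  # identical groups: zero reduction
  ts0 <- thickness_summary(list(a = mk(2), b = mk(2)),
                           c(a = "control", b = "disease"))
  expect_equal(ts0$reduction_pct, 0L)
  # single measurement per case
  ts1 <- thickness_summary(list(a = 2.5, b = 1.5),
                           c(a = "control", b = "disease"))
  expect_equal(ts1$per_case$thickness_mm, c(2.5, 1.5))
  expect_error(thickness_summary(list(), c()), "no cases")
  expect_error(thickness_summary(list(a = mk(2)), c(a = "control")),
               "two groups")
})
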