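test_that("CSR generator has Poisson intensity and is reproducible", {
  w <- window3d(1e4, 1e4, 1e4)  # 1000 um^3
  counts <- vapply(1:60, function(s) {
    npoints(simulate_csr_pattern(0.5, w, seed = s))
  }, numeric(1))
  # mean count ~ Poisson(500): SE = sqrt(500/60) ~ 2.9
  expect_lt(abs(mean(counts) - 500), 4 * sqrt(500 / 60))
  p1 <- simulate_csr_pattern(0.5, w, seed = 99)
  p2 <- simulate_csr_pattern(0.5, w, seed = 99)
  expect_identical(p1$points, p2$points)
  expect_error(simulate_csr_pattern(0, w, 1), "positive")
  expect_error(window3d(1e4, 1e4, 0), "positive")
})

test_that("hard-core patterns respect the minimum separation", {
  w <- window3d(8e3, 8e3, 8e3)
  for (s in 1:5) {
    hp <- simulate_hardcore_pattern(0.5, 250, w, seed = s)
    d <- dist(hp$points)
    expect_gte(min(d), 500)
    expect_equal(npoints(hp), round(0.5 * window_volume_um3(w)))
  }
  # radius zero reduces to a fixed-n binomial process
  p0 <- simulate_hardcore_pattern(0.5, 0, w, seed = 3)
  expect_equal(npoints(p0), round(0.5 * window_volume_um3(w)))
  # same seed, same pattern
  expect_identical(simulate_hardcore_pattern(0.4, 200, w, seed = 7)$points,
                   simulate_hardcore_pattern(0.4, 200, w, seed = 7)$points)
})

test_that("RSA saturation raises an explicit failure naming the count", {
  w <- window3d(1500, 1500, 1500)
  expect_error(
    simulate_hardcore_pattern(300, 700, w, seed = 1, max_attempts = 5000),
    "achieved [0-9]+ of [0-9]+"
  )
})

test_that("synthetic SAS caps hit requested area and curvature", {
  m <- synthesize_sas_mesh(117800, 0.049, seed = 1)
  expect_equal(mesh_area(m), 117800, tolerance = 1e-9)  # calibrated
  expect_equal(sas_curvature(m), 0.049, tolerance = 0.02)
  # flat limit: planar disc of the requested area
  mf <- synthesize_sas_mesh(5e4, 0, seed = 2)
  expect_equal(sas_curvature(mf), 0, tolerance = 1e-9)
  expect_equal(mesh_perimeter(mf), 2 * sqrt(pi * 5e4), tolerance = 0.01)
  # hemisphere: projected area is half the surface area
  mh <- synthesize_sas_mesh(2 * pi * 150^2, 0.5, seed = 3)
  expect_equal(projected_area(mh), mesh_area(mh) / 2, tolerance = 0.01)
  expect_error(synthesize_sas_mesh(1e4, 1), "curvature")
  expect_error(synthesize_sas_mesh(-5, 0.1), "area")
})

test_that("mesh discretisation error decreases with resolution", {
  area <- 9e4
  curv <- 0.2
  errs <- vapply(c(60, 480, 1920), function(res) {
    m <- synthesize_sas_mesh(area, curv, resolution = res, seed = 4,
                             calibrate = FALSE)
    abs(mesh_area(m) - area) / area
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[2], 0.01)  # documented 1% at ~default resolution
})

test_that("artifact masks occupy the requested volume without overlap", {
  w <- default_stack_window(80)
  for (frac in c(0.03, 0.15, 0.33)) {
    a <- artifact_masks(w, frac, seed = round(100 * frac))
    expect_equal(attr(a, "volume_nm3") / window_volume_nm3(w), frac,
                 tolerance = 1e-12)
    # pairwise disjoint: sampled points can be inside at most one ellipsoid
    set.seed(1)
    pts <- cbind(runif(2000, 0, w$extents[1]), runif(2000, 0, w$extents[2]),
                 runif(2000, 0, w$extents[3]))
    nin <- rowSums(vapply(seq_len(nrow(a)), function(j) {
      ((pts[, 1] - a$cx[j]) / a$ax[j])^2 +
        ((pts[, 2] - a$cy[j]) / a$ay[j])^2 +
        ((pts[, 3] - a$cz[j]) / a$az[j])^2 <= 1
    }, logical(2000)))
    expect_lte(max(nin), 1)
    # every ellipsoid fits inside the window
    expect_true(all(a$cx - a$ax >= 0 & a$cx + a$ax <= w$extents[1]))
    expect_true(all(a$cz - a$az >= 0 & a$cz + a$az <= w$extents[3]))
  }
  expect_error(artifact_masks(w, 0.6, 1), "fraction")
})

test_that("generated cases honour composition and are reproducible", {
  w <- window3d(5e3, 5e3, 4e3)
  cp <- case_params(intensity = 1.5, n_stacks = 2, window = w,
                    as_fraction = 1, artifact_fraction = 0.1, seed = 21)
  cs <- generate_case(cp)
  expect_true(all(unlist(lapply(cs$stacks, `[[`, "type")) == "AS"))
  # artifact volume fraction is exact (analytic placement)
  for (st in cs$stacks) {
    expect_equal(st$artifact_volume_nm3 / window_volume_nm3(w), 0.1,
                 tolerance = 1e-12)
  }
  cs2 <- generate_case(cp)
  expect_identical(cs$stacks[[1]]$pattern$points,
                   cs2$stacks[[1]]$pattern$points)
  expect_identical(cs$stacks[[2]]$sas_area_nm2, cs2$stacks[[2]]$sas_area_nm2)
})

test_that("empirical AS fraction matches the Bernoulli parameter", {
  w <- window3d(8e3, 8e3, 8e3)
  cp <- case_params(intensity = 1.2, n_stacks = 3, window = w,
                    as_fraction = 0.9564, artifact_fraction = 0, seed = 5)
  cs <- generate_case(cp)
  types <- unlist(lapply(cs$stacks, `[[`, "type"))
  n <- length(types)
  phat <- mean(types == "AS")
  se <- sqrt(0.9564 * (1 - 0.9564) / n)
  expect_lt(abs(phat - 0.9564), 4 * se)
})

test_that("semithin renders have exact label composition", {
  img <- render_semithin(c(7.17, 0.50, 3.28), image_size = 200, seed = 2)
  truth <- attr(img, "truth")
  expect_equal(unname(truth["neuropil"]), 89.05, tolerance = 1e-3)
  # pixel tally agrees with the stored truth exactly
  m <- unclass(img)
  for (k in 1:3) {
    expect_equal(sum(m == k) / length(m) * 100, unname(truth[k]),
                 tolerance = 1e-12)
  }
  expect_lt(max(abs(truth[1:3] - c(7.17, 0.50, 3.28))), 0.1)
  # degenerate request: uniform neuropil
  img0 <- render_semithin(c(0, 0, 0), image_size = 64, seed = 1)
  expect_true(all(unclass(img0) == 0L))
  expect_error(render_semithin(c(60, 30, 15), 64, 1), "sum")
})

test_that("study generation separates groups and derives seeds cleanly", {
  sp <- study_params(n_cases_per_group = 2, seed = 3,
                     control = case_params(window = window3d(4e3, 4e3, 3e3),
                                           artifact_fraction = 0.05),
                     disease = case_params(intensity = 0.3,
                                           window = window3d(4e3, 4e3, 3e3),
                                           artifact_fraction = 0.05))
  st <- generate_study(sp)
  groups <- vapply(st$cases, `[[`, character(1), "group")
  expect_equal(sum(groups == "control"), 2)
  expect_equal(sum(groups == "disease"), 2)
  # distinct cases get distinct patterns
  expect_false(identical(st$cases[[1]]$stacks[[1]]$pattern$points,
                         st$cases[[2]]$stacks[[1]]$pattern$points))
  st2 <- generate_study(sp)
  expect_identical(st$cases[[3]]$stacks[[1]]$pattern$points,
                   st2$cases[[3]]$stacks[[1]]$pattern$points)
})
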