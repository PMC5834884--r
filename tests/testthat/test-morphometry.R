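test_that("mesh area and perimeter agree with closed forms", {
  sq <- unit_square_mesh()
  expect_equal(mesh_area(sq), 1)
  expect_equal(mesh_perimeter(sq), 4)
  # polygonised disc: area and perimeter approach pi r^2 and 2 pi r
  disc <- synthesize_sas_mesh(pi * 200^2, 0, resolution = 2000, seed = 1,
                              calibrate = FALSE)
  expect_equal(mesh_area(disc), pi * 200^2, tolerance = 0.005)
  expect_equal(mesh_perimeter(disc), 2 * pi * 200, tolerance = 0.005)
  # degenerate triangle rejected with its index
  bad <- sas_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0)),
                  rbind(c(1, 2, 4), c(1, 2, 3)))
  expect_error(mesh_area(bad), "degenerate")
  # closed mesh has no perimeter
  expect_error(mesh_perimeter(tetrahedron_mesh()), "closed")
})

test_that("projected area handles planar, curved and folded meshes", {
  sq <- unit_square_mesh()
  expect_equal(projected_area(sq), 1)
  expect_equal(sas_curvature(sq), 0)
  # hemisphere: projection is the equatorial disc
  R <- 120
  mh <- synthesize_sas_mesh(2 * pi * R^2, 0.5, resolution = 2000, seed = 2,
                            calibrate = FALSE)
  expect_equal(projected_area(mh), pi * R^2, tolerance = 0.01)
  expect_equal(sas_curvature(mh), 0.5, tolerance = 0.01)
  # folded strip: overlapping projections counted once
  fm <- folded_strip_mesh()
  pl <- synapse3d:::bestfit_plane(fm$vertices)
  cen <- sweep(fm$vertices, 2, pl$centre)
  p2d <- cbind(cen %*% pl$u, cen %*% pl$v)
  signed_sum <- abs(sum(synapse3d:::triangle_crosses(fm)[, 3]) / 2)
  ua <- projected_area(fm)
  expect_lt(ua, sum(abs(p2d[fm$faces[, 1], 1])) + 100)  # finite
  expect_equal(ua, raster_union_area(p2d, fm$faces), tolerance = 0.005)
  # union is smaller than the naive sum of projected triangle areas
  tri_sum <- sum(vapply(seq_len(nrow(fm$faces)), function(t) {
    v <- p2d[fm$faces[t, ], ]
    abs((v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
          (v[3, 1] - v[1, 1]) * (v[2, 2] - v[1, 2])) / 2
  }, numeric(1)))
  expect_lt(ua, tri_sum)
  # projection never exceeds surface area, curvature stays in [0, 1)
  for (s in 1:5) {
    m <- synthesize_sas_mesh(runif(1, 2e4, 2e5), runif(1, 0, 0.6),
                             seed = s)
    expect_lte(projected_area(m), mesh_area(m) * (1 + 1e-9))
    cv <- sas_curvature(m)
    expect_gte(cv, 0)
    expect_lt(cv, 1)
  }
})

test_that("sweep union area matches rasterisation on random triangle soups", {
  set.seed(7)
  for (rep in 1:3) {
    n_tri <- 12
    p2d <- matrix(runif(6 * n_tri, 0, 10), ncol = 2)
    faces <- matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE)
    ua <- union_area_triangles(p2d, faces)
    ra <- raster_union_area(p2d, faces)
    expect_equal(ua, ra, tolerance = 0.005)
  }
})

test_that("SAS features are invariant under rigid motions", {
  m <- synthesize_sas_mesh(117800, 0.049, seed = 11)
  f0 <- sas_features(m)
  expect_equal(f0$curvature, 0.049, tolerance = 0.02)
  set.seed(3)
  rot <- synapse3d:::random_rotation()
  shift <- c(1e5, -2e4, 3e3)
  m2 <- sas_mesh(sweep(m$vertices %*% t(rot), 2, shift, "+"), m$faces)
  f1 <- sas_features(m2)
  expect_equal(f1$area, f0$area, tolerance = 1e-6)
  expect_equal(f1$perimeter, f0$perimeter, tolerance = 1e-6)
  expect_equal(f1$curvature, f0$curvature, tolerance = 1e-6)
})

test_that("log-normal fitting recovers parameters and flags degeneracy", {
  set.seed(5)
  x <- rlnorm(1e4, meanlog = 11.4, sdlog = 0.73)
  fit <- fit_lognormal(x)
  expect_lt(abs(fit$mu - 11.4), 3 * 0.73 / sqrt(1e4))
  expect_lt(abs(fit$sigma - 0.73), 3 * 0.73 / sqrt(2e4))
  expect_true(fit$ks_p > 0.01)
  # closed-form MLE agrees with a general-purpose ML fitter
  if (requireNamespace("fitdistrplus", quietly = TRUE)) {
    fd <- fitdistrplus::fitdist(x[1:500], "lnorm")
    f2 <- fit_lognormal(x[1:500])
    expect_equal(unname(fd$estimate["meanlog"]), f2$mu, tolerance = 1e-4)
    expect_equal(unname(fd$estimate["sdlog"]), f2$sigma, tolerance = 0.01)
  }
  expect_true(fit_lognormal(rep(3, 10))$degenerate)
  expect_error(fit_lognormal(c(1, -2, 3)), "positive")
  expect_error(fit_lognormal(c(1, 2)), "at least 3")
})

test_that("generated SAS areas pass the log-normal fit in most seeds", {
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rlnorm(500, meanlog = log(117800) - 0.73^2 / 2, sdlog = 0.73)
    fit_lognormal(x)$ks_p > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("feature summaries respect grouping and the AS > SS ordering", {
  w <- window3d(6e3, 6e3, 6e3)
  cs <- generate_case(case_params(intensity = 1.5, n_stacks = 2,
                                  window = w, artifact_fraction = 0,
                                  seed = 8), case_id = "C1")
  feats <- do.call(rbind, lapply(cs$stacks, function(st) {
    data.frame(type = st$type, group = "control",
               area = st$sas_area_nm2, curvature = st$curvature)
  }))
  fd <- feature_distributions(feats, feature_cols = c("area", "curvature"))
  s <- fd$summary
  expect_gt(s$area_mean[s$type == "AS"], s$area_mean[s$type == "SS"])
  expect_true(all(c("mid", "count") %in%
                    names(fd$frequency[[1]]$area)))
  # single observation: SEM flagged as NA
  one <- feature_distributions(
    data.frame(type = "AS", group = "g", area = 5), "area")
  expect_true(is.na(one$summary$area_sem))
})
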