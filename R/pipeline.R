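#' Quantify a (synthetic or loaded) study
#'
#' Runs the full measurement chain on a study: per-stack counting-frame
#' selection, artifact discounting and shrinkage correction, density and
#' type proportions, SAS morphometry, nearest-neighbour distances,
#' Cavalieri volume fractions on rendered semithin sections, cortical
#' thickness summaries, optional spatial CSR-envelope verdicts, and the
#' group comparison table. All reported lengths/areas/volumes/densities are
#' shrinkage-corrected with `p2`.
#'
#' @param study A `study_sample` from [generate_study()].
#' @param p2 Areal shrinkage factor (default 0.933).
#' @param frame_margin Counting-frame guard margin fraction (default 0.05).
#' @param grid A [grid_spec()] for Cavalieri point counting.
#' @param image_size Semithin render size in px (default 512 at 2 um/px,
#'   i.e. a ~1 mm^2 field, which gives ~2600 points under the default
#'   400 um^2 grid).
#' @param spatial If `TRUE`, compute G/F/K CSR envelopes per stack (slow).
#' @param n_sim CSR simulations per envelope (default 100).
#' @param seed Seed for the semithin renders and envelopes.
#' @return Object of class `study_report`: list of data frames and
#'   summaries (see Details in the package vignette).
#' @export
quantify_study <- function(study, p2 = 0.933, frame_margin = 0.05,
                           grid = grid_spec(), image_size = 512,
                           spatial = FALSE, n_sim = 100, seed = 1) {
  stopifnot(inherits(study, "study_sample"))
  stack_rows <- list()
  feat_rows <- list()
  case_map <- character(0)
  group_map <- character(0)
  spatial_rows <- list()
  for (cs in study$cases) {
    group_map[cs$case_id] <- cs$group
    for (st in cs$stacks) {
      case_map[st$stack_id] <- cs$case_id
      frame <- counting_frame(st$window, frame_margin)
      fv <- frame_volume_um3(frame)
      art <- st$artifacts
      art_in_frame <- 0
      if (nrow(art) > 0) {
        art_in_frame <- sum(vapply(seq_len(nrow(art)), function(j) {
          ellipsoid_box_volume(art[j, ], frame$lo, frame$hi)
        }, numeric(1))) / .NM3_PER_UM3
      }
      cv_raw <- discount_artifacts(fv, art_in_frame)
      cv <- correct_measurement(as.numeric(cv_raw), p2, 3)
      dec <- apply_counting_frame(st$extents, frame)
      ok <- dec$counted
      n_as <- sum(ok & st$type == "AS")
      n_ss <- sum(ok & st$type == "SS")
      de <- density_estimate(n_as, n_ss, cv)
      nn_nm <- NA_real_
      if (npoints(st$pattern) >= 2) {
        nn_raw <- mean(nn_distances(st$pattern))
        nn_nm <- correct_measurement(nn_raw, p2, 1)
      }
      stack_rows[[st$stack_id]] <- data.frame(
        stack = st$stack_id, case = cs$case_id, group = cs$group,
        n_total = de$n_total, n_as = n_as, n_ss = n_ss,
        n_incomplete = sum(dec$status == "incomplete"),
        n_excluded = sum(dec$status == "exclusion"),
        cf_volume_um3 = cv, density = de$density_total,
        density_as = de$density_as, density_ss = de$density_ss,
        pct_as = de$pct_as, nn_nm = nn_nm)
      if (any(ok)) {
        if (!is.null(st$meshes)) {
          fs <- lapply(st$meshes[ok], sas_features)
          area <- correct_measurement(
            vapply(fs, `[[`, numeric(1), "area"), p2, 2)
          perim <- correct_measurement(
            vapply(fs, `[[`, numeric(1), "perimeter"), p2, 1)
          curv <- vapply(fs, `[[`, numeric(1), "curvature")
        } else {
          # ground-truth features travel on the corrected scale already
          area <- st$sas_area_nm2[ok]
          curv <- st$curvature[ok]
          perim <- cap_perimeter(area, curv)
        }
        feat_rows[[st$stack_id]] <- data.frame(
          stack = st$stack_id, case = cs$case_id, group = cs$group,
          type = st$type[ok], area = area, perimeter = perim,
          curvature = curv)
      }
      if (spatial && npoints(st$pattern) >= 2) {
        env <- csr_envelope(st$pattern, fun = c("G", "F", "K"),
                            n_sim = n_sim,
                            seed = derive_seed(seed, length(spatial_rows)))
        spatial_rows[[st$stack_id]] <- data.frame(
          stack = st$stack_id, case = cs$case_id, group = cs$group,
          fun = c("G", "F", "K"),
          prop_outside = vapply(env, attr, numeric(1), "prop_outside"),
          verdict = vapply(env, attr, character(1), "verdict"),
          dead_space_nm = c(as.numeric(dead_space_radius(env$G)), NA, NA))
      }
    }
  }
  per_stack <- do.call(rbind, c(stack_rows, list(make.row.names = FALSE)))
  features <- do.call(rbind, c(feat_rows, list(make.row.names = FALSE)))
  agg <- aggregate_cases(per_stack, case_map, group_map,
                         value_cols = c("density", "density_as",
                                        "density_ss", "pct_as", "nn_nm",
                                        "cf_volume_um3"))
  # group totals (pooled counts and volume), Table-style
  totals <- do.call(rbind, lapply(split(per_stack, per_stack$group),
                                  function(d) data.frame(
    group = d$group[1], n_as = sum(d$n_as), n_ss = sum(d$n_ss),
    n_total = sum(d$n_total), cf_volume_um3 = sum(d$cf_volume_um3),
    pooled_density = sum(d$n_total) / sum(d$cf_volume_um3))))
  # per-case SAS means and volume fractions and thickness
  sas_case <- do.call(rbind, lapply(split(features, features$case),
                                    function(d) data.frame(
    case = d$case[1], sas_area = mean(d$area),
    sas_perimeter = mean(d$perimeter), sas_curvature = mean(d$curvature))))
  vv_rows <- lapply(study$cases, function(cs) {
    img <- render_semithin(cs$vv_true, image_size = image_size,
                           pixel_size_um = 2,
                           seed = derive_seed(seed, 600 + cs$params$seed %% 1000))
    vf <- cavalieri_point_count(img, grid)
    data.frame(case = cs$case_id, vv_neurons = vf[["neurons"]],
               vv_glia = vf[["glia"]], vv_vessels = vf[["vessels"]],
               vv_neuropil = vf[["neuropil"]])
  })
  vv_case <- do.call(rbind, c(vv_rows, list(make.row.names = FALSE)))
  thick <- thickness_summary(
    lapply(study$cases, function(cs) cs$thickness),
    vapply(study$cases, function(cs) cs$group, character(1)),
    control = "control")
  per_case <- Reduce(function(a, b) merge(a, b, by = "case"),
                     list(agg$per_case, sas_case, vv_case,
                          thick$per_case[c("case", "thickness_mm")]))
  per_case <- per_case[order(per_case$group, per_case$case), ]
  pooled_sas <- split(features$area, features$group)
  cmp_cols <- c("case", "group", "density", "pct_as", "nn_nm", "sas_area",
                "sas_curvature", "thickness_mm", "vv_neurons", "vv_glia",
                "vv_vessels", "vv_neuropil")
  comparisons <- compare_study(per_case[cmp_cols], pooled_sas = pooled_sas,
                               control = "control")
  sas_fit <- lapply(pooled_sas, fit_lognormal)
  report <- list(
    per_stack = per_stack,
    per_case = per_case,
    per_group = agg$per_group,
    group_totals = totals,
    sas_features = features,
    sas_summary = feature_distributions(features)$summary,
    sas_lognormal = data.frame(
      group = names(sas_fit),
      mu = vapply(sas_fit, `[[`, numeric(1), "mu"),
      sigma = vapply(sas_fit, `[[`, numeric(1), "sigma"),
      ks_p = vapply(sas_fit, `[[`, numeric(1), "ks_p"), row.names = NULL),
    thickness = thick$per_group,
    thickness_reduction_pct = thick$reduction_pct,
    comparisons = comparisons,
    spatial_verdicts = if (length(spatial_rows) > 0) {
      do.call(rbind, c(spatial_rows, list(make.row.names = FALSE)))
    } else NULL,
    provenance = list(p2 = p2, frame_margin = frame_margin,
                      grid_point_area_um2 = grid$point_area,
                      n_sim = if (spatial) n_sim else 0, seed = seed,
                      study_seed = study$params$seed,
                      package_version = as.character(
                        utils::packageVersion("synapse3d")))
  )
  class(report) <- c("study_report", "list")
  report
}

# analytic perimeter of a spherical cap with given (corrected) area and
# curvature index
cap_perimeter <- function(area, curvature) {
  flat <- curvature < 1e-9
  out <- numeric(length(area))
  out[flat] <- 2 * sqrt(pi * area[flat])
  if (any(!flat)) {
    c2 <- curvature[!flat]
    R <- sqrt(area[!flat] / (4 * pi * c2))
    theta <- acos(1 - 2 * c2)
    out[!flat] <- 2 * pi * R * sin(theta)
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("study report\n")
  cat("  per-group estimates:\n")
  print(x$per_group)
  cat(sprintf("  thickness reduction: %d%%\n", x$thickness_reduction_pct))
  cat(sprintf("  comparisons: %d variables (%d significant at 0.05)\n",
              nrow(x$comparisons),
              sum(x$comparisons$significant, na.rm = TRUE)))
  invisible(x)
}

#' Run the full pipeline from a configuration
#'
#' Generates a synthetic study from the `study` section of the config (or
#' its defaults), quantifies it, and attaches provenance (config hash,
#' seeds, package version). Deterministic: the same config produces an
#' identical report.
#'
#' @param config A config list or path to a YAML file
#'   (see [read_study_config()]). Recognised keys: `seed`, `p2`,
#'   `frame_margin`, `grid_point_area_um2`, `spatial` (`enabled`, `n_sim`),
#'   `study` (`n_cases_per_group`, `build_meshes`, `n_sections`, and
#'   `control` / `disease` blocks of [case_params()] arguments).
#' @return A `study_report` (see [quantify_study()]).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_study_config(config)
  cfg <- validate_config(config)
  sp <- build_study_params(cfg)
  study <- generate_study(sp, build_meshes = isTRUE(cfg$study$build_meshes))
  report <- quantify_study(
    study, p2 = cfg$p2, frame_margin = cfg$frame_margin,
    grid = grid_spec(cfg$grid_point_area_um2, seed = cfg$seed),
    spatial = isTRUE(cfg$spatial$enabled), n_sim = cfg$spatial$n_sim,
    seed = cfg$seed)
  report$provenance$config_hash <- config_hash(cfg)
  report
}

# assemble study_params from a config list
build_study_params <- function(cfg) {
  st <- cfg$study
  window <- if (!is.null(st$n_sections)) {
    default_stack_window(st$n_sections)
  } else {
    default_stack_window()
  }
  mk <- function(defaults, overrides) {
    args <- defaults
    for (nm in names(overrides)) {
      if (nm %in% names(formals(case_params))) {
        v <- overrides[[nm]]
        if (nm %in% c("sas_area_mean", "vv_means", "vv_sds")) v <- unlist(v)
        args[[nm]] <- v
      }
    }
    args$window <- window
    args$p2 <- cfg$p2
    do.call(case_params, args)
  }
  control <- mk(list(seed = derive_seed(cfg$seed, 1)), st$control)
  disease_defaults <- list(
    intensity = 0.37, intensity_sd = 0.15, as_fraction = 0.9447,
    sas_area_mean = c(AS = 123200, SS = 67750),
    thickness_mean = 1.74, thickness_sd = 0.39,
    vv_means = c(neurons = 5.86, glia = 0.35, vessels = 3.71),
    vv_sds = c(neurons = 0.84, glia = 0.12, vessels = 0.48),
    seed = derive_seed(cfg$seed, 2))
  disease <- mk(disease_defaults, st$disease)
  n_cases <- if (!is.null(st$n_cases_per_group)) st$n_cases_per_group else 5
  study_params(control = control, disease = disease,
               n_cases_per_group = n_cases, seed = cfg$seed)
}
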