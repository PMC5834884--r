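#' Parameters for one simulated case (subject)
#'
#' Bundles everything the generator needs to emulate the FIB/SEM material of
#' one subject: synapse intensity, hard-core separation, AS/SS mix,
#' log-normal SAS areas, curvature distribution, fixation-artifact load and
#' stack geometry.
#'
#' Intensities and SAS areas are interpreted on the *shrinkage-corrected*
#' scale (the scale on which results are reported); the generator converts
#' them to raw stack coordinates using `p2`, so that quantifying the
#' synthetic stacks at the same `p2` recovers the requested values.
#'
#' @param intensity Synapses per um^3 (shrinkage-corrected scale).
#' @param hardcore_radius Hard-core radius in nm (default 250; minimum
#'   centroid separation is twice this).
#' @param as_fraction Proportion of synapses that are asymmetric (AS), in
#'   `[0, 1]`.
#' @param sas_area_mean Named numeric `c(AS = , SS = )`: target arithmetic
#'   mean SAS area (nm^2, corrected scale) per synapse type.
#' @param sas_area_sigma SD of log SAS area (shared by both types). The
#'   log-mean is derived as `log(mean) - sigma^2 / 2`.
#' @param curvature_mean,curvature_sd Mean and SD of the per-synapse
#'   curvature index; a Beta distribution with these moments is used.
#' @param artifact_fraction Either a single fraction or a range
#'   `c(lo, hi)` from which each stack's artifact volume fraction is drawn
#'   uniformly. `c(0.03, 0.33)` reproduces the observed artifact range.
#' @param n_stacks Image stacks per case (default 3).
#' @param window Stack window, a [window3d()].
#' @param p2 Areal shrinkage factor applied by tissue processing
#'   (default 0.933).
#' @param intensity_sd Between-case SD of intensity, used when this object
#'   serves as a group template in [study_params()].
#' @param thickness_mean,thickness_sd Cortical thickness (mm): group mean
#'   and between-case SD.
#' @param vv_means,vv_sds Named numeric `c(neurons=, glia=, vessels=)`:
#'   volume-fraction percentages (group mean and between-case SD).
#' @param seed Integer seed.
#' @return An object of class `case_params`.
#' @export
case_params <- function(intensity = 0.51,
                        hardcore_radius = 250,
                        as_fraction = 0.9564,
                        sas_area_mean = c(AS = 117800, SS = 76190),
                        sas_area_sigma = 0.73,
                        curvature_mean = 0.049,
                        curvature_sd = 0.05,
                        artifact_fraction = c(0.03, 0.33),
                        n_stacks = 3,
                        window = default_stack_window(),
                        p2 = 0.933,
                        intensity_sd = 0.14,
                        thickness_mean = 2.66,
                        thickness_sd = 0.37,
                        vv_means = c(neurons = 7.17, glia = 0.50,
                                     vessels = 3.28),
                        vv_sds = c(neurons = 0.98, glia = 0.14,
                                   vessels = 0.41),
                        seed = 1) {
  stopifnot(inherits(window, "window3d"))
  if (intensity <= 0) stop("case_params: intensity must be > 0")
  if (as_fraction < 0 || as_fraction > 1) {
    stop("case_params: as_fraction must be in [0, 1]")
  }
  af <- range(artifact_fraction)
  if (af[1] < 0 || af[2] >= 1) {
    stop("case_params: artifact_fraction must be in [0, 1)")
  }
  if (curvature_mean < 0 || curvature_mean >= 1) {
    stop("case_params: curvature_mean must be in [0, 1)")
  }
  if (n_stacks < 1) stop("case_params: n_stacks must be >= 1")
  if (p2 <= 0) stop("case_params: p2 must be > 0")
  structure(list(
    intensity = intensity, hardcore_radius = hardcore_radius,
    as_fraction = as_fraction,
    sas_area_mean = sas_area_mean, sas_area_sigma = sas_area_sigma,
    sas_area_mu = log(sas_area_mean) - sas_area_sigma^2 / 2,
    curvature_mean = curvature_mean, curvature_sd = curvature_sd,
    artifact_fraction = artifact_fraction, n_stacks = n_stacks,
    window = window, p2 = p2, intensity_sd = intensity_sd,
    thickness_mean = thickness_mean, thickness_sd = thickness_sd,
    vv_means = vv_means, vv_sds = vv_sds, seed = as.integer(seed)
  ), class = "case_params")
}

#' Parameters for a two-group simulated study
#'
#' Defaults reproduce the study design this package emulates: 5 control and
#' 5 disease cases, 3 stacks per case, group-level means and SDs for
#' density, AS proportion, SAS size, curvature, cortical thickness and
#' cortical-element volume fractions.
#'
#' @param control,disease [case_params()] templates for the two groups.
#' @param n_cases_per_group Cases per group (default 5).
#' @param seed Integer seed.
#' @return Object of class `study_params`.
#' @export
study_params <- function(control = case_params(),
                         disease = case_params(
                           intensity = 0.37, intensity_sd = 0.15,
                           as_fraction = 0.9447,
                           sas_area_mean = c(AS = 123200, SS = 67750),
                           thickness_mean = 1.74, thickness_sd = 0.39,
                           vv_means = c(neurons = 5.86, glia = 0.35,
                                        vessels = 3.71),
                           vv_sds = c(neurons = 0.84, glia = 0.12,
                                      vessels = 0.48)),
                         n_cases_per_group = 5,
                         seed = 1) {
  stopifnot(inherits(control, "case_params"), inherits(disease, "case_params"))
  if (n_cases_per_group < 1) {
    stop("study_params: n_cases_per_group must be >= 1")
  }
  structure(list(control = control, disease = disease,
                 n_cases_per_group = n_cases_per_group,
                 seed = as.integer(seed)),
            class = "study_params")
}

#' Generate one synthetic case
#'
#' Produces `n_stacks` stack samples. Each stack holds a hard-core synapse
#' pattern avoiding its artifact masks, Bernoulli AS/SS labels, per-synapse
#' SAS areas (log-normal, corrected scale) and curvature indices, the
#' synapse bounding extents used by the counting frame, plus per-case
#' cortical-thickness measurements and ground-truth cortical-element
#' fractions.
#'
#' @param params A [case_params()].
#' @param build_meshes If `TRUE`, a triangulated SAS mesh is synthesized for
#'   every synapse (slower); otherwise extents are derived from the sampled
#'   areas and features are carried as numbers.
#' @param case_id,group Identifiers stored in the output.
#' @return Object of class `case_sample`: list with `stacks`, `thickness`
#'   (sections x 3 matrix, mm), `vv_true`, `params`.
#' @export
generate_case <- function(params, build_meshes = FALSE,
                          case_id = "case1", group = "control") {
  stopifnot(inherits(params, "case_params"))
  p2 <- params$p2
  raw_intensity <- params$intensity / p2^(3 / 2)  # corrected -> raw scale
  af <- params$artifact_fraction
  stacks <- vector("list", params$n_stacks)
  for (s in seq_len(params$n_stacks)) {
    sseed <- derive_seed(params$seed, 1000 + s)
    set.seed(sseed)
    frac <- if (length(af) == 2) stats::runif(1, af[1], af[2]) else af
    art <- artifact_masks(params$window, frac,
                          seed = derive_seed(sseed, 1))
    pat <- simulate_hardcore_pattern(raw_intensity, params$hardcore_radius,
                                     params$window,
                                     seed = derive_seed(sseed, 2),
                                     avoid = art)
    n <- npoints(pat)
    set.seed(derive_seed(sseed, 3))
    is_as <- stats::rbinom(n, 1, params$as_fraction) == 1
    type <- ifelse(is_as, "AS", "SS")
    mu <- params$sas_area_mu[type]
    area_corr <- stats::rlnorm(n, meanlog = mu, sdlog = params$sas_area_sigma)
    curv <- rbeta_moments(n, params$curvature_mean, params$curvature_sd)
    area_raw <- area_corr * p2
    meshes <- NULL
    if (build_meshes && n > 0) {
      meshes <- lapply(seq_len(n), function(i) {
        m <- synthesize_sas_mesh(area_raw[i], curv[i],
                                 seed = derive_seed(sseed, 10 + i))
        m$vertices <- sweep(m$vertices, 2, pat$points[i, ], "+")
        m
      })
      ext <- t(vapply(meshes, function(m) {
        c(apply(m$vertices, 2, min), apply(m$vertices, 2, max))
      }, numeric(6)))
    } else {
      # approximate junction extent from the disc-equivalent radius
      r_eff <- sqrt(area_raw / pi)
      half <- cbind(r_eff * stats::runif(n, 0.7, 1),
                    r_eff * stats::runif(n, 0.7, 1),
                    r_eff * stats::runif(n, 0.25, 0.5))
      ext <- cbind(pat$points - half, pat$points + half)
    }
    colnames(ext) <- c("xlo", "ylo", "zlo", "xhi", "yhi", "zhi")
    stacks[[s]] <- list(
      stack_id = sprintf("%s_stack%d", case_id, s),
      window = params$window, pattern = pat, type = type,
      sas_area_nm2 = area_corr,   # corrected scale (ground truth)
      curvature = curv, extents = ext, meshes = meshes,
      artifacts = art,
      artifact_volume_nm3 = attr(art, "volume_nm3"),
      seed = sseed
    )
  }
  set.seed(derive_seed(params$seed, 77))
  n_sections <- sample(3:5, 1)
  thickness <- matrix(
    stats::rnorm(n_sections * 3, params$thickness_mean, 0.02) +
      rep(stats::rnorm(n_sections, 0, 0.05), each = 3),
    nrow = n_sections, byrow = TRUE
  )
  thickness[thickness <= 0.1] <- 0.1
  vv <- pmax(0.01, stats::rnorm(3, params$vv_means, params$vv_sds))
  names(vv) <- c("neurons", "glia", "vessels")
  if (sum(vv) >= 99) vv <- vv * 99 / sum(vv)
  structure(list(case_id = case_id, group = group, stacks = stacks,
                 thickness = thickness, vv_true = vv, params = params),
            class = "case_sample")
}

# Beta deviates with given mean and SD (clipped to a proper Beta)
rbeta_moments <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  v <- min(sd^2, mean * (1 - mean) * 0.95)
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

#' Generate a full two-group synthetic study
#'
#' Draws case-level parameters (intensity, thickness, volume fractions)
#' from the group templates, then generates every case. Case intensities
#' are Normal(group mean, `intensity_sd`), truncated at 0.05 synapses/um^3.
#'
#' @param params A [study_params()].
#' @param build_meshes Passed to [generate_case()].
#' @return Object of class `study_sample`: list of `case_sample`s plus the
#'   originating parameters.
#' @export
generate_study <- function(params, build_meshes = FALSE) {
  stopifnot(inherits(params, "study_params"))
  cases <- list()
  for (g in c("control", "disease")) {
    tmpl <- params[[g]]
    for (i in seq_len(params$n_cases_per_group)) {
      cseed <- derive_seed(params$seed,
                           ifelse(g == "control", 0, 500) + i)
      set.seed(cseed)
      ci <- max(0.05, stats::rnorm(1, tmpl$intensity, tmpl$intensity_sd))
      cth <- max(0.2, stats::rnorm(1, tmpl$thickness_mean, tmpl$thickness_sd))
      cp <- tmpl
      cp$intensity <- ci
      cp$thickness_mean <- cth
      cp$seed <- derive_seed(cseed, 9)
      case_id <- sprintf("%s%d", ifelse(g == "control", "C", "AD"), i)
      cases[[case_id]] <- generate_case(cp, build_meshes = build_meshes,
                                        case_id = case_id, group = g)
    }
  }
  structure(list(cases = cases, params = params), class = "study_sample")
}

#' @export
print.study_sample <- function(x, ...) {
  groups <- vapply(x$cases, function(cs) cs$group, character(1))
  cat(sprintf("synthetic study: %d cases (%d control, %d disease), %d stacks\n",
              length(x$cases), sum(groups == "control"),
              sum(groups == "disease"),
              sum(vapply(x$cases, function(cs) length(cs$stacks), numeric(1)))))
  invisible(x)
}
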