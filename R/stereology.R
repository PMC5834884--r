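#' Stereological point grid specification
#'
#' A systematic-random point grid for Cavalieri point counting: each grid
#' point "covers" `point_area` um^2; the grid origin receives one uniform
#' random offset (seeded), then points repeat at regular spacing.
#'
#' @param point_area Area per grid point in um^2 (default 400, i.e. a
#'   20 x 20 um mesh).
#' @param seed Seed for the random grid offset (default 1).
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(point_area = 400, seed = 1) {
  if (point_area <= 0) stop("grid_spec: point_area must be > 0")
  structure(list(point_area = point_area, seed = as.integer(seed)),
            class = "grid_spec")
}

#' Cavalieri point-count volume fractions
#'
#' Overlays the grid on a semithin label image and estimates the volume
#' fraction of each cortical element as the percentage of grid points
#' hitting it; the neuropil fraction is obtained by complement.
#'
#' @param image A [semithin_image()].
#' @param grid A [grid_spec()].
#' @return Object of class `volume_fractions`: named numeric with
#'   `neurons`, `glia`, `vessels`, `neuropil` (percent, summing to 100),
#'   with attribute `n_points` (grid points used).
#' @export
cavalieri_point_count <- function(image, grid = grid_spec()) {
  stopifnot(inherits(image, "semithin_image"), inherits(grid, "grid_spec"))
  px <- attr(image, "pixel_size_um")
  spacing_px <- sqrt(grid$point_area) / px
  nr <- nrow(image)
  nc <- ncol(image)
  if (spacing_px > nr && spacing_px > nc) {
    stop("cavalieri_point_count: grid spacing exceeds the image; no points")
  }
  set.seed(grid$seed)
  off <- stats::runif(2, 0, spacing_px)
  xi <- seq(1 + off[1], nr, by = spacing_px)
  yi <- seq(1 + off[2], nc, by = spacing_px)
  if (length(xi) == 0 || length(yi) == 0) {
    stop("cavalieri_point_count: grid has zero points inside the image")
  }
  hits <- unclass(image)[cbind(rep(round(xi), times = length(yi)),
                               rep(round(yi), each = length(xi)))]
  total <- length(hits)
  pct <- vapply(1:3, function(l) 100 * sum(hits == l) / total, numeric(1))
  vf <- c(pct, neuropil_complement(pct[1], pct[2], pct[3]))
  names(vf) <- c("neurons", "glia", "vessels", "neuropil")
  structure(vf, class = "volume_fractions", n_points = total)
}

#' Neuropil volume fraction by complement
#'
#' The neuropil fraction is what remains after neuronal somata, glial
#' somata and blood vessels: `100 - (v_neurons + v_glia + v_vessels)`.
#'
#' @param v_neurons,v_glia,v_vessels Percentages (>= 0, summing to <= 100).
#' @return Neuropil percentage.
#' @examples
#' neuropil_complement(7.17, 0.50, 3.28)  # 89.05
#' @export
neuropil_complement <- function(v_neurons, v_glia, v_vessels) {
  vals <- c(v_neurons, v_glia, v_vessels)
  if (any(vals < 0)) stop("neuropil_complement: fractions must be >= 0")
  s <- sum(vals)
  if (s > 100) stop("neuropil_complement: fractions sum above 100%")
  100 - s
}

#' Tissue shrinkage factor from paired area measurements
#'
#' Electron-microscopy processing shrinks tissue; the areal shrinkage
#' factor p^2 is the area after processing divided by the area before.
#'
#' @param area_before,area_after Areas in consistent units (> 0).
#' @return Object of class `shrinkage_factor` (numeric p^2); values above 1
#'   (expansion) are allowed but flagged with a warning.
#' @examples
#' shrinkage_factor(100, 93.3)  # 0.933
#' @export
shrinkage_factor <- function(area_before, area_after) {
  if (area_before <= 0 || area_after <= 0) {
    stop("shrinkage_factor: areas must be positive")
  }
  p2 <- area_after / area_before
  if (p2 > 1) {
    warning("shrinkage_factor: p^2 > 1 (apparent expansion)")
  }
  structure(p2, class = "shrinkage_factor")
}

#' Correct a measurement for tissue shrinkage
#'
#' Measured (post-processing) values are scaled back to pre-shrinkage size:
#' `corrected = value / p2^(dimension/2)` for lengths (dimension 1), areas
#' (2) and volumes (3). Per-volume densities shrink the other way; pass
#' `dimension = -3` to multiply by `p2^(3/2)`.
#'
#' @param value Measured value(s).
#' @param p2 Areal shrinkage factor (a [shrinkage_factor()] or plain
#'   number).
#' @param dimension 1 (length), 2 (area), 3 (volume) or the negative for
#'   per-unit quantities (e.g. -3 for per-volume densities).
#' @return Corrected value(s).
#' @examples
#' correct_measurement(234.36, 0.933, 3)   # raw -> corrected stack volume
#' @export
correct_measurement <- function(value, p2, dimension) {
  p2 <- as.numeric(p2)
  if (p2 <= 0) stop("correct_measurement: p2 must be > 0")
  if (!dimension %in% c(-3, -2, -1, 1, 2, 3)) {
    stop("correct_measurement: dimension must be one of +/-1, 2, 3")
  }
  value / p2^(dimension / 2)
}

#' Discount fixation artifacts from a counting volume
#'
#' @param frame_volume Counting-frame volume (um^3).
#' @param artifact_volume Artifact volume inside the frame (um^3), must be
#'   smaller than `frame_volume`.
#' @return Corrected counting volume (um^3) with attribute
#'   `artifact_fraction`.
#' @export
discount_artifacts <- function(frame_volume, artifact_volume) {
  if (frame_volume <= 0) stop("discount_artifacts: frame_volume must be > 0")
  if (artifact_volume < 0 || artifact_volume >= frame_volume) {
    stop("discount_artifacts: artifact_volume must be in [0, frame_volume)")
  }
  structure(frame_volume - artifact_volume,
            artifact_fraction = artifact_volume / frame_volume)
}

#' Cortical thickness summaries and group contrast
#'
#' Each case contributes 3-5 sections with three measurements per section;
#' the case value is the mean over all its measurements, group statistics
#' are computed over case values (never over sections), and the contrast is
#' the percentage reduction of the disease group relative to control,
#' rounded to the nearest integer.
#'
#' @param records Named list of per-case measurement matrices (sections x
#'   measurements, mm) or numeric vectors.
#' @param groups Named character vector (or factor) mapping case name to
#'   group; must contain exactly two levels, control first.
#' @param control Name of the reference group (default `"control"`).
#' @return List with `per_case` (data frame), `per_group` (mean, SD, n) and
#'   `reduction_pct` (integer).
#' @export
thickness_summary <- function(records, groups, control = "control") {
  if (length(records) == 0) stop("thickness_summary: no cases")
  if (is.null(names(records)) || !all(names(records) %in% names(groups))) {
    stop("thickness_summary: records and groups must share case names")
  }
  case_means <- vapply(records, function(r) {
    v <- as.numeric(r)
    if (any(v <= 0)) stop("thickness_summary: measurements must be > 0")
    mean(v)
  }, numeric(1))
  per_case <- data.frame(case = names(records),
                         group = as.character(groups[names(records)]),
                         thickness_mm = unname(case_means))
  lv <- unique(per_case$group)
  if (length(lv) != 2 || !(control %in% lv)) {
    stop("thickness_summary: need exactly two groups including the control")
  }
  other <- setdiff(lv, control)
  agg <- lapply(c(control, other), function(g) {
    v <- per_case$thickness_mm[per_case$group == g]
    if (length(v) == 0) stop("thickness_summary: empty group ", g)
    data.frame(group = g, n = length(v), mean_mm = mean(v),
               sd_mm = if (length(v) > 1) stats::sd(v) else NA_real_)
  })
  per_group <- do.call(rbind, agg)
  reduction <- round(100 * (per_group$mean_mm[1] - per_group$mean_mm[2]) /
                       per_group$mean_mm[1])
  list(per_case = per_case, per_group = per_group,
       reduction_pct = as.integer(reduction))
}
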