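#' Unbiased 3D counting frame (brick)
#'
#' An inner box of the stack window with three inclusion faces (the low
#' x/y/z faces) and three exclusion faces (the high faces, extended to
#' planes). An object is counted when it intersects the frame and touches
#' no exclusion plane; objects may touch or cross inclusion faces.
#'
#' @param window A [window3d()].
#' @param margin Guard margin on each side of each axis, as a fraction of
#'   the window extent (default 0.05) or a length-3 vector of fractions.
#' @param lo,hi Optional explicit frame corners (nm), overriding `margin`.
#' @return Object of class `counting_frame` with fields `lo`, `hi`,
#'   `window`.
#' @export
counting_frame <- function(window, margin = 0.05, lo = NULL, hi = NULL) {
  stopifnot(inherits(window, "window3d"))
  if (is.null(lo) || is.null(hi)) {
    m <- rep(margin, length.out = 3) * window$extents
    lo <- window$origin + m
    hi <- window$origin + window$extents - m
  }
  if (any(hi <= lo)) stop("counting_frame: frame has non-positive extent")
  if (any(lo < window$origin) ||
      any(hi > window$origin + window$extents)) {
    stop("counting_frame: frame must lie within the window")
  }
  structure(list(lo = lo, hi = hi, window = window),
            class = "counting_frame")
}

#' Frame volume
#' @param frame A [counting_frame()].
#' @return Volume in um^3.
#' @export
frame_volume_um3 <- function(frame) {
  stopifnot(inherits(frame, "counting_frame"))
  prod(frame$hi - frame$lo) / .NM3_PER_UM3
}

#' Apply the unbiased brick rule to object extents
#'
#' Objects are axis-aligned extents (whole reconstructed junctions), given
#' as a matrix/data frame with columns `xlo, ylo, zlo, xhi, yhi, zhi` (nm).
#' Objects truncated by the physical stack boundary are flagged
#' `"incomplete"` and never counted (the two-step discard); among complete
#' objects, one is counted iff it intersects the frame and does not touch
#' any exclusion face or its extension plane.
#'
#' @param extents Object extents (n x 6).
#' @param frame A [counting_frame()].
#' @return Data frame with `id`, `status`
#'   (`counted` / `exclusion` / `outside` / `incomplete`) and `counted`
#'   logical.
#' @export
apply_counting_frame <- function(extents, frame) {
  stopifnot(inherits(frame, "counting_frame"))
  ext <- as.matrix(extents)
  if (ncol(ext) != 6) stop("apply_counting_frame: extents must have 6 columns")
  n <- nrow(ext)
  w <- frame$window
  wlo <- w$origin
  whi <- w$origin + w$extents
  status <- rep("counted", n)
  if (n > 0) {
    a <- ext[, 1:3, drop = FALSE]   # object min corner
    b <- ext[, 4:6, drop = FALSE]   # object max corner
    incomplete <- (a[, 1] <= wlo[1] | a[, 2] <= wlo[2] | a[, 3] <= wlo[3] |
                     b[, 1] >= whi[1] | b[, 2] >= whi[2] | b[, 3] >= whi[3])
    # touches an exclusion face or its extension plane
    excl <- (b[, 1] >= frame$hi[1] | b[, 2] >= frame$hi[2] |
               b[, 3] >= frame$hi[3])
    # intersects the frame (touching an inclusion face counts)
    inter <- (b[, 1] >= frame$lo[1] & b[, 2] >= frame$lo[2] &
                b[, 3] >= frame$lo[3] &
                a[, 1] < frame$hi[1] & a[, 2] < frame$hi[2] &
                a[, 3] < frame$hi[3])
    status[!inter] <- "outside"
    status[inter & excl] <- "exclusion"
    status[incomplete] <- "incomplete"
  }
  ids <- rownames(ext)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  data.frame(id = ids, status = status, counted = status == "counted",
             row.names = NULL)
}

#' Synapse density and type proportions in a counting volume
#'
#' @param n_as,n_ss Counted asymmetric and symmetric synapses.
#' @param counting_volume_um3 Counting volume in um^3 (artifact-discounted
#'   and shrinkage-corrected upstream), > 0.
#' @return Object of class `density_estimate`: list with counts, densities
#'   (per um^3) and percentages.
#' @examples
#' density_estimate(2545, 111, 5295)
#' @export
density_estimate <- function(n_as, n_ss, counting_volume_um3) {
  if (counting_volume_um3 <= 0) {
    stop("density_estimate: counting volume must be > 0")
  }
  if (n_as < 0 || n_ss < 0) stop("density_estimate: counts must be >= 0")
  total <- n_as + n_ss
  structure(list(
    n_as = n_as, n_ss = n_ss, n_total = total,
    counting_volume_um3 = counting_volume_um3,
    density_as = n_as / counting_volume_um3,
    density_ss = n_ss / counting_volume_um3,
    density_total = total / counting_volume_um3,
    pct_as = if (total > 0) 100 * n_as / total else NA_real_,
    pct_ss = if (total > 0) 100 * n_ss / total else NA_real_
  ), class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf(
    "density: %d synapses (%d AS + %d SS) in %.4g um^3 -> %.4g /um^3 (%.4g%% AS)\n",
    x$n_total, x$n_as, x$n_ss, x$counting_volume_um3, x$density_total,
    x$pct_as))
  invisible(x)
}

#' Aggregate per-stack estimates to case and group tables
#'
#' The sampling hierarchy is stacks within cases within groups; case values
#' are means over their stacks, and group statistics (mean, SD) are taken
#' over case values, never over stacks.
#'
#' @param per_stack Data frame of per-stack values; must contain a `stack`
#'   column plus the value columns to aggregate.
#' @param case_map Named character vector: stack id -> case id. Every stack
#'   must be assigned.
#' @param group_map Named character vector: case id -> group.
#' @param value_cols Columns of `per_stack` to aggregate (default: all
#'   numeric columns).
#' @return List with `per_case` and `per_group` data frames (`<col>_mean`,
#'   `<col>_sd`, `n` per group).
#' @export
aggregate_cases <- function(per_stack, case_map, group_map,
                            value_cols = NULL) {
  stopifnot("stack" %in% names(per_stack))
  if (!all(per_stack$stack %in% names(case_map))) {
    orphan <- setdiff(per_stack$stack, names(case_map))
    stop("aggregate_cases: stack(s) not assigned to a case: ",
         paste(orphan, collapse = ", "))
  }
  cases <- unname(case_map[per_stack$stack])
  if (!all(cases %in% names(group_map))) {
    stop("aggregate_cases: case(s) not assigned to a group: ",
         paste(setdiff(cases, names(group_map)), collapse = ", "))
  }
  if (is.null(value_cols)) {
    value_cols <- names(per_stack)[vapply(per_stack, is.numeric, logical(1))]
  }
  per_case <- do.call(rbind, lapply(split(per_stack[value_cols], cases),
                                    function(d) as.data.frame(lapply(d, mean))))
  per_case <- data.frame(case = rownames(per_case),
                         group = unname(group_map[rownames(per_case)]),
                         per_case, row.names = NULL)
  groups <- split(per_case, per_case$group)
  per_group <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    row <- data.frame(group = g, n_cases = nrow(d))
    for (vc in value_cols) {
      row[[paste0(vc, "_mean")]] <- mean(d[[vc]])
      row[[paste0(vc, "_sd")]] <- if (nrow(d) > 1) stats::sd(d[[vc]]) else NA_real_
    }
    row
  }))
  list(per_case = per_case, per_group = per_group)
}
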