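#' Mann-Whitney U test
#'
#' Unpaired two-sided rank test used for all group comparisons (the study
#' variables do not meet normality/homoscedasticity assumptions). The
#' p-value is exact (full enumeration of the U null distribution) when the
#' combined sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections is used.
#'
#' @param a,b Numeric samples (non-empty).
#' @return List with `U` (statistic for sample `a`), `p` (two-sided),
#'   `exact` (logical), `n_a`, `n_b`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("mann_whitney: both samples must be non-empty")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  # all-tied data: the normal approximation has zero variance; there is no
  # evidence against the null
  if (!is.finite(p)) p <- 1
  list(U = unname(wt$statistic), p = min(1, p), exact = exact,
       n_a = length(a), n_b = length(b))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' is the asymptotic two-sided one. Used for comparing pooled SAS
#' frequency distributions between groups.
#'
#' @param a,b Numeric samples (non-empty).
#' @return List with `D`, `p`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("ks_two_sample: both samples must be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Study-level group comparison table
#'
#' Runs the comparisons reported for a two-group study: Mann-Whitney on
#' per-case values (the case, not the stack, is the unit of analysis) for
#' density, type proportions, thickness, volume fractions, mean SAS size
#' and nearest-neighbour distance; Kolmogorov-Smirnov on the pooled SAS
#' area distributions.
#'
#' @param per_case Data frame with one row per case: columns `case`,
#'   `group`, plus any numeric variable columns.
#' @param pooled_sas Optional list with per-group numeric vectors of pooled
#'   SAS areas, named by group, for the KS comparison.
#' @param alpha Significance level (default 0.05).
#' @param control Name of the reference group.
#' @return Data frame of class `comparison_table`: one row per variable
#'   with group summaries, test name, statistic, p-value and decision.
#'   Variables missing for any case, or groups with a single case, are
#'   reported as not testable (`NA` p).
#' @export
compare_study <- function(per_case, pooled_sas = NULL, alpha = 0.05,
                          control = "control") {
  stopifnot(all(c("case", "group") %in% names(per_case)))
  groups <- unique(per_case$group)
  if (length(groups) != 2 || !(control %in% groups)) {
    stop("compare_study: need exactly two groups including the control")
  }
  other <- setdiff(groups, control)
  vars <- setdiff(names(per_case)[vapply(per_case, is.numeric, logical(1))],
                  c("case", "group"))
  rows <- lapply(vars, function(v) {
    x <- per_case[[v]][per_case$group == control]
    y <- per_case[[v]][per_case$group == other]
    summ <- function(z) sprintf("%.4g ± %.3g", mean(z, na.rm = TRUE),
                                stats::sd(z, na.rm = TRUE))
    if (anyNA(c(x, y))) {
      return(data.frame(variable = v, control = summ(x), disease = summ(y),
                        test = "Mann-Whitney", statistic = NA_real_,
                        p = NA_real_, significant = NA,
                        note = "missing per-case values"))
    }
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(variable = v, control = summ(x), disease = summ(y),
                        test = "Mann-Whitney", statistic = NA_real_,
                        p = NA_real_, significant = NA,
                        note = "fewer than 2 cases per group"))
    }
    mw <- mann_whitney(x, y)
    data.frame(variable = v, control = summ(x), disease = summ(y),
               test = ifelse(mw$exact, "Mann-Whitney (exact)",
                             "Mann-Whitney (normal approx.)"),
               statistic = mw$U, p = mw$p, significant = mw$p < alpha,
               note = "")
  })
  tab <- do.call(rbind, rows)
  if (!is.null(pooled_sas)) {
    ks <- ks_two_sample(pooled_sas[[control]], pooled_sas[[other]])
    tab <- rbind(tab, data.frame(
      variable = "sas_area_distribution",
      control = sprintf("n = %d", ks$n_a),
      disease = sprintf("n = %d", ks$n_b),
      test = "Kolmogorov-Smirnov", statistic = ks$D, p = ks$p,
      significant = ks$p < alpha, note = "pooled synapses"))
  }
  class(tab) <- c("comparison_table", "data.frame")
  tab
}
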