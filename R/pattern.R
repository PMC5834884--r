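#' 3D point pattern
#'
#' Container for a set of synapse centroids (or any points) observed in a
#' [window3d()]. Coordinates are in nm.
#'
#' @param points Numeric matrix with 3 columns (x, y, z) or a data frame with
#'   columns `x`, `y`, `z` (nm).
#' @param window A [window3d()] containing all points.
#' @return An object of class `point_pattern` with fields `points` (n x 3
#'   matrix) and `window`.
#' @export
point_pattern <- function(points, window) {
  stopifnot(inherits(window, "window3d"))
  if (is.data.frame(points)) {
    points <- as.matrix(points[, c("x", "y", "z")])
  }
  if (is.null(points) || length(points) == 0) {
    points <- matrix(numeric(0), 0, 3)
  }
  points <- matrix(as.numeric(points), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  lo <- window$origin
  hi <- window$origin + window$extents
  if (nrow(points) > 0) {
    inside <- points[, 1] >= lo[1] & points[, 1] <= hi[1] &
      points[, 2] >= lo[2] & points[, 2] <= hi[2] &
      points[, 3] >= lo[3] & points[, 3] <= hi[3]
    if (!all(inside)) {
      stop(sprintf("point_pattern: %d point(s) fall outside the window",
                   sum(!inside)))
    }
  }
  structure(list(points = points, window = window), class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("3D point pattern: %d points in a %.2f um^3 window\n",
              npoints(x), window_volume_um3(x$window)))
  invisible(x)
}

#' Number of points in a pattern
#' @param x A [point_pattern()].
#' @return Integer count.
#' @export
npoints <- function(x) {
  stopifnot(inherits(x, "point_pattern"))
  nrow(x$points)
}

#' Empirical intensity of a pattern
#' @param x A [point_pattern()].
#' @return Points per um^3.
#' @export
intensity_um3 <- function(x) {
  npoints(x) / window_volume_um3(x$window)
}

# full pairwise distance matrix, diagonal set to Inf
pairdist_matrix <- function(pts) {
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  d
}
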