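#' Three-dimensional sampling window
#'
#' A `window3d` is the axis-aligned box within which an image stack lives and
#' point patterns are observed. All coordinates are physical nanometres with
#' the origin at the stack corner: x/y in the imaging plane, z along the
#' milling axis.
#'
#' @param Lx,Ly,Lz Edge lengths in nm; all must be strictly positive.
#' @param origin Numeric length-3, position of the lower corner in nm.
#'
#' @return An object of class `window3d` with fields `origin` and `extents`.
#' @examples
#' # default FIB/SEM field of view: 2048 x 1536 px at 5 nm/px, 270 sections
#' # at 20 nm
#' w <- window3d(2048 * 5, 1536 * 5, 270 * 20)
#' window_volume_um3(w)
#' @export
window3d <- function(Lx, Ly, Lz, origin = c(0, 0, 0)) {
  ext <- as.numeric(c(Lx, Ly, Lz))
  if (length(ext) != 3 || anyNA(ext) || any(ext <= 0)) {
    stop("window3d: all extents (Lx, Ly, Lz) must be positive numbers")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3 || anyNA(origin)) {
    stop("window3d: origin must be a numeric length-3 vector")
  }
  structure(list(origin = origin, extents = ext), class = "window3d")
}

#' @export
print.window3d <- function(x, ...) {
  cat(sprintf(
    "3D window: %.0f x %.0f x %.0f nm (%.2f um^3), origin (%g, %g, %g) nm\n",
    x$extents[1], x$extents[2], x$extents[3], window_volume_um3(x),
    x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

#' Window volume
#'
#' @param window A [window3d()].
#' @return Volume in nm^3 (`window_volume_nm3`) or um^3 (`window_volume_um3`).
#' @export
window_volume_nm3 <- function(window) {
  stopifnot(inherits(window, "window3d"))
  prod(window$extents)
}

#' @rdname window_volume_nm3
#' @export
window_volume_um3 <- function(window) {
  window_volume_nm3(window) / 1e9
}

#' Default stack window used throughout the package
#'
#' The FIB/SEM field of view: 2048 x 1536 pixels at 5 nm/pixel in-plane and
#' 270 serial sections at 20 nm, i.e. 10.24 x 7.68 x 5.4 um. The raw volume
#' (424.7 um^3) corresponds to a shrinkage-corrected volume of 471.2 um^3 at
#' p^2 = 0.933, the mean stack volume of the study design this generator
#' emulates.
#'
#' @param n_sections Number of 20-nm serial sections (default 270).
#' @return A [window3d()].
#' @export
default_stack_window <- function(n_sections = 270) {
  window3d(2048 * 5, 1536 * 5, n_sections * 20)
}

# nm^3 per um^3
.NM3_PER_UM3 <- 1e9

# shortest distance from each point (rows of x) to the window boundary
boundary_distance <- function(x, window) {
  lo <- matrix(window$origin, nrow(x), 3, byrow = TRUE)
  hi <- matrix(window$origin + window$extents, nrow(x), 3, byrow = TRUE)
  d <- pmin(x - lo, hi - x)
  pmin(d[, 1], pmin(d[, 2], d[, 3]))
}

# derive a child RNG seed from a base seed and a stream index.
# Lehmer rounds interleaved with xor-shift mixing: nearby or affinely
# related (seed, index) pairs would otherwise give correlated draw streams
# from R's generator. Result stays below 2^31.
derive_seed <- function(seed, index) {
  x <- (as.double(seed) %% 2147483647) + 1
  x <- (x * 48271) %% 2147483647
  x <- (x + as.double(index) * 8191) %% 2147483647
  x <- (x * 48271) %% 2147483647
  x <- as.double(bitwXor(as.integer(x), as.integer(x %/% 65536)))
  x <- (x * 69621) %% 2147483647
  x <- as.double(bitwXor(as.integer(x), as.integer(x %/% 1024)))
  x <- (x * 16807) %% 2147483647
  as.integer(x)
}
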