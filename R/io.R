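#' Write synapse centroids to CSV
#'
#' Standard centroid table: `stack_id, synapse_id, x_nm, y_nm, z_nm, type`
#' with `type` in {AS, SS}. UTF-8, comma-separated, header row mandatory.
#'
#' @param df Data frame with the columns above.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_centroids <- function(df, path) {
  req <- c("stack_id", "synapse_id", "x_nm", "y_nm", "z_nm", "type")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("write_centroids: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(df[req], path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a synapse centroid CSV
#'
#' Validates the header, flags malformed rows by line number, and applies a
#' unit heuristic: when a window is supplied and every coordinate is below
#' 1% of the window extent, the file is rejected as probably being in um
#' rather than nm.
#'
#' @param path CSV file written by [write_centroids()] (or compatible).
#' @param window Optional [window3d()] for the unit check.
#' @return Data frame with the standard columns.
#' @export
read_centroids <- function(path, window = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("stack_id", "synapse_id", "x_nm", "y_nm", "z_nm", "type")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("read_centroids: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (cc in c("x_nm", "y_nm", "z_nm")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad) > 0) {
      stop(sprintf("read_centroids: malformed numeric in column %s, line(s) %s",
                   cc, paste(utils::head(bad + 1, 10), collapse = ", ")))
    }
    df[[cc]] <- v
  }
  badtype <- which(!df$type %in% c("AS", "SS"))
  if (length(badtype) > 0) {
    stop(sprintf("read_centroids: type must be AS or SS, line(s) %s",
                 paste(utils::head(badtype + 1, 10), collapse = ", ")))
  }
  if (!is.null(window) && nrow(df) > 0) {
    mx <- max(abs(c(df$x_nm, df$y_nm, df$z_nm)))
    if (mx > 0 && mx < 0.01 * max(window$extents)) {
      stop("read_centroids: coordinates are tiny relative to the window; ",
           "they look like um, but nm are required")
    }
  }
  df
}

#' Write a mesh as PLY
#'
#' @param mesh A [sas_mesh()].
#' @param path Output file.
#' @param format `"binary_little_endian"` (default) or `"ascii"`.
#' @return `path`, invisibly. Vertices are stored as float32.
#' @export
write_ply <- function(mesh, path, format = c("binary_little_endian",
                                             "ascii")) {
  stopifnot(inherits(mesh, "sas_mesh"))
  format <- match.arg(format)
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  header <- c("ply",
              paste("format", format, "1.0"),
              paste("element vertex", nv),
              "property float x", "property float y", "property float z",
              paste("element face", nf),
              "property list uchar int vertex_indices",
              "end_header")
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(format(mesh$vertices, digits = 9, trim = TRUE,
                              scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    verts <- as.numeric(t(mesh$vertices))
    writeBin(verts, con, size = 4, endian = "little")
    fb <- t(cbind(3L, mesh$faces - 1L))
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(fb[2:4, i]), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read a PLY mesh
#'
#' Supports the subset written by [write_ply()]: float32 vertex x/y/z and
#' uchar-counted int32 triangle faces, ascii or binary little-endian.
#'
#' @param path PLY file.
#' @return A [sas_mesh()].
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("read_ply: truncated header")
    header <- c(header, line)
    if (line == "end_header") break
  }
  fmt <- sub("^format ([a-z_]+) .*$", "\\1", grep("^format", header,
                                                  value = TRUE))
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face", header, value = TRUE)))
  if (fmt == "ascii") {
    vl <- readLines(con, n = nv)
    verts <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
                    ncol = 3, byrow = TRUE)
    fl <- readLines(con, n = nf)
    fc <- matrix(as.integer(unlist(strsplit(trimws(fl), "\\s+"))),
                 ncol = 4, byrow = TRUE)
    faces <- fc[, 2:4, drop = FALSE] + 1L
  } else if (fmt == "binary_little_endian") {
    verts <- matrix(readBin(con, "numeric", n = 3 * nv, size = 4,
                            endian = "little"),
                    ncol = 3, byrow = TRUE)
    faces <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1))
      if (cnt != 3L) stop("read_ply: only triangle faces are supported")
      faces[i, ] <- readBin(con, "integer", n = 3, size = 4,
                            endian = "little") + 1L
    }
  } else {
    stop("read_ply: unsupported format ", fmt)
  }
  sas_mesh(verts, faces)
}

#' Write a voxel label stack as multi-page TIFF
#'
#' uint8 labels: 0 background, 1 synapse, 2 artifact.
#'
#' @param labels 3D integer array (x, y, z) of labels in 0..255.
#' @param path Output TIFF.
#' @return `path`, invisibly.
#' @export
write_label_stack <- function(labels, path) {
  stopifnot(length(dim(labels)) == 3)
  pages <- lapply(seq_len(dim(labels)[3]), function(z) {
    m <- labels[, , z]
    storage.mode(m) <- "integer"
    m
  })
  tiff::writeTIFF(lapply(pages, function(m) m / 255), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' Read a voxel label stack from multi-page TIFF
#'
#' @param path TIFF written by [write_label_stack()].
#' @return 3D integer array of labels.
#' @export
read_label_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                           length(pages)))
  for (z in seq_along(pages)) {
    arr[, , z] <- as.integer(round(pages[[z]] * 255))
  }
  arr
}

#' Rasterize a synthetic stack to voxel labels
#'
#' Voxelizes synapse extents (label 1) and artifact ellipsoids (label 2,
#' which wins where they overlap) at the given spacing. Intended for small
#' windows; memory grows as the voxel count.
#'
#' @param stack One stack of a [generate_case()] result.
#' @param voxel_nm Voxel spacing (x, y, z) in nm, default `c(5, 5, 20)`.
#' @return 3D integer array (x, y, z).
#' @export
rasterize_stack <- function(stack, voxel_nm = c(5, 5, 20)) {
  w <- stack$window
  nvox <- pmax(1L, floor(w$extents / voxel_nm))
  ctr <- lapply(1:3, function(k) {
    w$origin[k] + (seq_len(nvox[k]) - 0.5) * voxel_nm[k]
  })
  arr <- array(0L, dim = nvox)
  ext <- stack$extents
  for (i in seq_len(nrow(ext))) {
    ix <- which(ctr[[1]] >= ext[i, 1] & ctr[[1]] <= ext[i, 4])
    iy <- which(ctr[[2]] >= ext[i, 2] & ctr[[2]] <= ext[i, 5])
    iz <- which(ctr[[3]] >= ext[i, 3] & ctr[[3]] <= ext[i, 6])
    arr[ix, iy, iz] <- 1L
  }
  art <- stack$artifacts
  for (j in seq_len(nrow(art))) {
    ux <- (ctr[[1]] - art$cx[j]) / art$ax[j]
    uy <- (ctr[[2]] - art$cy[j]) / art$ay[j]
    uz <- (ctr[[3]] - art$cz[j]) / art$az[j]
    m <- outer(outer(ux^2, uy^2, "+"), uz^2, "+") <= 1
    arr[m] <- 2L
  }
  arr
}

#' Read a study configuration from YAML
#'
#' @param path YAML file; see the packaged example in
#'   `system.file("cli", "example-config.yaml", package = "synapse3d")`.
#' @return Validated config list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$p2)) cfg$p2 <- 0.933
  if (cfg$p2 <= 0) stop("config: p2 must be > 0")
  if (is.null(cfg$voxel_nm)) cfg$voxel_nm <- c(5, 5, 20)
  if (any(cfg$voxel_nm <= 0)) stop("config: voxel spacing must be positive")
  if (is.null(cfg$frame_margin)) cfg$frame_margin <- 0.05
  if (is.null(cfg$grid_point_area_um2)) cfg$grid_point_area_um2 <- 400
  if (is.null(cfg$spatial)) cfg$spatial <- list(enabled = FALSE)
  if (is.null(cfg$spatial$n_sim)) cfg$spatial$n_sim <- 100
  if (is.null(cfg$study)) cfg$study <- list()
  cfg
}

# md5 of the canonical (sorted-key, pretty) JSON form of an object
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(sort_keys(cfg), tf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x) > 0) {
    x <- x[order(names(x))]
    lapply(x, sort_keys)
  } else x
}

#' Write a study report to disk
#'
#' Data-frame tables become CSV files; the remainder (summaries,
#' provenance) is written as pretty-printed JSON with sorted keys so the
#' report hash is stable.
#'
#' @param report A report from [quantify_study()] / [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of files written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(report)) {
    obj <- report[[nm]]
    if (is.data.frame(obj)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(obj, f, row.names = FALSE, fileEncoding = "UTF-8")
      written <- c(written, f)
      report[[nm]] <- paste0(nm, ".csv")
    }
  }
  f <- file.path(dir, "report.json")
  jsonlite::write_json(sort_keys(report), f, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(c(written, f))
}
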