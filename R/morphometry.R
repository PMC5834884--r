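#' Triangulated synaptic apposition surface
#'
#' An open triangulated surface (disc topology: exactly one boundary loop)
#' representing the apposition between pre- and post-synaptic densities.
#' Vertices are in nm.
#'
#' @param vertices Numeric n x 3 matrix.
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @return Object of class `sas_mesh`.
#' @export
sas_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (anyNA(vertices) || anyNA(faces)) stop("sas_mesh: NA in mesh data")
  if (min(faces) < 1 || max(faces) > nrow(vertices)) {
    stop("sas_mesh: face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "sas_mesh")
}

#' @export
print.sas_mesh <- function(x, ...) {
  cat(sprintf("SAS mesh: %d vertices, %d triangles, area %.4g nm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

# per-triangle cross products; rows are (v2-v1) x (v3-v1)
triangle_crosses <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Surface area of a mesh
#'
#' Sum of triangle areas.
#'
#' @param mesh A [sas_mesh()].
#' @param tol Relative degeneracy tolerance: triangles with area below
#'   `tol * mean_area` count as degenerate.
#' @return Area in nm^2.
#' @export
mesh_area <- function(mesh, tol = 1e-12) {
  stopifnot(inherits(mesh, "sas_mesh"))
  cr <- triangle_crosses(mesh)
  areas <- 0.5 * sqrt(rowSums(cr^2))
  bad <- which(areas <= tol * max(areas))
  if (length(bad) > 0) {
    stop(sprintf("mesh_area: %d degenerate triangle(s): %s",
                 length(bad), paste(utils::head(bad, 10), collapse = ", ")))
  }
  sum(areas)
}

# boundary edges = edges used by exactly one triangle.
# Returns 2-column matrix of vertex indices.
boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  e[key %in% names(cnt)[cnt == 1], , drop = FALSE]
}

# number of closed loops formed by boundary edges (each boundary vertex
# must have degree 2; walks the adjacency)
count_boundary_loops <- function(edges) {
  if (nrow(edges) == 0) return(0L)
  verts <- sort(unique(as.vector(edges)))
  deg <- table(factor(as.vector(edges), levels = verts))
  if (any(deg != 2)) return(NA_integer_)  # not a union of simple loops
  adj <- split(c(edges[, 2], edges[, 1]),
               factor(c(edges[, 1], edges[, 2]), levels = verts))
  visited <- stats::setNames(rep(FALSE, length(verts)), verts)
  loops <- 0L
  for (v0 in as.character(verts)) {
    if (visited[[v0]]) next
    loops <- loops + 1L
    prev <- NA
    cur <- v0
    repeat {
      visited[[cur]] <- TRUE
      nxt <- setdiff(as.character(adj[[cur]]), c(prev, NA))
      if (length(nxt) == 0) break
      prev <- cur
      cur <- nxt[1]
      if (visited[[cur]]) break
    }
  }
  loops
}

#' Perimeter of an open mesh
#'
#' Total length of the (single) boundary loop.
#'
#' @param mesh A [sas_mesh()].
#' @return Perimeter in nm.
#' @export
mesh_perimeter <- function(mesh) {
  stopifnot(inherits(mesh, "sas_mesh"))
  be <- boundary_edges(mesh)
  if (nrow(be) == 0) {
    stop("mesh_perimeter: mesh is closed (no boundary loop)")
  }
  loops <- count_boundary_loops(be)
  if (is.na(loops) || loops != 1L) {
    stop(sprintf("mesh_perimeter: expected exactly one boundary loop, found %s",
                 ifelse(is.na(loops), "a non-manifold boundary", loops)))
  }
  d <- mesh$vertices[be[, 1], , drop = FALSE] -
    mesh$vertices[be[, 2], , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# least-squares (principal-axes) plane basis: returns list with in-plane
# basis `u`, `v` and centre
bestfit_plane <- function(vertices) {
  ctr <- colMeans(vertices)
  sv <- svd(sweep(vertices, 2, ctr))
  list(u = sv$v[, 1], v = sv$v[, 2], normal = sv$v[, 3], centre = ctr)
}

#' Projected area of a mesh
#'
#' Area of the planar region covered by the mesh when projected onto its
#' least-squares best-fit plane. Overlapping (folded) triangles are counted
#' once: if the projected triangles share a consistent orientation the
#' projection is fold-free and the area is the sum of signed triangle
#' areas; otherwise an exact sweep-line union of the projected triangles is
#' computed.
#'
#' @param mesh A [sas_mesh()].
#' @return Projected area in nm^2.
#' @export
projected_area <- function(mesh) {
  stopifnot(inherits(mesh, "sas_mesh"))
  pl <- bestfit_plane(mesh$vertices)
  cen <- sweep(mesh$vertices, 2, pl$centre)
  p2d <- cbind(cen %*% pl$u, cen %*% pl$v)
  f <- mesh$faces
  x1 <- p2d[f[, 1], 1]; y1 <- p2d[f[, 1], 2]
  x2 <- p2d[f[, 2], 1]; y2 <- p2d[f[, 2], 2]
  x3 <- p2d[f[, 3], 1]; y3 <- p2d[f[, 3], 2]
  signed <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  tot <- sum(abs(signed))
  if (tot == 0) return(0)
  s <- sign(sum(signed))
  if (all(s * signed >= -1e-9 * max(abs(signed)))) {
    return(abs(sum(signed)))
  }
  union_area_triangles(p2d, f)
}

#' Exact union area of 2D triangles (sweep-line)
#'
#' Vertical-slab decomposition: slab boundaries are all vertex x-coordinates
#' and all pairwise edge-intersection x-coordinates, so within a slab the
#' union length of the per-triangle y-intervals is linear in x and the
#' midpoint rule is exact.
#'
#' @param p2d n x 2 matrix of 2D vertex coordinates.
#' @param faces m x 3 matrix of triangle vertex indices.
#' @return Union area.
#' @keywords internal
#' @export
union_area_triangles <- function(p2d, faces) {
  m <- nrow(faces)
  # edge list per triangle: columns x1,y1,x2,y2, triangle id
  ed <- do.call(rbind, lapply(1:3, function(k) {
    a <- faces[, k]
    b <- faces[, k %% 3 + 1]
    cbind(p2d[a, 1], p2d[a, 2], p2d[b, 1], p2d[b, 2], seq_len(m))
  }))
  xs <- c(ed[, 1], ed[, 3])
  # pairwise segment intersections (only interior crossings matter)
  ne <- nrow(ed)
  if (ne > 1) {
    pr <- utils::combn(ne, 2)
    i <- pr[1, ]; j <- pr[2, ]
    x1 <- ed[i, 1]; y1 <- ed[i, 2]; x2 <- ed[i, 3]; y2 <- ed[i, 4]
    x3 <- ed[j, 1]; y3 <- ed[j, 2]; x4 <- ed[j, 3]; y4 <- ed[j, 4]
    den <- (x2 - x1) * (y4 - y3) - (y2 - y1) * (x4 - x3)
    ok <- abs(den) > 1e-12
    t1 <- ((x3 - x1) * (y4 - y3) - (y3 - y1) * (x4 - x3)) / den
    t2 <- ((x3 - x1) * (y2 - y1) - (y3 - y1) * (x2 - x1)) / den
    hit <- ok & t1 > 0 & t1 < 1 & t2 > 0 & t2 < 1
    xs <- c(xs, (x1 + t1 * (x2 - x1))[hit])
  }
  xs <- sort(unique(xs))
  if (length(xs) < 2) return(0)
  area <- 0
  # precompute triangle x-ranges
  tx <- cbind(pmin(p2d[faces[, 1], 1], p2d[faces[, 2], 1], p2d[faces[, 3], 1]),
              pmax(p2d[faces[, 1], 1], p2d[faces[, 2], 1], p2d[faces[, 3], 1]))
  for (s in seq_len(length(xs) - 1)) {
    xl <- xs[s]; xr <- xs[s + 1]
    w <- xr - xl
    if (w <= 0) next
    xm <- (xl + xr) / 2
    act <- which(tx[, 1] < xm & tx[, 2] > xm)
    if (length(act) == 0) next
    ival <- matrix(NA_real_, length(act), 2)
    for (q in seq_along(act)) {
      t <- act[q]
      vs <- p2d[faces[t, ], , drop = FALSE]
      ys <- numeric(0)
      for (k in 1:3) {
        a <- vs[k, ]; b <- vs[k %% 3 + 1, ]
        if ((a[1] - xm) * (b[1] - xm) <= 0 && a[1] != b[1]) {
          tt <- (xm - a[1]) / (b[1] - a[1])
          ys <- c(ys, a[2] + tt * (b[2] - a[2]))
        }
      }
      if (length(ys) < 2) next
      ival[q, ] <- range(ys)
    }
    ival <- ival[!is.na(ival[, 1]), , drop = FALSE]
    if (nrow(ival) == 0) next
    o <- order(ival[, 1])
    ival <- ival[o, , drop = FALSE]
    len <- 0
    cur_lo <- ival[1, 1]; cur_hi <- ival[1, 2]
    if (nrow(ival) > 1) {
      for (q in 2:nrow(ival)) {
        if (ival[q, 1] > cur_hi) {
          len <- len + (cur_hi - cur_lo)
          cur_lo <- ival[q, 1]; cur_hi <- ival[q, 2]
        } else {
          cur_hi <- max(cur_hi, ival[q, 2])
        }
      }
    }
    len <- len + (cur_hi - cur_lo)
    area <- area + w * len
  }
  area
}

#' SAS curvature index
#'
#' One minus the ratio of the projected area to the surface area:
#' 0 for a flat surface, approaching 1 as the surface curves up around its
#' best-fit plane (a hemisphere scores 0.5).
#'
#' @param mesh A [sas_mesh()].
#' @return Curvature index in `[0, 1)`.
#' @export
sas_curvature <- function(mesh) {
  a <- mesh_area(mesh)
  if (a <= 0) stop("sas_curvature: zero-area mesh")
  1 - projected_area(mesh) / a
}

#' All SAS features of one mesh
#'
#' @param mesh A [sas_mesh()].
#' @return Named list: `area`, `perimeter`, `projected_area`, `curvature`.
#' @export
sas_features <- function(mesh) {
  a <- mesh_area(mesh)
  pa <- projected_area(mesh)
  list(area = a, perimeter = mesh_perimeter(mesh),
       projected_area = pa, curvature = 1 - pa / a)
}

#' Fit a log-normal distribution
#'
#' Maximum-likelihood fit (mean and SD of the log values) with a one-sample
#' Kolmogorov-Smirnov statistic of the log values against the fitted
#' normal as a goodness-of-fit summary.
#'
#' @param values Positive numeric vector, length >= 3.
#' @return List with `mu`, `sigma`, `ks_stat`, `ks_p`, `n`, and `degenerate`
#'   (`TRUE` when all values are equal, so `sigma` = 0).
#' @export
fit_lognormal <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("fit_lognormal: need at least 3 values")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("fit_lognormal: all values must be positive and finite")
  }
  lv <- log(values)
  mu <- mean(lv)
  sigma <- sqrt(mean((lv - mu)^2))   # MLE (denominator n)
  if (sigma == 0) {
    return(list(mu = mu, sigma = 0, ks_stat = NA_real_, ks_p = NA_real_,
                n = length(values), degenerate = TRUE))
  }
  ks <- suppressWarnings(stats::ks.test(lv, "pnorm", mean = mu, sd = sigma))
  list(mu = mu, sigma = sigma, ks_stat = unname(ks$statistic),
       ks_p = ks$p.value, n = length(values), degenerate = FALSE)
}

#' Group summaries and frequency tables of SAS features
#'
#' @param features Data frame with one row per synapse; must contain the
#'   feature columns plus `type` (AS/SS) and `group`.
#' @param feature_cols Feature columns to summarise
#'   (default `c("area", "perimeter", "curvature")`).
#' @param breaks Binning rule for the frequency tables; `"FD"`
#'   (Freedman-Diaconis, default) or anything accepted by [hist()].
#' @return List with `summary` (group x type rows: n, mean, sem per
#'   feature; SEM is `NA` when n = 1) and `frequency` (per group/type/
#'   feature histogram tables).
#' @export
feature_distributions <- function(features,
                                  feature_cols = c("area", "perimeter",
                                                   "curvature"),
                                  breaks = "FD") {
  stopifnot(all(c("type", "group") %in% names(features)))
  feature_cols <- intersect(feature_cols, names(features))
  cells <- split(features, list(features$group, features$type), drop = TRUE)
  rows <- lapply(names(cells), function(nm) {
    cell <- cells[[nm]]
    out <- data.frame(group = cell$group[1], type = cell$type[1],
                      n = nrow(cell))
    for (fc in feature_cols) {
      v <- cell[[fc]]
      out[[paste0(fc, "_mean")]] <- mean(v)
      out[[paste0(fc, "_sem")]] <- if (length(v) > 1) {
        stats::sd(v) / sqrt(length(v))
      } else NA_real_
    }
    out
  })
  freq <- lapply(cells, function(cell) {
    lapply(stats::setNames(feature_cols, feature_cols), function(fc) {
      v <- cell[[fc]]
      # Freedman-Diaconis degenerates for tiny or zero-IQR cells
      bk <- if (identical(breaks, "FD") &&
                (length(v) < 3 || stats::IQR(v) == 0)) "Sturges" else breaks
      h <- graphics::hist(v, breaks = bk, plot = FALSE)
      data.frame(mid = h$mids, count = h$counts, density = h$density)
    })
  })
  list(summary = do.call(rbind, rows), frequency = freq)
}
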