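#' Delaunay triangulation of sampling sites
#'
#' Triangulates the (projected, planar) site coordinates; the triangulation
#' covers the convex hull of the sites and every site is a vertex. Points
#' are ordered lexicographically before triangulating so that cocircular
#' degeneracies are broken reproducibly.
#'
#' @param points A data frame with numeric columns `x`, `y` (meters; one
#'   row per site) and optionally `sample_id`.
#' @return A `site_triangulation`: list with `points` (tibble `sample_id`,
#'   `x`, `y` in the triangulation's vertex order), `triangles` (integer
#'   matrix, one row per triangle, columns `i`, `j`, `k` indexing
#'   `points`), and `hull` (vertex indices of the convex hull, in order).
#' @export
triangulate <- function(points) {
  if (!all(c("x", "y") %in% names(points))) {
    abort("points must have numeric columns x and y")
  }
  pts <- tibble::tibble(
    sample_id = points$sample_id %||% paste0("p", seq_len(nrow(points))),
    x = as.numeric(points$x), y = as.numeric(points$y)
  )
  if (anyNA(pts$x) || anyNA(pts$y)) abort("coordinates must be non-missing")
  dup <- duplicated(pts[, c("x", "y")])
  if (any(dup)) {
    abort(paste0("duplicate coordinates for: ",
                 paste(pts$sample_id[dup], collapse = ", ")))
  }
  if (nrow(pts) < 3) abort("triangulation needs at least 3 points")
  pts <- pts[order(pts$x, pts$y), ]
  # collinearity: rank of centered coordinates
  cx <- pts$x - mean(pts$x); cy <- pts$y - mean(pts$y)
  if (abs(sum(cx * cy)^2 - sum(cx^2) * sum(cy^2)) <
      .Machine$double.eps * 1e4 * max(1, sum(cx^2) * sum(cy^2))) {
    abort(paste0("points are collinear; cannot triangulate (",
                 paste(head(pts$sample_id, 5), collapse = ", "), " ...)"))
  }
  tm <- interp::tri.mesh(pts$x, pts$y, duplicate = "error")
  tri <- interp::triangles(tm)[, c("node1", "node2", "node3"), drop = FALSE]
  colnames(tri) <- c("i", "j", "k")
  hull <- interp::convex.hull(tm)
  structure(list(points = pts, triangles = tri, hull = hull$i),
            class = "site_triangulation")
}

#' @export
print.site_triangulation <- function(x, ...) {
  cat("site_triangulation: ", nrow(x$points), " vertices, ",
      nrow(x$triangles), " triangles\n", sep = "")
  invisible(x)
}

# barycentric weights of query points (qx, qy) w.r.t. triangle (p1, p2, p3);
# each weight shares the determinant's arithmetic so a query at a vertex
# gets weight exactly 1
barycentric_weights <- function(qx, qy, p1, p2, p3) {
  det <- (p2[2] - p3[2]) * (p1[1] - p3[1]) + (p3[1] - p2[1]) * (p1[2] - p3[2])
  w1 <- ((p2[2] - p3[2]) * (qx - p3[1]) + (p3[1] - p2[1]) * (qy - p3[2])) / det
  w2 <- ((p3[2] - p1[2]) * (qx - p3[1]) + (p1[1] - p3[1]) * (qy - p3[2])) / det
  cbind(w1, w2, 1 - w1 - w2)
}

#' Piecewise-linear interpolation of a scattered field
#'
#' Linear interpolation for irregularly spaced data: inside each Delaunay
#' triangle the three vertex values are combined with barycentric weights
#' (a planar fit through the triangle's vertices), so the interpolant is
#' continuous, exact at the sites, and bounded by the vertex values. Grid
#' nodes outside the convex hull of the sites are missing, as are nodes in
#' triangles with a missing vertex value.
#'
#' @param tri A `site_triangulation` from [triangulate()], or a data frame
#'   of points to triangulate on the fly.
#' @param values Numeric vector of site values, named by `sample_id` or in
#'   the order of the point table given to [triangulate()].
#' @param resolution Number of grid cells along the longer bounding-box
#'   side; cells are square.
#' @param margin Fractional bounding-box margin added around the sites.
#' @return A `spatial_field`: list with `grid` (tibble `x`, `y`, `value`),
#'   `nx`, `ny`, `cellsize`, `xll`, `yll`, and the triangulation. Use
#'   [autoplot()] to draw it and [write_ascii_grid()] to export.
#' @export
interpolate_field <- function(tri, values, resolution = 200, margin = 0.02) {
  if (!inherits(tri, "site_triangulation")) tri <- triangulate(tri)
  pts <- tri$points
  if (!is.null(names(values))) {
    miss <- setdiff(pts$sample_id, names(values))
    if (length(miss) > 0) {
      abort(paste0("values missing for sites: ", paste(miss, collapse = ", ")))
    }
    v <- as.numeric(values[pts$sample_id])
  } else {
    # triangulate() re-sorts points lexicographically, so positional values
    # would silently misalign with the caller's original order
    abort("values must be a named vector (names = sample_id)")
  }

  xr <- range(pts$x); yr <- range(pts$y)
  mx <- margin * diff(xr); my <- margin * diff(yr)
  xll <- xr[1] - mx; yll <- yr[1] - my
  span <- max(diff(xr) + 2 * mx, diff(yr) + 2 * my)
  cellsize <- span / (resolution - 1)
  nx <- floor((diff(xr) + 2 * mx) / cellsize) + 1L
  ny <- floor((diff(yr) + 2 * my) / cellsize) + 1L
  gx <- xll + (seq_len(nx) - 1L) * cellsize
  gy <- yll + (seq_len(ny) - 1L) * cellsize
  grid <- tidyr::expand_grid(y = gy, x = gx)[, c("x", "y")]

  val <- interpolate_at(tri, v, grid$x, grid$y)
  structure(list(grid = tibble::tibble(x = grid$x, y = grid$y, value = val),
                 nx = nx, ny = ny, cellsize = cellsize, xll = xll, yll = yll,
                 triangulation = tri),
            class = "spatial_field")
}

#' Evaluate the piecewise-linear interpolant at arbitrary points
#'
#' @param tri A `site_triangulation`.
#' @param values Numeric vector of vertex values, in `tri$points` order.
#' @param qx,qy Query coordinates.
#' @return Numeric vector; `NA` outside the hull or where a vertex value of
#'   the containing triangle is missing.
#' @export
interpolate_at <- function(tri, values, qx, qy) {
  stopifnot(inherits(tri, "site_triangulation"))
  pts <- tri$points
  out <- rep(NA_real_, length(qx))
  unassigned <- rep(TRUE, length(qx))
  eps <- 1e-12
  for (t in seq_len(nrow(tri$triangles))) {
    if (!any(unassigned)) break
    ijk <- tri$triangles[t, ]
    p1 <- c(pts$x[ijk[1]], pts$y[ijk[1]])
    p2 <- c(pts$x[ijk[2]], pts$y[ijk[2]])
    p3 <- c(pts$x[ijk[3]], pts$y[ijk[3]])
    idx <- which(unassigned)
    w <- barycentric_weights(qx[idx], qy[idx], p1, p2, p3)
    inside <- w[, 1] >= -eps & w[, 2] >= -eps & w[, 3] >= -eps
    if (!any(inside)) next
    sel <- idx[inside]
    vv <- values[ijk]
    out[sel] <- w[inside, 1] * vv[1] + w[inside, 2] * vv[2] + w[inside, 3] * vv[3]
    unassigned[sel] <- FALSE
  }
  out
}

#' @export
print.spatial_field <- function(x, ...) {
  cat("spatial_field: ", x$nx, " x ", x$ny, " grid (cellsize ",
      signif(x$cellsize, 4), "), ", sum(!is.na(x$grid$value)),
      " nodes inside the hull\n", sep = "")
  invisible(x)
}

#' @export
autoplot.spatial_field <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$x, y = .data$y,
                                            fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = object$triangulation$points,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        inherit.aes = FALSE, shape = 21, fill = "white") +
    ggplot2::scale_fill_viridis_c(na.value = "transparent") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Export a field as an ESRI ASCII grid
#'
#' Text raster with the standard `ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header, readable by common GIS tools; rows are written
#' north to south.
#'
#' @param field A `spatial_field`.
#' @param path Output path.
#' @param nodata NODATA sentinel written for missing cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(field, path, nodata = -9999) {
  v <- field$grid$value
  v[is.na(v)] <- nodata
  m <- matrix(v, nrow = field$ny, ncol = field$nx, byrow = TRUE)
  hdr <- c(paste("ncols", field$nx), paste("nrows", field$ny),
           paste("xllcorner", field$xll), paste("yllcorner", field$yll),
           paste("cellsize", field$cellsize), paste("NODATA_value", nodata))
  body <- apply(m[field$ny:1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Per-KO point layers for mapping
#'
#' Joins the per-sample gene metrics with site coordinates, yielding one
#' mappable layer per KO: coordinates plus abundance (color gradients),
#' richness (point size) and variance. Undefined variances export as empty
#' fields.
#'
#' @param metrics Tibble from [compute_gene_metrics()].
#' @param env Metadata tibble with `sample_id`, `x`, `y`.
#' @param dir Optional directory; when given, one CSV per KO is written.
#' @return A tibble (`ko`, `sample_id`, `x`, `y`, `abundance`, `richness`,
#'   `variance`), invisibly when `dir` is given.
#' @export
export_point_layers <- function(metrics, env, dir = NULL) {
  if (!all(c("x", "y") %in% names(env))) {
    abort("env must carry coordinate columns x and y")
  }
  check_sample_overlap(metrics$sample_id, env$sample_id)
  layers <- metrics |>
    dplyr::inner_join(dplyr::select(env, "sample_id", "x", "y"),
                      by = "sample_id") |>
    dplyr::select("ko", "sample_id", "x", "y",
                  "abundance", "richness", "variance") |>
    dplyr::arrange(.data$ko, .data$sample_id)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (k in unique(layers$ko)) {
      readr::write_csv(layers[layers$ko == k, ],
                       file.path(dir, paste0(k, "_layer.csv")),
                       na = "", progress = FALSE)
    }
    return(invisible(layers))
  }
  layers
}

#' Map one KO's point layer
#'
#' Quick site map in the convention of gene-distribution figures: color is
#' abundance, point size is richness.
#'
#' @param layers Tibble from [export_point_layers()].
#' @param ko KO code to draw.
#' @return A ggplot object.
#' @export
plot_point_layer <- function(layers, ko) {
  d <- layers[layers$ko == ko, ]
  if (nrow(d) == 0) abort(paste0("no layer rows for KO ", ko))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  color = .data$abundance,
                                  size = .data$richness)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient(low = "orange", high = "darkgreen") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = ko) +
    ggplot2::theme_minimal()
}
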