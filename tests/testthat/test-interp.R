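pts_df <- function(x, y, ids = NULL) {
  if (is.null(ids)) ids <- paste0("p", seq_along(x))
  tibble::tibble(sample_id = ids, x = x, y = y)
}

test_that("triangulation covers the hull with the expected triangle counts", {
  t3 <- triangulate(pts_df(c(0, 1, 0), c(0, 0, 1)))
  expect_equal(nrow(t3$triangles), 1)

  t4 <- triangulate(pts_df(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(nrow(t4$triangles), 2)

  t5 <- triangulate(pts_df(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5)))
  expect_equal(nrow(t5$triangles), 4)

  # every site is a vertex of some triangle
  expect_setequal(unique(as.vector(t5$triangles)), 1:5)

  expect_error(triangulate(pts_df(c(0, 1, 2), c(0, 1, 2))), "collinear")
  expect_error(triangulate(pts_df(c(0, 0, 1), c(0, 0, 1), c("a", "b", "c"))),
               "duplicate")
  expect_error(triangulate(pts_df(c(0, 1), c(0, 1))), "at least 3")
})

test_that("linear interpolation is exact on affine fields", {
  withr::local_seed(31)
  for (case in 1:30) {
    n <- sample(5:20, 1)
    df <- pts_df(stats::runif(n, 0, 100), stats::runif(n, 0, 100))
    tri <- triangulate(df)
    a <- stats::runif(1, -5, 5); b <- stats::runif(1, -5, 5)
    c0 <- stats::runif(1, -10, 10)
    v <- stats::setNames(a * df$x + b * df$y + c0, df$sample_id)
    fld <- interpolate_field(tri, v, resolution = 25)
    g <- fld$grid[!is.na(fld$grid$value), ]
    expect_gt(nrow(g), 0)
    expect_lt(max(abs(g$value - (a * g$x + b * g$y + c0))), 1e-10)
  }
})

test_that("the interpolant reproduces site values and stays bounded", {
  withr::local_seed(8)
  df <- pts_df(stats::runif(15, 0, 10), stats::runif(15, 0, 10))
  tri <- triangulate(df)
  v <- stats::setNames(stats::rnorm(15), df$sample_id)
  # exact vertex reproduction
  at_sites <- interpolate_at(tri, v[tri$points$sample_id],
                             tri$points$x, tri$points$y)
  expect_identical(at_sites, unname(v[tri$points$sample_id]))

  # triangle-centroid value is the mean of the vertex values: (0+0+3)/3
  tc <- triangulate(pts_df(c(0, 1, 0), c(0, 0, 1)))
  vv <- stats::setNames(c(0, 0, 3), tc$points$sample_id)
  expect_equal(interpolate_at(tc, vv[tc$points$sample_id], 1 / 3, 1 / 3), 1)

  # boundedness within each triangle's vertex range
  fld <- interpolate_field(tri, v, resolution = 40)
  g <- fld$grid$value
  expect_true(all(g[!is.na(g)] >= min(v) - 1e-12))
  expect_true(all(g[!is.na(g)] <= max(v) + 1e-12))
})

test_that("grid nodes outside the convex hull are missing, and only those", {
  skip_if_not_installed("mgcv")
  withr::local_seed(14)
  for (case in 1:10) {
    n <- sample(6:25, 1)
    df <- pts_df(stats::runif(n), stats::runif(n))
    tri <- triangulate(df)
    v <- stats::setNames(stats::rnorm(n), df$sample_id)
    fld <- interpolate_field(tri, v, resolution = 30)
    hull <- tri$points[tri$hull, ]
    inside <- oracle_in_hull(fld$grid$x, fld$grid$y, hull$x, hull$y)
    # allow disagreement only for nodes essentially on the hull boundary
    mismatch <- xor(inside, !is.na(fld$grid$value))
    expect_lt(mean(mismatch), 0.02)
    expect_equal(mean(is.na(fld$grid$value)), mean(!inside), tolerance = 0.05)
  }
})

test_that("missing site values propagate to their incident triangles only", {
  # two-lobe layout: the NA site at (2, 0) only touches right-hand triangles
  df <- pts_df(c(0, 1, 0, 1, 2, 2), c(0, 0, 1, 1, 0, 1))
  tri <- triangulate(df)
  v <- stats::setNames(c(1, 2, 3, 4, NA, 5), df$sample_id)
  got <- interpolate_at(tri, v[tri$points$sample_id],
                        c(0.3, 0.5, 1.8), c(0.4, 0.9, 0.5))
  expect_false(anyNA(got[1:2]))   # left lobe untouched
  expect_true(is.na(got[3]))      # inside a triangle incident to the NA site
})

test_that("fields export as parseable ESRI ASCII grids", {
  df <- pts_df(c(0, 10, 10, 0), c(0, 0, 10, 10))
  fld <- interpolate_field(triangulate(df),
                           stats::setNames(c(1, 2, 3, 4), df$sample_id),
                           resolution = 11)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(fld, path)
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], " +")
  expect_equal(vapply(hdr, `[`, "", 1),
               c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                 "NODATA_value"))
  ncols <- as.integer(hdr[[1]][2]); nrows <- as.integer(hdr[[2]][2])
  expect_equal(length(lines), 6 + nrows)
  body <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(l, " ")[[1]])
  }))
  expect_equal(dim(body), c(nrows, ncols))
  # raster rows run north to south; row 1 is the top (max y) grid row
  top <- fld$grid[fld$grid$y == max(fld$grid$y), ]
  expect_equal(body[1, ], ifelse(is.na(top$value), -9999, top$value),
               tolerance = 1e-9)
})

test_that("point layers join metrics with coordinates per KO", {
  fx <- fixture_small()
  m <- compute_gene_metrics(fx$records, samples = fx$env$sample_id)
  layers <- export_point_layers(m, fx$env)
  expect_equal(nrow(layers), nrow(m))
  expect_equal(sum(layers$ko == "K00368"), 8)
  dir <- withr::local_tempdir()
  export_point_layers(m, fx$env, dir = dir)
  files <- list.files(dir, pattern = "_layer.csv$")
  expect_equal(length(files), dplyr::n_distinct(m$ko))
  re <- readr::read_csv(file.path(dir, "K00368_layer.csv"),
                        show_col_types = FALSE)
  expect_equal(nrow(re), 8)
  # undefined variance exported as empty, read back as NA
  expect_true(any(is.na(re$variance)))
})
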