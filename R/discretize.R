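#' Quantile discretization of a covariate
#'
#' Turns a quantitative variable into the categorical items used for rule
#' mining. Two schemes are supported, following the percentile bands
#' 0–50 / 50–100 and 0–30 / 30–70 / 70–100:
#'
#' * `bins = 2`: split at the empirical median; labels `"<50%"`, `">50%"`.
#' * `bins = 3`: split at the 30th and 70th empirical percentiles; labels
#'   `"<30%"`, `"30-70%"`, `">70%"`.
#'
#' Percentiles use linear interpolation between order statistics
#' (`quantile()` type 7); values equal to a cut point go to the lower bin.
#' Missing values yield `NA` (no item is emitted for that sample). A
#' constant vector cannot be partitioned: it comes back as a single
#' category flagged degenerate, and [discretize_env()] excludes such
#' variables from mining.
#'
#' @param values Numeric vector (one entry per sample).
#' @param bins 2 or 3.
#' @return A character vector of categories with attributes `cuts` (the
#'   partitioning values) and `degenerate` (logical).
#' @export
discretize <- function(values, bins = 3) {
  if (!bins %in% c(2, 3)) abort("bins must be 2 or 3")
  obs <- values[!is.na(values)]
  if (length(obs) < 1) abort("discretize needs at least one non-missing value")
  if (length(unique(obs)) == 1) {
    out <- ifelse(is.na(values), NA_character_, "constant")
    attr(out, "cuts") <- numeric(0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (bins == 2) {
    cuts <- unname(quantile(obs, 0.5, type = 7))
    labels <- c("<50%", ">50%")
  } else {
    cuts <- unname(quantile(obs, c(0.3, 0.7), type = 7))
    labels <- c("<30%", "30-70%", ">70%")
  }
  idx <- findInterval(values, cuts, left.open = TRUE) + 1L
  out <- labels[idx]
  attr(out, "cuts") <- cuts
  attr(out, "degenerate") <- FALSE
  out
}

#' Discretize a metadata table for rule mining
#'
#' Applies [discretize()] to every covariate column of a metadata table and
#' collects the resulting items in long form, together with the per-variable
#' partitioning values (the analogue of a supplementary cut-point table).
#' Coordinate columns (`x`, `y`) are never discretized.
#'
#' @param env Metadata tibble from [read_env_table()].
#' @param bins Default number of bins (2 or 3) for every variable, or a
#'   named vector/list giving per-variable bin counts, e.g.
#'   `c(rotifers = 2)`; unnamed variables fall back on `default_bins`.
#' @param default_bins Fallback when `bins` is a named vector.
#' @return A list with `items` (tibble `sample_id`, `variable`, `category`)
#'   and `cuts` (tibble `variable`, `bins`, `cuts` list-column,
#'   `degenerate`). Degenerate (constant) variables appear in `cuts` but
#'   emit no items.
#' @export
discretize_env <- function(env, bins = 3, default_bins = 3) {
  vars <- setdiff(names(env), c("sample_id", "x", "y"))
  if (length(vars) == 0) abort("metadata table has no covariate columns")
  get_bins <- function(v) {
    if (length(bins) == 1 && is.null(names(bins))) return(as.integer(bins))
    as.integer(bins[[v]] %||% default_bins)
  }
  items <- list(); cuts <- list()
  for (v in vars) {
    b <- get_bins(v)
    cat_v <- discretize(env[[v]], bins = b)
    degenerate <- attr(cat_v, "degenerate")
    cuts[[v]] <- tibble::tibble(variable = v, bins = b,
                                cuts = list(attr(cat_v, "cuts")),
                                degenerate = degenerate)
    if (degenerate) {
      inform(paste0("variable ", v, " is constant; excluded from mining"))
      next
    }
    keep <- !is.na(cat_v)
    items[[v]] <- tibble::tibble(sample_id = env$sample_id[keep],
                                 variable = v, category = cat_v[keep])
  }
  list(items = dplyr::bind_rows(items), cuts = dplyr::bind_rows(cuts))
}
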