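#' Pearson correlation for one pair of variables
#'
#' Pairwise-complete Pearson correlation with the two-sided t-test p-value
#' (t = r sqrt((n − 2) / (1 − r²)) on n − 2 degrees of freedom). The result
#' is flagged undefined (`NA` r and p) when fewer than 3 complete pairs
#' remain or when either vector is constant.
#'
#' @param x,y Numeric vectors of equal length; `NA`s are dropped pairwise.
#' @param alpha Significance level for the `significant` flag.
#' @return A one-row tibble: `r`, `p`, `n`, `significant`.
#' @export
cor_pearson <- function(x, y, alpha = 0.05) {
  ok <- complete.cases(x, y)
  n <- sum(ok)
  if (n < 3 || length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n, significant = NA))
  }
  ct <- cor.test(x[ok], y[ok], method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- ct$p.value
  tibble::tibble(r = r, p = p, n = n, significant = p < alpha)
}

#' Significance-screened correlation matrix
#'
#' Computes all pairwise Pearson correlations between the numeric columns of
#' `left` and `right` (gene–gene when both are gene-metric tables, or
#' gene–environment when `right` is a metadata table), joined on
#' `sample_id`. Every pair is retained in the output; pairs with p ≥ alpha
#' are flagged non-significant so that masked exports reproduce the
#' convention of correlogram figures, where non-significant cells are left
#' blank. No multiple-testing correction is applied by default (masking is
#' at the raw p < 0.05); Benjamini–Hochberg can be switched on via
#' `adjust = "BH"`.
#'
#' @param left A tibble with a `sample_id` column and numeric variable
#'   columns (see [metrics_wide()] to reshape a metrics table).
#' @param right Optional second tibble of the same shape. When `NULL`, all
#'   unordered pairs within `left` are computed.
#' @param alpha Significance level used for masking.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `corr_screen` object; use [tidy()] for the long results table,
#'   [glance()] for a one-row summary, [cor_matrix_wide()] for the masked
#'   wide matrix, and [autoplot()] for a correlogram-style heatmap.
#' @export
correlate_pairs <- function(left, right = NULL, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!"sample_id" %in% names(left)) abort("left must have a sample_id column")
  self <- is.null(right)
  if (self) right <- left
  if (!"sample_id" %in% names(right)) abort("right must have a sample_id column")

  shared <- check_sample_overlap(left$sample_id, right$sample_id,
                                 "left table", "right table")
  lv <- setdiff(names(left), c("sample_id", "x", "y"))
  rv <- setdiff(names(right), c("sample_id", "x", "y"))
  l <- left[match(shared, left$sample_id), lv, drop = FALSE]
  r <- right[match(shared, right$sample_id), rv, drop = FALSE]

  pairs <- if (self) {
    if (length(lv) < 2) abort("need at least two variables for a self screen")
    idx <- which(upper.tri(matrix(0, length(lv), length(lv))), arr.ind = TRUE)
    tibble::tibble(var_a = lv[idx[, "row"]], var_b = lv[idx[, "col"]])
  } else {
    tidyr::expand_grid(var_a = lv, var_b = rv)
  }

  res <- purrr::map2_dfr(pairs$var_a, pairs$var_b, function(a, b) {
    cor_pearson(l[[a]], r[[b]], alpha = alpha)
  })
  res <- dplyr::bind_cols(pairs, res)
  if (adjust == "BH") {
    res$p_adj <- NA_real_
    def <- !is.na(res$p)
    res$p_adj[def] <- p.adjust(res$p[def], method = "BH")
    res$significant <- ifelse(def, res$p_adj < alpha, NA)
  }
  structure(
    list(results = res, alpha = alpha, adjust = adjust,
         n_samples = length(shared)),
    class = "corr_screen"
  )
}

#' @export
tidy.corr_screen <- function(x, ...) x$results

#' @export
glance.corr_screen <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$results),
    n_defined = sum(!is.na(x$results$r)),
    n_significant = sum(x$results$significant %in% TRUE),
    alpha = x$alpha,
    adjust = x$adjust,
    n_samples = x$n_samples
  )
}

#' @export
print.corr_screen <- function(x, ...) {
  g <- glance(x)
  cat("Pearson correlation screen: ", g$n_pairs, " pairs over ",
      g$n_samples, " samples; ", g$n_significant,
      " significant at alpha = ", g$alpha,
      if (g$adjust != "none") paste0(" (", g$adjust, "-adjusted)") else "",
      "\n", sep = "")
  print(x$results, ...)
  invisible(x)
}

#' Masked wide correlation matrix
#'
#' Wide variables-by-variables matrix of `r` with non-significant (or
#' undefined) cells blanked to `NA` — the tabular equivalent of a masked
#' correlogram.
#'
#' @param screen A `corr_screen` object.
#' @param masked Blank non-significant cells (default `TRUE`).
#' @return A tibble; first column `var_a`, remaining columns one per
#'   `var_b`.
#' @export
cor_matrix_wide <- function(screen, masked = TRUE) {
  res <- screen$results
  if (masked) res$r[!(res$significant %in% TRUE)] <- NA_real_
  tidyr::pivot_wider(res[, c("var_a", "var_b", "r")],
                     names_from = "var_b", values_from = "r")
}

#' Export a correlation screen as TSV
#'
#' Long format: `var_a`, `var_b`, `r`, `p`, `n`, `significant` (plus
#' `p_adj` when adjustment was on).
#'
#' @param screen A `corr_screen` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlations_tsv <- function(screen, path) {
  readr::write_tsv(screen$results, path, na = "", progress = FALSE)
  invisible(path)
}

#' @export
autoplot.corr_screen <- function(object, masked = TRUE, ...) {
  res <- object$results
  if (masked) res$r[!(res$significant %in% TRUE)] <- NA_real_
  ggplot2::ggplot(res, ggplot2::aes(x = .data$var_b, y = .data$var_a,
                                    fill = .data$r)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(low = "firebrick3", mid = "white",
                                  high = "dodgerblue3", limits = c(-1, 1),
                                  na.value = "grey95") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Reshape a metrics table to samples-by-KOs
#'
#' One row per sample, one column per KO, holding the chosen statistic.
#' Undefined variances stay `NA` and are later dropped pairwise by the
#' correlation screen (never treated as zero).
#'
#' @param metrics Tibble from [compute_gene_metrics()].
#' @param value `"richness"`, `"abundance"` or `"variance"`.
#' @param transform Optional `"log1p"` for correlations on a damped scale.
#' @return A tibble: `sample_id` plus one numeric column per KO.
#' @export
metrics_wide <- function(metrics, value = c("richness", "abundance", "variance"),
                         transform = c("identity", "log1p")) {
  value <- match.arg(value)
  transform <- match.arg(transform)
  wide <- tidyr::pivot_wider(metrics[, c("sample_id", "ko", value)],
                             names_from = "ko", values_from = dplyr::all_of(value))
  if (transform == "log1p") {
    wide <- dplyr::mutate(wide, dplyr::across(-"sample_id", log1p))
  }
  wide
}
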