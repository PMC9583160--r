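#' Per-sample gene metrics
#'
#' For every (sample, catalog KO) pair, computes the three per-gene
#' statistics used throughout the pipeline:
#'
#' * **abundance** — the expected number of sequences of the gene, i.e. the
#'   sum of the Estimated Copy values of the GeneIDs annotated to that KO;
#' * **richness** — the number of distinct GeneIDs annotated to that KO;
#' * **variance** — the sample variance (n − 1 denominator) of those
#'   Estimated Copy values, undefined (`NA`) when fewer than two GeneIDs
#'   were observed.
#'
#' The result is complete over the catalog: KOs with no records in a sample
#' get an explicit zero row (abundance 0, richness 0, variance `NA`), so the
#' sample × KO matrix downstream is dense.
#'
#' @param records Gene-record tibble from [read_gene_records()] /
#'   [read_gene_manifest()] (columns `sample_id`, `gene_id`, `ko`,
#'   `estimated_copy`).
#' @param catalog Catalog tibble from [nitrogen_catalog()].
#' @param samples Optional character vector fixing the sample set (so samples
#'   with no retained records still appear). Defaults to the samples present
#'   in `records`.
#'
#' @return A tibble with one row per (sample, KO): `sample_id`, `ko`,
#'   `gene_symbols` (list), `protein`, `abundance`, `richness`, `variance`.
#' @export
compute_gene_metrics <- function(records, catalog = nitrogen_catalog(),
                                 samples = NULL) {
  unknown <- setdiff(unique(records$ko), catalog$ko)
  if (length(unknown) > 0) {
    abort(paste0("records contain KO(s) not in the catalog: ",
                 paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(records[, c("sample_id", "gene_id")])) {
    abort("duplicated (sample_id, gene_id) in records")
  }
  if (any(records$estimated_copy <= 0)) {
    abort("estimated_copy must be positive for every record")
  }
  samples <- sort(unique(c(samples, records$sample_id)))
  if (length(samples) == 0) {
    abort("no samples: supply `samples` or non-empty records")
  }

  observed <- records |>
    dplyr::group_by(.data$sample_id, .data$ko) |>
    dplyr::summarise(
      abundance = sum(.data$estimated_copy),
      richness = dplyr::n_distinct(.data$gene_id),
      variance = if (dplyr::n() >= 2) var(.data$estimated_copy) else NA_real_,
      .groups = "drop"
    )

  tidyr::expand_grid(sample_id = samples, ko = catalog$ko) |>
    dplyr::left_join(observed, by = c("sample_id", "ko")) |>
    dplyr::mutate(
      abundance = dplyr::coalesce(.data$abundance, 0),
      richness = dplyr::coalesce(.data$richness, 0L)
    ) |>
    dplyr::left_join(
      dplyr::select(catalog, "ko", "gene_symbols", "protein"),
      by = "ko"
    ) |>
    dplyr::select("sample_id", "ko", "gene_symbols", "protein",
                  "abundance", "richness", "variance")
}

#' Operon-completeness presence calls
#'
#' A protein (operon) is called present in a sample only when *every* KO of
#' its operon was detected there (richness ≥ 1). If a single gene from the
#' operon was found but the others were not, the protein is considered
#' absent — detection speaks only to the potential to encode the complete
#' protein.
#'
#' @param metrics Metrics tibble from [compute_gene_metrics()]; must be
#'   complete over the catalog KOs.
#' @param catalog Catalog tibble from [nitrogen_catalog()].
#' @return A tibble with columns `sample_id`, `protein`, `present` (logical).
#' @export
call_protein_presence <- function(metrics, catalog = nitrogen_catalog()) {
  missing <- metrics |>
    dplyr::distinct(.data$sample_id) |>
    tidyr::expand_grid(ko = catalog$ko) |>
    dplyr::anti_join(metrics, by = c("sample_id", "ko"))
  if (nrow(missing) > 0) {
    abort("metrics are not complete over the catalog KOs; recompute with compute_gene_metrics()")
  }
  metrics |>
    dplyr::select("sample_id", "ko", "richness") |>
    dplyr::inner_join(dplyr::select(catalog, "ko", "protein"), by = "ko") |>
    dplyr::group_by(.data$sample_id, .data$protein) |>
    dplyr::summarise(present = all(.data$richness >= 1), .groups = "drop")
}

#' Site prevalence of detected genes or complete operons
#'
#' The percentage of samples in which an item was detected, over a fixed
#' sample set, reported to one decimal with halves rounded away from zero
#' (7 of 32 sites is printed as 21.9%).
#'
#' @param x Either a presence tibble from [call_protein_presence()] (items
#'   are proteins, detection means the operon is complete) or a metrics
#'   tibble from [compute_gene_metrics()] (items are KOs, detection means
#'   richness ≥ 1).
#' @param item Optional item name(s) (protein or KO) to restrict to.
#' @return A tibble with `item`, `n_detected`, `n_samples`, `prevalence`
#'   (percent, one decimal).
#' @export
prevalence <- function(x, item = NULL) {
  if (all(c("protein", "present") %in% names(x)) && !"ko" %in% names(x)) {
    long <- dplyr::transmute(x, item = .data$protein,
                             sample_id = .data$sample_id,
                             detected = .data$present)
  } else if (all(c("ko", "richness") %in% names(x))) {
    long <- dplyr::transmute(x, item = .data$ko,
                             sample_id = .data$sample_id,
                             detected = .data$richness >= 1)
  } else {
    abort("x must be a presence table (protein, present) or a metrics table (ko, richness)")
  }
  n <- dplyr::n_distinct(long$sample_id)
  if (n == 0) abort("prevalence is undefined for an empty sample set")
  out <- long |>
    dplyr::group_by(.data$item) |>
    dplyr::summarise(n_detected = sum(.data$detected),
                     n_samples = n, .groups = "drop") |>
    dplyr::mutate(prevalence = round_half_up(100 * .data$n_detected / n, 1))
  if (!is.null(item)) {
    unknown <- setdiff(item, out$item)
    if (length(unknown) > 0) {
      abort(paste0("item(s) not found: ", paste(unknown, collapse = ", ")))
    }
    out <- out[match(item, out$item), ]
  }
  out
}
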