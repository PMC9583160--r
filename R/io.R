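#' Read per-sample gene annotation records
#'
#' Reads IMG-style gene annotation tables: tab-separated, one row per GeneID
#' with its KO code and Estimated Copy value (the expected number of sequences
#' for that GeneID). Only records whose KO belongs to the nitrogen-cycle
#' catalog are retained; how many rows were read and kept is reported.
#'
#' @param path Path to a TSV with header columns `gene_id`, `ko`,
#'   `estimated_copy`.
#' @param sample_id Sample identifier to attach to the records. Defaults to
#'   the file name without extension.
#' @param catalog Catalog tibble from [nitrogen_catalog()].
#' @param quiet Suppress the row-count message.
#'
#' @return A tibble with columns `sample_id`, `gene_id`, `ko`,
#'   `estimated_copy`, containing only catalog KOs.
#' @seealso [read_gene_manifest()] to read a whole survey at once.
#' @export
read_gene_records <- function(path, sample_id = NULL, catalog = nitrogen_catalog(),
                              quiet = FALSE) {
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("gene_id", "ko", "estimated_copy")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(paste0("gene record file ", path, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ec <- suppressWarnings(as.numeric(raw$estimated_copy))
  bad <- which(is.na(ec) | ec <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive or non-numeric estimated_copy in ", path,
                 " at data row(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  if (anyDuplicated(raw$gene_id)) {
    dup <- unique(raw$gene_id[duplicated(raw$gene_id)])
    abort(paste0("duplicated gene_id within sample ", sample_id, ": ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  keep <- raw$ko %in% catalog$ko
  records <- tibble::tibble(
    sample_id = sample_id,
    gene_id = raw$gene_id[keep],
    ko = raw$ko[keep],
    estimated_copy = ec[keep]
  )
  if (!quiet) {
    inform(paste0(sample_id, ": ", nrow(raw), " rows read, ",
                  nrow(records), " catalog-KO records retained"))
  }
  records
}

#' Read a survey of gene-record files via a manifest
#'
#' The manifest is a CSV with columns `sample_id` and `path` (absolute, or
#' relative to the manifest's own directory), mirroring per-metagenome
#' downloads from an annotation portal.
#'
#' @param manifest_path Path to the manifest CSV.
#' @inheritParams read_gene_records
#' @return A tibble of all samples' records, as in [read_gene_records()].
#' @export
read_gene_manifest <- function(manifest_path, catalog = nitrogen_catalog(),
                               quiet = FALSE) {
  man <- readr::read_csv(manifest_path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("sample_id", "path") %in% names(man))) {
    abort("manifest must have columns sample_id and path")
  }
  if (anyDuplicated(man$sample_id)) {
    abort("duplicated sample_id in manifest")
  }
  base <- dirname(manifest_path)
  paths <- ifelse(file.exists(man$path), man$path, file.path(base, man$path))
  purrr::map2_dfr(paths, man$sample_id, read_gene_records,
                  catalog = catalog, quiet = quiet)
}

#' Read a sample metadata table
#'
#' Reads the biogeochemical/biological metadata: a CSV whose first column is
#' `sample_id`, with planar projected coordinates in columns `x` and `y`
#' (meters) and all remaining columns numeric covariates (pH, soil water %,
#' nitrogen %, biomass, taxa counts, ...). Blank cells become `NA`, never 0.
#'
#' @param path Path to the CSV.
#' @param require_coords Error if `x`/`y` are absent (needed for mapping but
#'   not for correlation or rule mining).
#' @return A tibble with `sample_id`, optionally `x`, `y`, and numeric
#'   covariate columns.
#' @export
read_env_table <- function(path, require_coords = TRUE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = c("", "NA"))
  if (names(raw)[1] != "sample_id") {
    abort("first column of the metadata table must be sample_id")
  }
  if (anyDuplicated(raw$sample_id)) {
    abort("duplicated sample_id in metadata table")
  }
  if (require_coords && !all(c("x", "y") %in% names(raw))) {
    abort("metadata table must have coordinate columns x and y")
  }
  num <- setdiff(names(raw), "sample_id")
  for (v in num) {
    parsed <- suppressWarnings(as.numeric(raw[[v]]))
    newly_na <- sum(is.na(parsed) & !is.na(raw[[v]]))
    if (newly_na > 0) {
      abort(paste0("column ", v, " has ", newly_na, " non-numeric value(s)"))
    }
    raw[[v]] <- parsed
  }
  if (all(c("x", "y") %in% names(raw))) {
    if (anyDuplicated(raw[, c("x", "y")])) {
      abort("coordinate pairs must be distinct across samples")
    }
  }
  raw
}

# warn (once per call site) about samples present on one side of a join only
check_sample_overlap <- function(a, b, what_a = "gene data", what_b = "metadata") {
  shared <- intersect(a, b)
  if (length(shared) == 0) {
    abort(paste0("no shared samples between ", what_a, " and ", what_b))
  }
  orphans <- setdiff(b, a)
  if (length(orphans) > 0) {
    warn(paste0("samples in ", what_b, " but not in ", what_a, ": ",
                paste(orphans, collapse = ", ")))
  }
  shared
}

#' Write long-format metrics and presence tables
#'
#' Tab-separated exports of the per-sample gene metrics (empty field where
#' variance is undefined) and of the operon presence calls (`present` coded
#' 0/1).
#'
#' @param metrics A tibble from [compute_gene_metrics()].
#' @param presence A tibble from [call_protein_presence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  out <- metrics
  out$gene_symbols <- vapply(out$gene_symbols, paste, "", collapse = ", ")
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_metrics_tsv
#' @export
write_presence_tsv <- function(presence, path) {
  out <- presence
  out$present <- as.integer(out$present)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
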