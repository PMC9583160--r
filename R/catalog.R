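#' Nitrogen-cycle gene catalog
#'
#' Loads the packaged catalog of nitrogen-cycle KEGG Orthology (KO) terms.
#' Each row is one KO together with the gene symbols it covers (annotation is
#' KO-level, so e.g. K00370 covers narG/narZ/nxrA indistinguishably), the
#' protein (operon) it belongs to, and the nitrogen-cycle pathways the protein
#' participates in (nitrogen fixation, nitrification, denitrification,
#' dissimilatory/assimilatory nitrate reduction, anammox).
#'
#' @param path Path to a catalog TSV. Defaults to the catalog shipped with the
#'   package. The file must have columns `protein`, `gene_symbols`, `ko`,
#'   `pathways` (semicolon-separated).
#'
#' @return A tibble with columns `ko` (character, `K` + 5 digits),
#'   `gene_symbols` (list of character vectors), `protein` (character) and
#'   `pathways` (list of character vectors).
#' @examples
#' cat <- nitrogen_catalog()
#' catalog_lookup(cat, "K02588")
#' protein_members(cat, "Hzs")
#' @export
nitrogen_catalog <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "nitrogen_cycle_catalog.tsv", package = "nitroscape")
  if (!nzchar(path) || !file.exists(path)) {
    abort("catalog resource not found; the package installation is corrupt")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("protein", "gene_symbols", "ko", "pathways")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(paste0("catalog is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  cat <- tibble::tibble(
    ko = raw$ko,
    gene_symbols = strsplit(raw$gene_symbols, ",\\s*"),
    protein = raw$protein,
    pathways = strsplit(raw$pathways, ";\\s*")
  )
  validate_catalog(cat)
  cat
}

validate_catalog <- function(cat) {
  bad <- cat$ko[!grepl("^K\\d{5}$", cat$ko)]
  if (length(bad) > 0) {
    abort(paste0("malformed KO code(s) in catalog: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(cat$ko)) {
    abort(paste0("duplicated KO code(s) in catalog: ",
                 paste(unique(cat$ko[duplicated(cat$ko)]), collapse = ", ")))
  }
  if (any(lengths(cat$pathways) == 0)) {
    abort("catalog entries must list at least one pathway")
  }
  known <- c("nitrogen fixation", "nitrification", "denitrification",
             "DNR", "ANR", "anammox")
  extra <- setdiff(unique(unlist(cat$pathways)), known)
  if (length(extra) > 0) {
    abort(paste0("unknown pathway label(s): ", paste(extra, collapse = ", ")))
  }
  invisible(cat)
}

#' Look up catalog entries
#'
#' `catalog_lookup()` retrieves the entry for one or more KO codes;
#' `protein_members()` returns the KO codes that make up a protein's operon;
#' `pathway_members()` returns all entries annotated to a pathway.
#'
#' @param catalog A catalog tibble from [nitrogen_catalog()].
#' @param ko,protein,pathway Character identifiers to look up.
#' @return `catalog_lookup()` and `pathway_members()` return catalog rows;
#'   `protein_members()` a character vector of KO codes.
#' @export
catalog_lookup <- function(catalog, ko) {
  unknown <- setdiff(ko, catalog$ko)
  if (length(unknown) > 0) {
    abort(paste0("KO code(s) not in catalog: ", paste(unknown, collapse = ", ")))
  }
  catalog[match(ko, catalog$ko), ]
}

#' @rdname catalog_lookup
#' @export
protein_members <- function(catalog, protein) {
  if (!protein %in% catalog$protein) {
    abort(paste0("protein not in catalog: ", protein))
  }
  catalog$ko[catalog$protein == protein]
}

#' @rdname catalog_lookup
#' @export
pathway_members <- function(catalog, pathway) {
  keep <- vapply(catalog$pathways, function(p) pathway %in% p, logical(1))
  if (!any(keep)) {
    abort(paste0("pathway not in catalog: ", pathway))
  }
  catalog[keep, ]
}

#' Write a catalog back to TSV
#'
#' Inverse of [nitrogen_catalog()]; mainly used to round-trip the packaged
#' resource.
#'
#' @param catalog A catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  out <- tibble::tibble(
    protein = catalog$protein,
    gene_symbols = vapply(catalog$gene_symbols, paste, "", collapse = ", "),
    ko = catalog$ko,
    pathways = vapply(catalog$pathways, paste, "", collapse = ";")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
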