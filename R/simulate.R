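#' Configuration for the synthetic survey generator
#'
#' Default parameters emulate the structure of a 32-site polar-desert soil
#' metagenome survey: per-KO detection prevalences spanning ubiquitous
#' (nasAB-like) to never-detected (hzs-like), negative-binomial GeneID
#' counts per (sample, KO), log-normal Estimated Copy values per GeneID,
#' biogeochemical covariates coupled to chosen gene metrics through a
#' Gaussian copula with stated target correlations, a planted
#' covariate ⇒ operon association rule, and clustered site coordinates with
#' a smooth habitat gradient.
#'
#' @param n_samples Number of sites.
#' @param prevalence Named numeric vector: per-KO probability that at least
#'   one GeneID is detected in a sample. Unnamed KOs default to 0.5.
#' @param nb_size Negative-binomial dispersion of GeneID counts.
#' @param copy_meanlog,copy_sdlog Log-normal parameters of Estimated Copy.
#' @param latent_loading Loading of the shared habitat-quality field on each
#'   KO's latent (spatial clustering of gene detections).
#' @param operon_loading Loading of a shared per-operon latent (genes of one
#'   operon tend to co-occur).
#' @param covariates A tibble with columns `variable`, `rho` (target copula
#'   correlation to the richness of `target_ko`; `NA` for purely spatial or
#'   noise covariates), `target_ko`, and `marginal` (one of `"ph"`,
#'   `"lognormal_pct"`, `"count"`, `"gradient"`).
#' @param planted_rules List of planted implications, each a list with
#'   `variable`, `category` (a 3-bin label), `protein`, `obedience`
#'   (probability the implication is enforced in a matching sample).
#' @param catalog Catalog tibble.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 32,
                       prevalence = default_prevalence(),
                       nb_size = 1.5,
                       copy_meanlog = 0.25,
                       copy_sdlog = 0.6,
                       latent_loading = 0.55,
                       operon_loading = 0.45,
                       covariates = default_covariates(),
                       planted_rules = default_planted_rules(),
                       catalog = nitrogen_catalog()) {
  stopifnot(n_samples >= 3)
  if (any(is.na(prevalence) | prevalence < 0 | prevalence > 1)) {
    abort("prevalences must lie in [0, 1]")
  }
  if (any(!is.na(covariates$rho) & abs(covariates$rho) > 1)) {
    abort("target correlations must lie in [-1, 1]")
  }
  for (pr in planted_rules) {
    if (pr$obedience < 0 || pr$obedience > 1) {
      abort("rule obedience must lie in [0, 1]")
    }
  }
  if (latent_loading^2 + operon_loading^2 >= 1) {
    abort("latent loadings give a non-positive-definite latent structure")
  }
  structure(list(n_samples = n_samples, prevalence = prevalence,
                 nb_size = nb_size, copy_meanlog = copy_meanlog,
                 copy_sdlog = copy_sdlog, latent_loading = latent_loading,
                 operon_loading = operon_loading, covariates = covariates,
                 planted_rules = planted_rules, catalog = catalog),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_prevalence <- function() {
  c(
    # nitrate reduction / nitrite oxidation: ubiquitous
    K00370 = 0.95, K00371 = 0.95, K00374 = 0.95,
    K02567 = 0.60, K02568 = 0.16,         # napA common, napB rare
    K00367 = 0.00,                        # narB never detected
    K10534 = 0.19,                        # assimilatory NR sporadic
    K00372 = 0.97, K00360 = 0.90,         # nasAB nearly everywhere
    K00362 = 0.97, K00363 = 0.97,         # nirBD everywhere
    K03385 = 0.95, K15876 = 0.95,         # nrfAH everywhere
    K17877 = 0.30, K00366 = 0.97,         # NIT-6 sporadic, nirA ubiquitous
    K00368 = 0.97, K15864 = 0.34,         # nirK >> nirS
    K04561 = 0.94, K02305 = 0.53,         # norB > norC
    K00376 = 0.55,                        # nosZ patchy
    K02586 = 0.35, K02591 = 0.35, K02588 = 0.40,  # nifDKH patchy
    K00531 = 0.05,                        # anfG very rare
    K22896 = 0.03, K22897 = 0.03, K22898 = 0.03, K22899 = 0.03,
    K10944 = 0.75, K10945 = 0.75, K10946 = 0.75,  # amoCAB common
    K10535 = 0.16,                        # hao rare
    K20932 = 0.00, K20933 = 0.00, K20934 = 0.00, K20935 = 0.00  # anammox absent
  )
}

#' @rdname sim_config
#' @export
default_covariates <- function() {
  tibble::tribble(
    ~variable,          ~rho, ~target_ko, ~marginal,
    "pH",               -0.6, "K00368",   "ph",
    "soil_water",        0.6, "K00376",   "lognormal_pct",
    "nitrogen_pct",      0.5, "K02588",   "lognormal_pct",
    "taxa_richness",     0.55, "K02586",  "count",
    "carbon_pct",        NA,  NA,         "gradient",
    "biomass",           NA,  NA,         "gradient",
    "fungi_phylotypes",  NA,  NA,         "count",
    "rotifers",          NA,  NA,         "count"
  )
}

#' @rdname sim_config
#' @export
default_planted_rules <- function() {
  list(list(variable = "soil_water", category = ">70%",
            protein = "NosZ", obedience = 1))
}

# NB mean such that P(count >= 1) = prev for given dispersion
nb_mu_for_prevalence <- function(prev, size) {
  prev <- pmin(prev, 0.995)
  ifelse(prev <= 0, 0, size * ((1 - prev)^(-1 / size) - 1))
}

#' Generate a synthetic nitrogen-cycle survey
#'
#' Draws a full synthetic dataset in the formats the pipeline ingests:
#' per-sample gene records over the catalog KO alphabet, a metadata table
#' with covariates and planar coordinates, and a truth record storing every
#' planted parameter plus the realized statistics, so expected values can be
#' recomputed without re-sampling. The same seed reproduces the same output
#' exactly. The generator is a structural emulator of a survey of this
#' shape, not a statistical twin of any real dataset.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; fully determines the output.
#' @return A list with `records` (tibble `sample_id`, `gene_id`, `ko`,
#'   `estimated_copy`), `env` (tibble `sample_id`, `x`, `y`, covariates)
#'   and `truth` (list).
#' @export
generate_survey <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  n <- config$n_samples
  cat_tbl <- config$catalog
  kos <- cat_tbl$ko
  samples <- sprintf("S%02d", seq_len(n))

  # clustered site layout (meters): most sites near a "lake", the rest
  # scattered along the valley floor
  centers <- matrix(c(1000, 1200, 3500, 2600, 5200, 900, 2600, 3800),
                    ncol = 2, byrow = TRUE)
  ci <- rep_len(c(1, 1, 2, 3, 1, 4, 2, 3), n)   # cluster 1 over-represented
  x <- centers[ci, 1] + rnorm(n, 0, 450)
  y <- centers[ci, 2] + rnorm(n, 0, 450)
  while (anyDuplicated(cbind(x, y))) {          # vanishing probability
    x <- x + rnorm(n, 0, 1)
  }

  # habitat-quality field: smooth bump centered on the lake cluster
  bump <- exp(-((x - 1000)^2 + (y - 1200)^2) / (2 * 1800^2))
  quality <- as.numeric(scale(bump + rnorm(n, 0, 0.35)))

  # per-KO latent -> NB richness via Gaussian copula
  prev <- config$prevalence[kos]
  prev[is.na(prev)] <- 0.5
  mu <- nb_mu_for_prevalence(prev, config$nb_size)
  aL <- config$latent_loading
  aP <- config$operon_loading
  resid <- sqrt(1 - aL^2 - aP^2)
  operon_latent <- matrix(rnorm(n * length(unique(cat_tbl$protein))), nrow = n,
                          dimnames = list(NULL, unique(cat_tbl$protein)))
  z <- matrix(NA_real_, n, length(kos), dimnames = list(samples, kos))
  counts <- z
  for (j in seq_along(kos)) {
    zj <- aL * quality + aP * operon_latent[, cat_tbl$protein[j]] +
      resid * rnorm(n)
    z[, j] <- zj
    counts[, j] <- qnbinom(pnorm(zj), size = config$nb_size, mu = mu[j])
  }

  # covariates: copula-coupled to a KO's latent, or spatial/noise marginals
  env <- tibble::tibble(sample_id = samples, x = x, y = y)
  cov_spec <- config$covariates
  for (i in seq_len(nrow(cov_spec))) {
    v <- cov_spec$variable[i]
    rho <- cov_spec$rho[i]
    lat <- if (!is.na(rho)) {
      rho * z[, cov_spec$target_ko[i]] + sqrt(1 - rho^2) * rnorm(n)
    } else if (cov_spec$marginal[i] == "gradient") {
      as.numeric(scale(bump)) + 0.5 * rnorm(n)
    } else {
      rnorm(n)
    }
    env[[v]] <- unname(switch(
      cov_spec$marginal[i],
      ph = pmin(pmax(8.6 + 0.55 * lat, 7.4), 9.7),
      lognormal_pct = exp(log(2) + 0.8 * lat),
      count = pmax(0L, as.integer(round(12 + 6 * lat))),
      gradient = exp(0.9 + 0.7 * lat),
      abort(paste0("unknown marginal: ", cov_spec$marginal[i]))
    ))
  }

  # planted rules: force operon completeness where the antecedent holds
  planted <- list()
  for (pr in config$planted_rules) {
    cats <- discretize(env[[pr$variable]], bins = 3)
    match_idx <- which(!is.na(cats) & cats == pr$category)
    enforce <- match_idx[runif(length(match_idx)) <= pr$obedience]
    members <- cat_tbl$ko[cat_tbl$protein == pr$protein]
    counts[enforce, members] <- pmax(counts[enforce, members, drop = FALSE], 1)
    planted <- c(planted, list(c(pr, list(n_antecedent = length(match_idx),
                                          n_enforced = length(enforce)))))
  }

  # expand counts to GeneID records with log-normal Estimated Copy
  idx <- which(counts > 0, arr.ind = TRUE)
  reps <- counts[idx]
  srow <- rep(idx[, 1], reps)
  kcol <- rep(idx[, 2], reps)
  gnum <- sequence(reps)
  records <- tibble::tibble(
    sample_id = samples[srow],
    gene_id = paste0(samples[srow], "_", kos[kcol], "_g",
                     formatC(gnum, width = 3, flag = "0")),
    ko = kos[kcol],
    estimated_copy = rlnorm(length(srow), config$copy_meanlog, config$copy_sdlog)
  )
  records <- records[order(records$sample_id, records$ko, records$gene_id), ]

  realized_rho <- purrr::pmap_dbl(
    cov_spec, function(variable, rho, target_ko, marginal) {
      if (is.na(rho)) return(NA_real_)
      suppressWarnings(stats::cor(env[[variable]], counts[, target_ko]))
    })

  truth <- list(
    seed = as.integer(seed),
    n_samples = n,
    prevalence_target = as.list(prev),
    nb_size = config$nb_size,
    nb_mu = as.list(setNames(mu, kos)),
    copy_meanlog = config$copy_meanlog,
    copy_sdlog = config$copy_sdlog,
    covariates = lapply(seq_len(nrow(cov_spec)), function(i) {
      list(variable = cov_spec$variable[i], rho_target = cov_spec$rho[i],
           target_ko = cov_spec$target_ko[i],
           rho_realized = realized_rho[i])
    }),
    planted_rules = planted,
    richness_matrix = counts
  )
  list(records = records, env = env, truth = truth)
}

#' Write a synthetic survey to disk
#'
#' Emits the on-disk layout the readers expect: one gene-record TSV per
#' sample plus a `manifest.csv`, a metadata CSV, and the truth record as
#' YAML.
#'
#' @param survey Output of [generate_survey()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- unique(survey$env$sample_id)
  paths <- file.path(dir, paste0(samples, "_genes.tsv"))
  for (i in seq_along(samples)) {
    rec <- survey$records[survey$records$sample_id == samples[i],
                          c("gene_id", "ko", "estimated_copy")]
    readr::write_tsv(rec, paths[i], progress = FALSE)
  }
  readr::write_csv(tibble::tibble(sample_id = samples,
                                  path = basename(paths)),
                   file.path(dir, "manifest.csv"), progress = FALSE)
  readr::write_csv(survey$env, file.path(dir, "env.csv"), na = "",
                   progress = FALSE)
  truth <- survey$truth
  truth$richness_matrix <- NULL        # large; recomputable from the records
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' A tiny deterministic fixture dataset
#'
#' Eight samples by six detected KOs with hand-checkable values (e.g. sample
#' S1 carries nirK GeneIDs with Estimated Copy 1.0, 2.5 and 3.0, so its nirK
#' abundance is 6.5, richness 3 and variance 1.0833...). Coordinates form a
#' convex layout suitable for triangulation. Used in documentation and
#' tests; no randomness involved.
#'
#' @return A list with `records` and `env` tibbles.
#' @export
fixture_small <- function() {
  rec <- function(s, ko, copies) {
    tibble::tibble(sample_id = s,
                   gene_id = paste0(s, "_", ko, "_g", seq_along(copies)),
                   ko = ko, estimated_copy = copies)
  }
  records <- dplyr::bind_rows(
    # nirK: worked-example numbers in S1; present everywhere except S8
    rec("S1", "K00368", c(1.0, 2.5, 3.0)),
    rec("S2", "K00368", c(2.0, 2.0)),
    rec("S3", "K00368", 4.0),
    rec("S4", "K00368", c(1.5, 0.5)),
    rec("S5", "K00368", c(1.0, 1.0, 1.0, 1.0)),
    rec("S6", "K00368", 2.5),
    rec("S7", "K00368", c(3.0, 1.0)),
    # nosZ: present in half the sites
    rec("S1", "K00376", c(2.0, 1.0)),
    rec("S2", "K00376", 1.0),
    rec("S5", "K00376", c(1.0, 4.0)),
    rec("S7", "K00376", 2.0),
    # nifDKH: complete operon only in S1 and S5; nifH alone in S3
    rec("S1", "K02586", 1.0), rec("S1", "K02591", 1.5), rec("S1", "K02588", 2.0),
    rec("S5", "K02586", 2.0), rec("S5", "K02591", 1.0), rec("S5", "K02588", 1.0),
    rec("S3", "K02588", 3.0),
    # hao: rare
    rec("S2", "K10535", 1.0)
  )
  env <- tibble::tibble(
    sample_id = paste0("S", 1:8),
    x = c(0, 100, 200, 40, 160, 90, 10, 190),
    y = c(0, 10, 0, 90, 80, 170, 150, 160),
    pH = c(8.1, 8.4, 9.2, 7.8, 8.0, 9.5, 8.6, 9.0),
    soil_water = c(6.0, 4.5, 1.0, 8.0, 7.0, 0.8, 5.0, 1.5),
    taxa_richness = c(25, 18, 7, 30, 28, 5, 20, NA)
  )
  list(records = records, env = env)
}
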