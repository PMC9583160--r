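#' Encode samples as transactions
#'
#' Each sample becomes one transaction: the set of its discretized covariate
#' items plus one `Protein=Present` / `Protein=Absent` item per catalog
#' protein. Item tokens are `variable=category` strings, so a transaction
#' contains at most one item per variable. Samples missing a covariate
#' simply lack that variable's item; whether covariate *absence* should
#' instead be an explicit item of its own is controlled by
#' `missing_as_item` (off by default).
#'
#' @param disc Output of [discretize_env()] (or any tibble with columns
#'   `sample_id`, `variable`, `category` passed as `disc$items`).
#' @param presence Presence tibble from [call_protein_presence()]; may be
#'   `NULL` to mine covariates alone.
#' @param missing_as_item Emit `variable=Missing` items for samples lacking
#'   a covariate value.
#' @return A `transaction_db`: list with `transactions` (named list of
#'   character item vectors), `items` (the alphabet) and `n`.
#' @export
build_transactions <- function(disc, presence = NULL, missing_as_item = FALSE) {
  items <- if (is.data.frame(disc)) disc else disc$items
  stopifnot(all(c("sample_id", "variable", "category") %in% names(items)))
  long <- dplyr::transmute(items, sample_id = .data$sample_id,
                           token = paste0(.data$variable, "=", .data$category))
  samples <- unique(items$sample_id)
  if (!is.null(presence)) {
    shared <- check_sample_overlap(presence$sample_id, items$sample_id,
                                   "presence calls", "covariate items")
    pres <- dplyr::transmute(
      presence, sample_id = .data$sample_id,
      token = paste0(.data$protein, "=",
                     ifelse(.data$present, "Present", "Absent")))
    long <- dplyr::bind_rows(long, pres)
    samples <- union(samples, presence$sample_id)
  }
  if (missing_as_item) {
    vars <- unique(items$variable)
    have <- dplyr::distinct(items, .data$sample_id, .data$variable)
    miss <- tidyr::expand_grid(sample_id = samples, variable = vars) |>
      dplyr::anti_join(have, by = c("sample_id", "variable")) |>
      dplyr::transmute(sample_id = .data$sample_id,
                       token = paste0(.data$variable, "=Missing"))
    long <- dplyr::bind_rows(long, miss)
  }
  if (anyDuplicated(long[, c("sample_id", "token")])) {
    abort("a transaction may contain at most one item per variable")
  }
  tx <- split(long$token, factor(long$sample_id, levels = sort(samples)))
  tx <- lapply(tx, function(t) sort(unique(t)))
  structure(list(transactions = tx, items = sort(unique(long$token)),
                 n = length(tx)),
            class = "transaction_db")
}

#' @export
print.transaction_db <- function(x, ...) {
  cat("transaction_db: ", x$n, " transactions, ", length(x$items),
      " distinct items\n", sep = "")
  invisible(x)
}

#' Export transactions in basket format
#'
#' One line per sample, comma-separated `variable=category` tokens.
#'
#' @param db A `transaction_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_basket <- function(db, path) {
  writeLines(vapply(db$transactions, paste, "", collapse = ","), path)
  invisible(path)
}

itemset_key <- function(ids) paste(ids, collapse = " ")

#' Frequent item-sets by level-wise Apriori
#'
#' Classic Apriori: frequent 1-item-sets first, then candidate k-item-sets
#' generated by joining frequent (k−1)-sets that share a prefix, pruned by
#' downward closure (every (k−1)-subset must itself be frequent) before
#' their support is counted. Support of an item-set is the fraction of
#' transactions containing all of its items. Returns exactly the item-sets
#' with support ≥ `min_support`.
#'
#' @param db A `transaction_db` from [build_transactions()].
#' @param min_support Minimum support, in (0, 1].
#' @param max_len Maximum item-set size to expand to (bounds the lattice).
#' @return A tibble with `items` (list of character vectors, sorted),
#'   `size`, `count` (transactions containing the set) and `support`
#'   (`count / n`); attribute `n_transactions`.
#' @export
mine_frequent_itemsets <- function(db, min_support, max_len = Inf) {
  stopifnot(inherits(db, "transaction_db"))
  if (!is.numeric(min_support) || length(min_support) != 1 ||
      min_support <= 0 || min_support > 1) {
    abort("min_support must be a number in (0, 1]")
  }
  n <- db$n
  alphabet <- db$items
  empty <- tibble::tibble(items = list(), size = integer(),
                          count = integer(), support = numeric())
  attr(empty, "n_transactions") <- n
  if (length(alphabet) == 0) return(empty)

  # membership matrix: transactions x items (logical), so the support of a
  # joined candidate is a vectorized AND of its parents' columns
  memb <- matrix(FALSE, n, length(alphabet))
  for (i in seq_along(db$transactions)) {
    memb[i, match(db$transactions[[i]], alphabet)] <- TRUE
  }

  out_sets <- list(); out_count <- integer(0)
  # level 1
  counts1 <- colSums(memb)
  f1 <- which(counts1 / n >= min_support)
  level <- lapply(f1, identity)          # list of integer vectors (size 1)
  level_tid <- lapply(f1, function(j) memb[, j])
  out_sets <- c(out_sets, lapply(f1, identity))
  out_count <- c(out_count, counts1[f1])

  k <- 1L
  freq_keys <- new.env(parent = emptyenv())
  for (s in level) assign(itemset_key(s), TRUE, envir = freq_keys)

  while (length(level) > 1 && k < max_len) {
    # join step: pairs sharing the first k-1 items
    prefixes <- vapply(level, function(s) itemset_key(s[-length(s)]), "")
    cand <- list(); cand_tid <- list()
    groups <- split(seq_along(level), prefixes)
    for (g in groups) {
      if (length(g) < 2) next
      for (a in seq_len(length(g) - 1)) {
        for (b in seq(a + 1, length(g))) {
          ia <- g[a]; ib <- g[b]
          new_set <- sort(union(level[[ia]], level[[ib]]))
          # prune: all k-subsets must be frequent
          ok <- all(vapply(seq_along(new_set), function(d) {
            exists(itemset_key(new_set[-d]), envir = freq_keys)
          }, logical(1)))
          if (!ok) next
          tid <- level_tid[[ia]] & level_tid[[ib]]
          if (sum(tid) / n >= min_support) {
            cand[[length(cand) + 1L]] <- new_set
            cand_tid[[length(cand_tid) + 1L]] <- tid
          }
        }
      }
    }
    if (length(cand) == 0) break
    # joining different pairs can produce the same set; keep one copy
    keys <- vapply(cand, itemset_key, "")
    keep <- !duplicated(keys)
    cand <- cand[keep]; cand_tid <- cand_tid[keep]
    for (s in cand) assign(itemset_key(s), TRUE, envir = freq_keys)
    out_sets <- c(out_sets, cand)
    out_count <- c(out_count, vapply(cand_tid, function(t) sum(t), 0))
    level <- cand; level_tid <- cand_tid
    k <- k + 1L
  }

  res <- tibble::tibble(
    items = lapply(out_sets, function(ids) alphabet[ids]),
    size = lengths(out_sets),
    count = as.integer(out_count),
    support = out_count / n
  )
  res <- res[order(res$size, -res$support), ]
  attr(res, "n_transactions") <- n
  res
}

#' Mine association rules
#'
#' Runs [mine_frequent_itemsets()] and partitions each frequent item-set of
#' size ≥ 2 into antecedent ⇒ consequent rules. A rule is emitted when its
#' confidence (support of the whole set divided by support of the
#' antecedent — the conditional frequency of the consequent given the
#' antecedent) reaches `min_confidence`. Lift divides confidence by the
#' consequent's own support; 1 means antecedent and consequent are
#' independent, larger values mean the antecedent raises the probability of
#' the consequent.
#'
#' @param db A `transaction_db`.
#' @param min_support Minimum rule support (joint frequency of antecedent
#'   and consequent over all transactions), in (0, 1].
#' @param min_confidence Minimum confidence, in (0, 1].
#' @param consequent_filter Restrict which items may appear in a consequent:
#'   `NULL` (any), a regular expression matched against item tokens (e.g.
#'   `"=Present$|=Absent$"` for operon-presence consequents), or a predicate
#'   function.
#' @param max_antecedent Maximum number of items in an antecedent.
#' @param max_consequent Maximum number of items in a consequent (default 1,
#'   the convention of operon-presence rule figures).
#' @return A `rule_set` tibble: `antecedent` (list-column of tokens),
#'   `consequent` (list-column), `support`, `confidence`, `lift`,
#'   `n_antecedent`, `n_consequent`, `n_both`; attributes carry the mining
#'   parameters. Ranked by lift, then support.
#' @export
mine_rules <- function(db, min_support = 0.1, min_confidence = 0.8,
                       consequent_filter = NULL, max_antecedent = 10,
                       max_consequent = 1) {
  if (min_confidence <= 0 || min_confidence > 1) {
    abort("min_confidence must be in (0, 1]")
  }
  freq <- mine_frequent_itemsets(db, min_support,
                                 max_len = max_antecedent + max_consequent)
  n <- attr(freq, "n_transactions")
  supp <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(freq))) {
    assign(itemset_key(freq$items[[i]]), freq$count[i], envir = supp)
  }
  admissible <- function(item) {
    if (is.null(consequent_filter)) return(TRUE)
    if (is.function(consequent_filter)) return(isTRUE(consequent_filter(item)))
    grepl(consequent_filter, item)
  }

  ante_l <- list(); cons_l <- list()
  n_ante_v <- integer(0); n_cons_v <- integer(0); n_both_v <- integer(0)
  admissible_item <- vapply(db$items, admissible, logical(1))
  names(admissible_item) <- db$items
  big <- freq[freq$size >= 2, ]
  for (i in seq_len(nrow(big))) {
    set <- big$items[[i]]
    n_both <- big$count[i]
    sz <- length(set)
    for (csize in seq_len(min(max_consequent, sz - 1))) {
      cons_idx <- utils::combn(sz, csize, simplify = FALSE)
      for (ci in cons_idx) {
        cons <- set[ci]
        if (!all(admissible_item[cons])) next
        ante <- set[-ci]
        if (length(ante) > max_antecedent) next
        n_ante <- get(itemset_key(ante), envir = supp)
        if (n_both / n_ante < min_confidence) next
        n_cons <- get(itemset_key(cons), envir = supp)
        if (n_cons == 0) {
          inform("dropping rule with zero-support consequent (lift undefined)")
          next
        }
        j <- length(ante_l) + 1L
        ante_l[[j]] <- ante; cons_l[[j]] <- cons
        n_ante_v[j] <- n_ante; n_cons_v[j] <- n_cons; n_both_v[j] <- n_both
      }
    }
  }
  res <- tibble::tibble(
    antecedent = ante_l, consequent = cons_l,
    support = n_both_v / n, confidence = n_both_v / n_ante_v,
    lift = (n_both_v / n_ante_v) / (n_cons_v / n),
    n_antecedent = n_ante_v, n_consequent = n_cons_v, n_both = n_both_v
  )
  res <- res[order(-res$lift, -res$support), ]
  structure(res,
            class = c("rule_set", class(res)),
            n_transactions = n,
            params = list(min_support = min_support,
                          min_confidence = min_confidence,
                          max_antecedent = max_antecedent,
                          max_consequent = max_consequent))
}

#' @export
tidy.rule_set <- function(x, ...) {
  tibble::tibble(
    antecedent = vapply(x$antecedent, paste, "", collapse = ","),
    consequent = vapply(x$consequent, paste, "", collapse = ","),
    support = x$support, confidence = x$confidence, lift = x$lift,
    n_antecedent = x$n_antecedent, n_both = x$n_both
  )
}

#' @export
glance.rule_set <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_rules = nrow(x),
    n_transactions = attr(x, "n_transactions"),
    min_support = p$min_support,
    min_confidence = p$min_confidence,
    max_antecedent = p$max_antecedent,
    mean_lift = if (nrow(x) > 0) mean(x$lift) else NA_real_
  )
}

#' Group rules by their consequent
#'
#' Arranges single-consequent rules into a consequents-by-antecedents grid
#' (rows: e.g. `NosZ=Present`; columns: distinct antecedents) carrying
#' support and lift per cell — the tabular form of a clustered rule figure.
#'
#' @param rules A `rule_set` with single-item consequents.
#' @return A tibble `consequent`, `antecedent`, `support`, `lift` with class
#'   `rule_matrix`; [autoplot()] draws the bubble grid (size = support,
#'   color = lift).
#' @export
group_rules_by_consequent <- function(rules) {
  if (any(lengths(rules$consequent) != 1)) {
    abort("group_rules_by_consequent() needs single-item consequents")
  }
  out <- tibble::tibble(
    consequent = vapply(rules$consequent, identity, ""),
    antecedent = vapply(rules$antecedent, paste, "", collapse = ","),
    support = rules$support, lift = rules$lift
  )
  structure(out, class = c("rule_matrix", class(out)))
}

#' @export
autoplot.rule_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$antecedent,
                                       y = .data$consequent,
                                       size = .data$support,
                                       color = .data$lift)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(x = "antecedent", y = "consequent") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Export mined rules as TSV
#'
#' @param rules A `rule_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rules_tsv <- function(rules, path) {
  readr::write_tsv(tidy(rules), path, progress = FALSE)
  invisible(path)
}

#' Read or write a mining configuration block
#'
#' A YAML record of the discretization and mining parameters (bins per
#' variable, support/confidence thresholds, antecedent cap, consequent
#' filter) so a mining run can be repeated from its config.
#'
#' @param path YAML path.
#' @param config A named list, e.g.
#'   `list(bins = list(pH = 3), min_support = 0.1, min_confidence = 0.8,
#'   max_antecedent = 10, consequent_filter = "=Present$|=Absent$")`.
#' @return `read_mining_config()` the list; `write_mining_config()` the
#'   path, invisibly.
#' @export
write_mining_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_mining_config
#' @export
read_mining_config <- function(path) {
  yaml::read_yaml(path)
}
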