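# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms than the package code:
# record-by-record accumulation for the metrics, bitmask subset enumeration
# for frequent item-sets, and closed-form formulas for Pearson.

# brute-force per-(sample, KO) metrics by scanning the records once per cell
oracle_metrics <- function(records, kos, samples) {
  n_cells <- length(samples) * length(kos)
  s_out <- character(n_cells); k_out <- character(n_cells)
  ab <- numeric(n_cells); ri <- integer(n_cells); va <- rep(NA_real_, n_cells)
  cell <- 0L
  for (s in samples) {
    for (k in kos) {
      cell <- cell + 1L
      hit <- records$sample_id == s & records$ko == k
      copies <- records$estimated_copy[hit]
      s_out[cell] <- s; k_out[cell] <- k
      ab[cell] <- if (length(copies)) sum(copies) else 0
      ri[cell] <- length(unique(records$gene_id[hit]))
      if (length(copies) >= 2) va[cell] <- stats::var(copies)
    }
  }
  tibble::tibble(sample_id = s_out, ko = k_out, abundance = ab,
                 richness = ri, variance = va)
}

# exhaustive frequent-item-set enumeration over all 2^k - 1 subsets,
# counting support through integer bitmasks (k <= 12)
oracle_frequent_itemsets <- function(transactions, min_support) {
  alphabet <- sort(unique(unlist(transactions)))
  k <- length(alphabet)
  stopifnot(k <= 12)
  n <- length(transactions)
  if (k == 0 || n == 0) {
    return(tibble::tibble(key = character(), count = integer(),
                          support = numeric()))
  }
  tx_mask <- vapply(transactions, function(t) {
    sum(bitwShiftL(1L, match(t, alphabet) - 1L))
  }, 0L)
  masks <- seq_len(2^k - 1)
  counts <- vapply(masks, function(m) {
    sum(bitwAnd(tx_mask, m) == m)
  }, 0L)
  keep <- counts / n >= min_support
  keys <- vapply(masks[keep], function(m) {
    paste(alphabet[bitwAnd(bitwShiftL(1L, seq_len(k) - 1L), m) != 0],
          collapse = " ")
  }, "")
  tibble::tibble(key = keys, count = counts[keep],
                 support = counts[keep] / n)
}

# exhaustive rule enumeration (single-item consequents) from the oracle's
# frequent sets
oracle_rules <- function(transactions, min_support, min_confidence) {
  n <- length(transactions)
  fi <- oracle_frequent_itemsets(transactions, min_support)
  supp <- stats::setNames(fi$count, fi$key)
  rows <- list()
  for (key in fi$key) {
    set <- strsplit(key, " ")[[1]]
    if (length(set) < 2) next
    for (ci in seq_along(set)) {
      cons <- set[ci]
      ante <- set[-ci]
      n_ante <- supp[[paste(ante, collapse = " ")]]
      n_both <- supp[[key]]
      conf <- n_both / n_ante
      if (conf < min_confidence) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        rule = paste(paste(ante, collapse = ","), "=>", cons),
        support = n_both / n, confidence = conf,
        lift = conf / (supp[[cons]] / n)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(rule = character(), support = numeric(),
                          confidence = numeric(), lift = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), rule)
}

# random transaction database over a small alphabet
random_db <- function(n_items, n_tx, p = 0.4) {
  alphabet <- paste0("i", seq_len(n_items))
  tx <- lapply(seq_len(n_tx), function(i) {
    t <- alphabet[stats::runif(n_items) < p]
    if (length(t) == 0) t <- sample(alphabet, 1)
    sort(t)
  })
  names(tx) <- paste0("T", seq_len(n_tx))
  tx
}

# wrap a plain list of item vectors as a transaction_db
as_tdb <- function(tx) {
  structure(list(transactions = tx, items = sort(unique(unlist(tx))),
                 n = length(tx)),
            class = "transaction_db")
}

# normalize a frequent-itemset table to oracle keys for comparison
itemsets_as_keys <- function(fi) {
  tibble::tibble(
    key = vapply(fi$items, function(it) paste(sort(it), collapse = " "), ""),
    count = fi$count, support = fi$support
  ) |> dplyr::arrange(key)
}

rules_as_keys <- function(rules) {
  tibble::tibble(
    rule = paste(
      vapply(rules$antecedent, function(a) paste(sort(a), collapse = ","), ""),
      "=>", vapply(rules$consequent, paste, "", collapse = ",")),
    support = rules$support, confidence = rules$confidence, lift = rules$lift
  ) |> dplyr::arrange(rule)
}

# closed-form Pearson r
oracle_r <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# point-in-convex-polygon test, independent of the triangulation code
oracle_in_hull <- function(px, py, hx, hy) {
  mgcv::in.out(rbind(cbind(hx, hy), c(hx[1], hy[1])), cbind(px, py))
}
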