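test_that("quantile discretization matches the declared percentile rule", {
  # 1..10, 3 bins: cuts at the 30th/70th percentiles (3.7, 7.3)
  d <- discretize(1:10, bins = 3)
  expect_equal(attr(d, "cuts"), c(3.7, 7.3))
  expect_equal(d[1:3], rep("<30%", 3))
  expect_equal(d[4:7], rep("30-70%", 4))
  expect_equal(d[8:10], rep(">70%", 3))

  # values equal to a cut point fall in the lower bin: for 0..10 the
  # percentile cuts land exactly on the data values 3 and 7
  d2 <- discretize(0:10, bins = 3)
  expect_equal(attr(d2, "cuts"), c(3, 7))
  expect_equal(unclass(d2)[4], "<30%", ignore_attr = TRUE)
  expect_equal(unclass(d2)[8], "30-70%", ignore_attr = TRUE)

  # 2-bin split at the median
  d3 <- discretize(1:4, bins = 2)
  expect_equal(attr(d3, "cuts"), 2.5)
  expect_equal(unclass(d3), c("<50%", "<50%", ">50%", ">50%"),
               ignore_attr = TRUE)

  # constant vector is degenerate; missing values emit no category
  dc <- discretize(rep(1, 5))
  expect_true(attr(dc, "degenerate"))
  dm <- discretize(c(1, NA, 3, 10))
  expect_true(is.na(dm[2]))

  env <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                        pH = c(7, 8, 9, 10), flat = rep(1, 4),
                        gap = c(1, NA, 3, 4))
  disc <- suppressMessages(discretize_env(env, bins = 3))
  expect_false("flat" %in% disc$items$variable)
  expect_true(disc$cuts$degenerate[disc$cuts$variable == "flat"])
  expect_equal(sum(disc$items$variable == "gap"), 3)  # no item for the NA
})

test_that("samples become transactions of at most one item per variable", {
  env <- tibble::tibble(sample_id = paste0("S", 1:9),
                        pH = c(1:9), water = c(9:1))
  env$water[4] <- NA
  disc <- discretize_env(env, bins = 3)
  presence <- tibble::tibble(sample_id = rep(paste0("S", 1:9), 2),
                             protein = rep(c("NosZ", "NirK"), each = 9),
                             present = rep(c(TRUE, FALSE), length.out = 18))
  db <- build_transactions(disc, presence)
  expect_equal(db$n, 9)
  expect_true(all(lengths(db$transactions) <= 2 + 2))
  expect_true("pH=>70%" %in% db$transactions[["S8"]])
  expect_false(any(grepl("^water=", db$transactions[["S4"]])))
  vars <- lapply(db$transactions, function(t) sub("=.*", "", t))
  expect_true(all(vapply(vars, anyDuplicated, 0L) == 0))

  # optional explicit missing item
  db2 <- build_transactions(disc, presence, missing_as_item = TRUE)
  expect_true("water=Missing" %in% db2$transactions[["S4"]])

  bask <- withr::local_tempfile(fileext = ".txt")
  write_basket(db, bask)
  expect_equal(length(readLines(bask)), 9)
})

test_that("the worked four-transaction example mines exactly as enumerated", {
  db <- as_tdb(list(T1 = c("A", "B"), T2 = c("A", "B"), T3 = "A", T4 = "B"))
  fi <- mine_frequent_itemsets(db, min_support = 0.5)
  keys <- itemsets_as_keys(fi)           # arranged by key: A, A B, B
  expect_equal(keys$key, c("A", "A B", "B"))
  expect_equal(keys$support, c(0.75, 0.5, 0.75))

  # min_support = 1: only item-sets in every transaction
  all_tx <- as_tdb(list(c("A", "B"), c("A", "B", "C"), c("A", "B")))
  fi1 <- mine_frequent_itemsets(all_tx, min_support = 1)
  expect_setequal(itemsets_as_keys(fi1)$key, c("A", "B", "A B"))

  # empty alphabet
  expect_equal(nrow(mine_frequent_itemsets(
    structure(list(transactions = list(), items = character(), n = 0L),
              class = "transaction_db"), 0.5)), 0)

  expect_error(mine_frequent_itemsets(db, 0), "min_support")
  expect_error(mine_frequent_itemsets(db, 1.5), "min_support")
})

test_that("apriori equals exhaustive enumeration on random databases", {
  withr::local_seed(42)
  for (case in 1:60) {
    tx <- random_db(n_items = sample(4:12, 1), n_tx = sample(5:40, 1),
                    p = stats::runif(1, 0.2, 0.6))
    ms <- sample(c(0.1, 0.2, 0.3, 0.5), 1)
    fi <- mine_frequent_itemsets(as_tdb(tx), ms)
    expect_equal(itemsets_as_keys(fi),
                 dplyr::arrange(oracle_frequent_itemsets(tx, ms), key),
                 ignore_attr = TRUE)
  }
})

test_that("every subset of a frequent item-set is itself frequent", {
  withr::local_seed(11)
  tx <- random_db(10, 30, p = 0.5)
  fi <- mine_frequent_itemsets(as_tdb(tx), 0.2)
  keys <- itemsets_as_keys(fi)$key
  for (k in keys) {
    set <- strsplit(k, " ")[[1]]
    if (length(set) < 2) next
    for (d in seq_along(set)) {
      expect_true(paste(set[-d], collapse = " ") %in% keys)
    }
  }
})

test_that("rule statistics obey their identities and match enumeration", {
  withr::local_seed(99)
  supp_of <- function(fi) {
    k <- itemsets_as_keys(fi)
    stats::setNames(k$support, k$key)
  }
  for (case in 1:20) {
    tx <- random_db(sample(4:10, 1), sample(8:40, 1), p = 0.5)
    db <- as_tdb(tx)
    rs <- mine_rules(db, min_support = 0.2, min_confidence = 0.5,
                     max_antecedent = 12)
    expect_equal(rules_as_keys(rs)[, c("rule", "support", "confidence", "lift")],
                 oracle_rules(tx, 0.2, 0.5), ignore_attr = TRUE,
                 tolerance = 1e-12)
    fi <- mine_frequent_itemsets(db, 0.2)
    supp <- supp_of(fi)
    n <- db$n
    for (i in seq_len(nrow(rs))) {
      a_key <- paste(sort(rs$antecedent[[i]]), collapse = " ")
      c_key <- paste(sort(rs$consequent[[i]]), collapse = " ")
      expect_lte(rs$support[i], min(supp[[a_key]], supp[[c_key]]) + 1e-15)
      expect_equal(rs$confidence[i], rs$n_both[i] / rs$n_antecedent[i])
      expect_equal(rs$lift[i] * supp[[c_key]], rs$confidence[i],
                   tolerance = 1e-12)
      expect_lte(rs$support[i], rs$confidence[i] + 1e-15)
    }
  }
})

test_that("consequent filters and caps restrict the rule space", {
  db <- as_tdb(list(c("pH=<30%", "NosZ=Present", "w=>70%"),
                    c("pH=<30%", "NosZ=Present"),
                    c("pH=<30%", "NosZ=Absent"),
                    c("w=>70%", "NosZ=Present")))
  rs <- mine_rules(db, min_support = 0.25, min_confidence = 0.5,
                   consequent_filter = "=Present$|=Absent$")
  cons <- unlist(rs$consequent)
  expect_true(all(grepl("=Present$|=Absent$", cons)))
  rs1 <- mine_rules(db, min_support = 0.25, min_confidence = 0.5,
                    max_antecedent = 1)
  expect_true(all(lengths(rs1$antecedent) <= 1))
  expect_error(mine_rules(db, min_support = 0.25, min_confidence = 0), "min_confidence")
})

test_that("rules group by consequent into a support/lift grid", {
  db <- as_tdb(list(c("a=1", "P=Present"), c("a=1", "P=Present"),
                    c("b=1", "P=Present"), c("b=1", "Q=Present")))
  rs <- mine_rules(db, min_support = 0.25, min_confidence = 0.5,
                   consequent_filter = "Present$")
  grid <- group_rules_by_consequent(rs)
  expect_true(all(c("consequent", "antecedent", "support", "lift") %in%
                    names(grid)))
  expect_gte(length(unique(grid$consequent)), 2)

  empty <- mine_rules(db, min_support = 1, min_confidence = 1)
  expect_equal(nrow(group_rules_by_consequent(empty)), 0)
})
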