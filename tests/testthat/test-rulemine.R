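# Apriori mining and rule induction, checked against exhaustive
# enumeration and hand-computed supports.

test_that("the worked six-transaction database mines exactly as computed by hand", {
  db <- list(c("kettle", "fridge"), c("kettle", "fridge", "toaster"),
             c("kettle", "toaster"), "fridge", c("kettle", "fridge"),
             "wardrobe")
  freq <- frequent_itemsets(db, 0.3)
  got <- itemset_key(freq$items, freq$support)
  want <- itemset_key(
    list("fridge", "kettle", "toaster", c("fridge", "kettle"),
         c("kettle", "toaster")),
    c(4 / 6, 4 / 6, 2 / 6, 3 / 6, 2 / 6))
  expect_setequal(got, want)
})

test_that("near-unanimous support returns only the ubiquitous singleton", {
  db <- list(c("a", "b"), c("a", "c"), c("a"), c("a", "b", "c"))
  freq <- frequent_itemsets(db, 0.999)
  expect_identical(freq$items, list("a"))
  expect_identical(freq$support, 1)
})

test_that("apriori equals exhaustive enumeration on random databases", {
  for (seed in 0:19) {
    db <- random_db(seed)
    min_s <- withr::with_seed(seed + 1000, runif(1, 0.05, 0.6))
    got <- frequent_itemsets(db, min_s)
    want <- brute_frequent(db, min_s)
    expect_setequal(
      itemset_key(got$items, got$support),
      itemset_key(lapply(want, `[[`, "items"),
                  vapply(want, `[[`, 0, "support")))
  }
  expect_error(frequent_itemsets(list(), 0.5),
               class = "adlminer_config_error")
})

test_that("downward closure holds on mined output", {
  db <- random_db(99, max_items = 8)
  freq <- frequent_itemsets(db, 0.1)
  supp <- stats::setNames(freq$support,
                          vapply(freq$items, paste, "", collapse = "|"))
  for (i in seq_len(nrow(freq))) {
    s <- freq$items[[i]]
    if (length(s) < 2) next
    for (j in seq_along(s)) {
      sub <- paste(s[-j], collapse = "|")
      expect_true(sub %in% names(supp))
      expect_lte(freq$support[i], supp[[sub]] + 1e-12)
    }
  }
})

make_tx <- function(item_sets, labels) {
  tibble::tibble(
    participant_id = "P01",
    window_start = utc("2023-03-01T00:00:00Z") + 300 * seq_along(item_sets),
    window_end = window_start + 3600,
    items = item_sets,
    label = labels
  )
}

test_that("a perfectly separable item yields a confidence-1 rule", {
  tx <- make_tx(c(replicate(10, "kettle", simplify = FALSE),
                  replicate(10, "wardrobe", simplify = FALSE)),
                c(rep("eating_drinking", 10), rep(NA, 10)))
  rules <- induce_rules(tx, "eating_drinking", mining_params(seed = 1))
  r <- rules[vapply(rules$antecedent, identical, TRUE, "kettle"), ]
  expect_identical(nrow(r), 1L)
  expect_identical(r$confidence, 1)
  expect_identical(r$support, 0.5)
  expect_identical(r$provenance, "P01")
})

test_that("a 90%-co-occurring item yields a confidence-0.9 rule", {
  # the tv item accompanies 9 of 10 positive windows and 1 negative
  pos <- c(replicate(9, c("breakfast_items", "tv_plug"), simplify = FALSE),
           list("breakfast_items"))
  neg <- c(list("tv_plug"), replicate(9, "wardrobe", simplify = FALSE))
  tx <- make_tx(c(pos, neg), c(rep("eating_drinking", 10), rep(NA, 10)))
  rules <- induce_rules(tx, "eating_drinking", mining_params(seed = 1))
  r <- rules[vapply(rules$antecedent, identical, TRUE, "tv_plug"), ]
  expect_equal(r$confidence, 0.9)
})

test_that("rule confidence recomputed from the mining database matches exactly", {
  cfg <- cohort_config(2, 7, seed = 21, annotation_days = 2)
  sim <- simulate_cohort(cfg)
  txs <- cohort_transactions(sim$events, sim$catalogs, sim$annotations)
  params <- mining_params(seed = 5)
  tx <- txs$eating_drinking$P01
  rules <- induce_rules(tx, "eating_drinking", params)
  expect_gt(nrow(rules), 0)
  db <- adlminer:::build_mining_db(tx, "eating_drinking",
                                   params$negative_sampling_ratio, params$seed)
  n <- length(db)
  for (i in seq_len(nrow(rules))) {
    x <- rules$antecedent[[i]]
    full <- c(x, "adl:eating_drinking")
    s_full <- mean(vapply(db, function(t) all(full %in% t), logical(1)))
    s_x <- mean(vapply(db, function(t) all(x %in% t), logical(1)))
    expect_equal(rules$support[i], s_full, tolerance = 1e-12)
    expect_equal(rules$confidence[i], s_full / s_x, tolerance = 1e-12)
  }
})

test_that("mining is deterministic with a stable rule ordering", {
  cfg <- cohort_config(2, 7, seed = 21, annotation_days = 2)
  sim <- simulate_cohort(cfg)
  txs <- cohort_transactions(sim$events, sim$catalogs, sim$annotations)
  p <- mining_params(seed = 3)
  r1 <- pool_rules(txs$dressing, "dressing", p)
  r2 <- pool_rules(txs$dressing, "dressing", p)
  expect_equal(r1, r2)
  sizes <- lengths(r1$antecedent)
  expect_true(all(diff(sizes) >= 0))
  keys <- vapply(r1$antecedent, paste, "", collapse = "|")
  for (k in unique(sizes)) {
    expect_false(is.unsorted(keys[sizes == k]))
  }
})

test_that("dominated supersets are pruned, antecedents exclude label tokens", {
  # "a" alone is a perfect predictor; {a, b} can do no better
  pos <- replicate(10, c("a", "b"), simplify = FALSE)
  neg <- replicate(10, "c", simplify = FALSE)
  tx <- make_tx(c(pos, neg), c(rep("dressing", 10), rep(NA, 10)))
  rules <- induce_rules(tx, "dressing", mining_params(seed = 1))
  expect_true(all(lengths(rules$antecedent) == 1))
  expect_setequal(vapply(rules$antecedent, paste, ""), c("a", "b"))
  expect_false(any(grepl("^adl:", unlist(rules$antecedent))))
})

test_that("mining without positives asks for more annotations", {
  tx <- make_tx(replicate(5, "kettle", simplify = FALSE), rep(NA, 5))
  expect_error(induce_rules(tx, "bathing"),
               class = "adlminer_no_training_error")
})

test_that("pooling homogeneous participants reproduces the per-participant rules", {
  mk <- function(pid) {
    tx <- make_tx(c(replicate(8, c("wardrobe", "drawer"), simplify = FALSE),
                    replicate(8, "kettle", simplify = FALSE)),
                  c(rep("dressing", 8), rep(NA, 8)))
    tx$participant_id <- pid
    tx
  }
  p <- mining_params(seed = 2)
  single <- induce_rules(mk("P01"), "dressing", p)
  pooled <- pool_rules(list(P01 = mk("P01"), P02 = mk("P02")), "dressing", p)
  expect_identical(unique(pooled$provenance), "pooled")
  key <- function(r) vapply(r$antecedent, paste, "", collapse = "|")
  expect_setequal(key(pooled), key(single))
  # fewer than two contributors: warning, then per-participant behaviour
  expect_warning(pool_rules(list(P01 = mk("P01")), "dressing", p),
                 "pooling degenerates")
})

test_that("mining parameter validation rejects out-of-range thresholds", {
  expect_error(mining_params(min_support = 0), class = "adlminer_config_error")
  expect_error(mining_params(min_confidence = 1.01),
               class = "adlminer_config_error")
  p <- mining_params()
  expect_identical(p$min_support, 0.15)
  expect_identical(p$min_confidence, 0.5)
})
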