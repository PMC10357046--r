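# Apriori frequent-itemset mining and per-ADL association rule induction.
#
# The mining database for one ADL consists of all labelled-positive windows
# (with the ADL label injected as an extra item token "adl:<label>") plus a
# seeded sample of unlabelled windows (negative_sampling_ratio per
# positive, without replacement). Support is the fraction of database
# transactions containing an itemset; confidence of X => adl is
# support(X + label) / support(X). Rules are emitted for every frequent
# itemset containing the label token whose antecedent is a nonempty set of
# sensor items, subject to min_confidence and max_antecedent_size, with
# dominated supersets (no confidence gain over a subset rule) pruned.

adl_item <- function(adl) paste0("adl:", adl)

#' Mining parameters
#'
#' @param min_support Minimum fraction of database transactions an itemset
#'   (antecedent plus ADL label) must occur in (default 0.15).
#' @param min_confidence Minimum rule confidence (default 0.5).
#' @param max_antecedent_size Largest antecedent emitted (default 4).
#' @param negative_sampling_ratio Unlabelled windows sampled per positive
#'   window when assembling the mining database (default 1).
#' @param seed Seed for the negative sample.
#' @return A `mining_params` list.
#' @export
mining_params <- function(min_support = 0.15, min_confidence = 0.5,
                          max_antecedent_size = 4,
                          negative_sampling_ratio = 1, seed = 1L) {
  if (!(min_support > 0 && min_support <= 1)) {
    abort("min_support must lie in (0, 1]", class = "adlminer_config_error")
  }
  if (!(min_confidence > 0 && min_confidence <= 1)) {
    abort("min_confidence must lie in (0, 1]", class = "adlminer_config_error")
  }
  stopifnot(max_antecedent_size >= 1, negative_sampling_ratio >= 0)
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 max_antecedent_size = max_antecedent_size,
                 negative_sampling_ratio = negative_sampling_ratio,
                 seed = as.integer(seed)),
            class = "mining_params")
}

#' Apriori frequent-itemset mining
#'
#' Level-wise candidate generation with downward-closure pruning: size-k
#' candidates are joined from frequent size-(k-1) itemsets sharing their
#' first k-2 (sorted) items, and a candidate is counted only if every
#' (k-1)-subset is frequent.
#'
#' @param transactions List of character vectors (item sets).
#' @param min_support Minimum support fraction in (0, 1].
#' @param max_size Optional cap on itemset size (default unlimited).
#' @return Tibble with list-column `items` (sorted) and `support`, ordered
#'   by (size, lexicographic items).
#' @export
frequent_itemsets <- function(transactions, min_support, max_size = Inf) {
  if (length(transactions) == 0) {
    abort("cannot mine an empty transaction list", class = "adlminer_config_error")
  }
  stopifnot(min_support > 0, min_support <= 1)
  n <- length(transactions)
  universe <- sort(unique(unlist(transactions)))
  if (length(universe) == 0) {
    return(tibble(items = list(), support = double()))
  }
  # incidence matrix: transactions x items
  m <- matrix(FALSE, nrow = n, ncol = length(universe),
              dimnames = list(NULL, universe))
  ti <- rep(seq_len(n), lengths(transactions))
  m[cbind(ti, match(unlist(transactions), universe))] <- TRUE

  supp_of <- function(sets) {
    # sets: list of character vectors, all the same size k
    k <- length(sets[[1]])
    vapply(sets, function(s) {
      if (k == 1) mean(m[, s]) else mean(rowSums(m[, s, drop = FALSE]) == k)
    }, numeric(1))
  }

  s1 <- colMeans(m)
  keep1 <- s1 >= min_support
  levels <- list()
  levels[[1]] <- tibble(items = purrr::map(universe[keep1], identity),
                        support = unname(s1[keep1]))
  k <- 1
  while (nrow(levels[[k]]) > 0 && k < max_size) {
    prev <- levels[[k]]$items
    prev_key <- vapply(prev, paste, "", collapse = "\x1f")
    cand <- list()
    if (length(prev) >= 2) {
      # join step: pairs sharing the first k-1 items (sorted order)
      prefix <- vapply(prev, function(s) paste(s[-length(s)], collapse = "\x1f"), "")
      for (g in split(seq_along(prev), prefix)) {
        if (length(g) < 2) next
        for (i in seq_len(length(g) - 1)) {
          for (j in (i + 1):length(g)) {
            a <- prev[[g[i]]]; b <- prev[[g[j]]]
            cand[[length(cand) + 1]] <- sort(unique(c(a, b)))
          }
        }
      }
    }
    if (length(cand) == 0) break
    cand <- unique(cand)
    # prune step: all k-subsets must be frequent
    ok <- vapply(cand, function(s) {
      subs <- vapply(seq_along(s), function(i) paste(s[-i], collapse = "\x1f"), "")
      all(subs %in% prev_key)
    }, logical(1))
    cand <- cand[ok]
    if (length(cand) == 0) break
    supp <- supp_of(cand)
    keep <- supp >= min_support
    k <- k + 1
    levels[[k]] <- tibble(items = cand[keep], support = supp[keep])
    if (nrow(levels[[k]]) == 0) break
  }
  out <- bind_rows(levels)
  if (nrow(out) == 0) return(tibble(items = list(), support = double()))
  key <- vapply(out$items, paste, "", collapse = "\x1f")
  out[order(lengths(out$items), key), , drop = FALSE]
}

# assemble the mining database for one ADL from labelled transactions:
# positives carry the injected label item; negatives are a seeded sample of
# unlabelled windows (ratio per positive, without replacement)
build_mining_db <- function(transactions, adl, ratio, seed) {
  pos <- transactions[!is.na(transactions$label) &
                        transactions$label == adl, , drop = FALSE]
  if (nrow(pos) == 0) {
    abort(sprintf(
      "no labelled-positive windows for %s: collect more annotations for this ADL",
      dQuote(adl)), class = "adlminer_no_training_error")
  }
  neg_pool <- transactions[is.na(transactions$label), , drop = FALSE]
  n_neg <- min(floor(ratio * nrow(pos)), nrow(neg_pool))
  neg_idx <- if (n_neg > 0) {
    with_local_seed(seed, sort(sample.int(nrow(neg_pool), n_neg)))
  } else integer()
  c(
    purrr::map(pos$items, ~ c(.x, adl_item(adl))),
    neg_pool$items[neg_idx]
  )
}

# mine rules X => adl from an assembled database
mine_rules_from_db <- function(db, adl, params, provenance) {
  label <- adl_item(adl)
  freq <- frequent_itemsets(db, params$min_support,
                            max_size = params$max_antecedent_size + 1)
  if (nrow(freq) == 0) return(empty_rules())
  key <- vapply(freq$items, paste, "", collapse = "\x1f")
  supp <- setNames(freq$support, key)
  with_label <- purrr::map_lgl(freq$items, ~ label %in% .x)
  cand <- freq[with_label & lengths(freq$items) >= 2, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_rules())

  rules <- purrr::map(seq_len(nrow(cand)), function(i) {
    x <- setdiff(cand$items[[i]], label)
    if (length(x) == 0 || length(x) > params$max_antecedent_size) return(NULL)
    if (any(startsWith(x, "adl:"))) return(NULL)
    sx <- supp[[paste(x, collapse = "\x1f")]]
    conf <- cand$support[i] / sx
    if (conf < params$min_confidence) return(NULL)
    tibble(adl = adl, antecedent = list(x), support = cand$support[i],
           confidence = conf)
  }) %>% bind_rows()
  if (nrow(rules) == 0) return(empty_rules())

  # stable ordering: (adl, antecedent size, lexicographic items)
  akey <- vapply(rules$antecedent, paste, "", collapse = "\x1f")
  rules <- rules[order(lengths(rules$antecedent), akey), , drop = FALSE]

  # dominated-rule pruning: drop X' when some kept X subset of X' has
  # confidence >= confidence(X') (scanning in size order keeps minimal rules)
  kept <- list()
  keep_flag <- logical(nrow(rules))
  for (i in seq_len(nrow(rules))) {
    x <- rules$antecedent[[i]]
    dominated <- any(purrr::map_lgl(kept, function(j) {
      all(rules$antecedent[[j]] %in% x) &&
        rules$confidence[j] >= rules$confidence[i]
    }))
    if (!dominated) {
      keep_flag[i] <- TRUE
      kept[[length(kept) + 1]] <- i
    }
  }
  rules <- rules[keep_flag, , drop = FALSE]
  rules <- mutate(rules,
                  rule_id = sprintf("%s_%s_%03d", provenance, adl, row_number()),
                  provenance = provenance) %>%
    select("rule_id", "adl", "antecedent", "support", "confidence", "provenance")
  structure(rules, class = c("adl_rules", class(tibble())))
}

#' Induce association rules for one ADL
#'
#' Builds the mining database (labelled-positive windows plus a seeded
#' negative sample of unlabelled windows), mines frequent itemsets with
#' apriori, and emits rules `antecedent => adl` meeting the support and
#' confidence thresholds. Antecedents contain only sensor-item tokens;
#' dominated rules (a superset antecedent with no confidence gain) are
#' pruned.
#'
#' @param transactions Labelled transaction tibble (see [label_windows()]);
#'   typically one participant's windows for this ADL's window size.
#' @param adl The consequent ADL.
#' @param params [mining_params()].
#' @param provenance Provenance string recorded on the rules; defaults to
#'   the single participant id present in `transactions`.
#' @return An `adl_rules` tibble: `rule_id`, `adl`, `antecedent`
#'   (list-column), `support`, `confidence`, `provenance`, in stable
#'   (antecedent size, lexicographic) order.
#' @export
induce_rules <- function(transactions, adl, params = mining_params(),
                         provenance = NULL) {
  stopifnot(inherits(params, "mining_params"), adl %in% adl_labels())
  if (is.null(provenance)) {
    pid <- unique(transactions$participant_id)
    provenance <- if (length(pid) == 1) pid else "pooled"
  }
  db <- build_mining_db(transactions, adl, params$negative_sampling_ratio,
                        params$seed)
  mine_rules_from_db(db, adl, params, provenance)
}

#' Pool rules across participants
#'
#' Concatenates the per-participant mining databases (negative sampling is
#' done per participant, with a participant-specific offset of the seed)
#' and mines a single rule set over the union. Item tokens are
#' location-canonical, so the pooled rules transfer to participants who
#' contributed no annotations.
#'
#' @param per_participant_transactions Named list (by participant id) of
#'   labelled transaction tibbles, or a single tibble covering several
#'   participants.
#' @param adl The consequent ADL.
#' @param params [mining_params()].
#' @return An `adl_rules` tibble with `provenance = "pooled"`. With fewer
#'   than two participants contributing positives, a warning is issued and
#'   mining proceeds on whatever is available.
#' @export
pool_rules <- function(per_participant_transactions, adl,
                       params = mining_params()) {
  stopifnot(inherits(params, "mining_params"), adl %in% adl_labels())
  if (is.data.frame(per_participant_transactions)) {
    per_participant_transactions <-
      split(per_participant_transactions,
            per_participant_transactions$participant_id)
  }
  txs <- per_participant_transactions
  has_pos <- purrr::map_lgl(txs, function(tx) {
    any(!is.na(tx$label) & tx$label == adl)
  })
  if (sum(has_pos) == 0) {
    abort(sprintf("no participant has labelled windows for %s", dQuote(adl)),
          class = "adlminer_no_training_error")
  }
  if (sum(has_pos) < 2) {
    warn(sprintf(
      "only %d participant(s) contribute positives for %s; pooling degenerates to per-participant mining",
      sum(has_pos), dQuote(adl)))
  }
  dbs <- purrr::imap(txs[has_pos], function(tx, pid) {
    build_mining_db(tx, adl, params$negative_sampling_ratio,
                    params$seed + match(pid, names(txs)))
  })
  mine_rules_from_db(do.call(c, unname(dbs)), adl, params, "pooled")
}
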