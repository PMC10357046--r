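# Summary views over detections (raw counts, day-normalised counts,
# per-participant ADL proportions), core-sensor ranking, precision/recall
# evaluation against planted truth, and leave-one-participant-out
# generalization.

#' Summarise detections per participant
#'
#' For each catalogued participant and each of the four ADLs: the raw
#' detection count, the count normalised to a reference logging duration
#' (`normalized = raw * reference_days / logging_days`), the per-day rate,
#' and the proportion of that participant's detections (proportions sum to
#' 1 whenever the participant has any detection).
#'
#' @param detections Detection tibble.
#' @param catalogs Catalog tibble (defines `logging_days` per participant).
#' @param reference_days Reference duration in days, or `"max"` to use the
#'   longest logging duration in the cohort.
#' @return An `adl_summary` tibble, one row per (participant, ADL).
#' @export
summarize_adl <- function(detections, catalogs, reference_days = "max") {
  logging_days <- as.numeric(difftime(catalogs$logging_end,
                                      catalogs$logging_start, units = "days"))
  if (any(logging_days <= 0)) {
    abort("participant with zero logging days", class = "adlminer_config_error")
  }
  if (identical(reference_days, "max")) reference_days <- max(logging_days)
  stopifnot(is.numeric(reference_days), reference_days > 0)

  unknown <- setdiff(unique(detections$participant_id), catalogs$participant_id)
  if (length(unknown) > 0) {
    abort(sprintf("detections reference uncatalogued participant(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "adlminer_validation_error")
  }

  base <- tidyr::expand_grid(participant_id = catalogs$participant_id,
                             adl = adl_labels())
  counts <- detections %>%
    dplyr::count(.data$participant_id, .data$adl, name = "n_raw")
  out <- base %>%
    left_join(counts, by = c("participant_id", "adl")) %>%
    mutate(n_raw = tidyr::replace_na(.data$n_raw, 0L)) %>%
    left_join(tibble(participant_id = catalogs$participant_id,
                     logging_days = logging_days),
              by = "participant_id") %>%
    group_by(.data$participant_id) %>%
    mutate(
      n_normalized = .data$n_raw * .env$reference_days / .data$logging_days,
      per_day = .data$n_raw / .data$logging_days,
      proportion = if (sum(.data$n_raw) > 0) .data$n_raw / sum(.data$n_raw) else 0
    ) %>%
    ungroup() %>%
    mutate(adl = factor(.data$adl, levels = adl_labels())) %>%
    arrange(.data$participant_id, .data$adl) %>%
    mutate(adl = as.character(.data$adl))
  structure(out, class = c("adl_summary", class(tibble())),
            reference_days = reference_days)
}

#' Rank core sensors
#'
#' Scores each sensor item by how often it appears in the pooled rules
#' (`rule_presence`: fraction of rules whose antecedent contains it) and
#' how often it participates in actual detections (`fire_share`: fraction
#' of detections whose firing rule's antecedent contains it); the combined
#' score is the unweighted mean of the two. The top-ranked items identify a
#' core deployment set for future homes.
#'
#' @param rules Pooled `adl_rules` tibble.
#' @param detections Detection tibble whose `fired_rule_id` values refer to
#'   `rules`.
#' @param top_k Number of sensors to return (default 11); if fewer distinct
#'   items exist, the full list is returned.
#' @return Tibble (`item`, `rule_presence`, `fire_share`, `score`), ranked
#'   by decreasing score with lexicographic tie-break.
#' @export
core_sensor_ranking <- function(rules, detections, top_k = 11) {
  if (nrow(rules) == 0) {
    return(tibble(item = character(), rule_presence = double(),
                  fire_share = double(), score = double()))
  }
  items <- sort(unique(unlist(rules$antecedent)))
  rule_presence <- vapply(items, function(it) {
    mean(purrr::map_lgl(rules$antecedent, ~ it %in% .x))
  }, numeric(1))
  fire_share <- if (nrow(detections) > 0) {
    fired <- rules$antecedent[match(detections$fired_rule_id, rules$rule_id)]
    vapply(items, function(it) {
      mean(purrr::map_lgl(fired, ~ !is.null(.x) && it %in% .x))
    }, numeric(1))
  } else {
    setNames(rep(0, length(items)), items)
  }
  out <- tibble(item = items, rule_presence = unname(rule_presence),
                fire_share = unname(fire_share)) %>%
    mutate(score = (.data$rule_presence + .data$fire_share) / 2) %>%
    arrange(dplyr::desc(.data$score), .data$item)
  head(out, min(top_k, nrow(out)))
}

#' Evaluate detections against planted truth
#'
#' Greedy one-to-one matching in time order, per participant and ADL: a
#' truth record matches the earliest unmatched detection of the same ADL
#' whose interval contains its timestamp. Precision with zero detections is
#' undefined and reported as 0 with `precision_defined = FALSE`.
#'
#' @param detections Detection tibble.
#' @param truth Annotation tibble of planted occurrences
#'   (`source = "simulated_truth"`).
#' @return An `adl_eval` tibble, one row per ADL, aggregated over
#'   participants: `n_truth`, `n_detections`, `tp`, `precision`, `recall`,
#'   `f1`, `precision_defined`.
#' @export
evaluate_detections <- function(detections, truth) {
  per <- purrr::map(adl_labels(), function(a) {
    tr <- truth[truth$adl == a, , drop = FALSE]
    de <- detections[detections$adl == a, , drop = FALSE]
    tp <- 0L
    for (pid in unique(c(tr$participant_id, de$participant_id))) {
      tp <- tp + greedy_match_count(
        de[de$participant_id == pid, , drop = FALSE],
        tr[tr$participant_id == pid, , drop = FALSE])
    }
    nd <- nrow(de); nt <- nrow(tr)
    precision <- if (nd > 0) tp / nd else 0
    recall <- if (nt > 0) tp / nt else NA_real_
    f1 <- if (nd > 0 && nt > 0 && (precision + recall) > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    tibble(adl = a, n_truth = nt, n_detections = nd, tp = tp,
           precision = precision, recall = recall, f1 = f1,
           precision_defined = nd > 0)
  })
  structure(bind_rows(per), class = c("adl_eval", class(tibble())))
}

# greedy one-to-one matching in time order for one (participant, adl)
greedy_match_count <- function(detections, truth) {
  if (nrow(detections) == 0 || nrow(truth) == 0) return(0L)
  de <- arrange(detections, .data$window_start)
  tt <- sort(as.numeric(truth$timestamp))
  s <- as.numeric(de$window_start); e <- as.numeric(de$window_end)
  used <- logical(length(tt))
  tp <- 0L
  for (i in seq_along(s)) {
    j <- which(!used & tt >= s[i] & tt < e[i])
    if (length(j) > 0) {
      used[j[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

#' Build labelled transactions for every participant and ADL
#'
#' Convenience wrapper running [build_windows()] and [label_windows()] for
#' each (participant, ADL) pair; the result feeds [induce_rules()],
#' [pool_rules()] and [adl_loocv()].
#'
#' @param events Cohort event tibble.
#' @param catalogs Catalog tibble.
#' @param annotations Briefing annotation tibble used for labelling.
#' @param spec A [window_spec()].
#' @return Named list (by ADL) of named lists (by participant) of labelled
#'   transaction tibbles.
#' @export
cohort_transactions <- function(events, catalogs, annotations,
                                spec = window_spec()) {
  pids <- catalogs$participant_id
  setNames(purrr::map(adl_labels(), function(a) {
    setNames(purrr::map(pids, function(pid) {
      ev <- events[events$participant_id == pid, , drop = FALSE]
      ct <- catalogs[catalogs$participant_id == pid, , drop = FALSE]
      an <- annotations[annotations$participant_id == pid, , drop = FALSE]
      label_windows(build_windows(ev, ct, a, spec), an, a)
    }), pids)
  }), adl_labels())
}

#' Leave-one-participant-out evaluation
#'
#' For each participant: pool rules from all other participants'
#' annotations, detect on the held-out participant's events, and evaluate
#' against their planted truth. This measures whether pooled rules
#' generalize to unseen homes without new training data.
#'
#' @param events Cohort event tibble.
#' @param catalogs Catalog tibble.
#' @param annotations Briefing annotations (training labels).
#' @param truth Planted ground-truth annotations (evaluation only).
#' @param params [mining_params()].
#' @param spec [window_spec()].
#' @param transactions Optional precomputed [cohort_transactions()] result
#'   (built from `events`/`annotations` when omitted).
#' @return Tibble, one row per (held-out participant, ADL), with the
#'   [evaluate_detections()] metrics.
#' @export
adl_loocv <- function(events, catalogs, annotations, truth,
                      params = mining_params(), spec = window_spec(),
                      transactions = NULL) {
  if (is.null(transactions)) {
    transactions <- cohort_transactions(events, catalogs, annotations, spec)
  }
  pids <- catalogs$participant_id
  purrr::map(pids, function(held) {
    rules <- purrr::map(adl_labels(), function(a) {
      txs <- transactions[[a]][setdiff(pids, held)]
      tryCatch(pool_rules(txs, a, params),
               adlminer_no_training_error = function(e) empty_rules())
    }) %>% bind_rows()
    rules <- structure(rules, class = c("adl_rules", class(tibble())))
    if (nrow(rules) == 0) return(NULL)
    det <- detect_all(
      events[events$participant_id == held, , drop = FALSE],
      catalogs[catalogs$participant_id == held, , drop = FALSE],
      rules, spec)
    ev <- evaluate_detections(det, truth[truth$participant_id == held, ,
                                         drop = FALSE])
    mutate(ev, held_out = held, .before = 1)
  }) %>% bind_rows()
}
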