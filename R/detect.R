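# Rule application: scan the stride grid in start order; a window fires
# when ANY rule's antecedent is a subset of its item set. On firing, a
# detection spanning the window is emitted and the next candidate start
# jumps past the window's end, so same-ADL detections never overlap.
# Different ADLs are detected independently and may overlap in time
# (dressing directly after a bath, say).

#' Detect one ADL in an event stream
#'
#' @param events Event tibble for one participant.
#' @param catalog One-row catalog tibble for that participant.
#' @param rules An `adl_rules` tibble whose rows all share one ADL
#'   consequent.
#' @param spec A [window_spec()].
#' @return Detection tibble: `participant_id`, `adl`, `window_start`,
#'   `window_end`, `fired_rule_id`. Ties among simultaneously applicable
#'   rules resolve to the first rule in the set's stable order.
#' @export
detect_adl <- function(events, catalog, rules, spec = window_spec()) {
  if (nrow(rules) == 0) {
    abort("empty rule set: this ADL cannot be detected",
          class = "adlminer_no_rules_error")
  }
  adl <- unique(rules$adl)
  if (length(adl) != 1) {
    abort("detect_adl() expects rules for exactly one ADL")
  }
  tx <- build_windows(events, catalog, adl, spec)
  if (nrow(tx) == 0) return(empty_detections())

  fired <- first_firing_rule(tx$items, rules$antecedent)

  # greedy scan: emit at the first firing window, then jump past its end
  out_start <- list(); out_rule <- integer()
  last_end <- -Inf
  s <- as.numeric(tx$window_start)
  e <- as.numeric(tx$window_end)
  for (i in which(!is.na(fired))) {
    if (s[i] >= last_end) {
      out_start[[length(out_start) + 1]] <- i
      out_rule[length(out_rule) + 1] <- fired[i]
      last_end <- e[i]
    }
  }
  idx <- unlist(out_start)
  if (is.null(idx)) return(empty_detections())
  tibble(
    participant_id = tx$participant_id[idx],
    adl = adl,
    window_start = tx$window_start[idx],
    window_end = tx$window_end[idx],
    fired_rule_id = rules$rule_id[out_rule]
  )
}

# index of the first rule whose antecedent is contained in each item set
first_firing_rule <- function(item_sets, antecedents) {
  universe <- sort(unique(unlist(antecedents)))
  if (length(universe) == 0) return(rep(NA_integer_, length(item_sets)))
  n <- length(item_sets)
  m <- matrix(FALSE, nrow = n, ncol = length(universe),
              dimnames = list(NULL, universe))
  pres <- purrr::map(item_sets, ~ intersect(.x, universe))
  ti <- rep(seq_len(n), lengths(pres))
  if (length(ti) > 0) m[cbind(ti, match(unlist(pres), universe))] <- TRUE
  fired <- rep(NA_integer_, n)
  for (r in rev(seq_along(antecedents))) {
    a <- antecedents[[r]]
    hit <- if (length(a) == 1) m[, a] else rowSums(m[, a, drop = FALSE]) == length(a)
    fired[hit] <- r
  }
  fired
}

#' Detect all ADLs in an event stream
#'
#' Runs [detect_adl()] once per ADL; detections of different ADLs may
#' overlap in time.
#'
#' @param events Event tibble for one participant.
#' @param catalog One-row catalog tibble.
#' @param rules An `adl_rules` tibble (typically pooled).
#' @param spec A [window_spec()].
#' @param adls ADLs to detect; defaults to those present in `rules`. An
#'   explicitly requested ADL without rules is an error.
#' @return Detection tibble sorted by (`adl`, `window_start`).
#' @export
detect_all <- function(events, catalog, rules, spec = window_spec(),
                       adls = intersect(adl_labels(), unique(rules$adl))) {
  missing <- setdiff(adls, unique(rules$adl))
  if (length(missing) > 0) {
    abort(sprintf("no rules for ADL(s): %s", paste(missing, collapse = ", ")),
          class = "adlminer_no_rules_error")
  }
  purrr::map(adls, function(a) {
    detect_adl(events, catalog, rules[rules$adl == a, , drop = FALSE], spec)
  }) %>%
    bind_rows() %>%
    arrange(.data$adl, .data$window_start)
}
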