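# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an association rule set
#'
#' @param x An `adl_rules` tibble.
#' @param ... Unused.
#' @return A plain tibble, one row per rule, with the antecedent collapsed
#'   to a `+`-joined string.
#' @method tidy adl_rules
#' @export
tidy.adl_rules <- function(x, ...) {
  as_tibble(x) %>%
    mutate(antecedent = purrr::map_chr(.data$antecedent, paste,
                                       collapse = " + "),
           antecedent_size = lengths(x$antecedent)) %>%
    select("rule_id", "adl", "antecedent", "antecedent_size", "support",
           "confidence", "provenance")
}

#' One-row summary of a rule set
#'
#' @param x An `adl_rules` tibble.
#' @param ... Unused.
#' @return Tibble with rule counts and support/confidence summaries.
#' @method glance adl_rules
#' @export
glance.adl_rules <- function(x, ...) {
  tibble(
    n_rules = nrow(x),
    n_adls = dplyr::n_distinct(x$adl),
    mean_support = mean(x$support),
    mean_confidence = mean(x$confidence),
    max_antecedent_size = if (nrow(x) > 0) max(lengths(x$antecedent)) else 0L
  )
}

#' Tidy an evaluation result
#'
#' @param x An `adl_eval` tibble.
#' @param ... Unused.
#' @return A plain tibble (already one row per ADL).
#' @method tidy adl_eval
#' @export
tidy.adl_eval <- function(x, ...) as_tibble(x)

#' One-row macro summary of an evaluation
#'
#' @param x An `adl_eval` tibble.
#' @param ... Unused.
#' @return Tibble with macro-averaged precision/recall/F1 over ADLs with
#'   nonempty truth.
#' @method glance adl_eval
#' @export
glance.adl_eval <- function(x, ...) {
  d <- filter(as_tibble(x), .data$n_truth > 0)
  tibble(
    n_adls = nrow(d),
    macro_precision = mean(d$precision),
    macro_recall = mean(d$recall),
    macro_f1 = mean(d$f1)
  )
}
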