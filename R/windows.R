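# Sliding-window segmentation: an event stream becomes, per ADL, a sequence
# of order-independent item sets ("transactions") on a stride grid anchored
# at local midnight of each logging day. Windows are half-open
# [start, start + W); an event at time t belongs to every window whose
# start satisfies start <= t < start + W. Item tokens:
#   <sensor_id>            boolean contact/plug activation
#   presence:<location>    motion sensor or environmental motion channel
#   humidity_rise:<loc>    derived: (max - first) humidity reading in the
#                          window >= threshold, needs >= 2 readings

#' Window configuration for ADL detection
#'
#' @param window_min Named numeric vector of per-ADL window sizes in
#'   minutes. Defaults: 60 for eating/drinking and bathing, 30 for dressing
#'   and leaving the house.
#' @param stride_min Stride in minutes between candidate window starts
#'   (default 5). Each window size must be a positive multiple of the
#'   stride.
#' @param humidity_rise_threshold Minimum within-window humidity increase
#'   (%RH) for the derived `humidity_rise` item (default 10).
#' @return A `window_spec` list.
#' @export
window_spec <- function(window_min = c(eating_drinking = 60, dressing = 30,
                                       bathing = 60, leaving_house = 30),
                        stride_min = 5,
                        humidity_rise_threshold = 10) {
  stopifnot(stride_min > 0, humidity_rise_threshold > 0,
            all(window_min > 0), all(window_min %% stride_min == 0))
  structure(list(window_min = window_min, stride_min = stride_min,
                 humidity_rise_threshold = humidity_rise_threshold),
            class = "window_spec")
}

# map events to item tokens; humidity readings handled separately
event_items <- function(events, sensors) {
  type <- setNames(sensors$sensor_type, sensors$sensor_id)
  loc <- setNames(sensors$location, sensors$sensor_id)
  st <- type[events$sensor_id]
  is_presence <- st == "motion" |
    (st == "environmental" & events$channel == "motion")
  is_bool <- st %in% c("contact", "plug")
  keep <- is_presence | is_bool
  tibble(
    timestamp = events$timestamp[keep],
    item = ifelse(is_presence[keep],
                  paste0("presence:", loc[events$sensor_id[keep]]),
                  events$sensor_id[keep])
  )
}

# window index range (0-based k within a day) covering offset seconds
window_k_range <- function(offset_s, w_s, stride_s, k_max) {
  k_hi <- pmin(offset_s %/% stride_s, k_max)
  k_lo <- pmax((offset_s - w_s) %/% stride_s + 1L, 0L)
  list(lo = k_lo, hi = k_hi)
}

#' Build sliding-window transactions for one ADL
#'
#' Emits every window on the stride grid (anchored at midnight of each
#' logging day, no cross-midnight windows) that lies fully inside the
#' home's logging interval — including windows with empty item sets, which
#' carry information as negatives when estimating rule confidence.
#'
#' @param events Event tibble for one participant.
#' @param catalog One-row catalog tibble for that participant.
#' @param adl The ADL whose window size applies (one of [adl_labels()]).
#' @param spec A [window_spec()].
#' @return Tibble of transactions: `participant_id`, `window_start`,
#'   `window_end`, `items` (list-column of sorted unique tokens), `label`
#'   (`NA` until [label_windows()]).
#' @export
build_windows <- function(events, catalog, adl, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"), nrow(catalog) == 1)
  if (!adl %in% names(spec$window_min)) {
    abort(sprintf("no window size configured for ADL %s", dQuote(adl)),
          class = "adlminer_config_error")
  }
  if (nrow(events) > 0 &&
      !all(events$participant_id == catalog$participant_id)) {
    abort("events must belong to the catalog's participant")
  }
  w_s <- as.integer(spec$window_min[[adl]] * 60)
  stride_s <- as.integer(spec$stride_min * 60)
  k_max <- (86400L - w_s) %/% stride_s

  t0 <- catalog$logging_start
  t1 <- catalog$logging_end
  day0 <- as.POSIXct(trunc(t0, units = "days"), tz = "UTC")
  n_days <- as.integer(ceiling(as.numeric(difftime(t1, day0, units = "days"))))
  day_starts <- day0 + (seq_len(n_days) - 1) * 86400

  # all candidate windows, then restrict to those inside [t0, t1)
  grid <- tidyr::expand_grid(day = seq_len(n_days), k = 0:k_max)
  start <- day_starts[grid$day] + grid$k * stride_s
  inside <- start >= t0 & (start + w_s) <= t1
  grid <- grid[inside, , drop = FALSE]
  start <- start[inside]
  wid <- (grid$day - 1L) * (k_max + 1L) + grid$k  # dense per-day window id
  id_order <- order(wid)
  grid <- grid[id_order, , drop = FALSE]
  start <- start[id_order]
  wid <- wid[id_order]

  sensors <- catalog$sensors[[1]]

  # boolean / presence items
  items_by_wid <- list()
  bool <- event_items(events, sensors)
  if (nrow(bool) > 0) {
    day_idx <- as.integer(difftime(trunc(bool$timestamp, units = "days"),
                                   day0, units = "days")) + 1L
    off <- as.integer(round(as.numeric(bool$timestamp) -
                              as.numeric(day_starts[day_idx])))
    rng <- window_k_range(off, w_s, stride_s, k_max)
    n_rep <- pmax(rng$hi - rng$lo + 1L, 0L)
    keep <- n_rep > 0
    ks <- sequence(n_rep[keep]) - 1L + rep(rng$lo[keep], n_rep[keep])
    ev_wid <- rep((day_idx[keep] - 1L) * (k_max + 1L), n_rep[keep]) + ks
    inc <- tibble(wid = ev_wid, item = rep(bool$item[keep], n_rep[keep]))
    inc <- distinct(inc)
    inc <- inc[inc$wid %in% wid, , drop = FALSE]
    items_by_wid <- split(inc$item, inc$wid)
  }

  # derived humidity-rise items: (max - first reading) >= threshold
  type <- setNames(sensors$sensor_type, sensors$sensor_id)
  loc <- setNames(sensors$location, sensors$sensor_id)
  hum <- events[!is.na(type[events$sensor_id]) &
                  type[events$sensor_id] == "environmental" &
                  events$channel == "humidity", , drop = FALSE]
  rise_by_wid <- list()
  if (nrow(hum) > 0) {
    hum <- arrange(hum, .data$timestamp)
    day_idx <- as.integer(difftime(trunc(hum$timestamp, units = "days"),
                                   day0, units = "days")) + 1L
    off <- as.integer(round(as.numeric(hum$timestamp) -
                              as.numeric(day_starts[day_idx])))
    rng <- window_k_range(off, w_s, stride_s, k_max)
    n_rep <- pmax(rng$hi - rng$lo + 1L, 0L)
    keep <- n_rep > 0
    ks <- sequence(n_rep[keep]) - 1L + rep(rng$lo[keep], n_rep[keep])
    inc <- tibble(
      wid = rep((day_idx[keep] - 1L) * (k_max + 1L), n_rep[keep]) + ks,
      ts = rep(as.numeric(hum$timestamp[keep]), n_rep[keep]),
      loc = rep(unname(loc[hum$sensor_id[keep]]), n_rep[keep]),
      value = rep(hum$value[keep], n_rep[keep])
    )
    inc <- inc[inc$wid %in% wid, , drop = FALSE]
    if (nrow(inc) > 0) {
      agg <- inc %>%
        group_by(.data$wid, .data$loc) %>%
        summarise(first = .data$value[which.min(.data$ts)],
                  max = max(.data$value), n = dplyr::n(), .groups = "drop") %>%
        filter(.data$n >= 2,
               .data$max - .data$first >= .env$spec$humidity_rise_threshold)
      if (nrow(agg) > 0) {
        rise_by_wid <- split(paste0("humidity_rise:", agg$loc), agg$wid)
      }
    }
  }

  wid_chr <- as.character(wid)
  base_items <- items_by_wid[match(wid_chr, names(items_by_wid))]
  rise_items <- rise_by_wid[match(wid_chr, names(rise_by_wid))]
  items <- purrr::map2(base_items, rise_items,
                       function(a, b) as.character(sort(unique(c(a, b)))))

  tibble(
    participant_id = catalog$participant_id,
    window_start = start,
    window_end = start + w_s,
    items = items,
    label = NA_character_
  )
}

#' Label transactions from ADL annotations
#'
#' A transaction receives `label = adl` iff at least one annotation of that
#' ADL (for the same participant) has `window_start <= timestamp <
#' window_end`; all other transactions keep their label unchanged.
#'
#' @param transactions Transaction tibble from [build_windows()].
#' @param annotations Annotation tibble, filtered to the same participant.
#' @param adl The ADL being labelled.
#' @return The transactions with the `label` column updated.
#' @export
label_windows <- function(transactions, annotations, adl) {
  ann <- annotations[annotations$adl == adl, , drop = FALSE]
  if (nrow(ann) == 0 || nrow(transactions) == 0) return(transactions)
  ts <- as.numeric(ann$timestamp)
  s <- as.numeric(transactions$window_start)
  e <- as.numeric(transactions$window_end)
  hit <- purrr::map_lgl(seq_along(s), function(i) any(ts >= s[i] & ts < e[i]))
  transactions$label[hit] <- adl
  transactions
}
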