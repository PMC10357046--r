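# Independent oracles and small fixture builders used across the suite.

utc <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# exhaustive frequent-itemset oracle: enumerate every subset of the item
# universe and count support directly
brute_frequent <- function(transactions, min_support) {
  universe <- sort(unique(unlist(transactions)))
  out <- list()
  for (k in seq_along(universe)) {
    combos <- utils::combn(universe, k, simplify = FALSE)
    for (s in combos) {
      supp <- mean(vapply(transactions, function(tx) all(s %in% tx), logical(1)))
      if (supp >= min_support) out[[length(out) + 1]] <- list(items = s, support = supp)
    }
  }
  out
}

# canonical key for a set of itemsets, for order-insensitive comparison
itemset_key <- function(items, support) {
  paste0(vapply(items, paste, "", collapse = "|"), "@", sprintf("%.12f", support))
}

random_db <- function(seed, max_items = 10, max_trans = 40) {
  withr::with_seed(seed, {
    n_items <- sample(2:max_items, 1)
    n_trans <- sample(5:max_trans, 1)
    universe <- paste0("i", seq_len(n_items))
    lapply(seq_len(n_trans), function(i) {
      k <- sample(0:n_items, 1)
      sort(sample(universe, k))
    })
  })
}

# one-day single-sensor-type home for window tests
kitchen_catalog <- function(pid = "P01", days = 1,
                            start = utc("2023-03-01T00:00:00Z")) {
  sensors <- dplyr::bind_rows(
    sensor_def("kettle", "plug", "kettle"),
    sensor_def("fridge", "contact", "fridge_door"),
    sensor_def("toaster", "plug", "toaster"),
    sensor_def("wardrobe", "contact", "wardrobe_door"),
    sensor_def("front_door", "contact", "front_door"),
    sensor_def("motion_kitchen", "motion", "kitchen"),
    sensor_def("env_bath", "environmental", "bathroom")
  )
  home_catalog(pid, sensors, start, start + days * 86400)
}

bool_event <- function(pid, ts, sensor_id) {
  tibble::tibble(participant_id = pid, timestamp = utc(ts),
                 sensor_id = sensor_id, channel = "", value = 1)
}

humidity_event <- function(pid, ts, value, sensor_id = "env_bath") {
  tibble::tibble(participant_id = pid, timestamp = utc(ts),
                 sensor_id = sensor_id, channel = "humidity", value = value)
}

random_events <- function(seed, n = 100, pid = "P01",
                          catalog = kitchen_catalog(pid)) {
  withr::with_seed(seed, {
    sensors <- catalog$sensors[[1]]
    bool_ids <- sensors$sensor_id[sensors$sensor_type %in%
                                    c("contact", "plug", "motion")]
    t0 <- as.numeric(catalog$logging_start)
    span <- as.numeric(catalog$logging_end) - t0
    is_hum <- runif(n) < 0.3
    tibble::tibble(
      participant_id = pid,
      timestamp = as.POSIXct(t0 + floor(runif(n, 0, span)), tz = "UTC",
                             origin = "1970-01-01"),
      sensor_id = ifelse(is_hum, "env_bath", sample(bool_ids, n, replace = TRUE)),
      channel = ifelse(is_hum, "humidity", ""),
      value = ifelse(is_hum, round(runif(n, 30, 90), 4), 1)
    ) |>
      dplyr::arrange(participant_id, timestamp)
  })
}

# a routine with a single ADL and no noise, for surgically structured tests
quiet_routine <- function(active = character(), caller_rate = 0, noise = 0) {
  r <- default_routine_spec()
  r$schedule$prob <- ifelse(r$schedule$adl %in% active, r$schedule$prob, 0)
  r$noise_rate_per_hour <- noise
  r$caller_rate_per_day <- caller_rate
  r
}

# planted signature item tokens per ADL (what mined antecedents may contain)
signature_tokens <- function(routine = default_routine_spec(),
                             sensors = default_home_sensors()) {
  loc <- stats::setNames(sensors$location, sensors$sensor_id)
  type <- stats::setNames(sensors$sensor_type, sensors$sensor_id)
  toks <- lapply(routine$signatures, function(sig) {
    ifelse(type[sig$sensor_id] %in% c("motion", "environmental"),
           paste0("presence:", loc[sig$sensor_id]),
           sig$sensor_id)
  })
  toks$bathing <- c(toks$bathing, paste0("humidity_rise:", routine$humidity$room))
  toks
}

# maximum bipartite matching size between detections and truth records
# (igraph oracle for the greedy evaluator)
optimal_match_count <- function(detections, truth) {
  if (nrow(detections) == 0 || nrow(truth) == 0) return(0L)
  s <- as.numeric(detections$window_start)
  e <- as.numeric(detections$window_end)
  tt <- as.numeric(truth$timestamp)
  edges <- integer()
  for (i in seq_along(s)) {
    for (j in seq_along(tt)) {
      if (tt[j] >= s[i] && tt[j] < e[i]) edges <- c(edges, i, nrow(detections) + j)
    }
  }
  if (length(edges) == 0) return(0L)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nrow(detections)), rep(TRUE, nrow(truth))),
    edges = edges)
  igraph::max_bipartite_match(g)$matching_size
}

no_events <- function() {
  tibble::tibble(participant_id = character(), timestamp = utc(character()),
                 sensor_id = character(), channel = character(),
                 value = double())
}
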