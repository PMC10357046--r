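# Readers and writers for the five interchange formats:
#   events.csv      participant_id,timestamp,sensor_id,channel,value
#   annotations.csv participant_id,timestamp,adl,source
#   detections.csv  participant_id,adl,window_start,window_end,fired_rule_id
#   catalog.json    home catalogs (participant, logging interval, sensors)
#   rules.json      association rules (antecedent items, support, confidence)
# Readers validate and reject malformed records (naming the offending file
# line) rather than silently coercing; writers are exact inverses so that
# read(write(x)) is the identity.

read_csv_strict <- function(path, required_cols) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "adlminer_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(dQuote(missing), collapse = ", ")),
          class = "adlminer_parse_error")
  }
  df
}

# parse a timestamp column, reporting the 1-based file line (header = line 1)
parse_ts_column <- function(x, path, column) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: malformed %s %s", path, bad[1] + 1L, column,
                  dQuote(x[bad[1]])),
          class = "adlminer_parse_error")
  }
  out
}

parse_num_column <- function(x, path, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & nzchar(x))
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: non-numeric %s %s", path, bad[1] + 1L, column,
                  dQuote(x[bad[1]])),
          class = "adlminer_parse_error")
  }
  out
}

check_enum_column <- function(x, allowed, path, column) {
  bad <- which(!x %in% allowed)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: invalid %s %s (expected one of %s)",
                  path, bad[1] + 1L, column, dQuote(x[bad[1]]),
                  paste(allowed, collapse = ", ")),
          class = "adlminer_parse_error")
  }
  invisible(x)
}

fmt_value <- function(x) sprintf("%.12g", x)

# --- sensor events ---------------------------------------------------------

#' Read a sensor event log
#'
#' One row per sensor activation or environmental reading. The `channel`
#' column is empty for boolean (contact/motion/plug) activations, whose
#' `value` is 1; environmental readings carry the channel name and a real
#' value.
#'
#' @param path Path to an `events.csv` file.
#' @return Tibble of events sorted by (`participant_id`, `timestamp`),
#'   regardless of row order in the file.
#' @export
read_events <- function(path) {
  df <- read_csv_strict(path, c("participant_id", "timestamp", "sensor_id",
                                "channel", "value"))
  if (nrow(df) == 0) return(empty_events())
  tibble(
    participant_id = df$participant_id,
    timestamp = parse_ts_column(df$timestamp, path, "timestamp"),
    sensor_id = df$sensor_id,
    channel = df$channel,
    value = parse_num_column(df$value, path, "value")
  ) %>%
    arrange(.data$participant_id, .data$timestamp)
}

#' Write a sensor event log
#'
#' @param events Event tibble (see [read_events()] for the schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- tibble(
    participant_id = as.character(events$participant_id),
    timestamp = format_timestamp(events$timestamp),
    sensor_id = as.character(events$sensor_id),
    channel = as.character(events$channel),
    value = fmt_value(events$value)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# --- ADL annotations -------------------------------------------------------

#' Read an ADL annotation log
#'
#' Annotations are timestamped ADL occurrences, either recalled by
#' participants during data-informed briefings (`source = "briefing"`) or
#' planted by the simulator (`source = "simulated_truth"`).
#'
#' @param path Path to an `annotations.csv` file.
#' @return Tibble sorted by (`participant_id`, `timestamp`).
#' @export
read_annotations <- function(path) {
  df <- read_csv_strict(path, c("participant_id", "timestamp", "adl", "source"))
  if (nrow(df) == 0) return(empty_annotations())
  check_enum_column(df$adl, adl_labels(), path, "adl")
  check_enum_column(df$source, c("briefing", "simulated_truth"), path, "source")
  tibble(
    participant_id = df$participant_id,
    timestamp = parse_ts_column(df$timestamp, path, "timestamp"),
    adl = df$adl,
    source = df$source
  ) %>%
    arrange(.data$participant_id, .data$timestamp)
}

#' Write an ADL annotation log
#'
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  out <- tibble(
    participant_id = as.character(annotations$participant_id),
    timestamp = format_timestamp(annotations$timestamp),
    adl = as.character(annotations$adl),
    source = as.character(annotations$source)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# --- detections ------------------------------------------------------------

#' Read detected ADL occurrences
#'
#' @param path Path to a `detections.csv` file.
#' @return Tibble sorted by (`participant_id`, `adl`, `window_start`).
#' @export
read_detections <- function(path) {
  df <- read_csv_strict(path, c("participant_id", "adl", "window_start",
                                "window_end", "fired_rule_id"))
  if (nrow(df) == 0) return(empty_detections())
  check_enum_column(df$adl, adl_labels(), path, "adl")
  out <- tibble(
    participant_id = df$participant_id,
    adl = df$adl,
    window_start = parse_ts_column(df$window_start, path, "window_start"),
    window_end = parse_ts_column(df$window_end, path, "window_end"),
    fired_rule_id = df$fired_rule_id
  )
  if (any(out$window_end <= out$window_start)) {
    bad <- which(out$window_end <= out$window_start)[1]
    abort(sprintf("%s line %d: window_end not after window_start", path, bad + 1L),
          class = "adlminer_parse_error")
  }
  arrange(out, .data$participant_id, .data$adl, .data$window_start)
}

#' Write detected ADL occurrences
#'
#' @param detections Detection tibble (see [read_detections()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  out <- tibble(
    participant_id = as.character(detections$participant_id),
    adl = as.character(detections$adl),
    window_start = format_timestamp(detections$window_start),
    window_end = format_timestamp(detections$window_end),
    fired_rule_id = as.character(detections$fired_rule_id)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# --- catalogs (JSON) -------------------------------------------------------

#' Read home catalogs
#'
#' @param path Path to a `catalog.json` file.
#' @return Catalog tibble, one row per participant, with a `sensors`
#'   list-column.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "adlminer_io_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  homes <- purrr::map(raw, function(h) {
    sensors <- purrr::map(h$sensors, function(s) {
      sensor_def(
        sensor_id = s$sensor_id, sensor_type = s$sensor_type,
        location = s$location,
        channels = if (identical(s$sensor_type, "environmental"))
          as.character(unlist(s$channels)) else character()
      )
    }) %>% bind_rows()
    home_catalog(
      participant_id = h$participant_id,
      sensors = sensors,
      logging_start = parse_timestamp(h$logging_start),
      logging_end = parse_timestamp(h$logging_end)
    )
  })
  bind_rows(homes)
}

#' Write home catalogs
#'
#' @param catalogs Catalog tibble ([home_catalog()] rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalogs, path) {
  payload <- purrr::pmap(catalogs, function(participant_id, logging_start,
                                            logging_end, sensors) {
    list(
      participant_id = participant_id,
      logging_start = format_timestamp(logging_start),
      logging_end = format_timestamp(logging_end),
      sensors = purrr::pmap(sensors, function(sensor_id, sensor_type,
                                              location, channels) {
        list(sensor_id = sensor_id, sensor_type = sensor_type,
             location = location, channels = as.list(channels))
      })
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# --- rules (JSON) ----------------------------------------------------------

#' Read an association rule set
#'
#' @param path Path to a `rules.json` file.
#' @return An `adl_rules` tibble (see [induce_rules()]).
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "adlminer_io_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(raw) == 0) return(empty_rules())
  rules <- purrr::map(raw, function(r) {
    if (!r$adl %in% adl_labels()) {
      abort(sprintf("%s: invalid adl %s", path, dQuote(r$adl)),
            class = "adlminer_parse_error")
    }
    ante <- as.character(unlist(r$antecedent))
    if (length(ante) == 0) {
      abort(sprintf("%s: rule %s has an empty antecedent", path, dQuote(r$rule_id)),
            class = "adlminer_parse_error")
    }
    if (r$support < 0 || r$support > 1 || r$confidence < 0 || r$confidence > 1) {
      abort(sprintf("%s: rule %s has support/confidence outside [0, 1]",
                    path, dQuote(r$rule_id)), class = "adlminer_parse_error")
    }
    tibble(rule_id = r$rule_id, adl = r$adl, antecedent = list(ante),
           support = as.numeric(r$support), confidence = as.numeric(r$confidence),
           provenance = r$provenance)
  }) %>% bind_rows()
  structure(rules, class = c("adl_rules", class(tibble())))
}

#' Write an association rule set
#'
#' @param rules An `adl_rules` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  payload <- purrr::pmap(
    select(as_tibble(rules), "rule_id", "adl", "antecedent", "support",
           "confidence", "provenance"),
    function(rule_id, adl, antecedent, support, confidence, provenance) {
      list(rule_id = rule_id, adl = adl, antecedent = as.list(antecedent),
           support = support, confidence = confidence, provenance = provenance)
    })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# --- transactions (CSV) ----------------------------------------------------

#' Read sliding-window transactions
#'
#' @param path Path to a `transactions.csv` file (items `;`-joined).
#' @return Transaction tibble as produced by [build_windows()].
#' @export
read_transactions <- function(path) {
  df <- read_csv_strict(path, c("participant_id", "window_start",
                                "window_end", "items", "label"))
  if (nrow(df) == 0) {
    return(tibble(participant_id = character(),
                  window_start = parse_timestamp(character()),
                  window_end = parse_timestamp(character()),
                  items = list(), label = character()))
  }
  tibble(
    participant_id = df$participant_id,
    window_start = parse_ts_column(df$window_start, path, "window_start"),
    window_end = parse_ts_column(df$window_end, path, "window_end"),
    items = purrr::map(strsplit(df$items, ";", fixed = TRUE),
                       function(x) sort(x[nzchar(x)])),
    label = ifelse(nzchar(df$label), df$label, NA_character_)
  ) %>%
    arrange(.data$participant_id, .data$window_start)
}

#' Write sliding-window transactions
#'
#' @param transactions Transaction tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transactions <- function(transactions, path) {
  out <- tibble(
    participant_id = as.character(transactions$participant_id),
    window_start = format_timestamp(transactions$window_start),
    window_end = format_timestamp(transactions$window_end),
    items = purrr::map_chr(transactions$items, paste, collapse = ";"),
    label = ifelse(is.na(transactions$label), "", transactions$label)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
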