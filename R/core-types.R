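# Shared domain vocabulary: sensor taxonomy, ADL labels, timestamp handling,
# catalog construction and validation. All tabular objects are tibbles; all
# timestamps are timezone-aware POSIXct in UTC with whole-second resolution.

#' The four activity-of-daily-living labels
#'
#' The detector targets four basic self-care activities commonly used to
#' assess independent functioning at home: eating or drinking, dressing,
#' bathing, and leaving the house. Every annotation, rule consequent and
#' detection carries exactly one of these labels.
#'
#' @return Character vector of the four canonical ADL labels.
#' @export
#' @examples
#' adl_labels()
adl_labels <- function() {
  c("eating_drinking", "dressing", "bathing", "leaving_house")
}

#' Recognised sensor types
#'
#' Ambient homes in this framework carry four sensor categories: magnetic
#' `contact` sensors on doors/cupboards/drawers, passive-infrared `motion`
#' sensors, power-monitoring smart `plug` sensors, and multi-channel
#' `environmental` ("6-in-1") sensors reporting humidity, temperature,
#' light and motion.
#'
#' @return Character vector of sensor type names.
#' @export
sensor_types <- function() {
  c("contact", "motion", "plug", "environmental")
}

# --- timestamps ------------------------------------------------------------

#' Parse ISO-8601 UTC timestamps
#'
#' Timestamps throughout the package are ISO-8601 strings with an explicit
#' `Z` (UTC) suffix and whole-second resolution, e.g. `2023-03-01T08:00:00Z`.
#'
#' @param x Character vector of timestamps.
#' @return POSIXct vector in UTC. Unparseable elements raise an error.
#' @export
parse_timestamp <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed timestamp %s at position %d (expected e.g. 2023-03-01T08:00:00Z)",
      dQuote(x[bad[1]]), bad[1]
    ), class = "adlminer_parse_error")
  }
  out
}

#' Format timestamps as ISO-8601 UTC strings
#'
#' @param x POSIXct vector.
#' @return Character vector like `"2023-03-01T08:00:00Z"`.
#' @export
format_timestamp <- function(x) {
  format(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# --- sensors and catalogs --------------------------------------------------

#' Describe one deployed sensor
#'
#' @param sensor_id Identifier, unique within a home.
#' @param sensor_type One of [sensor_types()].
#' @param location Free-text room/object label (e.g. `"fridge_door"`,
#'   `"bathroom"`). Locations, not participant-specific ids, become the item
#'   tokens used in mining so that rules pool across homes.
#' @param channels For environmental sensors, the measured quantities
#'   (subset of `"humidity"`, `"temperature"`, `"light"`, `"motion"`).
#'   Boolean sensors (contact/motion/plug) have exactly one boolean channel
#'   and must leave this as its default.
#' @return One-row tibble with a list-column `channels`.
#' @export
sensor_def <- function(sensor_id, sensor_type, location,
                       channels = if (sensor_type == "environmental")
                         c("humidity", "temperature", "light", "motion") else character()) {
  stopifnot(is.character(sensor_id), length(sensor_id) == 1)
  if (!sensor_type %in% sensor_types()) {
    abort(sprintf("unknown sensor_type %s", dQuote(sensor_type)),
          class = "adlminer_parse_error")
  }
  if (sensor_type != "environmental" && length(channels) > 0) {
    abort("contact/motion/plug sensors have exactly one boolean channel; do not set `channels`")
  }
  if (sensor_type == "environmental" && length(channels) == 0) {
    abort("environmental sensors need at least one channel")
  }
  tibble(
    sensor_id = sensor_id, sensor_type = sensor_type,
    location = location, channels = list(channels)
  )
}

#' Construct a home catalog
#'
#' A catalog records, for one participant's home, the deployed sensors and
#' the logging interval. Intervals are half-open `[logging_start,
#' logging_end)`.
#'
#' @param participant_id Identifier string.
#' @param sensors Tibble of sensors, as built by row-binding [sensor_def()]
#'   calls (1 to 64 rows, unique `sensor_id`).
#' @param logging_start,logging_end POSIXct (UTC) logging interval bounds.
#' @return One-row tibble with a list-column `sensors`.
#' @export
home_catalog <- function(participant_id, sensors, logging_start, logging_end) {
  sensors <- as_tibble(sensors)
  if (nrow(sensors) < 1 || nrow(sensors) > 64) {
    abort("a home carries between 1 and 64 sensors")
  }
  if (anyDuplicated(sensors$sensor_id) > 0) {
    abort("sensor_id must be unique within a home")
  }
  if (!logging_start < logging_end) {
    abort("logging_start must precede logging_end")
  }
  tibble(
    participant_id = participant_id,
    logging_start = logging_start,
    logging_end = logging_end,
    sensors = list(sensors)
  )
}

# sensors of one participant, or all homes stacked with participant_id
catalog_sensors <- function(catalogs, participant = NULL) {
  if (!is.null(participant)) {
    catalogs <- filter(catalogs, .data$participant_id == participant)
  }
  tidyr::unnest(select(catalogs, "participant_id", "sensors"), "sensors")
}

#' Validate sensor events against a home catalog
#'
#' Checks that every event references a catalogued sensor of its participant
#' and falls inside the home's logging interval (half-open).
#'
#' @param events Event tibble (`participant_id`, `timestamp`, `sensor_id`,
#'   `channel`, `value`).
#' @param catalogs Catalog tibble ([home_catalog()] rows).
#' @return `events`, invisibly, if valid; otherwise an error.
#' @export
validate_events <- function(events, catalogs) {
  sens <- catalog_sensors(catalogs)
  key <- paste(events$participant_id, events$sensor_id)
  known <- paste(sens$participant_id, sens$sensor_id)
  bad <- which(!key %in% known)
  if (length(bad) > 0) {
    abort(sprintf("event %d references unknown sensor %s for participant %s",
                  bad[1], dQuote(events$sensor_id[bad[1]]),
                  dQuote(events$participant_id[bad[1]])),
          class = "adlminer_validation_error")
  }
  iv <- select(catalogs, "participant_id", "logging_start", "logging_end")
  ev <- left_join(events, iv, by = "participant_id")
  out <- which(ev$timestamp < ev$logging_start | ev$timestamp >= ev$logging_end)
  if (length(out) > 0) {
    abort(sprintf("event %d at %s lies outside the logging interval of %s",
                  out[1], format_timestamp(ev$timestamp[out[1]]),
                  dQuote(ev$participant_id[out[1]])),
          class = "adlminer_validation_error")
  }
  invisible(events)
}

# stable empty prototypes used by readers on header-only files
empty_events <- function() {
  tibble(participant_id = character(), timestamp = parse_timestamp(character()),
         sensor_id = character(), channel = character(), value = double())
}

empty_annotations <- function() {
  tibble(participant_id = character(), timestamp = parse_timestamp(character()),
         adl = character(), source = character())
}

empty_detections <- function() {
  tibble(participant_id = character(), adl = character(),
         window_start = parse_timestamp(character()),
         window_end = parse_timestamp(character()),
         fired_rule_id = character())
}

empty_rules <- function() {
  structure(
    tibble(rule_id = character(), adl = character(), antecedent = list(),
           support = double(), confidence = double(), provenance = character()),
    class = c("adl_rules", class(tibble())))
}
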