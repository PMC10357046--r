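# Synthetic cohort generator. Emulates the statistical structure the
# detector assumes: per-participant daily routines whose occurrences light
# up ADL-specific sensor signatures, homogeneous Poisson background noise
# per sensor, door callers that open the front door without anybody
# leaving, a bathroom humidity process with configurable sampling interval,
# and sparse briefing-style annotations (a few recalled days, timestamps
# jittered by imperfect recall).

# derive an independent substream seed per (participant, component) so that
# changing one generative knob (say the caller rate) cannot shift the draws
# of any other component or participant
substream_seed <- function(base, participant_idx, component) {
  as.integer((as.numeric(base) + participant_idx * 1009 + component * 104729) %%
               2147483647)
}

# run code under a given RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default sensor deployment for one simulated home
#'
#' Eighteen sensors covering the canonical ADL signatures: kitchen contact
#' sensors (fridge, crockery/cutlery/staples cupboards) and smart plugs
#' (kettle, toaster, microwave) for eating/drinking; wardrobe and underwear
#' drawer contacts for dressing; a bathroom 6-in-1 environmental sensor
#' (humidity) for bathing; front/back/patio door contacts for leaving the
#' house; plus room motion sensors and a kitchen 6-in-1. Sensor ids are
#' location-canonical (identical across homes) so that mined rules pool.
#'
#' @return Sensor tibble suitable for [home_catalog()].
#' @export
default_home_sensors <- function() {
  bind_rows(
    sensor_def("fridge_door", "contact", "fridge_door"),
    sensor_def("cupboard_crockery", "contact", "cupboard_crockery"),
    sensor_def("cupboard_cutlery", "contact", "cupboard_cutlery"),
    sensor_def("cupboard_staples", "contact", "cupboard_staples"),
    sensor_def("wardrobe_door", "contact", "wardrobe_door"),
    sensor_def("underwear_drawer", "contact", "underwear_drawer"),
    sensor_def("front_door", "contact", "front_door"),
    sensor_def("back_door", "contact", "back_door"),
    sensor_def("patio_door", "contact", "patio_door"),
    sensor_def("kettle", "plug", "kettle"),
    sensor_def("toaster", "plug", "toaster"),
    sensor_def("microwave", "plug", "microwave"),
    sensor_def("motion_kitchen", "motion", "kitchen"),
    sensor_def("motion_bedroom", "motion", "bedroom"),
    sensor_def("motion_hallway", "motion", "hallway"),
    sensor_def("motion_living", "motion", "living_room"),
    sensor_def("env_bathroom", "environmental", "bathroom"),
    sensor_def("env_kitchen", "environmental", "kitchen")
  )
}

#' Default daily routine specification
#'
#' Describes, for one participant, when and how often each ADL occurs, which
#' sensors an occurrence activates (with what probability), background noise,
#' door-caller rate, and the bathroom humidity process.
#'
#' Defaults: eating/drinking three times daily (08:00, 13:00, 18:30; SD
#' 25 min; 25 min duration), dressing once (~08:30), bathing 0.8/day
#' (~21:00; humidity amplitude 20 %RH, exponential decay 30 min, sampled
#' every 1 min), leaving the house 0.9/day (~10:00); background noise 0.05
#' events/h/sensor; callers 0.5/day.
#'
#' @return A list with components `schedule` (tibble: `adl`, `clock_min`
#'   minutes after local midnight, `jitter_sd_min`, `prob` per-day occurrence
#'   probability, `duration_min`), `signatures` (per-ADL tibble of
#'   `sensor_id`, `prob`), `noise_rate_per_hour`, `caller_rate_per_day`, and
#'   `humidity` (`baseline`, `noise_sd`, `amplitude`, `decay_min`,
#'   `sampling_interval_min`, `room`).
#' @export
default_routine_spec <- function() {
  list(
    schedule = tibble(
      adl = c("eating_drinking", "eating_drinking", "eating_drinking",
              "dressing", "bathing", "leaving_house"),
      clock_min = c(8 * 60, 13 * 60, 18.5 * 60, 8.5 * 60, 21 * 60, 10 * 60),
      jitter_sd_min = c(25, 25, 25, 15, 30, 45),
      prob = c(1, 1, 1, 1, 0.8, 0.9),
      duration_min = c(25, 25, 25, 10, 20, 5)
    ),
    signatures = list(
      eating_drinking = tibble(
        sensor_id = c("fridge_door", "kettle", "toaster", "microwave",
                      "cupboard_crockery", "cupboard_cutlery",
                      "cupboard_staples", "motion_kitchen"),
        prob = c(0.9, 0.7, 0.35, 0.3, 0.6, 0.55, 0.5, 0.9)
      ),
      dressing = tibble(
        sensor_id = c("wardrobe_door", "underwear_drawer", "motion_bedroom"),
        prob = c(0.95, 0.85, 0.9)
      ),
      bathing = tibble(sensor_id = "env_bathroom", prob = 0.95),
      leaving_house = tibble(sensor_id = "front_door", prob = 1.0)
    ),
    noise_rate_per_hour = 0.05,
    caller_rate_per_day = 0.5,
    humidity = list(
      baseline = 50, noise_sd = 0.75, amplitude = 20,
      decay_min = 30, sampling_interval_min = 1, room = "bathroom"
    )
  )
}

validate_routine <- function(routine) {
  sch <- routine$schedule
  stopifnot(all(sch$prob >= 0 & sch$prob <= 1),
            all(sch$duration_min > 0), all(sch$jitter_sd_min >= 0))
  for (sig in routine$signatures) {
    stopifnot(all(sig$prob >= 0 & sig$prob <= 1))
  }
  stopifnot(routine$noise_rate_per_hour >= 0, routine$caller_rate_per_day >= 0,
            routine$humidity$sampling_interval_min >= 1)
  invisible(routine)
}

#' Build a cohort configuration
#'
#' @param n_participants Number of homes (>= 1).
#' @param days Logging duration in whole days (>= 1).
#' @param seed Integer seed; the whole simulation is deterministic given the
#'   configuration and this seed.
#' @param annotation_days Days per participant for which briefing-style
#'   annotations are emitted (<= `days`).
#' @param routine Baseline [default_routine_spec()]-shaped routine.
#' @param overrides Optional named list (by participant id, `"P01"`...) of
#'   partial routine overrides, merged element-wise into `routine`; the
#'   special element `drop_sensors` (character vector of sensor ids) removes
#'   sensors from that home's catalog.
#' @param start_date Date (UTC) of the first logging day.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants, days, seed, annotation_days = 2,
                          routine = default_routine_spec(), overrides = list(),
                          start_date = as.Date("2023-03-01")) {
  stopifnot(n_participants >= 1, days >= 1, annotation_days <= days,
            annotation_days >= 0)
  validate_routine(routine)
  structure(list(
    n_participants = as.integer(n_participants), days = as.integer(days),
    seed = as.integer(seed), annotation_days = as.integer(annotation_days),
    routine = routine, overrides = overrides, start_date = start_date
  ), class = "cohort_config")
}

#' The reference cohort configuration
#'
#' Five participants logged for 28 days (seed 7), each home carrying the 18
#' sensors of [default_home_sensors()], routines from
#' [default_routine_spec()], and briefing annotations on 2 days per
#' participant — a scaled-down stand-in for a multi-week deployment of ~20
#' sensors per home with two data-informed briefings.
#'
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function() {
  cohort_config(n_participants = 5, days = 28, seed = 7, annotation_days = 2)
}

# deep-merge override list into a routine; tibbles are replaced wholesale
merge_routine <- function(routine, override) {
  if (is.null(override)) return(routine)
  override$drop_sensors <- NULL
  utils::modifyList(routine, override)
}

round_sec <- function(t) as.POSIXct(round(as.numeric(t)), tz = "UTC",
                                    origin = "1970-01-01")

# plant ADL occurrences for one participant; returns tibble
# (adl, start, duration_min)
plant_occurrences <- function(routine, day_starts) {
  sch <- routine$schedule
  occ <- purrr::map(seq_along(day_starts), function(d) {
    day0 <- day_starts[d]
    keep <- runif(nrow(sch)) < sch$prob
    jit <- rnorm(nrow(sch), mean = 0, sd = sch$jitter_sd_min)
    start_min <- pmin(pmax(sch$clock_min + jit, 0), 1440 - sch$duration_min)
    tibble(adl = sch$adl,
           start = day0 + start_min * 60,
           duration_min = sch$duration_min)[keep, ]
  }) %>% bind_rows()
  occ$start <- round_sec(occ$start)
  arrange(occ, .data$start)
}

# sensor activations for planted occurrences; one activation per signature
# sensor that fires, uniform within the occurrence
signature_events <- function(occ, routine, sensors) {
  rows <- purrr::pmap(occ, function(adl, start, duration_min) {
    sig <- routine$signatures[[adl]]
    sig <- sig[sig$sensor_id %in% sensors$sensor_id, , drop = FALSE]
    if (nrow(sig) == 0) return(NULL)
    fire <- runif(nrow(sig)) < sig$prob
    if (!any(fire)) return(NULL)
    ids <- sig$sensor_id[fire]
    t <- start + runif(length(ids), 0, duration_min * 60)
    tibble(timestamp = round_sec(t), sensor_id = ids)
  })
  bind_rows(rows)
}

# homogeneous Poisson background noise, one activation stream per sensor
noise_events <- function(routine, sensors, t0, t1) {
  hours <- as.numeric(difftime(t1, t0, units = "hours"))
  rows <- purrr::map(seq_len(nrow(sensors)), function(i) {
    k <- rpois(1, routine$noise_rate_per_hour * hours)
    if (k == 0) return(NULL)
    tibble(timestamp = round_sec(t0 + sort(runif(k, 0, hours * 3600))),
           sensor_id = sensors$sensor_id[i])
  })
  bind_rows(rows)
}

# door callers: front-door activations with no leaving-house truth record
caller_events <- function(routine, sensors, day_starts) {
  if (!"front_door" %in% sensors$sensor_id) return(NULL)
  n_days <- length(day_starts)
  k <- rpois(1, routine$caller_rate_per_day * n_days)
  if (k == 0) return(NULL)
  day <- sample.int(n_days, k, replace = TRUE)
  # callers arrive during the day (08:00-20:00)
  t <- day_starts[day] + runif(k, 8 * 3600, 20 * 3600)
  tibble(timestamp = round_sec(sort(t)), sensor_id = "front_door")
}

# regular humidity sampling in the configured room, with linear rise during
# a bath and exponential relaxation afterwards
humidity_readings <- function(routine, sensors, occ, t0, t1) {
  hum <- routine$humidity
  env <- sensors[sensors$sensor_type == "environmental" &
                   sensors$location == hum$room, , drop = FALSE]
  env <- env[purrr::map_lgl(env$channels, ~ "humidity" %in% .x), , drop = FALSE]
  if (nrow(env) == 0) return(NULL)
  baths <- occ[occ$adl == "bathing", , drop = FALSE]
  step <- hum$sampling_interval_min * 60
  tt <- seq(from = as.numeric(t0), to = as.numeric(t1) - 1, by = step)
  value <- hum$baseline + rnorm(length(tt), 0, hum$noise_sd)
  if (nrow(baths) > 0) {
    s <- as.numeric(baths$start)
    e <- s + baths$duration_min * 60
    for (b in seq_along(s)) {
      rise <- tt >= s[b] & tt < e[b]
      value[rise] <- value[rise] + hum$amplitude * (tt[rise] - s[b]) / (e[b] - s[b])
      after <- tt >= e[b]
      value[after] <- value[after] +
        hum$amplitude * exp(-(tt[after] - e[b]) / (hum$decay_min * 60))
    }
  }
  purrr::map(seq_len(nrow(env)), function(i) {
    tibble(timestamp = as.POSIXct(tt, tz = "UTC", origin = "1970-01-01"),
           sensor_id = env$sensor_id[i], channel = "humidity",
           value = round(value, 2))
  }) %>% bind_rows()
}

#' Simulate a synthetic sensor cohort
#'
#' Generates, for each participant: a home catalog; a sensor event log
#' (signature activations for planted ADL occurrences, Poisson background
#' noise, caller-driven front-door activations, and a sampled bathroom
#' humidity series); the planted ground truth (`source = "simulated_truth"`,
#' one record per occurrence, timestamped at its start); and sparse briefing
#' annotations (`source = "briefing"`): the truth records of
#' `annotation_days` randomly chosen days, with timestamps jittered by
#' +/-10 min uniform (recalled, not logged).
#'
#' The humidity series is only sampled for routines that can produce baths
#' (bathing occurrence probability > 0); a silent routine emits no events at
#' all.
#'
#' @param config A [cohort_config()].
#' @return List with tibbles `catalogs`, `events`, `truth`, `annotations`.
#'   Deterministic given `config` (including its seed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  t0 <- as.POSIXct(paste0(format(config$start_date), "T00:00:00Z"),
                   format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  t1 <- t0 + config$days * 86400
  day_starts <- t0 + (seq_len(config$days) - 1) * 86400
  pids <- sprintf("P%02d", seq_len(config$n_participants))

  per <- purrr::map(seq_along(pids), function(i) {
      pid <- pids[i]
      sseed <- function(component) substream_seed(config$seed, i, component)
      ov <- config$overrides[[pid]]
      routine <- validate_routine(merge_routine(config$routine, ov))
      sensors <- default_home_sensors()
      if (!is.null(ov$drop_sensors)) {
        sensors <- sensors[!sensors$sensor_id %in% ov$drop_sensors, , drop = FALSE]
      }
      catalog <- home_catalog(pid, sensors, t0, t1)

      occ <- with_local_seed(sseed(1), plant_occurrences(routine, day_starts))
      bool_ev <- bind_rows(
        with_local_seed(sseed(2), signature_events(
          occ[occ$adl != "bathing", , drop = FALSE], routine, sensors)),
        with_local_seed(sseed(3), {
          # bathing presence: the 6-in-1 motion channel in the bathroom
          baths <- occ[occ$adl == "bathing", , drop = FALSE]
          sig <- routine$signatures$bathing
          sig <- sig[sig$sensor_id %in% sensors$sensor_id, , drop = FALSE]
          if (nrow(baths) > 0 && nrow(sig) > 0) {
            purrr::pmap(baths, function(adl, start, duration_min) {
              fire <- runif(nrow(sig)) < sig$prob
              if (!any(fire)) return(NULL)
              tibble(timestamp = round_sec(start + runif(sum(fire), 0, duration_min * 60)),
                     sensor_id = sig$sensor_id[fire])
            }) %>% bind_rows()
          } else NULL
        }),
        with_local_seed(sseed(4), noise_events(routine, sensors, t0, t1)),
        with_local_seed(sseed(5), caller_events(routine, sensors, day_starts))
      )
      sample_humidity <- any(routine$schedule$prob[routine$schedule$adl == "bathing"] > 0)
      hum_ev <- if (sample_humidity) {
        with_local_seed(sseed(6), humidity_readings(routine, sensors, occ, t0, t1))
      }

      events <- bind_rows(
        if (!is.null(bool_ev) && nrow(bool_ev) > 0) {
          type <- setNames(sensors$sensor_type, sensors$sensor_id)
          mutate(bool_ev,
                 channel = ifelse(type[.data$sensor_id] == "environmental",
                                  "motion", ""),
                 value = 1)
        },
        hum_ev
      )
      if (is.null(events) || nrow(events) == 0) {
        events <- empty_events()[0, c("timestamp", "sensor_id", "channel", "value")]
      }
      events <- mutate(events, participant_id = pid, .before = 1)
      # clamp to the half-open logging interval
      events <- filter(events, .data$timestamp >= t0, .data$timestamp < t1)

      truth <- tibble(participant_id = pid, timestamp = occ$start,
                      adl = occ$adl, source = "simulated_truth")

      ann <- if (config$annotation_days > 0 && nrow(truth) > 0) {
        with_local_seed(sseed(7), {
          chosen <- sort(sample.int(config$days, config$annotation_days))
          keep_day <- findInterval(truth$timestamp, day_starts) %in% chosen
          a <- truth[keep_day, , drop = FALSE]
          if (nrow(a) > 0) {
            jit <- runif(nrow(a), -10 * 60, 10 * 60)
            a$timestamp <- round_sec(pmin(pmax(a$timestamp + jit, t0), t1 - 1))
            a$source <- "briefing"
          }
          a
        })
      } else empty_annotations()

      list(catalog = catalog, events = events, truth = truth, annotations = ann)
    })

  list(
    catalogs = bind_rows(purrr::map(per, "catalog")),
    events = bind_rows(purrr::map(per, "events")) %>%
      arrange(.data$participant_id, .data$timestamp),
    truth = bind_rows(purrr::map(per, "truth")) %>%
      arrange(.data$participant_id, .data$timestamp),
    annotations = bind_rows(purrr::map(per, "annotations")) %>%
      arrange(.data$participant_id, .data$timestamp)
  )
}
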