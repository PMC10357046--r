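# Sliding-window segmentation: grid geometry, half-open membership,
# derived humidity items, labelling.

test_that("an empty day yields the closed-form number of empty windows", {
  cat1 <- kitchen_catalog(days = 1)
  empty_ev <- no_events()
  tx <- build_windows(empty_ev, cat1, "eating_drinking")
  expect_identical(nrow(tx), (1440L - 60L) %/% 5L + 1L)  # 277
  expect_true(all(lengths(tx$items) == 0))
  expect_identical(format_timestamp(tx$window_start[1]), "2023-03-01T00:00:00Z")
  expect_identical(format_timestamp(tx$window_start[277]), "2023-03-01T23:00:00Z")
  # 30-min windows: 283 per day
  tx30 <- build_windows(empty_ev, cat1, "dressing")
  expect_identical(nrow(tx30), (1440L - 30L) %/% 5L + 1L)
})

test_that("a morning kitchen burst lands in one order-independent item set", {
  ev <- dplyr::bind_rows(
    bool_event("P01", "2023-03-01T08:02:00Z", "kettle"),
    bool_event("P01", "2023-03-01T08:10:00Z", "fridge"),
    bool_event("P01", "2023-03-01T08:40:00Z", "toaster")
  )
  tx <- build_windows(ev, kitchen_catalog(), "eating_drinking")
  w <- tx[format_timestamp(tx$window_start) == "2023-03-01T07:45:00Z", ]
  expect_identical(w$items[[1]], c("fridge", "kettle", "toaster"))
  # order-independence: shuffled input gives identical transactions
  tx2 <- build_windows(ev[c(3, 1, 2), ], kitchen_catalog(), "eating_drinking")
  expect_equal(tx, tx2)
})

test_that("window membership matches a brute-force double loop", {
  ev <- random_events(42, n = 200)
  bool_ev <- ev[ev$channel == "", ]
  cat1 <- kitchen_catalog()
  for (adl in c("eating_drinking", "dressing")) {
    tx <- build_windows(bool_ev, cat1, adl)
    sensors <- cat1$sensors[[1]]
    loc <- stats::setNames(sensors$location, sensors$sensor_id)
    type <- stats::setNames(sensors$sensor_type, sensors$sensor_id)
    for (i in seq_len(nrow(tx))) {
      s <- as.numeric(tx$window_start[i]); e <- as.numeric(tx$window_end[i])
      hit <- bool_ev[as.numeric(bool_ev$timestamp) >= s &
                       as.numeric(bool_ev$timestamp) < e, ]
      expected <- as.character(sort(unique(unname(
        ifelse(type[hit$sensor_id] == "motion",
               paste0("presence:", loc[hit$sensor_id]),
               hit$sensor_id)))))
      expect_identical(tx$items[[i]], expected)
    }
  }
})

test_that("humidity rise items require a threshold rise and two readings", {
  cat1 <- kitchen_catalog()
  # steady climb of 12 %RH across 20 min
  ev <- humidity_event("P01", sprintf("2023-03-01T09:%02d:00Z", seq(0, 20, 5)),
                       c(50, 53, 56, 59, 62))
  tx <- build_windows(ev, cat1, "bathing")
  w <- tx[format_timestamp(tx$window_start) == "2023-03-01T08:30:00Z", ]
  expect_identical(w$items[[1]], "humidity_rise:bathroom")
  # a single reading in the window can never carry the item
  lone <- tx[format_timestamp(tx$window_start) == "2023-03-01T08:05:00Z", ]
  expect_identical(lone$items[[1]], character(0))
  # sub-threshold rise: no item
  ev2 <- humidity_event("P01", c("2023-03-01T09:00:00Z", "2023-03-01T09:30:00Z"),
                        c(50, 59))
  tx2 <- build_windows(ev2, cat1, "bathing")
  expect_true(all(lengths(tx2$items) == 0))
})

test_that("sparser humidity sampling cannot add humidity-rise windows", {
  r <- quiet_routine(active = "bathing")
  r$schedule$prob[r$schedule$adl == "bathing"] <- 1
  base <- cohort_config(1, 7, seed = 6, annotation_days = 0, routine = r)
  r10 <- r; r10$humidity$sampling_interval_min <- 10
  sparse <- cohort_config(1, 7, seed = 6, annotation_days = 0, routine = r10)
  count_rise <- function(cfg) {
    sim <- simulate_cohort(cfg)
    tx <- build_windows(sim$events, sim$catalogs, "bathing")
    sum(vapply(tx$items, function(x) "humidity_rise:bathroom" %in% x, logical(1)))
  }
  expect_lte(count_rise(sparse), count_rise(base))
})

test_that("enlarging the window never removes items from a shared start", {
  ev <- random_events(7, n = 120)
  cat1 <- kitchen_catalog()
  tx30 <- build_windows(ev, cat1, "dressing")    # 30 min
  tx60 <- build_windows(ev, cat1, "bathing")     # 60 min
  common <- intersect(format_timestamp(tx30$window_start),
                      format_timestamp(tx60$window_start))
  k30 <- stats::setNames(tx30$items, format_timestamp(tx30$window_start))
  k60 <- stats::setNames(tx60$items, format_timestamp(tx60$window_start))
  for (s in common) {
    # humidity-rise is an aggregate, not monotone in window size; boolean
    # and presence items must be preserved
    b30 <- setdiff(k30[[s]], grep("^humidity_rise:", k30[[s]], value = TRUE))
    b60 <- setdiff(k60[[s]], grep("^humidity_rise:", k60[[s]], value = TRUE))
    expect_true(all(b30 %in% b60))
  }
})

test_that("labelling uses half-open window membership", {
  cat1 <- kitchen_catalog()
  tx <- build_windows(no_events(), cat1, "dressing")
  ann <- tibble::tibble(participant_id = "P01",
                        timestamp = utc("2023-03-01T08:00:00Z"),
                        adl = "dressing", source = "briefing")
  lab <- label_windows(tx, ann, "dressing")
  starts <- format_timestamp(lab$window_start[!is.na(lab$label)])
  # annotation at a window's start labels it; at a window's end does not
  expect_true("2023-03-01T08:00:00Z" %in% starts)
  expect_false("2023-03-01T07:30:00Z" %in% starts)
  expect_identical(min(starts), "2023-03-01T07:35:00Z")

  # brute-force oracle over random annotations
  ann2 <- tibble::tibble(
    participant_id = "P01",
    timestamp = utc("2023-03-01T00:00:00Z") + withr::with_seed(1, floor(runif(20, 0, 86400))),
    adl = "dressing", source = "briefing")
  lab2 <- label_windows(tx, ann2, "dressing")
  for (i in seq_len(nrow(lab2))) {
    expected <- any(as.numeric(ann2$timestamp) >= as.numeric(lab2$window_start[i]) &
                      as.numeric(ann2$timestamp) < as.numeric(lab2$window_end[i]))
    expect_identical(!is.na(lab2$label[i]), expected)
  }
})

test_that("an unconfigured ADL window size is a configuration error", {
  spec <- window_spec(window_min = c(dressing = 30))
  expect_error(build_windows(no_events(), kitchen_catalog(), "bathing", spec),
               class = "adlminer_config_error")
  expect_error(window_spec(stride_min = 7))
})
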