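# Summaries, core-sensor ranking, evaluation, leave-one-out.

fake_detections <- function(pid, counts,
                            day0 = utc("2023-03-01T00:00:00Z")) {
  rows <- purrr::imap(counts, function(n, adl) {
    if (n == 0) return(NULL)
    tibble::tibble(
      participant_id = pid, adl = adl,
      window_start = day0 + 3600 * seq_len(n),
      window_end = day0 + 3600 * seq_len(n) + 1800,
      fired_rule_id = paste0("pooled_", adl, "_001"))
  })
  dplyr::bind_rows(rows)
}

two_homes <- function(days1 = 28, days2 = 14) {
  dplyr::bind_rows(kitchen_catalog("P01", days = days1),
                   kitchen_catalog("P02", days = days2))
}

test_that("summaries compute proportions and day-normalised counts", {
  det <- fake_detections("P01", c(eating_drinking = 40, dressing = 20,
                                  bathing = 20, leaving_house = 20))
  smry <- summarize_adl(det, two_homes(), reference_days = 28)
  p1 <- smry[smry$participant_id == "P01", ]
  expect_identical(p1$proportion,
                   c(0.4, 0.2, 0.2, 0.2))
  expect_identical(p1$adl, adl_labels())
  # P02 logged 14 days against a 28-day reference: normalised = 2x raw
  det2 <- dplyr::bind_rows(det, fake_detections("P02", c(eating_drinking = 7)))
  smry2 <- summarize_adl(det2, two_homes(), reference_days = 28)
  p2 <- smry2[smry2$participant_id == "P02" &
                smry2$adl == "eating_drinking", ]
  expect_identical(p2$n_normalized, 14)
  expect_identical(p2$per_day, 0.5)
  expect_identical(p2$proportion, 1)
  # doubling the reference doubles every normalised count
  smry3 <- summarize_adl(det2, two_homes(), reference_days = 56)
  expect_equal(smry3$n_normalized, 2 * smry2$n_normalized)
  # "max" resolves to the longest logging duration in the cohort
  smry4 <- summarize_adl(det2, two_homes())
  expect_identical(attr(smry4, "reference_days"), 28)
})

test_that("proportions sum to one for every participant with detections", {
  det <- dplyr::bind_rows(
    fake_detections("P01", c(eating_drinking = 13, dressing = 7, bathing = 3)),
    fake_detections("P02", c(leaving_house = 5)))
  smry <- summarize_adl(det, two_homes())
  sums <- tapply(smry$proportion, smry$participant_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # a participant with no detections for an ADL reports proportion 0
  expect_identical(
    smry$proportion[smry$participant_id == "P02" &
                      smry$adl == "eating_drinking"], 0)
})

test_that("core-sensor ranking scores rule presence and firing share", {
  rules <- structure(tibble::tibble(
    rule_id = c("pooled_eating_drinking_001", "pooled_eating_drinking_002"),
    adl = "eating_drinking",
    antecedent = list("kettle", c("fridge", "kettle")),
    support = c(0.4, 0.2), confidence = c(0.9, 0.95), provenance = "pooled"
  ), class = c("adl_rules", class(tibble::tibble())))
  det <- fake_detections("P01", c(eating_drinking = 10))
  ranking <- core_sensor_ranking(rules, det)
  expect_identical(ranking$item[1], "kettle")
  expect_identical(ranking$rule_presence[ranking$item == "kettle"], 1)
  expect_identical(ranking$fire_share[ranking$item == "kettle"], 1)
  expect_identical(ranking$fire_share[ranking$item == "fridge"], 0)
  # top_k beyond the distinct item count returns the full list, no padding
  expect_identical(nrow(core_sensor_ranking(rules, det, top_k = 50)), 2L)
  # permutation-invariance in the inputs
  r2 <- core_sensor_ranking(rules[2:1, ], det[sample.int(nrow(det)), ])
  expect_equal(r2$item, ranking$item)
  expect_equal(r2$score, ranking$score)
})

test_that("evaluation handles perfect, empty and degenerate cases", {
  truth <- tibble::tibble(
    participant_id = "P01",
    timestamp = utc(c("2023-03-01T08:10:00Z", "2023-03-01T13:10:00Z")),
    adl = "eating_drinking", source = "simulated_truth")
  det <- tibble::tibble(
    participant_id = "P01", adl = "eating_drinking",
    window_start = utc(c("2023-03-01T08:00:00Z", "2023-03-01T13:00:00Z")),
    window_end = utc(c("2023-03-01T09:00:00Z", "2023-03-01T14:00:00Z")),
    fired_rule_id = "r1")
  ev <- evaluate_detections(det, truth)
  row <- ev[ev$adl == "eating_drinking", ]
  expect_identical(row$precision, 1)
  expect_identical(row$recall, 1)
  expect_identical(row$f1, 1)
  # empty detections, nonempty truth: recall 0, precision flagged undefined
  ev0 <- evaluate_detections(det[0, ], truth)
  row0 <- ev0[ev0$adl == "eating_drinking", ]
  expect_identical(row0$recall, 0)
  expect_identical(row0$precision, 0)
  expect_false(row0$precision_defined)
})

test_that("greedy matching is near the optimal bipartite matching", {
  skip_if_not_installed("igraph")
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n_det <- sample(3:12, 1)
      n_tr <- sample(3:12, 1)
      day0 <- utc("2023-03-01T00:00:00Z")
      det <- tibble::tibble(
        participant_id = "P01", adl = "dressing",
        window_start = day0 + sort(floor(runif(n_det, 0, 82800))),
        fired_rule_id = "r1") |>
        dplyr::mutate(window_end = window_start + 1800) |>
        dplyr::select(participant_id, adl, window_start, window_end,
                      fired_rule_id)
      truth <- tibble::tibble(
        participant_id = "P01",
        timestamp = day0 + floor(runif(n_tr, 0, 86400)),
        adl = "dressing", source = "simulated_truth")
      ev <- evaluate_detections(det, truth)
      tp_greedy <- ev$tp[ev$adl == "dressing"]
      tp_opt <- optimal_match_count(det, truth)
      f1 <- function(tp) if (tp == 0) 0 else {
        p <- tp / n_det; r <- tp / n_tr; 2 * p * r / (p + r)
      }
      expect_lte(abs(f1(tp_greedy) - f1(tp_opt)), 0.05)
      expect_lte(tp_greedy, tp_opt)
    })
  }
})

test_that("leave-one-out gives zero recall only where sensors are missing", {
  # dressing-only cohort; P03 has no dressing-related sensors at all
  r <- quiet_routine(active = "dressing")
  cfg <- cohort_config(
    3, 10, seed = 23, annotation_days = 3, routine = r,
    overrides = list(P03 = list(drop_sensors = c("wardrobe_door",
                                                 "underwear_drawer",
                                                 "motion_bedroom"))))
  sim <- simulate_cohort(cfg)
  res <- adl_loocv(sim$events, sim$catalogs, sim$annotations, sim$truth)
  d3 <- res[res$held_out == "P03" & res$adl == "dressing", ]
  expect_identical(d3$recall, 0)
  others <- res[res$held_out != "P03" & res$adl == "dressing", ]
  expect_true(all(others$recall > 0.9))
})
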