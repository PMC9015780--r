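# differential_engine: minute differentials, daily aggregation, window statistic

test_that("minute differentials follow the right-minus-left convention", {
  s <- flat_stream(mins = 1L, left = 92, right = 95)
  d <- minute_differentials(s)
  expect_equal(nrow(d), 6L)  # one record per site
  expect_true(all(d$delta == 3))
  expect_true(all(d$abs_delta == 3))
})

test_that("minutes without bilateral wear are skipped, not zero-filled", {
  dt <- flat_stream(n_days = 1L, mins = 4L)$data
  dt[minute == 2L, worn_right := FALSE]
  d <- minute_differentials(patient_stream("P1", dt))
  expect_equal(sort(unique(d$minute)), c(0L, 1L, 3L))
  # a stream never worn at all gives empty output, not an error
  empty <- flat_stream(n_days = 1L, mins = 2L, worn_left = FALSE, worn_right = FALSE)
  expect_equal(nrow(minute_differentials(empty)), 0L)
  # one foot never appearing is unsupported (no contralateral reference)
  expect_error(minute_differentials(flat_stream(mins = 3L, worn_right = FALSE)),
               "both feet")
})

test_that("daily averages equal a brute-force triple loop on random small streams", {
  set.seed(77)
  for (rep in 1:20) {
    n_days <- sample(1:3, 1)
    mins <- sample(3:10, 1)
    dt <- data.table::CJ(day = 0:(n_days - 1L), minute = 0:(mins - 1L))
    dt[, worn_left := runif(.N) > 0.2]
    dt[, worn_right := runif(.N) > 0.2]
    for (col in as.vector(outer(FEET, FOOT_LOCATIONS, paste, sep = "_"))) {
      data.table::set(dt, j = col, value = round(runif(nrow(dt), 85, 95), 2))
    }
    s <- patient_stream("BF", dt)
    got <- daily_averages(minute_differentials(s))
    # naive recomputation: loop days, locations, minutes
    for (dd in 0:(n_days - 1L)) {
      for (loc in FOOT_LOCATIONS) {
        vals <- c()
        for (mm in 0:(mins - 1L)) {
          r <- dt[day == dd & minute == mm]
          if (r$worn_left && r$worn_right) {
            vals <- c(vals, abs(r[[paste0("right_", loc)]] - r[[paste0("left_", loc)]]))
          }
        }
        row <- got[day == dd & location == loc]
        if (length(vals) == 0) {
          expect_equal(nrow(row), 0L)
        } else {
          expect_equal(row$mean_abs_delta, mean(vals))
          expect_equal(row$n_minutes, length(vals))
        }
      }
    }
  }
})

test_that("adding a constant to the right foot shifts a symmetric stream's deltas exactly", {
  s <- flat_stream(n_days = 2L, mins = 6L, left = 90, right = 90)
  shifted <- data.table::copy(s$data)
  for (loc in FOOT_LOCATIONS) {
    data.table::set(shifted, j = paste0("right_", loc),
                    value = shifted[[paste0("right_", loc)]] + 2.5)
  }
  d <- minute_differentials(patient_stream("P1", shifted))
  expect_true(all(d$abs_delta == 2.5))
})

test_that("daily averages are invariant to input row order", {
  cfg <- small_config(days = 3L, n_study = 0L, n_control = 1L,
                      wear_minutes_per_day_mean = 60, wear_minutes_per_day_sd = 0)
  d <- minute_differentials(generate_cohorts(cfg)$streams[[1]])
  shuffled <- d[sample(nrow(d))]
  expect_equal(daily_averages(shuffled), daily_averages(d))
})

test_that("window statistic pools retained minutes across sites", {
  # two sites with {1,2,3} and {4,5,6} over three retained minutes -> 3.5
  diffs <- data.table::data.table(
    patient_id = "P1", day = 0L, minute = rep(0:2, 2),
    location = rep(c("hallux", "heel"), each = 3),
    delta = c(1, 2, 3, 4, 5, 6), abs_delta = c(1, 2, 3, 4, 5, 6)
  )
  w <- analysis_window("P1", "pre_injury", 0L, 0L,
                       data.table::data.table(day = 0L, minute = 0:2), "all")
  expect_equal(patient_window_statistic(diffs, w), 3.5)
  # day_first collapses each (day, location) cell before averaging: same here
  expect_equal(patient_window_statistic(diffs, w, mode = "day_first"), 3.5)
  # constant case
  diffs2 <- data.table::copy(diffs)[, abs_delta := 2.0]
  expect_equal(patient_window_statistic(diffs2, w), 2.0)
  # empty selection errors
  w_empty <- analysis_window("P1", "pre_injury", 5L, 5L,
                             data.table::data.table(day = 5L, minute = 0L), "all")
  expect_error(patient_window_statistic(diffs, w_empty), "no differential")
})

test_that("the two statistic modes diverge under unbalanced minutes", {
  diffs <- data.table::data.table(
    patient_id = "P1", day = c(0L, 0L, 0L, 1L), minute = c(0L, 1L, 2L, 0L),
    location = "hallux", delta = c(1, 1, 1, 7), abs_delta = c(1, 1, 1, 7)
  )
  w <- analysis_window("P1", "pre_injury", 0L, 1L, diffs[, .(day, minute)], "all")
  expect_equal(patient_window_statistic(diffs, w, "minute_pooled"), 10 / 4)
  expect_equal(patient_window_statistic(diffs, w, "day_first"), (1 + 7) / 2)
})

test_that("matches an independent re-summation on a generated pre-injury window", {
  cfg <- small_config(bilateral_noise_sd = 0.4)
  inj <- short_injury(diagnosis_day = 30L, peak = 5, ramp = 4L, onset = 20L)
  s <- simulate_patient_stream(list(patient_id = "W", injury = inj), cfg)
  d <- minute_differentials(s)
  w <- extract_preinjury_window(s, 30L, seed = 5L)
  got <- patient_window_statistic(d, w)
  # oracle: re-sum by explicit key matching
  key <- paste(w$minutes$day, w$minutes$minute)
  vals <- d[paste(day, minute) %in% key, abs_delta]
  expect_equal(got, sum(vals) / length(vals))
})
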