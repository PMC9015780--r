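# synthetic_data: stream construction, calibration-free invariants, cohorts

test_that("identical config and seed give bit-identical registry and streams", {
  cfg <- small_config()
  a <- generate_cohorts(cfg)
  b <- generate_cohorts(cfg)
  expect_identical(a$registry, b$registry)
  for (pid in names(a$streams)) {
    expect_identical(a$streams[[pid]]$data, b$streams[[pid]]$data)
  }
  # a different seed actually changes the streams
  c2 <- generate_cohorts(small_config(seed = 202L))
  expect_false(identical(a$streams[[1]]$data, c2$streams[[1]]$data))
})

test_that("noiseless symmetric construction gives exactly zero differentials", {
  cfg <- small_config(n_study = 0L, n_control = 1L, bilateral_noise_sd = 0)
  s <- generate_cohorts(cfg)$streams[[1]]
  d <- minute_differentials(s)
  expect_gt(nrow(d), 0)
  expect_true(all(d$abs_delta == 0))  # circadian/drift/baseline cancel exactly
})

test_that("a step injury (ramp 0) forces the exact peak offset from onset", {
  cfg <- small_config(bilateral_noise_sd = 0)
  inj <- short_injury(diagnosis_day = 30L, peak = 5, ramp = 0L, onset = 20L)
  s <- simulate_patient_stream(list(patient_id = "X", injury = inj), cfg)
  d <- minute_differentials(s)
  at <- d[location == "hallux"]
  expect_true(all(at[day >= 20L]$delta == 5))
  expect_true(all(at[day < 20L]$delta == 0))
  expect_true(all(d[location != "hallux"]$abs_delta == 0))
})

test_that("minute differential sd matches noise_sd * sqrt(2) at large n", {
  cfg <- small_config(n_study = 0L, n_control = 1L, days = 25L,
                      wear_minutes_per_day_mean = 600,
                      wear_minutes_per_day_sd = 0, bilateral_noise_sd = 0.5)
  s <- generate_cohorts(cfg)$streams[[1]]
  d <- minute_differentials(s)[location == "heel"]
  expect_gte(nrow(d), 10000)
  expect_lt(abs(sd(d$delta) - 0.5 * sqrt(2)) / (0.5 * sqrt(2)), 0.05)
  # null symmetry: empirical mean within 4 standard errors of zero
  se <- sd(d$delta) / sqrt(nrow(d))
  expect_lt(abs(mean(d$delta)), 4 * se)
})

test_that("injected offset is recovered within the CLT bound after the ramp", {
  sigma <- 0.5
  cfg <- small_config(bilateral_noise_sd = sigma, days = 40L,
                      wear_minutes_per_day_mean = 300,
                      wear_minutes_per_day_sd = 0)
  inj <- short_injury(diagnosis_day = 30L, peak = 6, ramp = 5L, onset = 15L)
  s <- simulate_patient_stream(list(patient_id = "X", injury = inj), cfg)
  post <- minute_differentials(s)[location == "hallux" & day >= 20L & day < 40L]
  n <- nrow(post)
  expect_lt(abs(mean(post$abs_delta) - 6), 4 * sigma * sqrt(2) / sqrt(n))
})

test_that("daily wear budget matches the configured mean within 5%", {
  cfg <- small_config(n_study = 0L, n_control = 1L, days = 120L,
                      wear_minutes_per_day_mean = 480,
                      wear_minutes_per_day_sd = 60)
  s <- generate_cohorts(cfg)$streams[[1]]
  per_day <- s$data[, .(n = sum(worn_left & worn_right)), by = day]
  expect_lt(abs(mean(per_day$n) - 480) / 480, 0.05)
})

test_that("default registry reproduces the cohort margins", {
  reg <- build_registry(generator_config())
  expect_equal(sum(reg$cohort == "study"), 5L)
  expect_equal(sum(reg$cohort == "control"), 26L)
  ctl <- reg[cohort == "control"]
  expect_equal(sum(grepl("diabetes", ctl$diagnoses)), 24L)
  expect_equal(sum(grepl("peripheral_artery_disease", ctl$diagnoses)), 5L)
  expect_equal(sum(ctl$sex == "female"), 9L)
  expect_equal(round(mean(ctl$age), 1), 70.4)
  st <- reg[cohort == "study"]
  expect_equal(st$age, c(68L, 75L, 61L, 48L, 76L))
  expect_equal(sum(st$sex == "female"), 1L)
  # every patient carries the eligibility diagnosis; injury iff study
  expect_true(all(grepl("neuropathy", reg$diagnoses)))
  expect_true(all(is.na(reg$injury_type) == (reg$cohort == "control")))
})

test_that("degenerate and invalid configurations are rejected cleanly", {
  expect_s3_class(build_registry(small_config(n_study = 0L)), "data.table")
  expect_equal(nrow(build_registry(small_config(n_study = 0L, n_control = 3L))), 3L)
  expect_error(generator_config(ambient_temp = 90, baseline_temp_mean = 85),
               "ambient_temp")
  expect_error(injury_spec("charcot", "right", "hallux", 10, 20, 5, 3),
               "all 6 locations")
  expect_error(injury_spec("ulcer", "right", "hallux", 20, 10, 5, 3),
               "onset_day")
  expect_error(
    simulate_patient_stream(
      list(patient_id = "X", injury = short_injury(diagnosis_day = 90L, onset = 80L)),
      small_config(days = 40L)),
    "outside the observation span")
})
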