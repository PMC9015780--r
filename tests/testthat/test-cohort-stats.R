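# cohort_stats: summaries, Welch t from formula, demographics, orchestration

test_that("cohort summaries use the sample (n-1) standard deviation", {
  s <- summarize_cohort(c(3, 4, 5), "study")
  expect_equal(s$mean, 4.0)
  expect_equal(s$sd, 1.0)
  expect_equal(s$n, 3L)
  expect_equal(summarize_cohort(c(2, 2, 2), "control")$sd, 0)
  expect_error(summarize_cohort(numeric(), "study"), "empty")
  expect_error(summarize_cohort(3.2, "control"), "single patient")
})

test_that("welch_t matches the reference implementation on random samples", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(99)
  for (rep in 1:200) {
    a <- rnorm(sample(2:20, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:20, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    got <- welch_t(a, b)
    ref <- stats::t.test(a, b, var.equal = FALSE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(c(got$ci_low, got$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-10)
    # invariants
    expect_gt(got$df, 0)
    expect_true(got$ci_low <= got$mean_diff && got$mean_diff <= got$ci_high)
  }
  expect_error(welch_t(c(1, 1), c(2, 2)), "variances are zero")
})

test_that("scaling both samples scales the mean difference but not t", {
  a <- c(1.2, 3.4, 2.2, 4.1); b <- c(0.5, 1.1, 0.9)
  w1 <- welch_t(a, b); w3 <- welch_t(3 * a, 3 * b)
  expect_equal(w3$t, w1$t)
  expect_equal(w3$mean_diff, 3 * w1$mean_diff)
})

test_that("demographics percentages round half away from zero", {
  reg <- build_registry(generator_config())
  tab <- demographics_table(reg)
  expect_equal(tab[cohort == "control"]$diabetes_cell, "24 (92)")
  expect_equal(tab[cohort == "study"]$diabetes_cell, "3 (60)")
  expect_equal(tab[cohort == "study"]$pad_cell, "2 (40)")
  expect_equal(tab[cohort == "control"]$pad_cell, "5 (19)")
  one <- data.table::data.table(patient_id = "X", age = 50L, sex = "male",
                                diagnoses = "neuropathy", cohort = "study")
  t1 <- demographics_table(one)
  expect_equal(t1$male, 1L)
  expect_equal(t1$female, 0L)
  expect_error(demographics_table(one[0]), "empty")
})

test_that("noiseless symmetric cohorts are reported as a degenerate comparison", {
  cfg <- small_config(n_study = 0L, n_control = 4L, bilateral_noise_sd = 0,
                      days = 20L, wear_minutes_per_day_mean = 120,
                      wear_minutes_per_day_sd = 0)
  co <- generate_cohorts(cfg)
  # treat two controls as a pseudo-study arm so both cohorts exist
  co$registry[1:2, `:=`(cohort = "study", diagnosis_day = 18L, onset_day = 10L,
                        injury_type = "ulcer", injury_foot = "right",
                        injury_locations = "hallux")]
  rep <- run_cohort_comparison(co$registry, co$streams,
                               params = list(min_wear_days = 10L), seed = 4L)
  expect_null(rep$welch)
  expect_match(rep$degenerate, "variances are zero")
  expect_equal(rep$study$mean, 0)
  expect_equal(rep$control$mean, 0)
})

test_that("injected injuries push the study mean above the control mean", {
  wins <- vapply(1:8, function(i) {
    cfg <- small_config(n_study = 2L, n_control = 3L, seed = 1000L + i)
    co <- generate_cohorts(cfg, presets = list(
      short_injury(diagnosis_day = 30L, peak = 6, ramp = 3L, onset = 22L),
      injury_spec("osteomyelitis", "left", FOOT_LOCATIONS, 15L, 32L, 5, 8L)
    ))
    r <- run_cohort_comparison(co$registry, co$streams,
                               params = list(min_wear_days = 20L), seed = i)
    r$study$mean > r$control$mean
  }, logical(1))
  expect_true(all(wins))
})

test_that("reports are reproducible and serialize deterministically", {
  cfg <- small_config(seed = 7L)
  co <- generate_cohorts(cfg)
  params <- list(min_wear_days = 20L)
  r1 <- run_cohort_comparison(co$registry, co$streams, params, seed = 11L)
  r2 <- run_cohort_comparison(co$registry, co$streams, params, seed = 11L)
  expect_identical(as.character(report_to_json(r1)), as.character(report_to_json(r2)))
  # pseudo-replication mode is labeled and inflates the minute-level n
  rp <- run_cohort_comparison(co$registry, co$streams, params, seed = 11L,
                              pseudoreplicate_minutes = TRUE)
  expect_match(rp$unit_of_analysis, "pseudo-replication")
  # one study patient, 900 retained minutes x 6 sites
  expect_equal(rp$welch$n_a, 5400L)
})
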