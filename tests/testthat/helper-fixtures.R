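## Fixtures are always built in code, never stored.

## A flat hand-built stream: `mins` worn minutes per day for `n_days`, all
## left sensors at `left` and right sensors at `right` (scalars or vectors
## named by location). Extra unworn minutes can be appended per day.
flat_stream <- function(pid = "P1", n_days = 1L, mins = 10L,
                        left = 90, right = 90,
                        worn_left = TRUE, worn_right = TRUE,
                        unworn_mins = 0L, ambient = 72) {
  as_loc <- function(x) if (is.null(names(x))) setNames(rep_len(x, 6), FOOT_LOCATIONS) else x
  left <- as_loc(left)
  right <- as_loc(right)
  dt <- data.table::CJ(day = 0:(n_days - 1L), minute = 0:(mins + unworn_mins - 1L))
  worn <- dt$minute < mins
  wl <- worn & worn_left
  wr <- worn & worn_right
  dt[, worn_left := wl]
  dt[, worn_right := wr]
  for (loc in FOOT_LOCATIONS) {
    data.table::set(dt, j = paste0("left_", loc), value = ifelse(wl, left[[loc]], ambient))
    data.table::set(dt, j = paste0("right_", loc), value = ifelse(wr, right[[loc]], ambient))
  }
  patient_stream(pid, dt)
}

## tiny generator configs so simulation-backed tests stay fast
small_config <- function(...) {
  ## 70-day span so the default archetype presets (first diagnosis day 60)
  ## still fit when tests use generate_cohorts() without custom presets
  defaults <- list(n_study = 1L, n_control = 2L, days = 70L,
                   wear_minutes_per_day_mean = 240,
                   wear_minutes_per_day_sd = 30, seed = 101L)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

## an injury preset whose diagnosis fits a short span
short_injury <- function(diagnosis_day = 30L, type = "ulcer", peak = 5,
                         ramp = 0L, locations = "hallux", foot = "right",
                         onset = diagnosis_day - 10L) {
  injury_spec(type, foot, locations, onset, diagnosis_day, peak, ramp)
}

## naive alert-rule oracle: scan every row
oracle_alert_pairs <- function(dailies, threshold = 4, min_minutes = 30) {
  hits <- character()
  for (i in seq_len(nrow(dailies))) {
    r <- dailies[i]
    if (r$mean_abs_delta > threshold && r$n_minutes >= min_minutes) {
      hits <- c(hits, paste(r$patient_id, r$day, r$location))
    }
  }
  sort(hits)
}

## random dailies table for property tests
random_dailies <- function(n = 30L, pid = "P1") {
  data.table::data.table(
    patient_id = pid,
    day = sample.int(20L, n, replace = TRUE) - 1L,
    location = sample(FOOT_LOCATIONS, n, replace = TRUE),
    mean_abs_delta = round(stats::runif(n, 0, 8), 2),
    n_minutes = sample.int(120L, n, replace = TRUE)
  )[!duplicated(paste(day, location))]
}
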