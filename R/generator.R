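## Synthetic sensor-stream generator.
##
## Emulates a bilateral smart-sock monitoring registry: per-minute
## temperatures at the 6 plantar sites on each foot, daily wear/off cycles,
## a shared circadian rhythm, day-level drift, independent per-sensor noise,
## and injectable unilateral inflammation events. Every common-mode term is
## shared by both feet so the expected contralateral differential is exactly
## zero absent injury.

#' Generator configuration
#'
#' Parameters of the synthetic bilateral temperature-stream generator. The
#' defaults describe the monitored population the analysis pipeline assumes:
#' a 135-day observation span, roughly eight hours of daily sock wear, and a
#' per-sensor minute-level noise level calibrated so that the mean absolute
#' contralateral differential of an uninjured patient is about 2.2 degrees F
#' (see the methods vignette for the calibration argument).
#'
#' @param n_study number of injured (study-cohort) patients.
#' @param n_control number of uninjured (control-cohort) patients.
#' @param days observation span in days, day index 0-based from enrollment.
#' @param wear_minutes_per_day_mean,wear_minutes_per_day_sd normal mean/sd of
#'   the daily contiguous wear block length, in minutes (clamped to
#'   \[0, 1440\]). Both socks are worn as a pair.
#' @param baseline_temp_mean,baseline_temp_sd per-patient skin-contact
#'   baseline temperature, degrees F; drawn once per patient and shared by
#'   both feet.
#' @param bilateral_noise_sd independent per-sensor per-minute Gaussian noise
#'   sd, degrees F. The minute differential at a site is then
#'   N(0, bilateral_noise_sd * sqrt(2)) for an uninjured patient.
#' @param circadian_amplitude amplitude, degrees F, of a sinusoid with a
#'   1440-minute period shared by both feet (common mode; cancels in the
#'   differential).
#' @param drift_sd sd of the day-level random-walk drift shared by both feet,
#'   degrees F per day.
#' @param ambient_temp reading reported while the sock is not worn, degrees F.
#' @param seed integer master seed; identical config + seed gives
#'   bit-identical registries and streams.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_study = 5L,
                             n_control = 26L,
                             days = 135L,
                             wear_minutes_per_day_mean = 480,
                             wear_minutes_per_day_sd = 60,
                             baseline_temp_mean = 85,
                             baseline_temp_sd = 1.5,
                             bilateral_noise_sd = 1.95,
                             circadian_amplitude = 1.5,
                             drift_sd = 0.3,
                             ambient_temp = 72,
                             seed = 20201201L) {
  cfg <- list(
    n_study = as.integer(n_study), n_control = as.integer(n_control),
    days = as.integer(days),
    wear_minutes_per_day_mean = wear_minutes_per_day_mean,
    wear_minutes_per_day_sd = wear_minutes_per_day_sd,
    baseline_temp_mean = baseline_temp_mean,
    baseline_temp_sd = baseline_temp_sd,
    bilateral_noise_sd = bilateral_noise_sd,
    circadian_amplitude = circadian_amplitude,
    drift_sd = drift_sd,
    ambient_temp = ambient_temp,
    seed = as.integer(seed)
  )
  if (cfg$n_study < 0L || cfg$n_control < 0L) stopf("cohort sizes must be >= 0")
  if (cfg$days <= 0L) stopf("`days` must be > 0")
  if (cfg$wear_minutes_per_day_mean <= 0) stopf("`wear_minutes_per_day_mean` must be > 0")
  sds <- c(cfg$wear_minutes_per_day_sd, cfg$baseline_temp_sd,
           cfg$bilateral_noise_sd, cfg$drift_sd)
  if (any(sds < 0)) stopf("standard deviations must be >= 0")
  if (cfg$circadian_amplitude < 0) stopf("`circadian_amplitude` must be >= 0")
  if (cfg$ambient_temp >= cfg$baseline_temp_mean) {
    stopf("`ambient_temp` must be below `baseline_temp_mean`")
  }
  structure(cfg, class = "generator_config")
}

#' Injury event specification
#'
#' Describes one unilateral inflammation event: the affected foot and sites,
#' the day the process starts (`onset_day`), the day it was clinically
#' diagnosed (`diagnosis_day`), and a linear temperature ramp from 0 at
#' onset to `peak_offset` degrees F at `onset_day + ramp_days`, sustained
#' thereafter. Diffuse archetypes (charcot, osteomyelitis, dvt) must affect
#' all 6 sites; focal archetypes (ulcer, blister) affect 1-2.
#'
#' @param injury_type one of `"charcot"`, `"ulcer"`, `"osteomyelitis"`,
#'   `"dvt"`, `"blister"`.
#' @param foot `"left"` or `"right"`.
#' @param locations character vector of affected sites (subset of
#'   [FOOT_LOCATIONS]).
#' @param onset_day,diagnosis_day 0-based day indices, `onset_day <
#'   diagnosis_day`.
#' @param peak_offset peak added temperature on the affected side, degrees F
#'   (> 0).
#' @param ramp_days days from onset to peak; 0 means an immediate step to
#'   `peak_offset` at onset.
#' @return a validated `injury_spec` list.
#' @export
injury_spec <- function(injury_type, foot, locations, onset_day,
                        diagnosis_day, peak_offset, ramp_days) {
  types <- c("charcot", "ulcer", "osteomyelitis", "dvt", "blister")
  injury_type <- match.arg(injury_type, types)
  foot <- match.arg(foot, FEET)
  if (!all(locations %in% FOOT_LOCATIONS) || length(locations) == 0) {
    stopf("`locations` must be a non-empty subset of the 6 plantar sites")
  }
  locations <- FOOT_LOCATIONS[FOOT_LOCATIONS %in% locations]
  diffuse <- injury_type %in% c("charcot", "osteomyelitis", "dvt")
  if (diffuse && length(locations) != 6L) {
    stopf("diffuse archetype '%s' must affect all 6 locations", injury_type)
  }
  if (!diffuse && length(locations) > 2L) {
    stopf("focal archetype '%s' affects at most 2 locations", injury_type)
  }
  if (!(onset_day < diagnosis_day)) stopf("`onset_day` must precede `diagnosis_day`")
  if (onset_day < 0) stopf("`onset_day` must be >= 0")
  if (peak_offset <= 0) stopf("`peak_offset` must be > 0")
  if (ramp_days < 0) stopf("`ramp_days` must be >= 0")
  structure(
    list(injury_type = injury_type, foot = foot, locations = locations,
         onset_day = as.integer(onset_day),
         diagnosis_day = as.integer(diagnosis_day),
         peak_offset = peak_offset, ramp_days = as.integer(ramp_days)),
    class = "injury_spec"
  )
}

#' Default injury archetype presets
#'
#' Five clinical archetypes mirroring the kinds of events continuous plantar
#' monitoring is deployed to catch: early Charcot arthropathy (acute diffuse
#' hotspots a few days before presentation), a focal hallux blister, chronic
#' osteomyelitis (persistent hotspots at all six sites), a fifth-metatarsal
#' ulcer with adjacent involvement, and a deep-vein thrombosis warming the
#' entire foot. Peak offsets are calibrated (see `scripts/calibrate.R` and
#' the methods vignette) so that the expected study-cohort window statistic
#' is close to 3.6 degrees F under the default noise level.
#'
#' @param diagnosis_days diagnosis day for each archetype; the default spaces
#'   the five events across the default 135-day span.
#' @return list of [injury_spec()] objects.
#' @export
default_injury_presets <- function(diagnosis_days = c(60L, 75L, 90L, 105L, 120L)) {
  stopifnot(length(diagnosis_days) == 5L)
  d <- as.integer(diagnosis_days)
  list(
    injury_spec("charcot", "right", FOOT_LOCATIONS,
                onset_day = d[1] - 6L, diagnosis_day = d[1],
                peak_offset = 7.0, ramp_days = 3L),
    injury_spec("blister", "right", "hallux",
                onset_day = d[2] - 12L, diagnosis_day = d[2],
                peak_offset = 8.0, ramp_days = 5L),
    injury_spec("osteomyelitis", "left", FOOT_LOCATIONS,
                onset_day = d[3] - 25L, diagnosis_day = d[3],
                peak_offset = 4.8, ramp_days = 10L),
    injury_spec("ulcer", "right", c("mts5", "mts3"),
                onset_day = d[4] - 15L, diagnosis_day = d[4],
                peak_offset = 10.0, ramp_days = 7L),
    injury_spec("dvt", "right", FOOT_LOCATIONS,
                onset_day = d[5] - 3L, diagnosis_day = d[5],
                peak_offset = 8.0, ramp_days = 1L)
  )
}

#' Archetype presets fitted to a shorter observation span
#'
#' Keeps the five default archetypes but spaces their diagnosis days across
#' `days` (45%-90% of the span) so reduced-scale runs remain valid; the full
#' default span keeps the canonical diagnosis days.
#'
#' @param days observation span in days (>= 58 so the slowest archetype's
#'   onset stays inside the record).
#' @return list of [injury_spec()] objects.
#' @export
default_injury_presets_for_span <- function(days) {
  if (days >= 135L) return(default_injury_presets())
  dd <- as.integer(round(seq(0.45, 0.9, length.out = 5) * days))
  if (dd[1] < 26L) stopf("span of %d days too short for the archetype presets", days)
  default_injury_presets(dd)
}

## Bilateral fixed site offsets (degrees F) relative to the patient baseline:
## toes run cooler, heel warmer. Common to both feet, so they cancel in the
## contralateral differential; they only make absolute traces look plausible.
SITE_OFFSETS <- c(hallux = -1.0, heel = 0.8, arch = 0.3,
                  mts1 = -0.2, mts3 = -0.3, mts5 = -0.6)

#' Simulate one patient's minute-level bilateral temperature stream
#'
#' Produces one record per minute of the observation span. During the daily
#' wear block every sensor reads
#' `patient baseline + site offset + circadian + day drift + noise`, with all
#' terms except the noise shared by both feet; outside the wear block the
#' sensor reports `ambient_temp` with `worn = FALSE`. If the patient carries
#' an injury, the affected foot's affected sites additionally gain a linear
#' ramp from 0 at `onset_day` to `peak_offset` at `onset_day + ramp_days`,
#' sustained to the end of the span.
#'
#' @param patient a list or one-row registry with at least `patient_id`, and
#'   optionally `injury` (an [injury_spec()] or `NULL`).
#' @param config a [generator_config()].
#' @param seed optional integer; by default derived deterministically from
#'   `config$seed` and the patient id, so cohort generation order is
#'   irrelevant.
#' @return a `patient_stream` object (see [patient_stream()]).
#' @export
simulate_patient_stream <- function(patient, config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  pid <- as.character(patient$patient_id)
  if (length(pid) != 1L || is.na(pid) || !nzchar(pid)) stopf("patient needs a `patient_id`")
  injury <- patient$injury
  if (!is.null(injury) && !inherits(injury, "injury_spec")) {
    stopf("`patient$injury` must be an injury_spec or NULL")
  }
  if (!is.null(injury) && injury$diagnosis_day > config$days) {
    stopf("injury days outside the observation span (diagnosis_day=%d, days=%d)",
          injury$diagnosis_day, config$days)
  }
  seed <- seed %||% derive_seed(config$seed, pid)

  n_days <- config$days
  with_seed(seed, {
    ## daily contiguous wear block, both socks as a pair
    dur <- pmin(1440, pmax(0, round(rnorm(n_days, config$wear_minutes_per_day_mean,
                                          config$wear_minutes_per_day_sd))))
    start <- ifelse(dur >= 1440, 0L,
                    floor(runif(n_days) * (1440 - dur + 1)))
    drift <- cumsum(rnorm(n_days, 0, config$drift_sd))
    baseline <- rnorm(1, config$baseline_temp_mean, config$baseline_temp_sd)

    dt <- data.table::CJ(day = 0:(n_days - 1L), minute = 0:1439L)
    worn <- dt$minute >= start[dt$day + 1L] & dt$minute < start[dt$day + 1L] + dur[dt$day + 1L]
    dt[, worn_left := worn]
    dt[, worn_right := worn]

    circ <- config$circadian_amplitude *
      sin(2 * pi * (dt$minute - 480) / 1440)
    common <- baseline + circ + drift[dt$day + 1L]

    ramp <- if (is.null(injury)) NULL else injury_ramp(injury, 0:(n_days - 1L))
    for (ft in FEET) {
      for (loc in FOOT_LOCATIONS) {
        v <- common + SITE_OFFSETS[[loc]] +
          rnorm(nrow(dt), 0, config$bilateral_noise_sd)
        if (!is.null(injury) && ft == injury$foot && loc %in% injury$locations) {
          v <- v + ramp[dt$day + 1L]
        }
        v[!worn] <- config$ambient_temp
        data.table::set(dt, j = paste(ft, loc, sep = "_"),
                        value = pmin(TEMP_MAX, pmax(TEMP_MIN, v)))
      }
    }
    patient_stream(pid, dt)
  })
}

## Added temperature (degrees F) on the affected side for each day index:
## 0 before onset, linear rise over ramp_days, then sustained at peak.
injury_ramp <- function(injury, days) {
  t <- days - injury$onset_day
  frac <- if (injury$ramp_days == 0L) as.numeric(t >= 0) else pmin(1, pmax(0, t / injury$ramp_days))
  injury$peak_offset * frac
}

## ages printed for the five injury archetype patients (study cohort)
STUDY_AGES <- c(68L, 75L, 61L, 48L, 76L)

#' Build the default synthetic patient registry
#'
#' Registry margins reproduce the monitored population's demographics: 5
#' study patients (the archetype ages 68, 75, 61, 48, 76; 1 female; 3 with
#' diabetes, 2 with peripheral artery disease) and 26 controls (24 with
#' diabetes, 5 with PAD, 9 female, mean age 70.4). Every patient carries a
#' peripheral-neuropathy diagnosis, the eligibility condition for
#' prescription of the monitoring sock. For cohort sizes other than the
#' default the same margins are applied proportionally by recycling.
#'
#' @param config a [generator_config()].
#' @param presets list of [injury_spec()] templates recycled across study
#'   patients.
#' @return a `data.table` registry, one row per patient, with columns
#'   `patient_id, age, sex, diagnoses, cohort, injury_type, injury_foot,
#'   injury_locations, onset_day, diagnosis_day` (injury columns `NA` for
#'   controls). `diagnoses` and `injury_locations` are `;`-joined strings.
#' @export
build_registry <- function(config, presets = default_injury_presets()) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_study > 0L && length(presets) == 0L) {
    stopf("n_study > 0 requires at least one injury preset")
  }
  with_seed(derive_seed(config$seed, "registry"), {
    study <- if (config$n_study > 0L) {
      idx <- ((seq_len(config$n_study) - 1L) %% length(presets)) + 1L
      ages <- STUDY_AGES[((seq_len(config$n_study) - 1L) %% 5L) + 1L]
      ## one female among the archetypes: the 75-year-old blister patient
      sex <- rep("male", config$n_study)
      sex[((seq_len(config$n_study) - 1L) %% 5L) + 1L == 2L] <- "female"
      diag_sets <- c("diabetes_t1;neuropathy", "diabetes_t2;neuropathy",
                     "peripheral_artery_disease;neuropathy",
                     "diabetes_t2;neuropathy",
                     "peripheral_artery_disease;neuropathy")
      inj <- presets[idx]
      data.table(
        patient_id = sprintf("S%02d", seq_len(config$n_study)),
        age = ages, sex = sex,
        diagnoses = diag_sets[((seq_len(config$n_study) - 1L) %% 5L) + 1L],
        cohort = "study",
        injury_type = vapply(inj, `[[`, "", "injury_type"),
        injury_foot = vapply(inj, `[[`, "", "foot"),
        injury_locations = vapply(inj, function(x) paste(x$locations, collapse = ";"), ""),
        onset_day = vapply(inj, `[[`, 0L, "onset_day"),
        diagnosis_day = vapply(inj, `[[`, 0L, "diagnosis_day")
      )
    } else NULL

    control <- if (config$n_control > 0L) {
      n <- config$n_control
      ages <- round(rnorm(n, 70.4, 9))
      ages <- pmin(92L, pmax(45L, as.integer(ages)))
      ## nudge integer ages so the cohort mean prints 70.4 to one decimal
      target <- round(70.4 * n)
      while (sum(ages) != target) {
        i <- sample.int(n, 1L)
        step <- sign(target - sum(ages))
        cand <- ages[i] + step
        if (cand >= 45L && cand <= 92L) ages[i] <- cand
      }
      n_f <- round(9 / 26 * n)
      sex <- rep("male", n); sex[sample.int(n, n_f)] <- "female"
      n_dm <- round(24 / 26 * n); n_pad <- round(5 / 26 * n)
      has_dm <- seq_len(n) <= n_dm
      has_pad <- seq_len(n) <= n_pad     # PAD patients overlap the diabetic block
      dm_type <- ifelse(seq_len(n) %% 6L == 0L, "diabetes_t1", "diabetes_t2")
      diagnoses <- vapply(seq_len(n), function(i) {
        paste(c(if (has_dm[i]) dm_type[i], if (has_pad[i]) "peripheral_artery_disease",
                "neuropathy"), collapse = ";")
      }, "")
      ord <- sample.int(n)               # decouple id order from diagnosis blocks
      data.table(
        patient_id = sprintf("C%02d", seq_len(n)),
        age = ages[ord], sex = sex[ord], diagnoses = diagnoses[ord],
        cohort = "control",
        injury_type = NA_character_, injury_foot = NA_character_,
        injury_locations = NA_character_,
        onset_day = NA_integer_, diagnosis_day = NA_integer_
      )
    } else NULL

    rbind(study, control)
  })
}

#' Recover the injury specification from a registry row
#'
#' @param row one registry row (study patient).
#' @return an [injury_spec()], or `NULL` for a control row.
#' @export
registry_injury <- function(row) {
  if (is.na(row$injury_type)) return(NULL)
  ## peak/ramp are regenerated from the matching default preset shape
  presets <- default_injury_presets()
  tpl <- Filter(function(p) p$injury_type == row$injury_type, presets)[[1]]
  injury_spec(row$injury_type, row$injury_foot,
              strsplit(row$injury_locations, ";", fixed = TRUE)[[1]],
              row$onset_day, row$diagnosis_day,
              tpl$peak_offset, tpl$ramp_days)
}

#' Generate full synthetic cohorts: registry plus minute streams
#'
#' @inheritParams build_registry
#' @return `list(registry = data.table, streams = named list of
#'   patient_stream)`; `streams` is keyed by `patient_id`.
#' @export
generate_cohorts <- function(config, presets = default_injury_presets()) {
  registry <- build_registry(config, presets)
  streams <- vector("list", nrow(registry))
  names(streams) <- registry$patient_id
  n_study_seen <- 0L
  for (i in seq_len(nrow(registry))) {
    row <- registry[i]
    injury <- if (row$cohort == "study") {
      n_study_seen <- n_study_seen + 1L
      presets[[((n_study_seen - 1L) %% length(presets)) + 1L]]
    } else NULL
    streams[[row$patient_id]] <- simulate_patient_stream(
      list(patient_id = row$patient_id, injury = injury), config
    )
  }
  list(registry = registry, streams = streams)
}

#' Null distribution of the patient window statistic
#'
#' With no injury every common-mode term (baseline, circadian rhythm, day
#' drift, site offsets) is shared by both feet and cancels exactly, so each
#' worn-minute differential at a site is an independent
#' N(0, `noise_sd * sqrt(2)`) draw. A patient's window statistic -- the mean
#' absolute differential over `minutes_budget` retained minutes at all 6
#' sites -- is therefore the mean of `6 * minutes_budget` folded-normal
#' draws. This function samples that reduction directly, which is exact for
#' the generator's null and cheap enough for large type-I-error simulations.
#'
#' @param n number of patients to draw.
#' @param minutes_budget retained minutes per window (default 900).
#' @param noise_sd per-sensor noise sd, degrees F.
#' @param seed integer seed, or `NULL` to consume the caller's RNG stream
#'   (preferred inside replication loops: re-seeding every replicate with
#'   nearby integers induces cross-replicate correlation in the first draws
#'   of the Mersenne-Twister stream).
#' @return numeric vector of `n` window statistics.
#' @export
null_window_statistics <- function(n, minutes_budget = 900L,
                                   noise_sd = generator_config()$bilateral_noise_sd,
                                   seed = NULL) {
  m <- as.integer(minutes_budget) * 6L
  draw <- function() {
    x <- abs(matrix(rnorm(n * m, 0, noise_sd * sqrt(2)), nrow = m))
    colMeans(x)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
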