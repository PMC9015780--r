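## The clinical alert rule: a daily mean contralateral differential
## STRICTLY above 4 degrees F at any site triggers follow-up; a run of
## consecutive alert days at the same site escalates to a sustained-hotspot
## referral. Alerts are evaluated on daily averages, not raw minutes --
## minute-level spikes are noise-dominated.

#' Alert rule configuration
#'
#' @param threshold daily mean absolute differential (degrees F) above which
#'   an alert fires; the comparison is strict (`> threshold`), so exactly
#'   4.0 never alerts. Default 4.
#' @param escalation_days length of the consecutive-day run at one site that
#'   marks a sustained hotspot (default 5, the order of the "5-6 days of
#'   hotspots" seen ahead of an acute Charcot presentation).
#' @param min_minutes minimum minutes behind a daily value for it to be
#'   alert-eligible; guards against near-empty wear days. Default 30.
#' @return an `alert_config` list.
#' @export
alert_config <- function(threshold = 4.0, escalation_days = 5L, min_minutes = 30L) {
  if (threshold <= 0) stopf("`threshold` must be > 0")
  if (escalation_days < 1L) stopf("`escalation_days` must be >= 1")
  if (min_minutes < 0L) stopf("`min_minutes` must be >= 0")
  structure(list(threshold = threshold,
                 escalation_days = as.integer(escalation_days),
                 min_minutes = as.integer(min_minutes)),
            class = "alert_config")
}

#' Evaluate the daily alert rule
#'
#' Emits one alert event per (patient, day, location) whose daily mean
#' absolute differential strictly exceeds the threshold with at least
#' `min_minutes` contributing minutes. `consecutive_days` is the length of
#' the run of alert days at that site ending on that day, where a run
#' continues only across adjacent day indices; `escalated` marks runs that
#' have reached `escalation_days`.
#'
#' @param dailies daily averages from [daily_averages()].
#' @param config an [alert_config()].
#' @return `data.table` with columns `patient_id, day, location, value,
#'   consecutive_days, escalated`, sorted by patient, location, day.
#' @export
evaluate_alerts <- function(dailies, config = alert_config()) {
  stopifnot(inherits(config, "alert_config"))
  dailies <- data.table::as.data.table(dailies)
  hits <- dailies[mean_abs_delta > config$threshold & n_minutes >= config$min_minutes]
  if (nrow(hits) == 0L) {
    return(data.table(patient_id = character(), day = integer(),
                      location = character(), value = numeric(),
                      consecutive_days = integer(), escalated = logical()))
  }
  data.table::setorder(hits, patient_id, location, day)
  ## a run breaks when the day index jumps by more than 1 (non-alert or
  ## non-worn days in between reset the counter)
  hits[, run_id := cumsum(c(1L, diff(day) != 1L)), by = list(patient_id, location)]
  hits[, consecutive_days := seq_len(.N), by = list(patient_id, location, run_id)]
  hits[, escalated := consecutive_days >= config$escalation_days]
  out <- hits[, list(patient_id, day, location, value = mean_abs_delta,
                     consecutive_days, escalated)]
  out[]
}

#' Earliest alert day for a patient
#'
#' Supports lead-time reporting: how far ahead of clinical diagnosis the
#' monitoring rule first fired.
#'
#' @param events alert table from [evaluate_alerts()].
#' @param patient_id patient to look up.
#' @return earliest alert day index, or `NA_integer_` if the patient never
#'   alerted.
#' @export
first_alert_day <- function(events, patient_id) {
  events <- data.table::as.data.table(events)
  days <- events[events$patient_id == patient_id, day]
  if (length(days) == 0L) NA_integer_ else as.integer(min(days))
}
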