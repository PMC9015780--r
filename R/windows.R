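## Analysis-window extraction and record segmentation.
##
## The protocol's primary observation interval is the 15 days ending the day
## before clinical diagnosis, from which 900 monitored minutes are analyzed.
## Controls contribute a randomly selected 15-day span with a randomly
## selected 900 minutes. How the study arm's 900 minutes were chosen is not
## specified by the protocol; uniform seeded subsampling of bilaterally worn
## minutes is used for both arms for symmetry, with a per-day-quota mode
## (60 min/day x 15 days) as the labeled alternative.

#' Construct an analysis window
#'
#' @param patient_id patient identifier.
#' @param label one of `"pre_injury"`, `"control_random"`, `"baseline"`,
#'   `"active"`.
#' @param start_day,end_day inclusive day range.
#' @param minutes `data.table` of retained `(day, minute)` pairs, every one
#'   bilaterally worn.
#' @param mode how minutes were selected: `"all"`, `"uniform"`, or
#'   `"per_day_quota"`.
#' @return an `analysis_window` object.
#' @export
analysis_window <- function(patient_id, label, start_day, end_day, minutes,
                            mode = "uniform") {
  label <- match.arg(label, c("pre_injury", "control_random", "baseline", "active"))
  minutes <- data.table::as.data.table(minutes)
  stopifnot(all(c("day", "minute") %in% names(minutes)))
  data.table::setorder(minutes, day, minute)
  if (nrow(minutes) > 0L &&
      (min(minutes$day) < start_day || max(minutes$day) > end_day)) {
    stopf("retained minutes fall outside the window day range")
  }
  structure(list(patient_id = as.character(patient_id), label = label,
                 start_day = as.integer(start_day), end_day = as.integer(end_day),
                 minutes = minutes[], mode = mode),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window %s [%s]: days %d-%d, %d minutes (%s)>\n",
              x$patient_id, x$label, x$start_day, x$end_day,
              nrow(x$minutes), x$mode))
  invisible(x)
}

## bilaterally worn (day, minute) pairs of a stream within a day range
worn_minutes <- function(stream, start_day, end_day) {
  stream$data[worn_left & worn_right & day >= start_day & day <= end_day,
              list(day, minute)]
}

## shared minute-subsampling logic for both window extractors
select_minutes <- function(avail, minutes_budget, days_span, per_day_quota) {
  if (is.null(per_day_quota)) {
    if (nrow(avail) < minutes_budget) {
      stopf("insufficient bilaterally worn minutes: have %d, need %d (shortfall %d)",
            nrow(avail), minutes_budget, minutes_budget - nrow(avail))
    }
    if (nrow(avail) == minutes_budget) {
      list(minutes = avail, mode = "all")
    } else {
      list(minutes = avail[sort(sample.int(nrow(avail), minutes_budget))],
           mode = "uniform")
    }
  } else {
    per_day <- avail[, list(n_worn = .N), by = day]
    short <- per_day[n_worn < per_day_quota]
    if (nrow(per_day) < days_span || nrow(short) > 0L) {
      stopf("per-day quota of %d minutes not met on every window day", per_day_quota)
    }
    sel <- avail[, .SD[sort(sample.int(.N, per_day_quota))], by = day]
    list(minutes = sel, mode = "per_day_quota")
  }
}

#' Extract the pre-injury analysis window
#'
#' The window spans the `days` days ending the day BEFORE `diagnosis_day`
#' (diagnosis-day readings may already reflect clinical handling). Exactly
#' `minutes_budget` bilaterally worn minutes are retained: all of them when
#' supply equals the budget, otherwise a uniform seeded sample without
#' replacement. With `per_day_quota` set, `per_day_quota` minutes are
#' sampled from every window day instead and the budget is
#' `per_day_quota * days`.
#'
#' @param stream a [patient_stream()].
#' @param diagnosis_day 0-based day of clinical diagnosis.
#' @param minutes_budget total retained minutes (default 900).
#' @param days window length in days (default 15).
#' @param seed integer seed; the retained set is a pure function of
#'   (stream, parameters, seed).
#' @param per_day_quota optional per-day minute quota (e.g. 60).
#' @return an [analysis_window()] labeled `"pre_injury"`.
#' @export
extract_preinjury_window <- function(stream, diagnosis_day, minutes_budget = 900L,
                                     days = 15L, seed, per_day_quota = NULL) {
  stopifnot(inherits(stream, "patient_stream"))
  if (diagnosis_day < days) {
    stopf("diagnosis_day=%d leaves no room for a %d-day pre-injury window",
          diagnosis_day, days)
  }
  start_day <- as.integer(diagnosis_day - days)
  end_day <- as.integer(diagnosis_day - 1L)
  avail <- worn_minutes(stream, start_day, end_day)
  sel <- with_seed(seed, select_minutes(avail, minutes_budget, days, per_day_quota))
  analysis_window(stream$patient_id, "pre_injury", start_day, end_day,
                  sel$minutes, sel$mode)
}

#' Sample a random control analysis window
#'
#' Enumerates every `days`-long consecutive span of the stream that carries
#' at least `minutes_budget` bilaterally worn minutes (or meets the per-day
#' quota on every day), picks one uniformly at random, and subsamples
#' minutes exactly as [extract_preinjury_window()] does. Span eligibility is
#' recomputed from the worn flags, never assumed.
#'
#' @inheritParams extract_preinjury_window
#' @return an [analysis_window()] labeled `"control_random"`.
#' @export
sample_control_window <- function(stream, minutes_budget = 900L, days = 15L,
                                  seed, per_day_quota = NULL) {
  stopifnot(inherits(stream, "patient_stream"))
  last_day <- max(stream$data$day)
  if (last_day + 1L < days) stopf("stream shorter than the %d-day window", days)
  starts <- 0:(last_day - days + 1L)
  ## per-day bilateral worn counts once, then rolling span totals
  per_day <- stream$data[, list(n_worn = sum(worn_left & worn_right)), by = day]
  counts <- integer(last_day + 1L)
  counts[per_day$day + 1L] <- per_day$n_worn
  span_total <- vapply(starts, function(s) sum(counts[(s + 1L):(s + days)]), 0L)
  eligible <- if (is.null(per_day_quota)) {
    starts[span_total >= minutes_budget]
  } else {
    ok <- vapply(starts, function(s) all(counts[(s + 1L):(s + days)] >= per_day_quota), TRUE)
    starts[ok]
  }
  if (length(eligible) == 0L) {
    stopf("no eligible %d-day span with %d bilaterally worn minutes", days,
          if (is.null(per_day_quota)) minutes_budget else per_day_quota * days)
  }
  with_seed(seed, {
    s <- eligible[sample.int(length(eligible), 1L)]
    avail <- worn_minutes(stream, s, s + days - 1L)
    sel <- select_minutes(avail, minutes_budget, days, per_day_quota)
    analysis_window(stream$patient_id, "control_random", s, s + days - 1L,
                    sel$minutes, sel$mode)
  })
}

#' Segment a record into baseline / pre-injury / active periods
#'
#' Splits the observation span at the injury diagnosis: baseline is
#' everything before the `days`-day pre-injury window, the pre-injury period
#' is the `days` days ending the day before diagnosis, and the active-injury
#' period runs from the diagnosis day to the end of the record. The three
#' ranges partition the span exactly.
#'
#' @param stream a [patient_stream()].
#' @param injury an [injury_spec()]; `NULL` (a control patient) is an error
#'   since segmentation is anchored on a diagnosis.
#' @param days pre-injury window length (default 15).
#' @return a `period_segmentation` list with `baseline`, `pre_injury`,
#'   `active` integer ranges `c(first, last)`.
#' @export
segment_periods <- function(stream, injury, days = 15L) {
  stopifnot(inherits(stream, "patient_stream"))
  if (is.null(injury)) {
    stopf("segmentation requires a diagnosed injury; patient '%s' has none",
          stream$patient_id)
  }
  stopifnot(inherits(injury, "injury_spec"))
  diag <- injury$diagnosis_day
  if (diag < days + 1L) {
    stopf("diagnosis_day=%d leaves an empty baseline before a %d-day pre-injury window",
          diag, days)
  }
  last_day <- max(stream$data$day)
  if (diag > last_day) stopf("diagnosis_day=%d beyond the last observed day %d", diag, last_day)
  structure(
    list(patient_id = stream$patient_id,
         baseline = c(0L, as.integer(diag - days - 1L)),
         pre_injury = c(as.integer(diag - days), as.integer(diag - 1L)),
         active = c(as.integer(diag), as.integer(last_day))),
    class = "period_segmentation"
  )
}
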