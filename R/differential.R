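## Contralateral differential engine: the core measurement pipeline.
##
## Sign convention: delta = right - left. Monitoring and statistics operate
## on |delta|; the signed trace is preserved for plotting.

#' Per-minute contralateral differentials
#'
#' For every minute in which BOTH socks are worn, emits one record per
#' plantar site with the signed differential `delta = right - left` and its
#' magnitude `abs_delta`. Minutes with either foot not worn are skipped, not
#' zero-filled: a one-sided reading has no contralateral reference.
#'
#' @param stream a [patient_stream()].
#' @return `data.table` with columns `patient_id, day, minute, location,
#'   delta, abs_delta`, six rows per bilaterally worn minute.
#' @export
minute_differentials <- function(stream) {
  stopifnot(inherits(stream, "patient_stream"))
  d <- stream$data
  ## a never-worn stream is legal (empty output); one foot worn while the
  ## other never appears suggests unilateral use, which is unsupported
  if (nrow(d) > 0L && xor(any(d$worn_left), any(d$worn_right))) {
    never <- if (any(d$worn_left)) "right" else "left"
    stopf("foot '%s' never worn in stream '%s': contralateral analysis requires both feet",
          never, stream$patient_id)
  }
  b <- d[worn_left & worn_right]
  if (nrow(b) == 0L) {
    return(data.table(patient_id = character(), day = integer(),
                      minute = integer(), location = character(),
                      delta = numeric(), abs_delta = numeric()))
  }
  parts <- lapply(FOOT_LOCATIONS, function(loc) {
    data.table(
      patient_id = stream$patient_id, day = b$day, minute = b$minute,
      location = loc,
      delta = b[[paste0("right_", loc)]] - b[[paste0("left_", loc)]]
    )
  })
  out <- data.table::rbindlist(parts)
  out[, abs_delta := abs(delta)]
  data.table::setorder(out, day, minute, location)
  out[]
}

#' Daily per-location average differentials
#'
#' Aggregates minute differentials to one record per (patient, day,
#' location): the unweighted arithmetic mean of `abs_delta` over that day's
#' bilaterally worn minutes, with the contributing minute count. Days with
#' no bilateral minutes yield no record.
#'
#' @param diffs minute differential table from [minute_differentials()]
#'   (rows from several patients may be mixed).
#' @return `data.table` with columns `patient_id, day, location,
#'   mean_abs_delta, n_minutes`.
#' @export
daily_averages <- function(diffs) {
  diffs <- data.table::as.data.table(diffs)
  out <- diffs[, list(mean_abs_delta = mean(abs_delta), n_minutes = .N),
               by = list(patient_id, day, location)]
  data.table::setorder(out, patient_id, day, location)
  out[]
}

#' Patient-level window statistic
#'
#' Reduces one analysis window to a single scalar per patient: by default
#' the mean of `abs_delta` pooled over every retained minute and all six
#' sites, each retained minute weighted equally (`mode = "minute_pooled"`).
#' `mode = "day_first"` instead averages within each (day, location) cell
#' first and then averages the cell means -- the alternative reading of
#' "daily average per area", exposed so the two conventions can be compared.
#'
#' @param diffs minute differential table for the patient (from
#'   [minute_differentials()]).
#' @param window an [analysis_window()] whose minutes select the rows used.
#' @param mode `"minute_pooled"` (default) or `"day_first"`.
#' @return scalar mean absolute differential, degrees F.
#' @export
patient_window_statistic <- function(diffs, window,
                                     mode = c("minute_pooled", "day_first")) {
  mode <- match.arg(mode)
  stopifnot(inherits(window, "analysis_window"))
  diffs <- data.table::as.data.table(diffs)
  sel <- diffs[window$minutes, on = c("day", "minute"), nomatch = NULL]
  if (nrow(sel) == 0L) stopf("window selects no differential records")
  if (mode == "minute_pooled") {
    mean(sel$abs_delta)
  } else {
    cells <- sel[, list(m = mean(abs_delta)), by = list(day, location)]
    mean(cells$m)
  }
}
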