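## Cohort-level comparison: per-patient window statistics, cohort
## summaries, and a Welch two-sample t statistic implemented from formula
## (an established library implementation is used only as an independent
## oracle in the test suite).

#' Summarize a cohort of per-patient statistics
#'
#' @param values numeric vector, one window statistic per patient.
#' @param cohort_label `"study"` or `"control"`.
#' @return a `cohort_summary` list: `cohort`, `n`, `mean`, `sd` (sample,
#'   n-1 denominator), `values`.
#' @export
summarize_cohort <- function(values, cohort_label) {
  cohort_label <- match.arg(cohort_label, c("study", "control"))
  if (length(values) == 0L) stopf("empty cohort '%s'", cohort_label)
  if (length(values) == 1L) {
    stopf("cohort '%s' has a single patient: sample sd undefined", cohort_label)
  }
  structure(list(cohort = cohort_label, n = length(values),
                 mean = mean(values), sd = stats::sd(values),
                 values = as.numeric(values)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%s cohort (n=%d): mean %.2f F (SD %.2f)\n",
              x$cohort, x$n, x$mean, x$sd))
  invisible(x)
}

#' Welch two-sample t test (from formula)
#'
#' Computes `t = (mean(a) - mean(b)) / sqrt(var(a)/n_a + var(b)/n_b)`, the
#' Welch-Satterthwaite degrees of freedom
#' `df = se^4 / ((var(a)/n_a)^2/(n_a-1) + (var(b)/n_b)^2/(n_b-1))`, the
#' two-sided p value from the t distribution, and the confidence interval
#' `mean_diff +/- t_crit(df) * se`. Equal variances are not assumed.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param conf confidence level for the interval (default 0.95).
#' @return a `welch_result` list: `t`, `df`, `p`, `mean_diff`, `ci_low`,
#'   `ci_high`, `conf`, `n_a`, `n_b`.
#' @export
welch_t <- function(a, b, conf = 0.95) {
  if (length(a) < 2L || length(b) < 2L) stopf("both samples need n >= 2")
  if (conf <= 0 || conf >= 1) stopf("`conf` must be in (0, 1)")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    stopf("both sample variances are zero: Welch statistic undefined")
  }
  na <- length(a); nb <- length(b)
  sa2 <- va / na; sb2 <- vb / nb
  se <- sqrt(sa2 + sb2)
  md <- mean(a) - mean(b)
  t <- md / se
  df <- (sa2 + sb2)^2 / (sa2^2 / (na - 1) + sb2^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  tcrit <- stats::qt(1 - (1 - conf) / 2, df)
  structure(list(t = t, df = df, p = p, mean_diff = md,
                 ci_low = md - tcrit * se, ci_high = md + tcrit * se,
                 conf = conf, n_a = na, n_b = nb),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.3f, df = %.2f, p = %.3g\n", x$t, x$df, x$p))
  cat(sprintf("mean difference %.3f F (%d%% CI %.3f to %.3f)\n",
              x$mean_diff, round(100 * x$conf), x$ci_low, x$ci_high))
  invisible(x)
}

## round half away from zero (printed demographics use this convention)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Demographics summary table
#'
#' Per cohort: patient count, mean age, sex counts, and diagnosis counts
#' with integer percentages (100 * count / cohort n, rounded half away from
#' zero), plus printed-style `"count (pct)"` cells.
#'
#' @param registry registry `data.table` (see [build_registry()]).
#' @return `data.table`, one row per cohort present in the registry.
#' @export
demographics_table <- function(registry) {
  registry <- data.table::as.data.table(registry)
  if (nrow(registry) == 0L) stopf("empty registry")
  cohorts <- unique(registry$cohort)
  rows <- lapply(cohorts, function(co) {
    r <- registry[cohort == co]
    if (nrow(r) == 0L) stopf("empty cohort '%s'", co)
    n <- nrow(r)
    has <- function(pat) sum(grepl(pat, r$diagnoses))
    cnt <- c(diabetes = has("diabetes"),
             peripheral_artery_disease = has("peripheral_artery_disease"),
             neuropathy = has("neuropathy"))
    pct <- as.integer(round_half_away(100 * cnt / n))
    data.table(
      cohort = co, n = n, mean_age = mean(r$age),
      female = sum(r$sex == "female"), male = sum(r$sex == "male"),
      diabetes_n = cnt[["diabetes"]], diabetes_pct = pct[[1]],
      diabetes_cell = sprintf("%d (%d)", cnt[["diabetes"]], pct[[1]]),
      pad_n = cnt[["peripheral_artery_disease"]], pad_pct = pct[[2]],
      pad_cell = sprintf("%d (%d)", cnt[["peripheral_artery_disease"]], pct[[2]]),
      neuropathy_n = cnt[["neuropathy"]], neuropathy_pct = pct[[3]],
      neuropathy_cell = sprintf("%d (%d)", cnt[["neuropathy"]], pct[[3]])
    )
  })
  data.table::rbindlist(rows)
}

#' Run the full cohort comparison
#'
#' Orchestrates the analysis on a registry plus streams: wear-days
#' eligibility filtering, pre-injury window extraction for study patients
#' (anchored on each diagnosis day), random window sampling for controls,
#' per-patient window statistics, cohort summaries and the Welch test. The
#' result is fully reproducible from (inputs, parameters, seed).
#'
#' The unit of analysis is the patient (one scalar per patient; patients are
#' the independent units). `pseudoreplicate_minutes = TRUE` instead pools
#' every retained minute-level |delta| into the test -- a pseudo-replication
#' mode that inflates the t statistic by treating correlated minutes as
#' independent; it exists only to illustrate that behaviour and is labeled
#' as such in the report.
#'
#' @param registry registry `data.table`.
#' @param streams named list of [patient_stream()] keyed by patient id.
#' @param params list of protocol parameters; defaults:
#'   `window_days = 15`, `minutes_budget = 900`, `min_wear_days = 50`,
#'   `min_minutes_per_day = 30`, `per_day_quota = NULL`,
#'   `statistic_mode = "minute_pooled"`, `conf = 0.95`.
#' @param seed integer seed driving all window sampling.
#' @param pseudoreplicate_minutes see Details.
#' @return a `cohort_report` list; see [report_to_json()] for serialization.
#' @export
run_cohort_comparison <- function(registry, streams, params = list(), seed = 1L,
                                  pseudoreplicate_minutes = FALSE) {
  p <- utils::modifyList(list(
    window_days = 15L, minutes_budget = 900L, min_wear_days = 50L,
    min_minutes_per_day = 30L, per_day_quota = NULL,
    statistic_mode = "minute_pooled", conf = 0.95
  ), params)
  registry <- data.table::as.data.table(registry)
  eligible <- filter_eligible(registry, streams, p$min_wear_days,
                              p$min_minutes_per_day)
  if (nrow(eligible) == 0L) stopf("no eligible patients after the wear filter")

  per_patient <- vector("list", nrow(eligible))
  minute_values <- list(study = numeric(), control = numeric())
  for (i in seq_len(nrow(eligible))) {
    row <- eligible[i]
    stream <- streams[[row$patient_id]]
    wseed <- derive_seed(seed, paste0("window:", row$patient_id))
    window <- if (row$cohort == "study") {
      extract_preinjury_window(stream, row$diagnosis_day, p$minutes_budget,
                               p$window_days, wseed, p$per_day_quota)
    } else {
      sample_control_window(stream, p$minutes_budget, p$window_days, wseed,
                            p$per_day_quota)
    }
    diffs <- minute_differentials(stream)
    stat <- patient_window_statistic(diffs, window, p$statistic_mode)
    if (pseudoreplicate_minutes) {
      sel <- diffs[window$minutes, on = c("day", "minute"), nomatch = NULL]
      minute_values[[row$cohort]] <- c(minute_values[[row$cohort]], sel$abs_delta)
    }
    per_patient[[i]] <- data.table(
      patient_id = row$patient_id, cohort = row$cohort, label = window$label,
      start_day = window$start_day, end_day = window$end_day,
      n_minutes = nrow(window$minutes), statistic = stat
    )
  }
  per_patient <- data.table::rbindlist(per_patient)

  study_vals <- per_patient[cohort == "study", statistic]
  control_vals <- per_patient[cohort == "control", statistic]
  study <- if (length(study_vals) >= 2L) summarize_cohort(study_vals, "study") else NULL
  control <- if (length(control_vals) >= 2L) summarize_cohort(control_vals, "control") else NULL

  test_a <- if (pseudoreplicate_minutes) minute_values$study else study_vals
  test_b <- if (pseudoreplicate_minutes) minute_values$control else control_vals
  welch <- NULL
  degenerate <- NULL
  if (length(test_a) >= 2L && length(test_b) >= 2L) {
    welch <- tryCatch(welch_t(test_a, test_b, p$conf),
                      error = function(e) { degenerate <<- conditionMessage(e); NULL })
  } else {
    degenerate <- "a cohort has fewer than 2 units; test not run"
  }

  structure(list(
    n_total = nrow(registry), n_eligible = nrow(eligible),
    per_patient = per_patient, study = study, control = control,
    welch = welch, degenerate = degenerate,
    unit_of_analysis = if (pseudoreplicate_minutes)
      "minute (pseudo-replication mode)" else "patient",
    params = p, seed = as.integer(seed),
    config_hash = config_hash(c(p, seed = as.integer(seed)))
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort comparison: %d/%d patients eligible (unit: %s)\n",
              x$n_eligible, x$n_total, x$unit_of_analysis))
  if (!is.null(x$study)) print(x$study)
  if (!is.null(x$control)) print(x$control)
  if (!is.null(x$welch)) print(x$welch)
  if (!is.null(x$degenerate)) cat("degenerate comparison:", x$degenerate, "\n")
  invisible(x)
}

#' Serialize a cohort report to canonical JSON
#'
#' The rendering is deterministic (fixed field order, full precision), so a
#' re-run with identical inputs and seed produces a byte-identical file.
#'
#' @param report a `cohort_report` from [run_cohort_comparison()].
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "cohort_report"))
  unbox_summary <- function(s) if (is.null(s)) NULL else
    list(cohort = s$cohort, n = s$n, mean = s$mean, sd = s$sd, values = s$values)
  payload <- list(
    n_total = report$n_total, n_eligible = report$n_eligible,
    unit_of_analysis = report$unit_of_analysis,
    study = unbox_summary(report$study),
    control = unbox_summary(report$control),
    welch = if (is.null(report$welch)) NULL else unclass(report$welch),
    degenerate = report$degenerate,
    per_patient = report$per_patient,
    params = report$params, seed = report$seed,
    config_hash = report$config_hash
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
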