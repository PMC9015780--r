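## End-to-end pipeline: simulate -> validate -> monitor -> alerts ->
## windows -> analyze, with stage-boundary logging and a provenance
## manifest (config hash + seed) accompanying every artifact directory.

#' Pipeline configuration
#'
#' Houses the protocol constants: the 15-day window, the 900-minute budget,
#' the >50 wear-days inclusion rule and the 4 degree F alert threshold,
#' alongside the generator parameters.
#'
#' @param generator a [generator_config()].
#' @param alerts an [alert_config()].
#' @param window_days analysis window length (default 15).
#' @param minutes_budget retained minutes per window (default 900).
#' @param min_wear_days eligibility threshold, strict (default 50).
#' @param min_minutes_per_day minimum bilateral minutes for a day of wear
#'   (default 30).
#' @param per_day_quota optional per-day minute quota for window sampling.
#' @param statistic_mode `"minute_pooled"` or `"day_first"`.
#' @param seed master seed for the analysis stages (the generator carries
#'   its own).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            alerts = alert_config(),
                            window_days = 15L, minutes_budget = 900L,
                            min_wear_days = 50L, min_minutes_per_day = 30L,
                            per_day_quota = NULL,
                            statistic_mode = "minute_pooled",
                            seed = 1L) {
  stopifnot(inherits(generator, "generator_config"), inherits(alerts, "alert_config"))
  structure(list(generator = generator, alerts = alerts,
                 window_days = as.integer(window_days),
                 minutes_budget = as.integer(minutes_budget),
                 min_wear_days = as.integer(min_wear_days),
                 min_minutes_per_day = as.integer(min_minutes_per_day),
                 per_day_quota = if (is.null(per_day_quota)) NULL else as.integer(per_day_quota),
                 statistic_mode = statistic_mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return [read_pipeline_config()] returns a `pipeline_config`;
#'   [write_pipeline_config()] returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  y <- yaml::read_yaml(path)
  gen <- do.call(generator_config, y$generator %||% list())
  al <- do.call(alert_config, y$alerts %||% list())
  y$generator <- NULL; y$alerts <- NULL
  do.call(pipeline_config, c(list(generator = gen, alerts = al), y))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- unclass(config)
  y$generator <- unclass(config$generator)
  y$alerts <- unclass(config$alerts)
  yaml::write_yaml(y, path)
  invisible(path)
}

log_stage <- function(level, fmt, ...) {
  if (identical(Sys.getenv("PEDTHERM_QUIET"), "1")) return(invisible())
  message(sprintf("[pedtherm] %s: %s", level, sprintf(fmt, ...)))
}

#' Run the full demonstration pipeline
#'
#' Generates the synthetic cohorts, validates every stream, computes minute
#' and daily differentials, evaluates alerts, extracts analysis windows,
#' runs the cohort comparison, and (optionally) renders per-patient daily
#' differential traces with baseline / pre-injury / active-injury shading.
#' All artifacts land in `out_dir` together with a `manifest.json` carrying
#' the config hash and seed; re-running with the same configuration
#' reproduces every file byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir writable output directory (created if needed).
#' @param write_streams write every per-patient stream CSV (large; default
#'   `TRUE`).
#' @param plots render PNG trace plots for study patients (default `TRUE`).
#' @param presets injury archetypes for the study cohort; by default the
#'   standard archetypes, refitted if the span is shorter than 135 days.
#' @return the `cohort_report`, invisibly; artifacts on disk.
#' @export
run_full_demo <- function(config, out_dir, write_streams = TRUE, plots = TRUE,
                          presets = default_injury_presets_for_span(config$generator$days)) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass_deep(config))

  ## simulate
  cohorts <- generate_cohorts(config$generator, presets)
  log_stage("simulate", "%d patients (%d study, %d control)",
            nrow(cohorts$registry), sum(cohorts$registry$cohort == "study"),
            sum(cohorts$registry$cohort == "control"))
  write_registry(cohorts$registry, file.path(out_dir, "registry.csv"))
  if (write_streams) {
    sdir <- file.path(out_dir, "streams")
    dir.create(sdir, showWarnings = FALSE)
    for (pid in names(cohorts$streams)) {
      write_stream(cohorts$streams[[pid]], file.path(sdir, paste0(pid, ".csv")))
    }
  }

  ## validate
  for (s in cohorts$streams) validate_stream(s)
  log_stage("validate", "%d streams valid", length(cohorts$streams))

  ## monitor: minute differentials -> daily averages
  dailies <- data.table::rbindlist(lapply(cohorts$streams, function(s) {
    daily_averages(minute_differentials(s))
  }))
  data.table::fwrite(dailies, file.path(out_dir, "dailies.csv"))
  log_stage("monitor", "%d daily records", nrow(dailies))

  ## alerts
  alerts <- evaluate_alerts(dailies, config$alerts)
  data.table::fwrite(alerts, file.path(out_dir, "alerts.csv"))
  log_stage("alerts", "%d alert events (%d escalated)", nrow(alerts),
            sum(alerts$escalated))

  ## windows + analyze
  params <- list(window_days = config$window_days,
                 minutes_budget = config$minutes_budget,
                 min_wear_days = config$min_wear_days,
                 min_minutes_per_day = config$min_minutes_per_day,
                 per_day_quota = config$per_day_quota,
                 statistic_mode = config$statistic_mode)
  report <- run_cohort_comparison(cohorts$registry, cohorts$streams, params,
                                  config$seed)
  log_stage("analyze", "%d/%d eligible; study mean %s, control mean %s",
            report$n_eligible, report$n_total,
            if (is.null(report$study)) "NA" else sprintf("%.2f", report$study$mean),
            if (is.null(report$control)) "NA" else sprintf("%.2f", report$control$mean))
  windows_json(report, cohorts, config, file.path(out_dir, "windows.json"))
  report_to_json(report, file.path(out_dir, "report.json"))

  ## figure-style traces for study patients
  if (plots) render_traces(cohorts, dailies, config, out_dir)

  manifest <- list(config_hash = hash, seed = config$seed,
                   generator_seed = config$generator$seed,
                   files = list.files(out_dir, recursive = TRUE))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(report)
}

## strip S3 classes recursively so configs serialize as plain YAML/JSON maps
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

## windows.json: explicit retained minute lists per patient, for audit
windows_json <- function(report, cohorts, config, path) {
  wins <- lapply(seq_len(nrow(report$per_patient)), function(i) {
    row <- report$per_patient[i]
    stream <- cohorts$streams[[row$patient_id]]
    wseed <- derive_seed(report$seed, paste0("window:", row$patient_id))
    w <- if (row$cohort == "study") {
      drow <- cohorts$registry[patient_id == row$patient_id]
      extract_preinjury_window(stream, drow$diagnosis_day, config$minutes_budget,
                               config$window_days, wseed, config$per_day_quota)
    } else {
      sample_control_window(stream, config$minutes_budget, config$window_days,
                            wseed, config$per_day_quota)
    }
    list(patient_id = w$patient_id, label = w$label, mode = w$mode,
         start_day = w$start_day, end_day = w$end_day,
         minutes = w$minutes)
  })
  writeLines(jsonlite::toJSON(
    list(seed = report$seed, config_hash = report$config_hash, windows = wins),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  ), path)
  invisible(path)
}

## Daily |delta| trace per study patient, shaded baseline (green) /
## pre-injury (red) / active (grey), one line per affected site.
render_traces <- function(cohorts, dailies, config, out_dir) {
  tdir <- file.path(out_dir, "traces")
  dir.create(tdir, showWarnings = FALSE)
  study <- cohorts$registry[cohort == "study"]
  for (i in seq_len(nrow(study))) {
    row <- study[i]
    injury <- injury_spec(row$injury_type, row$injury_foot,
                          strsplit(row$injury_locations, ";")[[1]],
                          row$onset_day, row$diagnosis_day, 1, 1L)
    seg <- segment_periods(cohorts$streams[[row$patient_id]], injury,
                           config$window_days)
    d <- dailies[patient_id == row$patient_id & location %in% injury$locations]
    data.table::fwrite(d, file.path(tdir, paste0(row$patient_id, "_trace.csv")))
    grDevices::png(file.path(tdir, paste0(row$patient_id, "_trace.png")),
                   width = 900, height = 420)
    tryCatch({
      graphics::plot(NULL, xlim = range(d$day), ylim = c(0, max(d$mean_abs_delta) * 1.1),
                     xlab = "day", ylab = "daily mean |ΔT| (°F)",
                     main = sprintf("%s: %s (%s foot)", row$patient_id,
                                    row$injury_type, row$injury_foot))
      shade <- function(range, col) graphics::rect(range[1] - 0.5, -1, range[2] + 0.5,
                                                   1e3, col = col, border = NA)
      shade(seg$baseline, grDevices::adjustcolor("darkgreen", 0.12))
      shade(seg$pre_injury, grDevices::adjustcolor("red", 0.12))
      shade(seg$active, grDevices::adjustcolor("grey30", 0.15))
      for (loc in unique(d$location)) {
        dd <- d[location == loc]
        graphics::lines(dd$day, dd$mean_abs_delta, col = "grey25")
      }
      graphics::abline(h = config$alerts$threshold, lty = 2, col = "red3")
    }, finally = grDevices::dev.off())
  }
  invisible(tdir)
}
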