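## Data model and IO for per-minute bilateral temperature streams.
##
## Internally a stream is a wide data.table (one row per minute, 12
## temperature columns `<foot>_<location>` plus per-foot worn flags), which
## keeps a 135-day record at ~25 MB. On disk the canonical interchange
## formats are long: CSV with header
## `patient_id,day,minute,foot,location,temp_f,worn` (one sensor reading per
## row) and a JSONL variant with one object per reading.

#' Construct a patient stream
#'
#' @param patient_id opaque patient identifier.
#' @param data wide `data.table` with integer `day`, `minute` (0-1439),
#'   logical `worn_left`/`worn_right`, and the 12 numeric temperature columns
#'   `left_hallux`, ..., `right_mts5` (degrees F). Rows are sorted by
#'   (day, minute) on construction; duplicates are an error.
#' @return object of class `patient_stream`: a list with `$patient_id` and
#'   `$data`.
#' @export
patient_stream <- function(patient_id, data) {
  data <- data.table::as.data.table(data)
  required <- c("day", "minute", "worn_left", "worn_right", .temp_cols())
  missing <- setdiff(required, names(data))
  if (length(missing)) stopf("stream is missing columns: %s", paste(missing, collapse = ", "))
  data.table::setcolorder(data, required)
  data.table::setorder(data, day, minute)
  s <- structure(list(patient_id = as.character(patient_id), data = data),
                 class = "patient_stream")
  validate_stream(s)
  s
}

#' Validate a patient stream
#'
#' Checks the stream invariants: unique strictly-increasing (day, minute)
#' timestamps, minute-of-day within 0-1439, and all temperatures finite
#' inside the physiological/ambient sanity band of 32-120 degrees F.
#'
#' @param stream a [patient_stream()].
#' @return the stream, invisibly; errors describe the first violation.
#' @export
validate_stream <- function(stream) {
  stopifnot(inherits(stream, "patient_stream"))
  d <- stream$data
  if (nrow(d) == 0L) return(invisible(stream))
  if (anyDuplicated(d, by = c("day", "minute"))) {
    stopf("duplicate timestamp in stream '%s'", stream$patient_id)
  }
  if (any(d$minute < 0L | d$minute > 1439L)) stopf("minute-of-day outside 0-1439")
  if (any(d$day < 0L)) stopf("negative day index")
  for (col in .temp_cols()) {
    v <- d[[col]]
    if (!all(is.finite(v))) stopf("non-finite temperature in column %s", col)
    if (any(v < TEMP_MIN | v > TEMP_MAX)) {
      stopf("temperature outside [%d, %d] degrees F in column %s", TEMP_MIN, TEMP_MAX, col)
    }
  }
  invisible(stream)
}

#' @export
print.patient_stream <- function(x, ...) {
  worn <- sum(x$data$worn_left & x$data$worn_right)
  cat(sprintf("<patient_stream %s: %d minutes over %d days, %d bilaterally worn>\n",
              x$patient_id, nrow(x$data),
              data.table::uniqueN(x$data$day), worn))
  invisible(x)
}

## wide <-> long conversion ---------------------------------------------------

stream_to_long <- function(stream) {
  d <- stream$data
  out <- data.table::melt(
    d, id.vars = c("day", "minute", "worn_left", "worn_right"),
    measure.vars = .temp_cols(), variable.name = "key_", value.name = "temp_f",
    variable.factor = FALSE
  )
  out[, foot := sub("_.*$", "", key_)]
  out[, location := sub("^[^_]*_", "", key_)]
  out[, worn := ifelse(foot == "left", worn_left, worn_right)]
  out[, patient_id := stream$patient_id]
  out <- out[, list(patient_id, day, minute, foot, location, temp_f, worn)]
  data.table::setorder(out, day, minute, foot, location)
  out[]
}

long_to_stream <- function(long) {
  long <- data.table::as.data.table(long)
  required <- c("patient_id", "day", "minute", "foot", "location", "temp_f", "worn")
  missing <- setdiff(required, names(long))
  if (length(missing)) stopf("long stream missing columns: %s", paste(missing, collapse = ", "))
  bad_loc <- setdiff(unique(long$location), FOOT_LOCATIONS)
  if (length(bad_loc)) stopf("unknown location label(s): %s", paste(bad_loc, collapse = ", "))
  bad_foot <- setdiff(unique(long$foot), FEET)
  if (length(bad_foot)) stopf("unknown foot label(s): %s", paste(bad_foot, collapse = ", "))
  pid <- unique(long$patient_id)
  if (length(pid) != 1L) stopf("stream file contains %d patient ids; expected 1", length(pid))
  if (anyDuplicated(long, by = c("day", "minute", "foot", "location"))) {
    stopf("duplicate timestamp (day, minute, foot, location) in stream for '%s'", pid)
  }
  long[, key_ := paste(foot, location, sep = "_")]
  wide <- data.table::dcast(long, day + minute ~ key_, value.var = "temp_f")
  worn_w <- data.table::dcast(
    unique(long[, list(day, minute, foot, worn)]),
    day + minute ~ foot, value.var = "worn"
  )
  if (anyNA(wide)) stopf("incomplete minute record: each (day, minute) needs all 12 sensors")
  wide[worn_w, `:=`(worn_left = i.left, worn_right = i.right), on = c("day", "minute")]
  patient_stream(pid, wide)
}

## readers / writers ----------------------------------------------------------

#' Write a patient stream to disk
#'
#' @param stream a [patient_stream()].
#' @param path output file path.
#' @param format `"csv"` (long, one sensor reading per row) or `"jsonl"`
#'   (one JSON object per reading).
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  long <- stream_to_long(stream)
  if (format == "csv") {
    data.table::fwrite(long, path)
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    jsonlite::stream_out(long, con, verbose = FALSE, digits = NA)
  }
  invisible(path)
}

#' Read a patient stream from disk
#'
#' Rows need not be sorted in the file; the returned stream is sorted and
#' fully validated (unknown site labels, duplicate timestamps and incomplete
#' minute records are errors).
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return a [patient_stream()].
#' @export
read_stream <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  long <- if (format == "csv") {
    data.table::fread(path, colClasses = list(
      character = c("patient_id", "foot", "location"),
      integer = c("day", "minute"), numeric = "temp_f", logical = "worn"
    ))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rows[[i]] <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                            error = function(e) stopf("parse error at line %d: %s", i, conditionMessage(e)))
    }
    data.table::rbindlist(rows)
  }
  long_to_stream(long)
}

#' Write / read a patient registry
#'
#' CSV with header `patient_id,age,sex,diagnoses,cohort,injury_type,
#' injury_foot,injury_locations,onset_day,diagnosis_day`; `diagnoses` and
#' `injury_locations` are `;`-joined.
#'
#' @param registry registry `data.table` (see [build_registry()]).
#' @param path file path.
#' @return `path` (write) or the registry `data.table` (read).
#' @export
write_registry <- function(registry, path) {
  data.table::fwrite(registry, path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  data.table::fread(path, colClasses = list(
    character = c("patient_id", "sex", "diagnoses", "cohort",
                  "injury_type", "injury_foot", "injury_locations"),
    integer = c("age", "onset_day", "diagnosis_day")
  ), na.strings = c("", "NA"))
}

## eligibility ----------------------------------------------------------------

#' Count days of wear in a stream
#'
#' A "wear day" is a day with at least `min_minutes_per_day` minutes during
#' which BOTH socks are worn -- a contralateral differential needs both
#' feet, so unilateral wear does not count.
#'
#' @param stream a [patient_stream()].
#' @param min_minutes_per_day minimum bilateral minutes for a day to count
#'   (default 30).
#' @return integer count of qualifying days (0 for an empty stream).
#' @export
wear_days <- function(stream, min_minutes_per_day = 30L) {
  stopifnot(inherits(stream, "patient_stream"))
  if (min_minutes_per_day < 1L) stopf("`min_minutes_per_day` must be >= 1")
  d <- stream$data
  if (nrow(d) == 0L) return(0L)
  per_day <- d[, list(n_worn = sum(worn_left & worn_right)), by = day]
  sum(per_day$n_worn >= min_minutes_per_day)
}

#' Apply the wear-days inclusion filter
#'
#' Retains patients with strictly more than `min_wear_days` days of
#' bilateral wear (the inclusion rule is "greater than", so a patient with
#' exactly `min_wear_days` qualifying days is excluded).
#'
#' @param registry registry `data.table`.
#' @param streams named list of [patient_stream()] keyed by `patient_id`;
#'   every registry patient must have a stream.
#' @param min_wear_days inclusion threshold (default 50).
#' @param min_minutes_per_day passed to [wear_days()].
#' @return the eligible subset of `registry`, with a `wear_days` column
#'   appended.
#' @export
filter_eligible <- function(registry, streams, min_wear_days = 50L,
                            min_minutes_per_day = 30L) {
  registry <- data.table::as.data.table(registry)
  missing <- setdiff(registry$patient_id, names(streams))
  if (length(missing)) {
    stopf("missing stream(s) for patient(s): %s", paste(missing, collapse = ", "))
  }
  wd <- vapply(registry$patient_id,
               function(p) wear_days(streams[[p]], min_minutes_per_day),
               integer(1))
  out <- data.table::copy(registry)
  out[, wear_days := wd]
  out[wear_days > min_wear_days]
}
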