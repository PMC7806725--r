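#' Longitudinal EHR event tables
#'
#' The canonical unit of raw data is the *event record*: one dated clinical
#' fact for one patient.  An event table is a `data.table` with columns
#' `patient_id` (character), `event_date` (`Date`), `event_kind` (one of
#' `"encounter"`, `"measurement"`, `"medication"`, `"diagnosis"`), `code`
#' (character; measurement name, medication ingredient id, encounter type or
#' diagnosis code), `value` (numeric, measurements only), `unit` (character,
#' optional) and `action` (`"start"`/`"stop"`, medications only).
#'
#' Refill encounters carry a code listed in the disease configuration's
#' `refill_codes` (default `"refill"`); decision-point extraction skips them.
#'
#' @name event-tables
NULL

EVENT_KINDS <- c("encounter", "measurement", "medication", "diagnosis")
EVENT_COLS  <- c("patient_id", "event_date", "event_kind", "code",
                 "value", "unit", "action")

#' Read an event table from a delimited file
#'
#' Parses and validates a CSV of event records.  Invalid rows (unparseable
#' date, measurement without a value, medication without a start/stop
#' action, empty code, unknown kind) are rejected and reported; in strict
#' mode any rejection is an error.
#'
#' @param path Path to a delimited text file.
#' @param dialect Optional list: `column_map` (named character, canonical
#'   field -> source column name), `sep` (field separator, default `","`),
#'   `date_format` (passed to [as.Date()], default ISO-8601).
#' @param strict Logical; if `TRUE` any rejected row raises an error.
#' @return A validated event `data.table` (see [event-tables]).  Rejected
#'   rows with reasons are attached as attribute `"rejected"`.
#' @export
read_events <- function(path, dialect = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("event file not found: ", path)
  sep <- dialect$sep %||% ","
  raw <- data.table::fread(path, sep = sep, colClasses = "character",
                           na.strings = c("", "NA"))
  cmap <- dialect$column_map
  if (!is.null(cmap)) {
    present <- intersect(unname(cmap), names(raw))
    data.table::setnames(raw, unname(cmap), names(cmap),
                         skip_absent = TRUE)
  }
  missing_cols <- setdiff(c("patient_id", "event_date", "event_kind", "code"),
                          names(raw))
  if (length(missing_cols))
    stop("event file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in setdiff(EVENT_COLS, names(raw))) raw[, (col) := NA_character_]
  validate_events(raw, strict = strict, date_format = dialect$date_format)
}

#' Validate a raw event table
#'
#' @param raw A data.frame-like object with the canonical columns as
#'   character vectors (dates still unparsed).
#' @param strict Logical; error on any rejected row.
#' @param date_format Optional format string for [as.Date()].
#' @return Validated event `data.table` with attribute `"rejected"`.
#' @export
validate_events <- function(raw, strict = FALSE, date_format = NULL) {
  ev <- data.table::as.data.table(raw)[, EVENT_COLS, with = FALSE]
  dt <- if (is.null(date_format)) as.Date(ev$event_date, optional = TRUE)
        else as.Date(ev$event_date, format = date_format, optional = TRUE)
  val <- suppressWarnings(as.numeric(ev$value))

  reason <- rep(NA_character_, nrow(ev))
  bad <- function(cond, why) reason[is.na(reason) & cond] <<- why
  bad(is.na(dt), "unparseable event_date")
  bad(!(ev$event_kind %in% EVENT_KINDS), "unknown event_kind")
  bad(is.na(ev$code) | ev$code == "", "empty code")
  bad(ev$event_kind == "measurement" & (is.na(ev$value) | is.na(val)),
      "measurement without numeric value")
  bad(ev$event_kind == "medication" &
        !(ev$action %in% c("start", "stop")),
      "medication without start/stop action")

  rejected <- data.table::data.table(row = which(!is.na(reason)),
                                     reason = reason[!is.na(reason)])
  if (nrow(rejected) && strict)
    stop("strict mode: ", nrow(rejected), " invalid event row(s); first: ",
         rejected$reason[1])
  if (nrow(rejected))
    message(nrow(rejected), " event row(s) rejected (",
            paste(unique(rejected$reason), collapse = "; "), ")")

  keep <- is.na(reason)
  out <- data.table::data.table(
    patient_id = ev$patient_id[keep],
    event_date = dt[keep],
    event_kind = ev$event_kind[keep],
    code       = ev$code[keep],
    value      = val[keep],
    unit       = ev$unit[keep],
    action     = ev$action[keep])
  data.table::setattr(out, "rejected", rejected)
  out[]
}

#' Write an event table in canonical form
#'
#' Rows are sorted by (patient_id, event_date, event_kind, code, action) and
#' written as ISO-8601 CSV, so `write_events(read_events(f))` is a fixed
#' point: re-reading and re-writing reproduces the file byte for byte.
#'
#' @param events Validated event table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- data.table::as.data.table(events)[, EVENT_COLS, with = FALSE]
  data.table::setorder(ev, patient_id, event_date, event_kind, code,
                       action, na.last = TRUE)
  out <- data.table::copy(ev)
  out[, event_date := format(event_date, "%Y-%m-%d")]
  data.table::fwrite(out, path, na = "", quote = FALSE)
  invisible(path)
}

#' Code maps for medications, diagnoses and measurements
#'
#' A code map translates opaque event codes into analysis labels: medication
#' ingredient code -> (class, ingredient) labels, diagnosis code -> disease
#' category, measurement code -> canonical analyte name and unit.  Real
#' terminology resolution (RxNorm, LOINC, ICD/CCS) is out of scope; maps are
#' plain JSON.
#'
#' @param medication_map Named list: code -> list(class, label).
#' @param diagnosis_map Named character: code -> category label.
#' @param measurement_map Named list: code -> list(name, unit).
#' @return An object of class `pcto_code_map`.
#' @export
code_map <- function(medication_map = list(), diagnosis_map = character(),
                     measurement_map = list()) {
  stopifnot(all(vapply(medication_map, function(m)
    nzchar(m$class %||% "") && nzchar(m$label %||% ""), logical(1))))
  structure(list(medication_map = medication_map,
                 diagnosis_map = as.list(diagnosis_map),
                 measurement_map = measurement_map),
            class = "pcto_code_map")
}

#' @rdname code_map
#' @param path JSON file path.
#' @export
read_code_map <- function(path) {
  x <- jsonlite::read_json(path)
  code_map(medication_map = x$medication_map %||% list(),
           diagnosis_map = unlist(x$diagnosis_map) %||% character(),
           measurement_map = x$measurement_map %||% list())
}

#' @rdname code_map
#' @param map A `pcto_code_map`.
#' @export
write_code_map <- function(map, path) {
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Check that every code in `events` is covered by `map`; returns character
# vector of unmapped codes (empty when total).
unmapped_codes <- function(events, map) {
  c(setdiff(events$code[events$event_kind == "medication"],
            names(map$medication_map)),
    setdiff(events$code[events$event_kind == "diagnosis"],
            names(map$diagnosis_map)),
    setdiff(events$code[events$event_kind == "measurement"],
            names(map$measurement_map)))
}

#' Build per-patient timelines from an event table
#'
#' Groups events by patient, sorts them (date, then kind, then code) and
#' folds medication start/stop events into half-open active intervals
#' `[start, stop)`: a start with no later stop yields a right-open interval,
#' a stop with no open interval is logged and ignored, and a same-day
#' start/stop is a degenerate empty interval (logged, dropped).
#'
#' @param events Validated event table.
#' @param codes Optional [code_map()]; with `strict = TRUE`, any event code
#'   missing from the map is an error.
#' @param strict Logical.
#' @return An object of class `pcto_timelines`: list with `events` (keyed
#'   data.table), `intervals` (patient_id, code, start, stop with `NA` stop
#'   meaning open) and `patients`.
#' @export
build_timelines <- function(events, codes = NULL, strict = FALSE) {
  ev <- data.table::as.data.table(events)
  if (!is.null(codes)) {
    um <- unmapped_codes(ev, codes)
    if (length(um) && strict)
      stop("unmapped code(s): ", paste(unique(um), collapse = ", "))
  }
  data.table::setorder(ev, patient_id, event_date, event_kind, code,
                       action, na.last = TRUE)

  meds <- ev[event_kind == "medication"]
  ivals <- if (nrow(meds)) {
    meds[, fold_intervals(event_date, action), by = .(patient_id, code)]
  } else {
    data.table::data.table(patient_id = character(), code = character(),
                           start = as.Date(character()),
                           stop = as.Date(character()))
  }
  data.table::setkey(ev, patient_id, event_date)
  structure(list(events = ev, intervals = ivals,
                 patients = unique(ev$patient_id)),
            class = "pcto_timelines")
}

# Fold a date-sorted start/stop sequence for one (patient, ingredient) into
# non-overlapping half-open intervals.  Duplicate starts while open are
# ignored; orphan stops are ignored; empty [d, d) intervals dropped.
fold_intervals <- function(dates, actions) {
  starts <- as.Date(character()); stops <- as.Date(character())
  open <- as.Date(NA)
  for (k in seq_along(dates)) {
    if (actions[k] == "start") {
      if (is.na(open)) open <- dates[k]
    } else {
      if (is.na(open)) next                 # orphan stop
      if (dates[k] > open) {                # same-day start+stop -> empty
        starts <- c(starts, open); stops <- c(stops, dates[k])
      }
      open <- as.Date(NA)
    }
  }
  if (!is.na(open)) { starts <- c(starts, open); stops <- c(stops, as.Date(NA)) }
  list(start = starts, stop = stops)
}

#' @export
print.pcto_timelines <- function(x, ...) {
  cat("<pcto_timelines> ", length(x$patients), " patients, ",
      nrow(x$events), " events, ", nrow(x$intervals),
      " medication intervals\n", sep = "")
  invisible(x)
}

# Ingredient codes active for `patient` on date `d` (start <= d < stop).
active_meds <- function(timelines, patient, d) {
  iv <- timelines$intervals[patient_id == patient &
                              start <= d & (is.na(stop) | stop > d)]
  unique(iv$code)
}
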