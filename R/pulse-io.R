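#' Convert between dB re 1 uPa and linear pressure relative to 1 Pa
#'
#' Pulse-event recorders specify their detection threshold in dB re 1 uPa
#' (139 dB by default), while the stored pulse amplitudes and all ratio
#' criteria (SPLR, CV of SPL) operate on linear pressure relative to 1 Pa.
#' `dbToLinear(L)` returns `10^(L/20) * 1e-6`; `linearToDb` is its inverse.
#'
#' @param level_db sound pressure level(s) in dB re 1 uPa.
#' @param pressure_pa linear pressure(s) relative to 1 Pa (> 0).
#' @return numeric vector.
#' @examples
#' dbToLinear(120)   # 1 Pa
#' dbToLinear(139)   # ~8.91 Pa, the default detection threshold
#' linearToDb(dbToLinear(151))
#' @export
dbToLinear <- function(level_db) {
  stopifnot(is.numeric(level_db), all(is.finite(level_db)))
  10^(level_db / 20) * 1e-6
}

#' @rdname dbToLinear
#' @export
linearToDb <- function(pressure_pa) {
  stopifnot(is.numeric(pressure_pa), all(pressure_pa > 0))
  20 * log10(pressure_pa / 1e-6)
}

#' Construct a PulseSeries
#'
#' @param records data.frame with columns `t_ms`, `spl_a`, `spl_b`, `td_us`
#'   (see [PulseSeries-class] for units and quantization).
#' @param startDatetime POSIXct scalar or ISO 8601 string; recording start.
#' @param thresholdDb detection threshold in dB re 1 uPa.
#' @param meta free-form list of recording metadata.
#' @return a validated [PulseSeries-class] object.
#' @examples
#' PulseSeries(data.frame(t_ms = c(0, 10, 20.5), spl_a = 20, spl_b = 18,
#'                        td_us = c(1, 1.25, 0.75)))
#' @export
PulseSeries <- function(records, startDatetime = NA, thresholdDb = 139,
                        meta = list()) {
  if (is.character(startDatetime))
    startDatetime <- as.POSIXct(startDatetime, tz = "UTC",
                                tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                               "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (!inherits(startDatetime, "POSIXct")) startDatetime <- as.POSIXct(startDatetime)
  records <- as.data.frame(records)[, c("t_ms", "spl_a", "spl_b", "td_us")]
  rownames(records) <- NULL
  msg <- .validate_pulse_records(records, thresholdDb)
  if (!isTRUE(msg)) .validation_error(paste(msg, collapse = "; "))
  new("PulseSeries", records = records, startDatetime = startDatetime,
      thresholdDb = thresholdDb, meta = meta)
}

#' @rdname PulseSeries-class
#' @aliases pulseRecords nPulses startDatetime thresholdDb
setMethod("pulseRecords", "PulseSeries", function(x) x@records)

#' @rdname PulseSeries-class
setMethod("nPulses", "PulseSeries", function(x) nrow(x@records))

#' @rdname PulseSeries-class
setMethod("startDatetime", "PulseSeries", function(x) x@startDatetime)

#' @rdname PulseSeries-class
setMethod("startDatetime<-", "PulseSeries", function(x, value) {
  if (is.character(value)) value <- as.POSIXct(value, tz = "UTC")
  x@startDatetime <- value
  validObject(x)
  x
})

#' @rdname PulseSeries-class
setMethod("thresholdDb", "PulseSeries", function(x) x@thresholdDb)

#' @rdname PulseSeries-class
setMethod("length", "PulseSeries", function(x) nrow(x@records))

#' @rdname PulseSeries-class
#' @param i integer indices of pulses to keep (must stay strictly ordered).
setMethod("[", "PulseSeries", function(x, i) {
  initialize(x, records = x@records[i, , drop = FALSE])
})

setMethod("show", "PulseSeries", function(object) {
  n <- nrow(object@records)
  cat(sprintf("PulseSeries with %d pulse%s", n, if (n == 1) "" else "s"))
  if (n > 0)
    cat(sprintf(" spanning %.1f s", diff(range(object@records$t_ms)) / 1000))
  cat(sprintf("\n  detection threshold: %g dB re 1 uPa", object@thresholdDb))
  if (!is.na(object@startDatetime))
    cat(sprintf("\n  recording start: %s", format(object@startDatetime, usetz = TRUE)))
  cat("\n")
  invisible(NULL)
})

.PULSE_COLUMNS <- c("t_ms", "spl_a_pa", "spl_b_pa", "td_us")

#' Read and write pulse-event CSV files
#'
#' The interchange format is a UTF-8 CSV with mandatory header
#' `t_ms,spl_a_pa,spl_b_pa,td_us`. An optional JSON sidecar (same path with
#' `.json` appended) may carry `start_datetime` (ISO 8601), `threshold_db`,
#' and free-form metadata (`site`, `device`, ...). Rows violating the
#' recorder's quantization (0.5 ms time slots, 0.25 us arrival-time
#' differences), ordering, or the detection threshold are reported as
#' validation errors, never silently fixed. `writePulses` round-trips:
#' reading a written file reproduces the series field for field.
#'
#' @param path CSV file path.
#' @param sidecar JSON sidecar path, or NA to use `<path>.json` when present.
#' @param thresholdDb detection threshold used for validation when no
#'   sidecar value is available.
#' @param series a [PulseSeries-class].
#' @return `readPulses` returns a [PulseSeries-class]; `writePulses`
#'   invisibly returns `path`.
#' @seealso [readAnnotations()]
#' @export
readPulses <- function(path, sidecar = NA, thresholdDb = 139) {
  if (!file.exists(path)) .schema_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.PULSE_COLUMNS, names(df))
  if (length(missing) > 0)
    .schema_error(sprintf("pulse CSV %s is missing column(s): %s",
                          path, paste(missing, collapse = ", ")))
  start <- NA
  meta <- list()
  if (is.na(sidecar)) {
    cand <- paste0(path, ".json")
    if (file.exists(cand)) sidecar <- cand
  }
  if (!is.na(sidecar) && file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$start_datetime)) start <- side$start_datetime
    if (!is.null(side$threshold_db)) thresholdDb <- side$threshold_db
    meta <- side[setdiff(names(side), c("start_datetime", "threshold_db"))]
  }
  rec <- data.frame(t_ms = df$t_ms, spl_a = df$spl_a_pa, spl_b = df$spl_b_pa,
                    td_us = df$td_us)
  PulseSeries(rec, startDatetime = start, thresholdDb = thresholdDb, meta = meta)
}

#' @rdname readPulses
#' @export
writePulses <- function(series, path, sidecar = NA) {
  stopifnot(is(series, "PulseSeries"))
  rec <- series@records
  out <- data.frame(t_ms = rec$t_ms, spl_a_pa = rec$spl_a, spl_b_pa = rec$spl_b,
                    td_us = rec$td_us)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  side <- list(threshold_db = series@thresholdDb)
  if (!is.na(series@startDatetime))
    side$start_datetime <- format(series@startDatetime, "%Y-%m-%dT%H:%M:%S",
                                  tz = "UTC")
  side <- c(side, series@meta)
  if (!is.na(sidecar))
    jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.ANNOTATION_LABELS <- c("regular_click", "buzz", "click_train", "vessel", "noise")

#' Read and write annotation CSV files
#'
#' Annotations mark ground-truth events (manual or simulated) as spans in
#' series time with a label from the closed vocabulary `regular_click`,
#' `buzz`, `click_train`, `vessel`, `noise`. Format: CSV with header
#' `t_start_ms,t_end_ms,label`.
#'
#' @param path CSV file path.
#' @param annotations data.frame with columns `t_start_ms`, `t_end_ms`,
#'   `label`.
#' @return `readAnnotations` returns the validated data.frame.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) .schema_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("t_start_ms", "t_end_ms", "label"), names(df))
  if (length(missing) > 0)
    .schema_error(sprintf("annotation CSV %s is missing column(s): %s",
                          path, paste(missing, collapse = ", ")))
  validateAnnotations(df)
}

#' @rdname readAnnotations
#' @export
writeAnnotations <- function(annotations, path) {
  validateAnnotations(annotations)
  utils::write.csv(annotations[, c("t_start_ms", "t_end_ms", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readAnnotations
#' @export
validateAnnotations <- function(annotations) {
  annotations <- as.data.frame(annotations)
  bad <- which(annotations$t_start_ms > annotations$t_end_ms)
  if (length(bad) > 0)
    .validation_error(sprintf("annotation end before start at row %d", bad[1]))
  unknown <- setdiff(unique(annotations$label), .ANNOTATION_LABELS)
  if (length(unknown) > 0)
    .validation_error(sprintf("unknown annotation label(s): %s",
                              paste(unknown, collapse = ", ")))
  annotations
}
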