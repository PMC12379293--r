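#' @import methods
NULL

#' PulseSeries: a time-ordered stream of detected ultrasonic pulses
#'
#' The unit of data produced by a stereo pulse-event recorder and consumed by
#' the rule-based filters. One row of `records` per detected pulse:
#' \describe{
#'   \item{t_ms}{detection time in milliseconds since recording start,
#'     an exact multiple of 0.5 ms (the recorder's time resolution).}
#'   \item{spl_a, spl_b}{received sound pressure at hydrophones A and B,
#'     linear scale relative to 1 Pa, at or above the detection threshold.}
#'   \item{td_us}{signed arrival-time difference A minus B in microseconds,
#'     an exact multiple of 0.25 us; positive means the pulse arrived at
#'     hydrophone A first.}
#' }
#' Sound pressure is stored on a linear scale (not dB) because the
#' sound-pressure-ratio criterion (SPLR >= 0.6) and the coefficient of
#' variation of SPL are only meaningful as ratios of linear pressures; dB
#' values are converted on ingest with [dbToLinear()].
#'
#' @slot records data.frame with columns `t_ms`, `spl_a`, `spl_b`, `td_us`,
#'   strictly increasing in `t_ms` (no two pulses share a 0.5 ms slot).
#' @slot startDatetime POSIXct scalar; absolute wall-clock time of recording
#'   start (may be NA until temporal features are needed).
#' @slot thresholdDb numeric scalar; detection threshold in dB re 1 uPa
#'   (default 139): pulses below its linear equivalent are never stored.
#' @slot meta free-form list (site, device id, ...).
#'
#' @seealso [PulseSeries()], [readPulses()], [detectClickTrains()]
#' @export
setClass("PulseSeries",
  representation(records = "data.frame", startDatetime = "POSIXct",
                 thresholdDb = "numeric", meta = "list"),
  prototype(records = data.frame(t_ms = numeric(), spl_a = numeric(),
                                 spl_b = numeric(), td_us = numeric()),
            startDatetime = as.POSIXct(NA),
            thresholdDb = 139, meta = list()))

.validate_pulse_records <- function(rec, threshold_db) {
  required <- c("t_ms", "spl_a", "spl_b", "td_us")
  missing <- setdiff(required, names(rec))
  if (length(missing) > 0)
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  msgs <- character()
  bad_t <- which(!.is_multiple(rec$t_ms, .TIME_STEP_MS))
  if (length(bad_t) > 0)
    msgs <- c(msgs, sprintf(
      "t_ms not a multiple of 0.5 ms at row(s) %s (first value %s)",
      paste(utils::head(bad_t, 5), collapse = ", "), rec$t_ms[bad_t[1]]))
  bad_td <- which(!.is_multiple(rec$td_us, .TD_STEP_US))
  if (length(bad_td) > 0)
    msgs <- c(msgs, sprintf(
      "td_us not a multiple of 0.25 us at row(s) %s",
      paste(utils::head(bad_td, 5), collapse = ", ")))
  if (nrow(rec) > 1) {
    nonmono <- which(diff(rec$t_ms) <= 0)
    if (length(nonmono) > 0)
      msgs <- c(msgs, sprintf(
        "t_ms not strictly increasing at row %d (duplicate or reversed 0.5 ms slot)",
        nonmono[1] + 1L))
  }
  thr <- dbToLinear(threshold_db)
  low <- which(rec$spl_a < thr - 1e-9 | rec$spl_b < thr - 1e-9 |
                 rec$spl_a <= 0 | rec$spl_b <= 0)
  if (length(low) > 0)
    msgs <- c(msgs, sprintf(
      "sound pressure below the %g dB re 1 uPa detection threshold at row(s) %s",
      threshold_db, paste(utils::head(low, 5), collapse = ", ")))
  if (length(msgs) > 0) msgs else TRUE
}

setValidity("PulseSeries", function(object) {
  if (length(object@thresholdDb) != 1 || !is.finite(object@thresholdDb))
    return("thresholdDb must be a single finite number")
  if (length(object@startDatetime) != 1)
    return("startDatetime must be a single POSIXct (possibly NA)")
  .validate_pulse_records(object@records, object@thresholdDb)
})

#' CandidateEvents: contiguous pulse segments emitted by a rule-based filter
#'
#' Each event is a contiguous run of pulses in the filtered series, carrying
#' one boolean flag per criterion of the relevant rule table and a `passed`
#' column that is the conjunction of all flags. Segments that fail one or
#' more criteria are retained (flagged) so that false-positive accounting can
#' enumerate every pulse event the filter looked at; [passedEvents()] gives
#' the view that feeds the classifier.
#'
#' @slot kind "click" or "vessel" (which rule table produced the events).
#' @slot series the [PulseSeries-class] the `pulseIndices` refer to: the
#'   reflection-cleaned series for the click branch, the raw series for the
#'   vessel branch.
#' @slot table data.frame with one row per event: `event_id`, `t_start_ms`,
#'   `t_end_ms`, `n_pulses`, one logical column per criterion, `passed`.
#' @slot pulseIndices list of contiguous integer index vectors into `series`.
#' @seealso [detectClickTrains()], [detectVesselEvents()], [eventFeatures()]
#' @export
setClass("CandidateEvents",
  representation(kind = "character", series = "PulseSeries",
                 table = "data.frame", pulseIndices = "list"))

setValidity("CandidateEvents", function(object) {
  if (!object@kind %in% c("click", "vessel"))
    return("kind must be 'click' or 'vessel'")
  if (nrow(object@table) != length(object@pulseIndices))
    return("table rows and pulseIndices must align")
  t <- object@series@records$t_ms
  for (i in seq_along(object@pulseIndices)) {
    idx <- object@pulseIndices[[i]]
    if (length(idx) == 0 || any(diff(idx) != 1L))
      return(sprintf("pulseIndices[[%d]] must be contiguous and non-empty", i))
    if (object@table$t_start_ms[i] != t[idx[1]] ||
        object@table$t_end_ms[i] != t[idx[length(idx)]])
      return(sprintf("event %d span does not match its first/last pulse", i))
  }
  flag_cols <- setdiff(names(object@table),
                       c("event_id", "t_start_ms", "t_end_ms", "n_pulses", "passed"))
  if (length(flag_cols) > 0) {
    conj <- Reduce(`&`, object@table[flag_cols])
    if (nrow(object@table) > 0 && !identical(as.logical(conj), object@table$passed))
      return("passed must equal the conjunction of all criterion flags")
  }
  TRUE
})

#' TrainedEventModel: a fitted random-forest event classifier
#'
#' Wraps a fitted `ranger` ensemble together with the metadata needed to
#' apply it safely: branch, feature column order, hyperparameters and
#' training seed. Prediction refuses feature tables whose column order does
#' not match the training layout.
#'
#' @slot fit the fitted `ranger` object.
#' @slot branch "click" (classes regular_click / buzz / noise) or "vessel"
#'   (classes vessel / non_vessel).
#' @slot featureNames character; training feature columns, in order.
#' @slot hyperparams list as returned by [rfHyperparams()].
#' @slot levels character; class labels the model can emit.
#' @seealso [trainEventModel()], [featureImportances()]
#' @export
setClass("TrainedEventModel",
  representation(fit = "ANY", branch = "character",
                 featureNames = "character", hyperparams = "list",
                 levels = "character"))
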