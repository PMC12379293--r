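## Feature names, in the fixed export order. BuzzCheck is appended for the
## click branch only (18 features vs 17).
.FEATURE_NAMES_BASE <- c("Np", "Duration", "Start", "End",
                         "MaxPi", "MinPi", "AvPi", "SdPi",
                         "MaxSPLR", "AvSPLR", "SdSPLR",
                         "Maxtd", "Avtd", "Sdtd",
                         "MaxSPLA", "AvSPLA", "SdSPLA")

#' Feature column names for a branch
#'
#' The fixed, versioned feature order used by [eventFeatures()] and expected
#' by trained models: 18 columns for the click branch, 17 for the vessel
#' branch (no `BuzzCheck`).
#'
#' @param branch `"click"` or `"vessel"`.
#' @return character vector of column names.
#' @export
featureNames <- function(branch = c("click", "vessel")) {
  branch <- match.arg(branch)
  if (branch == "click") c(.FEATURE_NAMES_BASE, "BuzzCheck")
  else .FEATURE_NAMES_BASE
}

#' Buzz detector: runs of short inter-pulse intervals
#'
#' A buzz is a sequence of five or more consecutive pulses whose successive
#' intervals are all at most 10 ms (the terminal-phase clicking of a
#' porpoise closing on prey). Returns 1 if any such run exists, 0 otherwise.
#' Monotone under extension: appending pulses at <= 10 ms spacing never
#' turns a buzz into a non-buzz.
#'
#' @param t_ms ordered pulse times in ms (>= 1 pulse).
#' @param maxIntervalMs run interval bound (default 10 ms).
#' @param minPulses minimum pulses in a run (default 5).
#' @return integer 0 or 1.
#' @examples
#' buzzCheck(seq(0, 32, by = 8))           # five pulses at 8 ms -> 1
#' buzzCheck(seq(0, 250, by = 50))         # six pulses at 50 ms -> 0
#' @export
buzzCheck <- function(t_ms, maxIntervalMs = 10, minPulses = 5) {
  stopifnot(length(t_ms) >= 1)
  if (length(t_ms) < minPulses) return(0L)
  short <- diff(t_ms) <= maxIntervalMs + 1e-9
  runs <- rle(short)
  as.integer(any(runs$values & runs$lengths >= minPulses - 1))
}

.features_one <- function(t, a, b, td, start_epoch_s, branch) {
  n <- length(t)
  pi_ms <- diff(t)
  splr <- a / b
  start_min <- floor((start_epoch_s + t[1] / 1000) / 60)
  end_min <- floor((start_epoch_s + t[n] / 1000) / 60)
  out <- c(Np = n, Duration = t[n] - t[1], Start = start_min, End = end_min,
           MaxPi = max(pi_ms), MinPi = min(pi_ms), AvPi = mean(pi_ms),
           SdPi = stats::sd(pi_ms),
           MaxSPLR = max(splr), AvSPLR = mean(splr), SdSPLR = stats::sd(splr),
           Maxtd = max(td), Avtd = mean(td), Sdtd = stats::sd(td),
           MaxSPLA = max(a), AvSPLA = mean(a), SdSPLA = stats::sd(a))
  if (branch == "click") out <- c(out, BuzzCheck = buzzCheck(t))
  out
}

#' Extract the acoustic feature vector of each candidate event
#'
#' Computes, per candidate event, the fixed feature set used to train and
#' apply the event classifiers: pulse count, duration, start/end timestamps,
#' and maximum / minimum / mean / sample SD summaries of the pulse
#' intervals, per-pulse sound-pressure ratio A/B, signed arrival-time
#' differences, and hydrophone-A sound pressure; the click branch adds the
#' binary `BuzzCheck` flag ([buzzCheck()]). Conventions: all SDs use the
#' sample (n-1) denominator; `Maxtd` is the maximum of the signed values;
#' `Start`/`End` are minutes since the Unix epoch, truncated to the minute
#' (the recorder's timestamp precision), computed from the series'
#' `startDatetime` plus the pulse time.
#'
#' @param events a [CandidateEvents-class]; every event needs >= 2 pulses
#'   (guaranteed by the detectors) and the underlying series must carry a
#'   `startDatetime`.
#' @param branch feature layout; defaults to the events' own branch.
#' @return data.frame with one row per event: `event_id`, `kind`, then the
#'   [featureNames()] columns in fixed order.
#' @seealso [trainEventModel()]
#' @export
eventFeatures <- function(events, branch = NULL) {
  stopifnot(is(events, "CandidateEvents"))
  if (is.null(branch)) branch <- events@kind
  branch <- match.arg(branch, c("click", "vessel"))
  start <- events@series@startDatetime
  if (is.na(start))
    .schema_error("series startDatetime is required to extract Start/End features")
  start_epoch_s <- as.numeric(start)
  rec <- events@series@records
  idx_list <- events@pulseIndices
  if (any(lengths(idx_list) < 2))
    .validation_error("cannot featurize a single-pulse event")
  cols <- featureNames(branch)
  mat <- matrix(NA_real_, nrow = length(idx_list), ncol = length(cols),
                dimnames = list(NULL, cols))
  for (i in seq_along(idx_list)) {
    idx <- idx_list[[i]]
    mat[i, ] <- .features_one(rec$t_ms[idx], rec$spl_a[idx], rec$spl_b[idx],
                              rec$td_us[idx], start_epoch_s, branch)
  }
  cbind(data.frame(event_id = events@table$event_id,
                   kind = rep(events@kind, length(idx_list))),
        as.data.frame(mat))
}

#' @rdname eventFeatures
#' @param features data.frame from `eventFeatures`.
#' @param path output CSV path.
#' @export
writeFeatures <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
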