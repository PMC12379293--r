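#' Rule tables for the click-train and vessel-noise filters
#'
#' `clickTrainCriteria()` holds the nine criteria that a contiguous pulse
#' segment must satisfy to be a candidate porpoise click train:
#' \enumerate{
#'   \item pulse intervals >= `minPiMs` (2 ms; shorter gaps are surface or
#'     bottom reflections and are removed before segmentation),
#'   \item pulse intervals <= `maxPiMs` (100 ms; larger gaps split trains),
#'   \item at least `minPulses` pulses (6),
#'   \item coefficient of variation (sample SD / mean) of pulse intervals
#'     <= `maxCvPi` (0.4),
#'   \item mean per-pulse sound-pressure ratio A/B >= `minSplr` (0.6),
#'   \item duration (last minus first pulse time) >= `minDurationMs` (12 ms),
#'   \item sample SD of signed arrival-time differences < `maxSdTdUs`
#'     (25 us; a single animal gives a stable bearing),
#'   \item CV of hydrophone-A SPL, in percent, <= `maxCvSplPct` (100),
#'   \item median pulse interval < `maxMedianPiMs` (100 ms).
#' }
#' Boundary semantics follow the printed inequalities exactly: >=/<= are
#' inclusive, </> exclusive (an interval of exactly 100 ms stays inside a
#' train). `vesselCriteria()` holds the three vessel-noise criteria: pulse
#' intervals < `maxPiMs` (500 ms), strictly more than `minPulses - 1`
#' consecutive pulses (> 80), and continuous duration >= `minDurationS`
#' (10 s).
#'
#' @param minPiMs,maxPiMs,minPulses,maxCvPi,minSplr,minDurationMs,maxSdTdUs,maxCvSplPct,maxMedianPiMs
#'   click-train thresholds (defaults above).
#' @return a named list with class `"ClickTrainCriteria"` /
#'   `"VesselCriteria"`.
#' @export
clickTrainCriteria <- function(minPiMs = 2, maxPiMs = 100, minPulses = 6,
                               maxCvPi = 0.4, minSplr = 0.6,
                               minDurationMs = 12, maxSdTdUs = 25,
                               maxCvSplPct = 100, maxMedianPiMs = 100) {
  crit <- list(minPiMs = minPiMs, maxPiMs = maxPiMs, minPulses = minPulses,
               maxCvPi = maxCvPi, minSplr = minSplr,
               minDurationMs = minDurationMs, maxSdTdUs = maxSdTdUs,
               maxCvSplPct = maxCvSplPct, maxMedianPiMs = maxMedianPiMs)
  if (any(unlist(crit) <= 0) || minPiMs >= maxPiMs)
    .schema_error("click-train criteria must be positive with minPiMs < maxPiMs")
  structure(crit, class = "ClickTrainCriteria")
}

#' @rdname clickTrainCriteria
#' @param minDurationS minimum continuous vessel-event duration in seconds.
#' @export
vesselCriteria <- function(maxPiMs = 500, minPulses = 81, minDurationS = 10) {
  crit <- list(maxPiMs = maxPiMs, minPulses = minPulses,
               minDurationS = minDurationS)
  if (any(unlist(crit) <= 0))
    .schema_error("vessel criteria must be positive")
  structure(crit, class = "VesselCriteria")
}

#' Remove reflections from a pulse series
#'
#' Left-to-right sweep keeping a pulse iff its time minus the last kept
#' pulse's time is at least `minPiMs`; the first pulse is always kept. The
#' earlier pulse survives because a reflection always arrives after its
#' source. Idempotent.
#'
#' @param series a [PulseSeries-class].
#' @param minPiMs minimum pulse interval in ms (default 2, rule 1 of
#'   [clickTrainCriteria()]).
#' @return the cleaned [PulseSeries-class].
#' @examples
#' s <- PulseSeries(data.frame(t_ms = c(0, 1, 2.5), spl_a = 20, spl_b = 20,
#'                             td_us = 0))
#' pulseRecords(removeReflections(s))$t_ms  # 1.0 is a reflection of 0
#' @export
removeReflections <- function(series, minPiMs = 2) {
  t <- series@records$t_ms
  n <- length(t)
  if (n <= 1) return(series)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- t[1]
  for (i in 2:n) {
    if (t[i] - last >= minPiMs - 1e-9) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  series[which(keep)]
}

#' Split a pulse series into contiguous segments at large gaps
#'
#' Partitions the series index-wise: the click branch splits where an
#' inter-pulse interval exceeds the bound (`boundary = "exceeds"`, interval
#' of exactly 100 ms stays inside), the vessel branch where it reaches it
#' (`boundary = "at_or_exceeds"`, interval of exactly 500 ms splits).
#' Concatenating the segments reproduces the input series exactly.
#'
#' @param series a [PulseSeries-class].
#' @param thresholdMs gap threshold in ms.
#' @param boundary `"exceeds"` or `"at_or_exceeds"`.
#' @return list of contiguous integer index vectors into `series`.
#' @export
segmentByGap <- function(series, thresholdMs,
                         boundary = c("exceeds", "at_or_exceeds")) {
  boundary <- match.arg(boundary)
  t <- series@records$t_ms
  n <- length(t)
  if (n == 0) return(list())
  gaps <- diff(t)
  split_after <- if (boundary == "exceeds") gaps > thresholdMs + 1e-9
                 else gaps >= thresholdMs - 1e-9
  grp <- cumsum(c(0L, as.integer(split_after)))
  unname(split(seq_len(n), grp))
}

#' Evaluate the nine click-train criteria on one segment
#'
#' Computes the per-criterion pass flags for a contiguous pulse segment.
#' Statistics: pulse intervals are successive time differences; CVs are
#' sample standard deviation (n-1 denominator) over mean; duration is last
#' minus first pulse time; the SPLR flag uses the segment mean of the
#' per-pulse linear ratio spl_a/spl_b (`splrMode = "mean"`, the default; set
#' `"all_pulses"` to require every pulse to reach the bound); the SPL CV is
#' expressed in percent; the arrival-time-difference SD uses signed values.
#' Flags whose statistic is undefined (fewer than two intervals) fail.
#'
#' @param t_ms,spl_a,spl_b,td_us pulse vectors of one contiguous segment.
#' @param criteria a [clickTrainCriteria()] list.
#' @param splrMode `"mean"` or `"all_pulses"`.
#' @return named logical vector of length 9 (`min_interval`, `max_interval`,
#'   `min_pulses`, `cv_interval`, `splr`, `duration`, `sd_td`, `cv_spl`,
#'   `median_interval`).
#' @export
evaluateClickTrainCriteria <- function(t_ms, spl_a, spl_b, td_us,
                                       criteria = clickTrainCriteria(),
                                       splrMode = c("mean", "all_pulses")) {
  splrMode <- match.arg(splrMode)
  n <- length(t_ms)
  pi_ms <- diff(t_ms)
  splr <- spl_a / spl_b
  splr_stat <- if (splrMode == "mean") mean(splr) >= criteria$minSplr
               else all(splr >= criteria$minSplr)
  c(min_interval = n >= 2 && all(pi_ms >= criteria$minPiMs - 1e-9),
    max_interval = n >= 2 && all(pi_ms <= criteria$maxPiMs + 1e-9),
    min_pulses = n >= criteria$minPulses,
    cv_interval = isTRUE(.cv(pi_ms) <= criteria$maxCvPi),
    splr = isTRUE(splr_stat),
    duration = n >= 2 && (t_ms[n] - t_ms[1]) >= criteria$minDurationMs - 1e-9,
    sd_td = isTRUE(stats::sd(td_us) < criteria$maxSdTdUs),
    cv_spl = isTRUE(100 * .cv(spl_a) <= criteria$maxCvSplPct),
    median_interval = n >= 2 && stats::median(pi_ms) < criteria$maxMedianPiMs)
}

.evaluate_vessel_criteria <- function(t_ms, criteria) {
  n <- length(t_ms)
  pi_ms <- diff(t_ms)
  c(max_interval = n >= 2 && all(pi_ms < criteria$maxPiMs - 1e-9),
    min_pulses = n >= criteria$minPulses,
    duration = n >= 2 &&
      (t_ms[n] - t_ms[1]) >= criteria$minDurationS * 1000 - 1e-9)
}

.candidate_events <- function(kind, series, segments, flag_fun) {
  t <- series@records$t_ms
  segments <- Filter(function(idx) length(idx) >= 2, segments)
  rows <- lapply(seq_along(segments), function(i) {
    idx <- segments[[i]]
    flags <- flag_fun(idx)
    c(list(event_id = i, t_start_ms = t[idx[1]], t_end_ms = t[idx[length(idx)]],
           n_pulses = length(idx)), as.list(flags), list(passed = all(flags)))
  })
  tab <- if (length(rows) == 0) {
    flags <- flag_fun(integer())
    empty <- c(list(event_id = integer(), t_start_ms = numeric(),
                    t_end_ms = numeric(), n_pulses = integer()),
               stats::setNames(rep(list(logical()), length(flags)), names(flags)),
               list(passed = logical()))
    as.data.frame(empty)
  } else {
    do.call(rbind, lapply(rows, as.data.frame))
  }
  new("CandidateEvents", kind = kind, series = series, table = tab,
      pulseIndices = segments)
}

#' Detect candidate porpoise click trains
#'
#' Runs the click branch of the rule-based filter: reflection removal
#' (criterion 1), segmentation at inter-pulse gaps over 100 ms (criterion 2),
#' then evaluation of all nine criteria per segment. Every segment of at
#' least two pulses is returned with its flags; [passedEvents()] gives the
#' candidates satisfying all nine criteria (the set that feeds the
#' classifier). Segments are never re-split after a criterion failure:
#' false positives and negatives at this stage are tolerated and handled by
#' the downstream classifier.
#'
#' @param series a [PulseSeries-class] (raw; reflections are removed here).
#' @param criteria a [clickTrainCriteria()] list.
#' @param splrMode see [evaluateClickTrainCriteria()].
#' @return a [CandidateEvents-class] with `kind = "click"`, whose `series`
#'   slot holds the reflection-cleaned series its indices refer to.
#' @seealso [detectVesselEvents()], [eventFeatures()]
#' @export
detectClickTrains <- function(series, criteria = clickTrainCriteria(),
                              splrMode = c("mean", "all_pulses")) {
  splrMode <- match.arg(splrMode)
  cleaned <- removeReflections(series, criteria$minPiMs)
  segments <- segmentByGap(cleaned, criteria$maxPiMs, boundary = "exceeds")
  rec <- cleaned@records
  .candidate_events("click", cleaned, segments, function(idx) {
    evaluateClickTrainCriteria(rec$t_ms[idx], rec$spl_a[idx], rec$spl_b[idx],
                               rec$td_us[idx], criteria, splrMode)
  })
}

#' Detect candidate vessel-noise events
#'
#' Runs the vessel branch of the rule-based filter on the raw series (no
#' reflection removal; the vessel rule table has no minimum-interval rule):
#' segmentation at inter-pulse gaps of 500 ms or more, then the count
#' (> 80 pulses) and duration (>= 10 s) criteria per segment.
#'
#' @param series a [PulseSeries-class].
#' @param criteria a [vesselCriteria()] list.
#' @return a [CandidateEvents-class] with `kind = "vessel"`.
#' @export
detectVesselEvents <- function(series, criteria = vesselCriteria()) {
  segments <- segmentByGap(series, criteria$maxPiMs, boundary = "at_or_exceeds")
  t <- series@records$t_ms
  .candidate_events("vessel", series, segments, function(idx) {
    .evaluate_vessel_criteria(t[idx], criteria)
  })
}

#' @rdname CandidateEvents-class
#' @aliases eventTable nEvents passedEvents pulseIndices eventSeries
setMethod("eventTable", "CandidateEvents", function(x) x@table)

#' @rdname CandidateEvents-class
setMethod("nEvents", "CandidateEvents", function(x) nrow(x@table))

#' @rdname CandidateEvents-class
setMethod("passedEvents", "CandidateEvents", function(x) {
  keep <- which(x@table$passed)
  tab <- x@table[keep, , drop = FALSE]
  rownames(tab) <- NULL
  initialize(x, table = tab, pulseIndices = x@pulseIndices[keep])
})

#' @rdname CandidateEvents-class
setMethod("pulseIndices", "CandidateEvents", function(x) x@pulseIndices)

#' @rdname CandidateEvents-class
setMethod("eventSeries", "CandidateEvents", function(x) x@series)

#' @rdname CandidateEvents-class
setMethod("length", "CandidateEvents", function(x) nrow(x@table))

setMethod("show", "CandidateEvents", function(object) {
  cat(sprintf("CandidateEvents (%s branch): %d segment%s, %d passed\n",
              object@kind, nrow(object@table),
              if (nrow(object@table) == 1) "" else "s",
              sum(object@table$passed)))
  invisible(NULL)
})

#' Export candidate events to CSV
#'
#' Writes `kind,t_start_ms,t_end_ms,n_pulses,passed` plus one column per
#' criterion flag.
#'
#' @param events a [CandidateEvents-class].
#' @param path output CSV path.
#' @export
writeCandidates <- function(events, path) {
  tab <- events@table
  flag_cols <- setdiff(names(tab), c("event_id", "t_start_ms", "t_end_ms",
                                     "n_pulses", "passed"))
  out <- cbind(data.frame(kind = rep(if (events@kind == "click") "clicktrain"
                                     else "vessel", nrow(tab))),
               tab[, c("t_start_ms", "t_end_ms", "n_pulses", "passed"),
                   drop = FALSE],
               tab[, flag_cols, drop = FALSE])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
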