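#' Confusion counts for a binary (possibly merged-class) evaluation
#'
#' Reduces multi-class predictions to a binary confusion matrix against a
#' set of positive classes. For the click branch, regular clicks and buzzes
#' are combined into the single positive category "click train" (the
#' default); for the vessel branch the positive set is `vessel`. A pair
#' counts TP iff both prediction and truth are in the positive set, TN iff
#' neither is, FP iff only the prediction is, FN iff only the truth is —
#' so a buzz predicted as a regular click is still a true positive for the
#' click-train category.
#'
#' @param predicted,truth equal-length label vectors.
#' @param positiveClasses non-empty character set of positive labels.
#' @return named list with class `"ConfusionCounts"`: `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusionCounts(c("buzz", "noise"), c("regular_click", "noise"),
#'                 c("regular_click", "buzz"))
#' @export
confusionCounts <- function(predicted, truth,
                            positiveClasses = c("regular_click", "buzz")) {
  if (length(predicted) != length(truth))
    .schema_error("predicted and truth must have equal length")
  if (length(positiveClasses) == 0)
    .schema_error("positiveClasses must be non-empty")
  p <- as.character(predicted) %in% positiveClasses
  t <- as.character(truth) %in% positiveClasses
  structure(list(tp = sum(p & t), tn = sum(!p & !t),
                 fp = sum(p & !t), fn = sum(!p & t)),
            class = "ConfusionCounts")
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 p r / (p + r)`. When both precision and recall are
#' zero the harmonic mean is undefined and `NA` is returned as an explicit
#' undefined marker.
#'
#' @param precision,recall proportions in \[0, 1\].
#' @return proportion in \[0, 1\], or `NA` when undefined.
#' @examples
#' f1FromPrecisionRecall(0.94, 0.96)   # ~0.95
#' f1FromPrecisionRecall(1.00, 0.15)   # ~0.26
#' @export
f1FromPrecisionRecall <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`, F1 (harmonic mean of precision and recall) and
#' false positive rate `FP/(TN+FP)`. Any metric whose denominator is zero
#' is reported as `NA` — an explicit undefined marker, never a silent 0;
#' with the small event sets typical of field evaluations, degenerate
#' denominators are a realistic outcome, not an error. All-zero counts are
#' an error.
#'
#' @param cc a [confusionCounts()] result, or any list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @return named list with class `"MetricsReport"`: `accuracy`, `precision`,
#'   `recall`, `f1`, `fpr` as proportions in \[0, 1\] (`NA` = undefined).
#' @export
metricsReport <- function(cc) {
  counts <- c(cc$tp, cc$tn, cc$fp, cc$fn)
  if (any(counts < 0) || any(counts %% 1 != 0))
    .schema_error("confusion counts must be non-negative integers")
  if (sum(counts) == 0) .schema_error("all-zero confusion counts")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- frac(cc$tp, cc$tp + cc$fp)
  recall <- frac(cc$tp, cc$tp + cc$fn)
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
        else f1FromPrecisionRecall(precision, recall)
  structure(list(accuracy = frac(cc$tp + cc$tn, sum(counts)),
                 precision = precision, recall = recall, f1 = f1,
                 fpr = frac(cc$fp, cc$tn + cc$fp)),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat("MetricsReport (NA = undefined denominator)\n")
  for (m in names(x)) {
    v <- x[[m]]
    cat(sprintf("  %-9s %s\n", m,
                if (is.na(v)) "undefined" else sprintf("%.4f (%d%%)", v, percentHalfUp(v))))
  }
  invisible(x)
}

#' Match detected events to ground-truth annotations
#'
#' Greedy earliest-first one-to-one matching of detection spans to
#' annotation spans: detections are visited in time order and each takes the
#' earliest still-unmatched annotation whose span overlaps its own (closed
#' intervals, so sharing a single 0.5 ms slot counts; a minimum overlap
#' fraction of the annotation span can be required instead). Each annotation
#' is matched at most once; a second detection overlapping an already-taken
#' annotation stays unmatched (a false positive).
#'
#' @param detections data.frame with `t_start_ms`, `t_end_ms` (e.g.
#'   `eventTable(passedEvents(x))`), or a [CandidateEvents-class] whose
#'   passed events are used.
#' @param annotations data.frame with `t_start_ms`, `t_end_ms` (and
#'   optionally `label`).
#' @param minOverlapFraction required overlap as a fraction of the
#'   annotation span; default 0 = any overlap.
#' @return list: `pairs` (data.frame of matched `detection`/`annotation` row
#'   indices), `detectionMatched`, `annotationMatched` (logical vectors).
#' @export
matchEvents <- function(detections, annotations, minOverlapFraction = 0) {
  if (is(detections, "CandidateEvents"))
    detections <- eventTable(passedEvents(detections))
  d_ord <- order(detections$t_start_ms, detections$t_end_ms)
  a_ord <- order(annotations$t_start_ms, annotations$t_end_ms)
  a_taken <- logical(nrow(annotations))
  d_match <- rep(NA_integer_, nrow(detections))
  for (di in d_ord) {
    ds <- detections$t_start_ms[di]; de <- detections$t_end_ms[di]
    for (ai in a_ord) {
      if (a_taken[ai]) next
      as <- annotations$t_start_ms[ai]; ae <- annotations$t_end_ms[ai]
      ov <- min(de, ae) - max(ds, as)
      if (ov < -1e-9) next
      span <- max(ae - as, .TIME_STEP_MS)
      if (ov / span >= minOverlapFraction - 1e-12) {
        a_taken[ai] <- TRUE
        d_match[di] <- ai
        break
      }
    }
  }
  pairs <- data.frame(detection = which(!is.na(d_match)),
                      annotation = d_match[!is.na(d_match)])
  list(pairs = pairs, detectionMatched = !is.na(d_match),
       annotationMatched = a_taken)
}

.filter_evaluation <- function(nManual, nDetected, nTrueDetected) {
  structure(list(n_manual = nManual, n_detected = nDetected,
                 n_true_detected = nTrueDetected,
                 detection_rate = if (nManual == 0) NA_real_
                                  else nTrueDetected / nManual,
                 fp_proportion = if (nDetected == 0) NA_real_
                                 else (nDetected - nTrueDetected) / nDetected),
            class = "FilterEvaluation")
}

#' Detection rate and false-positive proportion of a rule-based filter
#'
#' The filter-level evaluation compares the events the filter emitted with
#' the manually confirmed (or simulated) target events: the detection rate
#' is the proportion of annotated events recovered by the filter, and the FP
#' proportion is the share of the filter's detections that match no
#' annotation. `filterEvaluation` matches spans with [matchEvents()];
#' `filterEvaluationCounts` computes the same quantities directly from the
#' three counts (useful when only the counts of a published evaluation are
#' available). Undefined rates (zero manual events, zero detections) are
#' reported as `NA`. Full precision is retained; `print` renders half-up
#' integer percentages.
#'
#' @param detections,annotations,minOverlapFraction as in [matchEvents()].
#' @param nManual number of manually annotated target events.
#' @param nDetected number of events emitted by the filter.
#' @param nTrueDetected detected events matched to an annotation.
#' @return named list with class `"FilterEvaluation"`: `n_manual`,
#'   `n_detected`, `n_true_detected`, `detection_rate`, `fp_proportion`.
#' @examples
#' filterEvaluationCounts(nManual = 532, nDetected = 2695, nTrueDetected = 500)
#' @export
filterEvaluation <- function(detections, annotations, minOverlapFraction = 0) {
  if (is(detections, "CandidateEvents"))
    detections <- eventTable(passedEvents(detections))
  m <- matchEvents(detections, annotations, minOverlapFraction)
  .filter_evaluation(nrow(annotations), nrow(detections), nrow(m$pairs))
}

#' @rdname filterEvaluation
#' @export
filterEvaluationCounts <- function(nManual, nDetected, nTrueDetected) {
  stopifnot(nManual >= 0, nDetected >= 0, nTrueDetected >= 0,
            nTrueDetected <= nDetected)
  .filter_evaluation(nManual, nDetected, nTrueDetected)
}

#' @export
print.FilterEvaluation <- function(x, ...) {
  cat(sprintf("FilterEvaluation: %d manual, %d detected, %d true detections\n",
              x$n_manual, x$n_detected, x$n_true_detected))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%d%%", percentHalfUp(v))
  cat(sprintf("  detection rate: %s   FP proportion: %s\n",
              fmt(x$detection_rate), fmt(x$fp_proportion)))
  invisible(x)
}
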