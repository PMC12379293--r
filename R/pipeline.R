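#' Run the rule-based detection stage end to end
#'
#' Applies both branches of the rule-based filter to a pulse series and
#' writes the candidate tables (`click_candidates.csv`,
#' `vessel_candidates.csv`) plus a summary of segment counts, passed
#' candidates and per-criterion failure counts.
#'
#' @param pulses a [PulseSeries-class] or a pulse CSV path.
#' @param outDir output directory (created if needed); NULL to skip writing.
#' @param clickRules,vesselRules rule tables (defaults per
#'   [clickTrainCriteria()] / [vesselCriteria()]).
#' @param splrMode see [evaluateClickTrainCriteria()].
#' @return invisibly, a list with the two [CandidateEvents-class] objects
#'   (`click`, `vessel`) and a `summary` list of counts.
#' @seealso [runFull()]
#' @export
runDetect <- function(pulses, outDir = NULL,
                      clickRules = clickTrainCriteria(),
                      vesselRules = vesselCriteria(),
                      splrMode = "mean") {
  series <- if (is.character(pulses)) readPulses(pulses) else pulses
  stopifnot(is(series, "PulseSeries"))
  click <- detectClickTrains(series, clickRules, splrMode = splrMode)
  vessel <- detectVesselEvents(series, vesselRules)
  fail_counts <- function(ev) {
    tab <- eventTable(ev)
    flags <- setdiff(names(tab), c("event_id", "t_start_ms", "t_end_ms",
                                   "n_pulses", "passed"))
    vapply(flags, function(f) sum(!tab[[f]]), integer(1))
  }
  summary <- list(n_pulses_in = nPulses(series),
                  click_segments = nEvents(click),
                  click_passed = nEvents(passedEvents(click)),
                  click_failures = fail_counts(click),
                  vessel_segments = nEvents(vessel),
                  vessel_passed = nEvents(passedEvents(vessel)),
                  vessel_failures = fail_counts(vessel))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCandidates(click, file.path(outDir, "click_candidates.csv"))
    writeCandidates(vessel, file.path(outDir, "vessel_candidates.csv"))
  }
  invisible(list(click = click, vessel = vessel, summary = summary))
}

## Assign a branch label to each passed candidate by greedy matching against
## the ground-truth annotations; unmatched candidates get the noise label.
.label_candidates <- function(events, annotations, branch) {
  target <- if (branch == "click") c("regular_click", "buzz", "click_train")
            else "vessel"
  ann <- annotations[annotations$label %in% target, , drop = FALSE]
  tab <- eventTable(events)
  m <- matchEvents(tab, ann)
  lab <- rep(if (branch == "click") "noise" else "non_vessel", nrow(tab))
  if (nrow(m$pairs) > 0) {
    matched_lab <- ann$label[m$pairs$annotation]
    matched_lab[matched_lab == "click_train"] <- "regular_click"
    lab[m$pairs$detection] <- matched_lab
  }
  lab
}

#' Run the full detect-featurize-classify-evaluate pipeline
#'
#' Mirrors the field workflow: rule-based filtering of the raw pulse stream,
#' feature extraction for every passed candidate, candidate labeling against
#' ground-truth annotations, a stratified 70/30 train/validation split,
#' random-forest training per branch, and evaluation — filter-level
#' detection rate / FP proportion against the annotations plus the
#' five classification metrics on the validation split (regular clicks and
#' buzzes merged into the positive click-train category; vessel the positive
#' vessel-branch class). A branch whose candidates cannot support training
#' (fewer than two classes, or too few rows) is skipped with a warning.
#'
#' @param pulses a [PulseSeries-class] or pulse CSV path.
#' @param annotations annotation data.frame or CSV path.
#' @param seed integer seed for the split and forest training.
#' @param trainFraction training proportion of the labeled candidates.
#' @param hp an [rfHyperparams()] list (its seed is overridden by `seed`).
#' @param clickRules,vesselRules rule tables.
#' @param outPath optional path for the JSON evaluation report.
#' @return list with one entry per branch: `filter` (a
#'   [filterEvaluation()]), `metrics` (a [metricsReport()] or NULL),
#'   `counts` (rows per stage), `model` (the trained model or NULL).
#' @export
runFull <- function(pulses, annotations, seed = 1, trainFraction = 0.7,
                    hp = rfHyperparams(),
                    clickRules = clickTrainCriteria(),
                    vesselRules = vesselCriteria(),
                    outPath = NULL) {
  if (is.character(annotations)) annotations <- readAnnotations(annotations)
  det <- runDetect(pulses, outDir = NULL, clickRules = clickRules,
                   vesselRules = vesselRules)
  hp$seed <- seed
  report <- list()
  for (branch in c("click", "vessel")) {
    events <- passedEvents(det[[branch]])
    target <- if (branch == "click") c("regular_click", "buzz", "click_train")
              else "vessel"
    ann <- annotations[annotations$label %in% target, , drop = FALSE]
    filt <- filterEvaluation(eventTable(events), ann)
    metrics <- NULL
    model <- NULL
    labels <- .label_candidates(events, annotations, branch)
    if (length(unique(labels)) >= 2 && nEvents(events) >= 10) {
      feats <- eventFeatures(events, branch)
      split <- splitTrainValidation(labels, trainFraction, seed = seed)
      model <- trainEventModel(feats[split$train, , drop = FALSE],
                               labels[split$train], branch, hp)
      pred <- predict(model, feats[split$valid, , drop = FALSE])
      positive <- if (branch == "click") c("regular_click", "buzz") else "vessel"
      metrics <- metricsReport(confusionCounts(pred, labels[split$valid],
                                               positive))
    } else {
      warning(sprintf("%s branch: not enough labeled candidates to train; skipped",
                      branch))
    }
    report[[branch]] <- list(
      filter = filt, metrics = metrics, model = model,
      counts = list(candidates = nEvents(det[[branch]]),
                    passed = nEvents(events),
                    labeled = length(labels)))
  }
  if (!is.null(outPath)) {
    serializable <- lapply(report, function(b) {
      list(filter = unclass(b$filter),
           metrics = if (is.null(b$metrics)) NULL else unclass(b$metrics),
           counts = b$counts)
    })
    jsonlite::write_json(serializable, outPath, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  }
  report
}
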