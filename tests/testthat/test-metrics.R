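test_that("confusion counts merge regular clicks and buzzes into click trains", {
  cc <- confusionCounts(c("buzz", "noise"), c("buzz", "noise"))
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 1L, tn = 1L, fp = 0L, fn = 0L), ignore_attr = TRUE)
  # a regular click predicted as buzz is still a click-train true positive
  cc2 <- confusionCounts("buzz", "regular_click")
  expect_equal(cc2$tp, 1)
  # swapped vessel/noise pair gives one FP and one FN
  cc3 <- confusionCounts(c("vessel", "noise"), c("noise", "vessel"), "vessel")
  expect_equal(c(cc3$fp, cc3$fn, cc3$tp, cc3$tn), c(1, 1, 0, 0))
  expect_error(confusionCounts("buzz", c("buzz", "noise")), "equal length",
               class = "ptSchemaError")
})

test_that("counts are conserved over random label vectors", {
  set.seed(2)
  vocab <- c("regular_click", "buzz", "noise")
  for (k in 1:50) {
    n <- sample(1:40, 1)
    cc <- confusionCounts(sample(vocab, n, TRUE), sample(vocab, n, TRUE))
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, n)
  }
})

test_that("the five classification metrics follow their defining equations", {
  perfect <- metricsReport(list(tp = 50, tn = 50, fp = 0, fn = 0))
  expect_equal(unlist(unclass(perfect)),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, fpr = 0))
  m <- metricsReport(list(tp = 3, tn = 5, fp = 1, fn = 1))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$fpr, 1 / 6)
  expect_error(metricsReport(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               "all-zero", class = "ptSchemaError")
})

test_that("undefined denominators surface as explicit markers, never zero", {
  m <- metricsReport(list(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_true(is.na(m$precision))   # no predicted positives
  expect_true(is.na(m$recall))      # no actual positives
  expect_true(is.na(m$f1))
  expect_equal(m$accuracy, 1)
  m2 <- metricsReport(list(tp = 5, tn = 0, fp = 0, fn = 0))
  expect_true(is.na(m2$fpr))        # no actual negatives
  expect_true(is.na(f1FromPrecisionRecall(0, 0)))
})

test_that("F1 is the harmonic mean with its identity and bound properties", {
  for (x in c(0.15, 0.5, 0.87, 1)) {
    expect_equal(f1FromPrecisionRecall(x, x), x)
  }
  set.seed(6)
  for (k in 1:100) {
    p <- runif(1); r <- runif(1)
    f1 <- f1FromPrecisionRecall(p, r)
    expect_lte(f1, max(p, r) + 1e-12)
    expect_gte(f1, min(p, r) - 1e-12)
  }
})

test_that("metric identities hold on random confusion tables", {
  set.seed(8)
  for (k in 1:100) {
    cc <- list(tp = sample(0:30, 1), tn = sample(0:30, 1),
               fp = sample(0:30, 1), fn = sample(0:30, 1))
    if (sum(unlist(cc)) == 0) next
    m <- metricsReport(cc)
    if (!is.na(m$fpr)) {
      specificity <- cc$tn / (cc$tn + cc$fp)
      expect_equal(m$fpr + specificity, 1)
    }
    if (!is.na(m$precision) && !is.na(m$recall) && !is.na(m$f1)) {
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    }
  }
})

test_that("greedy event matching is one-to-one and earliest-first", {
  ann <- data.frame(t_start_ms = c(0, 200), t_end_ms = c(100, 300))
  # identical spans all match
  m <- matchEvents(ann, ann)
  expect_equal(nrow(m$pairs), 2)
  # disjoint spans never match
  m2 <- matchEvents(data.frame(t_start_ms = 0, t_end_ms = 100),
                    data.frame(t_start_ms = 200, t_end_ms = 300))
  expect_equal(nrow(m2$pairs), 0)
  # two detections over one annotation: exactly one matches, one is an FP
  det <- data.frame(t_start_ms = c(0, 50), t_end_ms = c(40, 90))
  ann1 <- data.frame(t_start_ms = 0, t_end_ms = 100)
  m3 <- matchEvents(det, ann1)
  expect_equal(nrow(m3$pairs), 1)
  expect_equal(m3$detectionMatched, c(TRUE, FALSE))
  # never more pairs than the smaller list
  set.seed(13)
  for (k in 1:30) {
    nd <- sample(0:8, 1); na <- sample(0:8, 1)
    d <- data.frame(t_start_ms = sort(runif(nd, 0, 1000)))
    d$t_end_ms <- d$t_start_ms + runif(nd, 1, 200)
    a <- data.frame(t_start_ms = sort(runif(na, 0, 1000)))
    a$t_end_ms <- a$t_start_ms + runif(na, 1, 200)
    expect_lte(nrow(matchEvents(d, a)$pairs), min(nd, na))
  }
})

test_that("filter evaluation reproduces its defining ratios", {
  fe <- filterEvaluationCounts(nManual = 10, nDetected = 25, nTrueDetected = 9)
  expect_equal(fe$detection_rate, 0.9)
  expect_equal(fe$fp_proportion, 16 / 25)
  # identical detection and annotation lists give 100% / 0%
  ann <- data.frame(t_start_ms = c(0, 500), t_end_ms = c(100, 900),
                    label = c("buzz", "buzz"))
  fe2 <- filterEvaluation(ann[, 1:2], ann)
  expect_equal(fe2$detection_rate, 1)
  expect_equal(fe2$fp_proportion, 0)
  # undefined markers for empty denominators
  none <- data.frame(t_start_ms = numeric(), t_end_ms = numeric())
  expect_true(is.na(filterEvaluation(ann[, 1:2], none)$detection_rate))
  expect_true(is.na(filterEvaluation(none, ann)$fp_proportion))
})

test_that("integer-percent reporting rounds half up", {
  expect_equal(percentHalfUp(0.945), 95L)
  expect_equal(percentHalfUp(0.425), 43L)
  expect_equal(percentHalfUp(0.4199), 42L)
  expect_true(is.na(percentHalfUp(NA_real_)))
})
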