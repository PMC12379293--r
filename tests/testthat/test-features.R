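test_that("buzz detection finds runs of five pulses at <= 10 ms spacing", {
  expect_equal(buzzCheck(seq(0, 32, by = 8)), 1L)     # 5 pulses at 8 ms
  expect_equal(buzzCheck(seq(0, 250, by = 50)), 0L)   # no short interval
  # run at the end of a longer event still counts
  expect_equal(buzzCheck(cumsum(c(0, 8, 8, 40, 8, 8, 8, 8))), 1L)
  # 4 short intervals split by one long gap is not a buzz
  expect_equal(buzzCheck(cumsum(c(0, 8, 8, 40, 8, 8))), 0L)
  # exhaustive check against a brute-force window scan on random patterns
  set.seed(12)
  for (k in 1:100) {
    t <- cumsum(c(0, sample(c(4, 8, 10, 10.5, 12, 30), sample(4:12, 1),
                            replace = TRUE)))
    brute <- 0L
    for (i in seq_along(t)) for (j in seq_along(t)) {
      if (j - i + 1 >= 5 && all(diff(t[i:j]) <= 10 + 1e-9)) brute <- 1L
    }
    expect_identical(buzzCheck(t), brute)
  }
})

test_that("buzz flag is monotone under extension at buzz spacing", {
  set.seed(4)
  for (k in 1:30) {
    t <- cumsum(c(0, runif(sample(4:20, 1), 3, 30)))
    if (buzzCheck(t) == 1) {
      longer <- c(t, max(t) + cumsum(runif(5, 2, 10)))
      expect_equal(buzzCheck(longer), 1L)
    }
  }
})

test_that("feature statistics match hand-computed values", {
  # constant spacing degenerates all interval spread to zero
  s <- makeSeries(seq(0, 50, by = 10), start = "2023-01-01 00:00:00")
  ev <- detectClickTrains(s)
  f <- eventFeatures(ev)
  expect_equal(f$Np, 6)
  expect_equal(f$Duration, 50)
  expect_equal(f$SdPi, 0)
  expect_equal(c(f$MaxPi, f$MinPi, f$AvPi), c(10, 10, 10))
  # per-pulse SPLR (1.0, 0.8, 0.6, ...) -> hand-computed sample SD
  a <- c(20, 16, 12, 20, 16, 12)
  s2 <- makeSeries(seq(0, 50, by = 10), a = a, b = 20,
                   start = "2023-01-01 00:00:00")
  f2 <- eventFeatures(detectClickTrains(s2))
  expect_equal(f2$MaxSPLR, 1.0)
  expect_equal(f2$AvSPLR, 0.8)
  expect_equal(f2$SdSPLR, sqrt(sum((a / 20 - 0.8)^2) / 5))
  # signed Maxtd keeps the sign convention
  s3 <- makeSeries(seq(0, 50, by = 10), td = c(-30, -20, -25, -30, -20, -25),
                   start = "2023-01-01 00:00:00")
  expect_equal(eventFeatures(detectClickTrains(s3))$Maxtd, -20)
})

test_that("Start/End are epoch minutes truncated to the recorder's precision", {
  # 90 s into a recording starting 2023-01-01T00:00:00Z falls in minute 1:
  # floor((1672531200 + 90) / 60) = 27875521
  s <- makeSeries(c(90000, 90010, 90020, 90030, 90040, 90052),
                  start = "2023-01-01 00:00:00")
  f <- eventFeatures(detectClickTrains(s))
  expect_equal(f$Start, 27875521)
  expect_equal(f$End, 27875521)
  expect_true(f$Start <= f$End)
  # a missing start datetime is a configuration error
  s_bare <- makeSeries(seq(0, 50, by = 10))
  expect_error(eventFeatures(detectClickTrains(s_bare)), "startDatetime",
               class = "ptSchemaError")
})

test_that("feature layout is fixed per branch: 18 click / 17 vessel columns", {
  expect_length(featureNames("click"), 18)
  expect_length(featureNames("vessel"), 17)
  expect_false("BuzzCheck" %in% featureNames("vessel"))
  expect_equal(featureNames("click")[18], "BuzzCheck")
})

test_that("features survive a CSV round-trip and agree with filter flags", {
  sc <- simulateSoundscape(simConfig(durationS = 90, seed = 9,
    clickTrains = clickTrainSim(nEvents = 2), buzzes = buzzSim(nEvents = 1),
    vessels = vesselSim(nEvents = 0), shrimp = shrimpSim(rateHz = 1)))
  ev <- passedEvents(detectClickTrains(sc$series))
  f <- eventFeatures(ev)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatures(f, path)
  back <- utils::read.csv(path)
  num <- featureNames("click")
  expect_equal(as.matrix(back[num]), as.matrix(f[num]), tolerance = 1e-9)
  # passed candidates are internally consistent with the rule flags
  expect_true(all(f$SdPi / f$AvPi <= 0.4))
  expect_true(all(f$AvSPLR >= 0.6))
  expect_true(all(f$Duration >= 12))
  expect_true(all(f$Sdtd < 25))
})

test_that("single-pulse events cannot be featurized", {
  s <- makeSeries(c(0, 10, 20, 30, 40, 50), start = "2023-01-01 00:00:00")
  ev <- detectClickTrains(s)
  broken <- new("CandidateEvents", kind = "click", series = eventSeries(ev),
                table = data.frame(event_id = 1L, t_start_ms = 0, t_end_ms = 0,
                                   n_pulses = 1L, passed = TRUE),
                pulseIndices = list(1L))
  expect_error(eventFeatures(broken), "single-pulse", class = "ptValidationError")
})
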