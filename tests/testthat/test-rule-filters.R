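test_that("reflection removal keeps the earlier pulse and is idempotent", {
  # 1.0 ms after 0 is a reflection; 2.5 ms after the last KEPT pulse is real
  s <- makeSeries(c(0, 1, 2.5))
  expect_equal(pulseRecords(removeReflections(s))$t_ms, c(0, 2.5))
  # an interval of exactly 2 ms satisfies the inclusive >= 2 ms rule
  s2 <- makeSeries(c(0, 2, 4))
  expect_equal(pulseRecords(removeReflections(s2))$t_ms, c(0, 2, 4))
  # single pulse kept unchanged
  expect_equal(pulseRecords(removeReflections(makeSeries(0)))$t_ms, 0)
  # idempotence on random boundary-stressing series
  set.seed(31)
  for (k in 1:50) {
    s <- randomBoundarySeries()
    once <- removeReflections(s)
    expect_identical(pulseRecords(removeReflections(once)), pulseRecords(once))
  }
})

test_that("gap segmentation honours branch boundary semantics and partitions", {
  s <- makeSeries(cumsum(c(0, 50, 50, 150, 50)))
  expect_equal(lengths(segmentByGap(s, 100, "exceeds")), c(3L, 2L))
  # intervals of exactly 100 ms stay inside a click-branch segment
  s100 <- makeSeries(seq(0, 400, by = 100))
  expect_equal(lengths(segmentByGap(s100, 100, "exceeds")), 5L)
  # intervals of exactly 500 ms split the vessel branch (bound exclusive)
  s500 <- makeSeries(seq(0, 2000, by = 500))
  expect_equal(lengths(segmentByGap(s500, 500, "at_or_exceeds")), rep(1L, 5))
  # partition property: concatenated segments reproduce the input
  set.seed(7)
  for (k in 1:50) {
    s <- randomBoundarySeries()
    for (b in c("exceeds", "at_or_exceeds")) {
      segs <- segmentByGap(s, if (b == "exceeds") 100 else 500, b)
      expect_identical(unlist(segs), seq_len(nPulses(s)))
    }
  }
})

test_that("the nine click-train criteria evaluate as printed", {
  t <- seq(0, 90, by = 10)  # 10 pulses, constant 10 ms interval
  all_pass <- evaluateClickTrainCriteria(t, rep(20, 10), rep(20, 10), rep(0, 10))
  expect_true(all(all_pass))
  expect_named(all_pass, c("min_interval", "max_interval", "min_pulses",
                           "cv_interval", "splr", "duration", "sd_td",
                           "cv_spl", "median_interval"))
  # five pulses fail only the at-least-six rule
  five <- evaluateClickTrainCriteria(t[1:5], rep(20, 5), rep(20, 5), rep(0, 5))
  expect_false(five[["min_pulses"]])
  expect_true(all(five[setdiff(names(five), "min_pulses")]))
  # SPLR of 0.5 throughout fails only the >= 0.6 rule
  low <- evaluateClickTrainCriteria(t, rep(10, 10), rep(20, 10), rep(0, 10))
  expect_false(low[["splr"]])
  expect_true(all(low[setdiff(names(low), "splr")]))
  # mean mode: per-pulse ratios (0.5, 1.1, ...) can pass on average
  a <- c(10, 22, 22, 22, 22, 22, 22, 22, 22, 22)
  expect_true(evaluateClickTrainCriteria(t, a, rep(20, 10), rep(0, 10))[["splr"]])
  expect_false(evaluateClickTrainCriteria(t, a, rep(20, 10), rep(0, 10),
                                          splrMode = "all_pulses")[["splr"]])
})

test_that("vessel criteria enforce count, duration and interval bounds", {
  crit <- vesselCriteria()
  # 81 pulses at 100 ms spacing: 8 s duration, too short
  ev <- detectVesselEvents(makeSeries(seq(0, by = 100, length.out = 81)), crit)
  expect_equal(nEvents(passedEvents(ev)), 0L)
  expect_false(eventTable(ev)$duration)
  expect_true(eventTable(ev)$min_pulses)
  # 80 pulses at 200 ms spacing: 15.8 s but not more than 80 pulses
  ev2 <- detectVesselEvents(makeSeries(seq(0, by = 200, length.out = 80)), crit)
  expect_equal(nEvents(passedEvents(ev2)), 0L)
  expect_false(eventTable(ev2)$min_pulses)
  expect_true(eventTable(ev2)$duration)
  # 120 pulses, random intervals in [50, 400) ms, span >= 10 s: accepted
  set.seed(3)
  gaps <- round(runif(119, 50, 399) * 2) / 2
  ev3 <- detectVesselEvents(makeSeries(cumsum(c(0, gaps))), crit)
  expect_equal(nEvents(passedEvents(ev3)), 1L)
})

test_that("detected click-train candidates satisfy their contracts", {
  # empty series -> empty list
  empty <- makeSeries(numeric(0), a = numeric(0), b = numeric(0), td = numeric(0))
  expect_equal(nEvents(detectClickTrains(empty)), 0L)
  # a clean simulated train in silence -> exactly one passed event
  sc <- simulateSoundscape(simConfig(durationS = 30, seed = 2,
    clickTrains = clickTrainSim(nEvents = 1), buzzes = buzzSim(nEvents = 0),
    vessels = vesselSim(nEvents = 0), shrimp = shrimpSim(rateHz = 0)))
  ct <- passedEvents(detectClickTrains(sc$series))
  expect_equal(nEvents(ct), 1L)
  expect_equal(eventTable(ct)$t_start_ms, sc$annotations$t_start_ms)
  expect_equal(eventTable(ct)$t_end_ms, sc$annotations$t_end_ms)
  # two trains separated by a long silence -> two passed events
  sc2 <- simulateSoundscape(simConfig(durationS = 60, seed = 3,
    clickTrains = clickTrainSim(nEvents = 2), buzzes = buzzSim(nEvents = 0),
    vessels = vesselSim(nEvents = 0), shrimp = shrimpSim(rateHz = 0),
    eventGapS = c(5, 8)))
  expect_equal(nEvents(passedEvents(detectClickTrains(sc2$series))), 2L)
  # passed equals the conjunction of the flags, events disjoint in time
  tab <- eventTable(detectClickTrains(sc2$series))
  flags <- setdiff(names(tab), c("event_id", "t_start_ms", "t_end_ms",
                                 "n_pulses", "passed"))
  expect_identical(tab$passed, as.logical(Reduce(`&`, tab[flags])))
  if (nrow(tab) > 1)
    expect_true(all(tab$t_start_ms[-1] > tab$t_end_ms[-nrow(tab)]))
})

test_that("filters agree flag-for-flag with the brute-force oracle", {
  set.seed(101)
  for (k in 1:200) {
    s <- randomBoundarySeries()
    expect_oracle_agreement(detectClickTrains(s), bf_click_events(s))
    expect_oracle_agreement(detectVesselEvents(s), bf_vessel_events(s))
  }
})

test_that("tightening any threshold never increases passed candidates", {
  set.seed(17)
  tighter <- list(clickTrainCriteria(minPulses = 8),
                  clickTrainCriteria(maxCvPi = 0.2),
                  clickTrainCriteria(minSplr = 0.9),
                  clickTrainCriteria(minDurationMs = 50),
                  clickTrainCriteria(maxSdTdUs = 10),
                  clickTrainCriteria(maxMedianPiMs = 50))
  for (k in 1:30) {
    s <- randomBoundarySeries(n = 40)
    base <- nEvents(passedEvents(detectClickTrains(s)))
    for (crit in tighter) {
      expect_lte(nEvents(passedEvents(detectClickTrains(s, crit))), base)
    }
  }
})
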