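# Fixtures and brute-force oracles used across the suite.
#
# The oracle functions below re-derive the rule-table statistics from first
# principles (explicit loops, sum/sqrt arithmetic, literal inequalities as
# printed in the rule tables) and share no code with the package internals,
# so they can arbitrate the filter implementation.

makeSeries <- function(t, a = 20, b = 20, td = 0, start = NA, threshold = 139) {
  PulseSeries(data.frame(t_ms = t, spl_a = a, spl_b = b, td_us = td),
              startDatetime = start, thresholdDb = threshold)
}

bf_mean <- function(x) sum(x) / length(x)

bf_sd <- function(x) {
  if (length(x) < 2) return(NA_real_)
  m <- bf_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

bf_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# reflection sweep: keep a pulse iff >= 2 ms after the last kept one
bf_keep_indices <- function(t, min_pi = 2) {
  kept <- 1L
  for (i in seq_along(t)[-1]) {
    if (t[i] - t[kept[length(kept)]] >= min_pi - 1e-9) kept <- c(kept, i)
  }
  kept
}

# contiguous runs: click branch splits where a gap exceeds 100 ms,
# vessel branch where a gap reaches 500 ms
bf_runs <- function(t, limit, inclusive) {
  runs <- list()
  cur <- 1L
  for (i in seq_along(t)[-1]) {
    gap <- t[i] - t[i - 1]
    inside <- if (inclusive) gap <= limit + 1e-9 else gap < limit - 1e-9
    if (inside) cur <- c(cur, i)
    else { runs[[length(runs) + 1]] <- cur; cur <- i }
  }
  runs[[length(runs) + 1]] <- cur
  runs
}

bf_click_flags <- function(t, a, b, td) {
  n <- length(t)
  iv <- t[-1] - t[-n]
  ratio <- a / b
  cv_iv <- if (n >= 3) bf_sd(iv) / bf_mean(iv) else NA_real_
  cv_spl <- 100 * bf_sd(a) / bf_mean(a)
  c(min_interval = n >= 2 && !any(iv < 2 - 1e-9),
    max_interval = n >= 2 && !any(iv > 100 + 1e-9),
    min_pulses = n >= 6,
    cv_interval = !is.na(cv_iv) && cv_iv <= 0.4,
    splr = bf_mean(ratio) >= 0.6,
    duration = n >= 2 && t[n] - t[1] >= 12 - 1e-9,
    sd_td = !is.na(bf_sd(td)) && bf_sd(td) < 25,
    cv_spl = !is.na(cv_spl) && cv_spl <= 100,
    median_interval = n >= 2 && bf_median(iv) < 100)
}

# full click branch: sweep, split, evaluate; segments of >= 2 pulses
bf_click_events <- function(series) {
  rec <- pulseRecords(series)
  kept <- bf_keep_indices(rec$t_ms)
  t <- rec$t_ms[kept]; a <- rec$spl_a[kept]; b <- rec$spl_b[kept]
  td <- rec$td_us[kept]
  out <- list()
  for (run in bf_runs(t, 100, inclusive = TRUE)) {
    if (length(run) < 2) next
    out[[length(out) + 1]] <- list(
      t_start = t[run[1]], t_end = t[run[length(run)]], n = length(run),
      flags = bf_click_flags(t[run], a[run], b[run], td[run]))
  }
  out
}

bf_vessel_events <- function(series) {
  t <- pulseRecords(series)$t_ms
  out <- list()
  for (run in bf_runs(t, 500, inclusive = FALSE)) {
    if (length(run) < 2) next
    tt <- t[run]
    n <- length(run)
    iv <- tt[-1] - tt[-n]
    out[[length(out) + 1]] <- list(
      t_start = tt[1], t_end = tt[n], n = n,
      flags = c(max_interval = !any(iv >= 500 - 1e-9),
                min_pulses = n > 80,
                duration = tt[n] - tt[1] >= 10000 - 1e-9))
  }
  out
}

# compare a CandidateEvents object with the brute-force event list,
# span by span and flag by flag
expect_oracle_agreement <- function(events, oracle) {
  tab <- eventTable(events)
  expect_equal(nrow(tab), length(oracle))
  if (nrow(tab) == 0) return(invisible(TRUE))
  flag_cols <- setdiff(names(tab), c("event_id", "t_start_ms", "t_end_ms",
                                     "n_pulses", "passed"))
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$t_start_ms[i], oracle[[i]]$t_start)
    expect_equal(tab$t_end_ms[i], oracle[[i]]$t_end)
    expect_equal(tab$n_pulses[i], oracle[[i]]$n)
    got <- unlist(tab[i, flag_cols])
    names(got) <- flag_cols
    expect_identical(got[names(oracle[[i]]$flags)], oracle[[i]]$flags,
                     info = sprintf("event %d", i))
  }
  invisible(TRUE)
}

# random pulse series that deliberately stresses the rule boundaries:
# gaps include reflection-range values and the exact 2 / 100 / 500 ms edges
randomBoundarySeries <- function(n = NULL) {
  if (is.null(n)) n <- sample(2:60, 1)
  gap_pool <- c(0.5, 1, 1.5, 2, 2.5, 5, 8, 10, 25, 60, 99.5, 100, 100.5,
                150, 400, 499.5, 500, 600)
  gaps <- sample(gap_pool, n - 1, replace = TRUE)
  t <- cumsum(c(0, gaps))
  a <- round(runif(n, 13, 60), 3)
  ratio <- runif(n, 0.3, 1.4)
  makeSeries(t, a = a, b = a / ratio,
             td = round(runif(n, -150, 150) * 4) / 4)
}
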