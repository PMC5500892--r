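test_that("evoked peak is the windowed extremum of baseline-subtracted current", {
  # event constructed to peak exactly 1.2 ms after the AP at 100 pA:
  # triangular pulse, immune to waveform-shape assumptions
  dt <- 0.05
  t <- seq(0, 100, by = dt)
  cur <- rep(-5, length(t))                       # non-zero holding baseline
  on <- 50.4
  rising <- t >= on & t <= on + 0.8
  falling <- t > on + 0.8 & t <= on + 3
  cur[rising] <- -5 - 100 * (t[rising] - on) / 0.8
  cur[falling] <- -5 - 100 * (1 - (t[falling] - on - 0.8) / 2.2)
  tr <- epsc_trace(cur, dt_ms = dt)
  pk <- detect_evoked_peak(tr, 50)
  expect_equal(pk$amplitude_pA, 100)
  expect_equal(pk$peak_time_ms, 51.2)
  expect_equal(pk$baseline_pA, -5)

  flat <- epsc_trace(rep(0, 2001), dt_ms = dt)
  expect_equal(detect_evoked_peak(flat, 50)$amplitude_pA, 0)
  expect_error(detect_evoked_peak(flat, 99.5), "exceeds")
})

test_that("an event peaking after the 2-ms window is underestimated", {
  tr <- constructed_trace(53, 100, tau_rise = 1.5)   # peaks ~3 ms after AP
  pk <- detect_evoked_peak(tr, 50)
  expect_lt(pk$amplitude_pA, 95)
})

test_that("rise time matches closed forms for ramp, exponential and step", {
  dt <- 0.05
  t <- seq(0, 20, by = dt)
  # linear ramp 0 -> 100 pA over 1 ms: 20-80% interval = 0.6 ms
  ramp <- pmin(pmax((t - 5), 0) / 1, 1) * -100
  tr <- epsc_trace(ramp, dt_ms = dt)
  pk <- detect_evoked_peak(tr, 4.5)
  rise <- measure_rise_time(tr, pk)
  expect_equal(rise$rise_time_ms, 0.6, tolerance = 1e-6)

  # saturating exponential with tau_r = 0.5 ms: rise = ln4 * tau_r
  expo <- ifelse(t < 5, 0, -(1 - exp(-(t - 5) / 0.5)) * 100)
  tre <- epsc_trace(expo, dt_ms = dt)
  pke <- list(peak_index = length(t), amplitude_pA = max(abs(expo)),
              baseline_pA = 0, sign = -1)
  risee <- measure_rise_time(tre, pke)
  expect_equal(risee$rise_time_ms, 0.5 * log(4), tolerance = dt)

  # instantaneous step: rise bounded by one sampling interval
  step <- ifelse(t < 5, 0, -100)
  trs <- epsc_trace(step, dt_ms = dt)
  pks <- detect_evoked_peak(trs, 4.5)
  rises <- measure_rise_time(trs, pks)
  expect_lte(rises$rise_time_ms, dt)
})

test_that("latency is the 5%-of-peak onset delay with a 0.2-2 ms window", {
  tr <- constructed_trace(50.5, 100)
  pk <- detect_evoked_peak(tr, 50)
  lat <- measure_latency(tr, 50, pk)
  expect_true(lat$measurable)
  expect_equal(lat$latency_ms, 0.5, tolerance = 0.06)
  expect_true(lat$in_window)

  early <- constructed_trace(50.1, 100)
  lat_e <- measure_latency(early, 50, detect_evoked_peak(early, 50))
  expect_false(lat_e$in_window)

  late <- constructed_trace(52.5, 100, tau_rise = 0.2)
  pk_l <- detect_evoked_peak(late, 50, window_ms = 5)
  lat_l <- measure_latency(late, 50, pk_l)
  expect_false(lat_l$in_window)
})

test_that("noiseless mono-exponential decays are recovered over a tau grid", {
  dt <- 0.05
  t <- seq(0, 150, by = dt)
  for (tau in c(1, 2, 5, 10.1, 11.3, 20, 50, 100)) {
    cur <- ifelse(t < 20, 0, -100 * exp(-(t - 20) / tau))
    tr <- epsc_trace(cur, dt_ms = dt)
    pk <- list(peak_index = which(t == 20), amplitude_pA = 100,
               baseline_pA = 0, sign = -1)
    fit <- fit_decay_tau(tr, pk)
    expect_lt(abs(fit$tau_ms - tau) / tau, 1e-3)
    expect_true(fit$converged)
  }
})

test_that("decay fits stay within 5% of truth under recording noise", {
  errs <- sapply(1:40, function(seed) {
    tr <- constructed_trace(20.5, 100, noise_sd = 2, seed = seed,
                            duration_ms = 120)
    pk <- detect_evoked_peak(tr, 20)
    fit <- fit_decay_tau(tr, pk)
    abs(fit$tau_ms - 11.3) / 11.3
  })
  expect_lt(mean(errs), 0.05)
  expect_gt(mean(errs <= 0.05), 0.85)
})

test_that("each acceptance filter is individually necessary", {
  # violates only the amplitude rule
  a <- accept_event(amplitude_pA = 15, rise_time_ms = 1,
                    next_event_gap_ms = Inf)
  expect_false(a$accepted)
  expect_equal(a$rejection_reasons, "amplitude")
  # violates only the complete-decay rule
  b <- accept_event(amplitude_pA = 50, rise_time_ms = 1,
                    next_event_gap_ms = 30)
  expect_equal(b$rejection_reasons, "incomplete_decay")
  # violates only the rise-time rule (too fast, then too slow)
  c1 <- accept_event(amplitude_pA = 50, rise_time_ms = 0.3,
                     next_event_gap_ms = Inf)
  expect_equal(c1$rejection_reasons, "rise_time")
  c2 <- accept_event(amplitude_pA = 50, rise_time_ms = 2.4,
                     next_event_gap_ms = Inf)
  expect_equal(c2$rejection_reasons, "rise_time")
  # all rules satisfied
  ok <- accept_event(amplitude_pA = 25, rise_time_ms = 1,
                     next_event_gap_ms = 50)
  expect_true(ok$accepted)
  expect_length(ok$rejection_reasons, 0)
})

test_that("paired-pulse and AMPA/NMDA ratios follow their definitions", {
  expect_equal(paired_pulse_ratio(100, 146), 146)
  expect_equal(paired_pulse_ratio(80, 80), 100)
  expect_equal(paired_pulse_ratio(80, 0), 0)
  expect_error(paired_pulse_ratio(0, 50), "> 0")

  expect_equal(ampa_nmda_ratio(112, 100), 1.12)
  expect_equal(ampa_nmda_ratio(70, 70), 1)
  expect_equal(ampa_nmda_ratio(nmda_pA = 100, total_pA = 150), 0.5)
  expect_error(ampa_nmda_ratio(50, 0), "> 0")
})

test_that("a 50-Hz pair with designed amplitudes yields the designed PPR", {
  tr <- constructed_trace(c(50.5, 70.5), c(100, 146))
  res <- measure_paired_pulse(tr, 50, 70)
  expect_equal(res$ppr_percent, 146, tolerance = 0.01)
})

test_that("amplitude summaries normalize per-cell means to a reference", {
  s <- amplitude_summary(list(rep(100, 5)), reference_mean_pA = 100)
  expect_equal(unname(s$normalized), 1)

  s2 <- amplitude_summary(list(rep(50, 4), rep(150, 4)),
                          reference_mean_pA = 100)
  expect_equal(unname(s2$normalized), c(0.5, 1.5))
  expect_equal(s2$group_mean, 1)
  expect_equal(sum(s2$counts), 8)
  expect_error(amplitude_summary(list(numeric(0)), 100), "no accepted")
})

test_that("the spontaneous onset detector finds well-separated events", {
  p <- epsc_sim_params(amplitude_cv = 0, noise_sd_pA = 1,
                       ap_times_ms = c(100, 300, 600), latency_ms = 0.5)
  sim <- simulate_epsc_train(p, duration_s = 1, seed = 9)
  onsets <- detect_epsc_onsets(sim$trace, noise_sd_pA = 1)
  expect_length(onsets, 3)
  expect_true(all(abs(onsets - sim$events$onset_ms) < 2))
})

test_that("Mann-Whitney U keeps its nominal false-positive rate", {
  # true type-I error of the tie-corrected normal approximation at
  # n = 15 per group, computed against the exact null distribution of U
  # (continuous data, no ties)
  u_vals <- 0:(15 * 15)
  rejects <- vapply(u_vals, function(u) {
    mu <- 15 * 15 / 2
    sigma <- sqrt(15 * 15 * 31 / 12)
    z <- (u - mu - sign(u - mu) * 0.5) / sigma
    p <- min(2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)), 1)
    p < 0.05
  }, logical(1))
  rate <- sum(stats::dwilcox(u_vals, 15, 15)[rejects])
  expect_lte(rate, 0.055)

  # and a Monte-Carlo sanity check of the wrapper itself
  set.seed(17)
  rejections <- replicate(400, {
    mann_whitney_u(rnorm(15), rnorm(15))$p_value < 0.05
  })
  expect_lte(mean(rejections), 0.08)
})
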