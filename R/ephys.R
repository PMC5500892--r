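#' Current trace container
#'
#' A regularly sampled current recording. Inward synaptic currents are
#' stored with negative sign (whole-cell recordings at negative holding
#' potentials); all amplitudes are reported as positive magnitudes.
#'
#' @param current_pA numeric vector of current samples (pA), finite.
#' @param dt_ms sampling interval in ms (> 0); alternatively give
#'   `time_ms`.
#' @param time_ms optional vector of sample times (must be regular).
#' @param ap_times_ms optional presynaptic action-potential marker times.
#' @return object of class `epsc_trace` with elements `current_pA`,
#'   `dt_ms`, `ap_times_ms`.
#' @export
epsc_trace <- function(current_pA, dt_ms = NULL, time_ms = NULL,
                       ap_times_ms = numeric(0)) {
  if (any(!is.finite(current_pA))) stop("current samples must be finite")
  if (is.null(dt_ms)) {
    if (is.null(time_ms) || length(time_ms) < 2) {
      stop("supply dt_ms or a time vector")
    }
    steps <- diff(time_ms)
    if (diff(range(steps)) > 1e-6 * mean(steps)) {
      stop("time vector is not regularly sampled")
    }
    dt_ms <- mean(steps)
  }
  if (dt_ms <= 0) stop("sampling interval must be > 0")
  structure(list(current_pA = as.numeric(current_pA), dt_ms = dt_ms,
                 ap_times_ms = ap_times_ms), class = "epsc_trace")
}

#' @export
print.epsc_trace <- function(x, ...) {
  cat(sprintf("epsc_trace: %d samples, %.3f ms interval (%.1f kHz), %.1f ms\n",
              length(x$current_pA), x$dt_ms, 1 / x$dt_ms,
              length(x$current_pA) * x$dt_ms))
  invisible(x)
}

trace_times <- function(trace) (seq_along(trace$current_pA) - 1) * trace$dt_ms

sample_at <- function(trace, t_ms) {
  idx <- round(t_ms / trace$dt_ms) + 1
  idx[idx < 1 | idx > length(trace$current_pA)] <- NA_integer_
  idx
}

#' Evoked EPSC peak within a fixed window after the action potential
#'
#' The peak current is the extremum of the baseline-subtracted current in
#' the `(ap_time, ap_time + window_ms]` interval following the
#' presynaptic action potential (default 2 ms). Baseline is the mean
#' current over the `baseline_ms` (default 5 ms) preceding the AP.
#' The amplitude is reported as a positive magnitude. Events peaking
#' after the window are, by construction, underestimated.
#'
#' @param trace an [epsc_trace()].
#' @param ap_time_ms action-potential time (ms).
#' @param window_ms search window after the AP.
#' @param baseline_ms baseline window before the AP.
#' @return list with `amplitude_pA` (magnitude), `peak_time_ms`,
#'   `peak_index`, `baseline_pA`, `sign` (+1/-1 direction of the peak).
#' @export
detect_evoked_peak <- function(trace, ap_time_ms, window_ms = 2,
                               baseline_ms = 5) {
  stopifnot(inherits(trace, "epsc_trace"))
  t <- trace_times(trace)
  t_end <- t[length(t)]
  if (ap_time_ms + window_ms > t_end) {
    stop("peak window exceeds the trace")
  }
  base_idx <- which(t >= ap_time_ms - baseline_ms & t < ap_time_ms)
  baseline <- if (length(base_idx) > 0) mean(trace$current_pA[base_idx]) else 0
  win_idx <- which(t > ap_time_ms & t <= ap_time_ms + window_ms)
  seg <- trace$current_pA[win_idx] - baseline
  k <- which.max(abs(seg))
  list(amplitude_pA = abs(seg[k]),
       peak_time_ms = t[win_idx[k]],
       peak_index = win_idx[k],
       baseline_pA = baseline,
       sign = if (seg[k] >= 0) 1 else -1)
}

# Interpolated time of the last crossing of `level` (on the
# baseline-subtracted magnitude) before sample `peak_index`, searching
# backwards; NA when the magnitude never drops below the level.
crossing_before_peak <- function(trace, peak_index, baseline, sign, level) {
  mag <- sign * (trace$current_pA - baseline)
  i <- peak_index
  while (i > 1 && mag[i - 1] >= level) i <- i - 1
  if (i == 1 || mag[i - 1] >= level) return(NA_real_)
  # crossing between samples i-1 and i
  t <- trace_times(trace)
  frac <- (level - mag[i - 1]) / (mag[i] - mag[i - 1])
  t[i - 1] + frac * trace$dt_ms
}

#' 20-80% rise time of an EPSC
#'
#' Time between the 20% and 80% crossings of the peak amplitude on the
#' rising phase, with linear interpolation between samples; the last
#' crossing of each level before the peak is used, which for a monotone
#' rise equals the first crossing.
#'
#' @param trace an [epsc_trace()].
#' @param peak result of [detect_evoked_peak()] (or a list with
#'   `peak_index`, `amplitude_pA`, `baseline_pA`, `sign`).
#' @return list with `rise_time_ms` (NA with `measurable = FALSE` when a
#'   crossing cannot be found), `t20_ms`, `t80_ms`, `measurable`.
#' @export
measure_rise_time <- function(trace, peak) {
  t20 <- crossing_before_peak(trace, peak$peak_index, peak$baseline_pA,
                              peak$sign, 0.2 * peak$amplitude_pA)
  t80 <- crossing_before_peak(trace, peak$peak_index, peak$baseline_pA,
                              peak$sign, 0.8 * peak$amplitude_pA)
  ok <- !is.na(t20) && !is.na(t80) && t80 >= t20
  list(rise_time_ms = if (ok) t80 - t20 else NA_real_,
       t20_ms = t20, t80_ms = t80, measurable = ok)
}

#' Latency between action potential and EPSC onset
#'
#' Onset is defined as the 5%-of-peak crossing of the rising phase;
#' latency is onset time minus AP time. Evoked events with latency
#' outside the 0.2-2 ms window expected for monosynaptic transmission
#' are flagged.
#'
#' @param trace an [epsc_trace()].
#' @param ap_time_ms action-potential time (ms).
#' @param peak result of [detect_evoked_peak()].
#' @param window range of acceptable latencies (ms).
#' @return list with `latency_ms`, `onset_ms`, `in_window`, `measurable`.
#' @export
measure_latency <- function(trace, ap_time_ms, peak, window = c(0.2, 2)) {
  t5 <- crossing_before_peak(trace, peak$peak_index, peak$baseline_pA,
                             peak$sign, 0.05 * peak$amplitude_pA)
  if (is.na(t5)) {
    return(list(latency_ms = NA_real_, onset_ms = NA_real_,
                in_window = NA, measurable = FALSE))
  }
  lat <- t5 - ap_time_ms
  list(latency_ms = lat, onset_ms = t5,
       in_window = lat >= window[1] && lat <= window[2], measurable = TRUE)
}

#' Mono-exponential fit to the EPSC decay phase
#'
#' Least-squares fit of `A * exp(-t / tau)` to the baseline-subtracted
#' current magnitude from the peak over the following `window_ms`
#' (default 40 ms, the guaranteed interference-free segment of accepted
#' events). Start values come from a log-linear regression; the
#' Levenberg-Marquardt refinement makes the fit robust to noise.
#'
#' @param trace an [epsc_trace()].
#' @param peak result of [detect_evoked_peak()].
#' @param window_ms fit window length after the peak.
#' @return list with `tau_ms`, `amplitude_pA`, `rss` (residual sum of
#'   squares), `converged`, `n_samples`.
#' @export
fit_decay_tau <- function(trace, peak, window_ms = 40) {
  t <- trace_times(trace)
  idx <- which(t >= t[peak$peak_index] & t <= t[peak$peak_index] + window_ms)
  if (length(idx) < 10) stop("fewer than 10 samples in the decay window")
  y <- peak$sign * (trace$current_pA[idx] - peak$baseline_pA)
  x <- t[idx] - t[idx[1]]
  pos <- y > 0
  if (sum(pos) < 5) {
    return(list(tau_ms = NA_real_, amplitude_pA = NA_real_, rss = NA_real_,
                converged = FALSE, n_samples = length(idx)))
  }
  init <- lm(log(y[pos]) ~ x[pos])
  tau0 <- -1 / coef(init)[2]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- window_ms / 4
  a0 <- exp(coef(init)[1])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-x / tau),
                      start = list(A = unname(a0), tau = unname(tau0)),
                      lower = c(0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(tau_ms = NA_real_, amplitude_pA = NA_real_,
                rss = sum((y - a0 * exp(-x / tau0))^2), converged = FALSE,
                n_samples = length(idx)))
  }
  cf <- coef(fit)
  list(tau_ms = unname(cf["tau"]), amplitude_pA = unname(cf["A"]),
       rss = sum(residuals(fit)^2), converged = TRUE,
       n_samples = length(idx))
}

#' Event acceptance filters
#'
#' An EPSC enters analysis only when (1) its amplitude exceeds
#' `min_amplitude_pA` (20 pA, more than twofold above the recording
#' noise), (2) its decay is complete, i.e. no further event onset occurs
#' within `clean_ms` (40 ms) so the trace returns to baseline
#' uninterfered, and (3) its 20-80% rise time lies within `rise_range_ms`
#' (0.4-2.0 ms). Every violated rule is named in `rejection_reasons`.
#'
#' @param amplitude_pA peak amplitude magnitude (pA).
#' @param rise_time_ms 20-80% rise time (ms); `NA` counts as violating
#'   the rise-time rule.
#' @param next_event_gap_ms time to the next event onset (ms; `Inf` when
#'   none follows).
#' @param min_amplitude_pA,clean_ms,rise_range_ms filter parameters.
#' @return list with `accepted` and `rejection_reasons` (character
#'   vector among `"amplitude"`, `"incomplete_decay"`, `"rise_time"`).
#' @export
accept_event <- function(amplitude_pA, rise_time_ms, next_event_gap_ms = Inf,
                         min_amplitude_pA = 20, clean_ms = 40,
                         rise_range_ms = c(0.4, 2)) {
  reasons <- character(0)
  if (!is.na(amplitude_pA) && amplitude_pA <= min_amplitude_pA) {
    reasons <- c(reasons, "amplitude")
  }
  if (next_event_gap_ms < clean_ms) {
    reasons <- c(reasons, "incomplete_decay")
  }
  if (is.na(rise_time_ms) || rise_time_ms < rise_range_ms[1] ||
      rise_time_ms > rise_range_ms[2]) {
    reasons <- c(reasons, "rise_time")
  }
  list(accepted = length(reasons) == 0, rejection_reasons = reasons)
}

#' Measure one evoked EPSC end to end
#'
#' Chains [detect_evoked_peak()], [measure_rise_time()],
#' [measure_latency()], [fit_decay_tau()] and [accept_event()] for a
#' single AP marker.
#'
#' @param trace an [epsc_trace()].
#' @param ap_time_ms action-potential time.
#' @param next_event_gap_ms gap to the next event onset (for the
#'   complete-decay filter).
#' @param peak_window_ms,decay_window_ms analysis windows.
#' @return one-row data.frame (an EPSC event record) with `onset_ms`,
#'   `latency_ms`, `amplitude_pA`, `rise_time_ms`, `tau_decay_ms`,
#'   `accepted`, `rejection_reasons` (collapsed `;`-separated),
#'   `latency_in_window`.
#' @export
measure_evoked_epsc <- function(trace, ap_time_ms, next_event_gap_ms = Inf,
                                peak_window_ms = 2, decay_window_ms = 40) {
  peak <- detect_evoked_peak(trace, ap_time_ms, window_ms = peak_window_ms)
  rise <- measure_rise_time(trace, peak)
  lat <- measure_latency(trace, ap_time_ms, peak)
  decay <- fit_decay_tau(trace, peak, window_ms = decay_window_ms)
  acc <- accept_event(peak$amplitude_pA, rise$rise_time_ms, next_event_gap_ms)
  data.frame(onset_ms = lat$onset_ms,
             latency_ms = lat$latency_ms,
             amplitude_pA = peak$amplitude_pA,
             rise_time_ms = rise$rise_time_ms,
             tau_decay_ms = decay$tau_ms,
             accepted = acc$accepted,
             rejection_reasons = paste(acc$rejection_reasons, collapse = ";"),
             latency_in_window = isTRUE(lat$in_window),
             stringsAsFactors = FALSE)
}

#' Paired-pulse measurement from a two-stimulus trace
#'
#' Measures both evoked EPSC amplitudes of a paired-pulse protocol and
#' their ratio. Because the second response rides on the decay of the
#' first, the first event's fitted mono-exponential decay is
#' extrapolated under the second peak and subtracted before the second
#' amplitude is read, the standard correction for overlapping paired
#' responses.
#'
#' @param trace an [epsc_trace()].
#' @param ap1_ms,ap2_ms the two action-potential times (`ap2_ms` >
#'   `ap1_ms`).
#' @param peak_window_ms peak search window after each AP.
#' @return list with `amplitude1_pA`, `amplitude2_pA`, `ppr_percent`,
#'   `tau1_ms`.
#' @export
measure_paired_pulse <- function(trace, ap1_ms, ap2_ms, peak_window_ms = 2) {
  stopifnot(ap2_ms > ap1_ms)
  pk1 <- detect_evoked_peak(trace, ap1_ms, window_ms = peak_window_ms)
  t <- trace_times(trace)
  fit_window <- min(40, ap2_ms - t[pk1$peak_index])
  fit1 <- fit_decay_tau(trace, pk1, window_ms = fit_window)
  win2 <- which(t > ap2_ms & t <= ap2_ms + peak_window_ms)
  carry <- if (fit1$converged) {
    fit1$amplitude_pA * exp(-(t[win2] - t[pk1$peak_index]) / fit1$tau_ms)
  } else rep(0, length(win2))
  seg2 <- pk1$sign * (trace$current_pA[win2] - pk1$baseline_pA) - carry
  k <- which.max(abs(seg2))
  amp2 <- abs(seg2[k])
  list(amplitude1_pA = pk1$amplitude_pA, amplitude2_pA = amp2,
       ppr_percent = paired_pulse_ratio(pk1$amplitude_pA, amp2),
       tau1_ms = fit1$tau_ms)
}

#' Detect spontaneous EPSC onsets by derivative threshold
#'
#' A deliberately simple detector for simulated spontaneous activity:
#' the trace is smoothed by a short running mean, and onsets are marked
#' where the smoothed derivative of the inward current exceeds
#' `threshold_k` times its own noise s.d., with a refractory gap between
#' detections. Only the post-hoc acceptance filters
#' ([accept_event()]) are specified by the analysis conventions;
#' this pre-filter is a configurable stand-in.
#'
#' @param trace an [epsc_trace()].
#' @param noise_sd_pA baseline noise s.d. (pA).
#' @param threshold_k detection threshold in noise s.d. units.
#' @param smooth_n running-mean width (samples).
#' @param refractory_ms minimum separation of detections.
#' @return numeric vector of estimated onset times (ms).
#' @export
detect_epsc_onsets <- function(trace, noise_sd_pA, threshold_k = 3,
                               smooth_n = 5, refractory_ms = 5) {
  cur <- trace$current_pA
  kern <- rep(1 / smooth_n, smooth_n)
  sm <- stats::filter(cur, kern, sides = 2)
  sm[is.na(sm)] <- cur[is.na(sm)]
  d <- c(0, diff(as.numeric(sm)))
  d_sd <- noise_sd_pA * sqrt(2 / smooth_n)   # s.d. of the smoothed difference
  hits <- which(-d > threshold_k * d_sd)
  if (length(hits) == 0) return(numeric(0))
  t <- trace_times(trace)
  onsets <- numeric(0)
  last <- -Inf
  for (h in hits) {
    if (t[h] - last >= refractory_ms) {
      onsets <- c(onsets, t[h])
      last <- t[h]
    }
  }
  onsets
}

#' Paired-pulse ratio
#'
#' Second over first EPSC amplitude for two stimuli in rapid succession,
#' in percent; a readout of presynaptic release probability.
#'
#' @param amp1_pA,amp2_pA amplitudes of the first and second EPSC (pA,
#'   magnitudes); `amp1_pA` must be > 0.
#' @return PPR in percent.
#' @export
paired_pulse_ratio <- function(amp1_pA, amp2_pA) {
  if (any(amp1_pA <= 0)) stop("first amplitude must be > 0")
  100 * amp2_pA / amp1_pA
}

#' AMPA/NMDA current ratio
#'
#' Ratio of the AMPAR-mediated to the NMDAR-mediated EPSC component.
#' When only the total dual-component current and the pharmacologically
#' isolated NMDA component are recorded, the AMPA component is their
#' difference.
#'
#' @param ampa_pA AMPA component amplitude; omit when `total_pA` given.
#' @param nmda_pA NMDA component amplitude (> 0).
#' @param total_pA optional total (AMPA + NMDA) amplitude.
#' @return ratio (unitless).
#' @export
ampa_nmda_ratio <- function(ampa_pA = NULL, nmda_pA, total_pA = NULL) {
  if (any(nmda_pA <= 0)) stop("NMDA amplitude must be > 0")
  if (is.null(ampa_pA)) {
    if (is.null(total_pA)) stop("supply ampa_pA or total_pA")
    ampa_pA <- total_pA - nmda_pA
  }
  ampa_pA / nmda_pA
}

#' Amplitude histograms and normalized per-cell means
#'
#' Bins accepted event amplitudes into fixed-width bins, computes each
#' cell's mean amplitude, normalizes cell means to a reference (e.g. the
#' mean of control cells) and summarizes the group as mean +/- s.e.m.
#'
#' @param amplitudes_per_cell list of numeric vectors (accepted event
#'   amplitudes per cell, pA); at least one non-empty cell required.
#' @param reference_mean_pA reference amplitude for normalization.
#' @param bin_width_pA histogram bin width.
#' @return list with `breaks`, `counts` (pooled histogram), `cell_means`,
#'   `normalized` (cell means / reference), `group_mean`, `group_sem`.
#' @export
amplitude_summary <- function(amplitudes_per_cell, reference_mean_pA,
                              bin_width_pA = 10) {
  amplitudes_per_cell <- lapply(amplitudes_per_cell, function(a) a[!is.na(a)])
  if (all(lengths(amplitudes_per_cell) == 0)) {
    stop("no accepted events to summarize")
  }
  pooled <- unlist(amplitudes_per_cell)
  breaks <- seq(0, ceiling(max(pooled) / bin_width_pA) * bin_width_pA,
                by = bin_width_pA)
  counts <- table(cut(pooled, breaks, include.lowest = TRUE))
  cell_means <- vapply(amplitudes_per_cell,
                       function(a) if (length(a) == 0) NA_real_ else mean(a),
                       numeric(1))
  normalized <- cell_means / reference_mean_pA
  ok <- !is.na(normalized)
  list(breaks = breaks, counts = as.integer(counts),
       cell_means = cell_means, normalized = normalized,
       group_mean = mean(normalized[ok]),
       group_sem = if (sum(ok) > 1) sd(normalized[ok]) / sqrt(sum(ok))
                   else NA_real_)
}
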