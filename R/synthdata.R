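#' Ground-truth model of an AP-MS experiment
#'
#' Holds the latent per-protein molecular abundances underlying a
#' simulated set of AP datasets, plus the ids of the truly specific
#' interactors (bait and co-purifying prey), so recovery by the
#' quantification and specificity stages can be scored.
#'
#' @param abundance numeric matrix (proteins x datasets) of true
#'   abundances, all >= 0; dimnames required.
#' @param datasets optional dataset metadata (see [dataset_meta()]).
#' @param specific character vector of truly specific protein ids.
#' @return object of class `complex_model`.
#' @export
complex_model <- function(abundance, datasets = NULL, specific = character(0)) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
    stop("abundance matrix needs protein row names and dataset column names")
  }
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("true abundances must be finite and >= 0")
  }
  if (!is.null(datasets)) {
    datasets <- validate_dataset_meta(as.data.frame(datasets))
    stopifnot(identical(colnames(abundance), datasets$dataset_id))
  }
  structure(list(abundance = abundance, datasets = datasets,
                 specific = specific), class = "complex_model")
}

#' Noise model for simulated peak volumes
#'
#' Peak volumes are generated as
#' `PV = abundance * response(peptide) * noise(peptide, dataset)`:
#' a log-normal per-peptide response factor (ionization efficiency),
#' log-normal multiplicative measurement noise of coefficient of
#' variation `cv`, optional outlier peptides whose PVs are additionally
#' scrambled by an independent log-normal factor per dataset
#' (emulating false peptide-feature assignments), and missingness that
#' is logistic in log-PV so low-abundance peptides drop out
#' preferentially (a detection limit).
#'
#' @param cv coefficient of variation of measurement noise (>= 0).
#' @param sigma_response sdlog of the per-peptide response factor.
#' @param outlier_prob probability that a peptide is an outlier.
#' @param outlier_sigma sdlog of the per-dataset scrambling factor of
#'   outlier peptides.
#' @param miss_lod PV at which the dropout probability is 50% (0
#'   disables missingness).
#' @param miss_scale logistic scale of dropout in log-PV units.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.2, sigma_response = 0.5, outlier_prob = 0,
                        outlier_sigma = 2, miss_lod = 0, miss_scale = 1) {
  stopifnot(cv >= 0, sigma_response >= 0, outlier_prob >= 0,
            outlier_prob <= 1, outlier_sigma >= 0, miss_lod >= 0,
            miss_scale > 0)
  structure(list(cv = cv, sigma_response = sigma_response,
                 outlier_prob = outlier_prob, outlier_sigma = outlier_sigma,
                 miss_lod = miss_lod, miss_scale = miss_scale),
            class = "noise_model")
}

random_peptide_sequences <- function(n, min_len = 8, max_len = 14) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Simulate a peptide peak-volume matrix with known ground truth
#'
#' Generates `n_peptides_per_protein` peptides per protein and applies
#' the [noise_model()]: `PV(p of protein i, d) = abundance(i, d) *
#' response(p) * noise(p, d)`, then outlier scrambling and log-PV
#' logistic missingness. Proteins with abundance 0 in a dataset are
#' recorded missing there. Seed-deterministic.
#'
#' @param model a [complex_model()].
#' @param noise a [noise_model()].
#' @param n_peptides_per_protein integer >= 1.
#' @param seed integer random seed.
#' @return list with `pv` (a [pv_matrix()]) and `truth` (list with
#'   `abundance`, `response`, `is_outlier`, `missing`, `specific`).
#' @export
simulate_apms <- function(model, noise = noise_model(),
                          n_peptides_per_protein = 6, seed = 1) {
  stopifnot(inherits(model, "complex_model"), inherits(noise, "noise_model"),
            n_peptides_per_protein >= 1)
  if (all(model$abundance == 0)) {
    stop("degenerate model: all true abundances are zero")
  }
  set.seed(as.integer(seed))
  a <- model$abundance
  n_prot <- nrow(a)
  n_pep <- n_prot * n_peptides_per_protein
  protein_of <- rep(rownames(a), each = n_peptides_per_protein)
  pep_ids <- paste0(protein_of, "_p",
                    rep(seq_len(n_peptides_per_protein), times = n_prot))
  sequences <- random_peptide_sequences(n_pep)
  response <- rlnorm(n_pep, 0, noise$sigma_response)
  sdlog <- sqrt(log(1 + noise$cv^2))
  base <- a[protein_of, , drop = FALSE] * response
  eps <- if (sdlog > 0) {
    matrix(rlnorm(n_pep * ncol(a), -sdlog^2 / 2, sdlog), n_pep, ncol(a))
  } else matrix(1, n_pep, ncol(a))
  values <- base * eps
  is_outlier <- runif(n_pep) < noise$outlier_prob
  if (any(is_outlier)) {
    scram <- matrix(rlnorm(sum(is_outlier) * ncol(a), 0, noise$outlier_sigma),
                    sum(is_outlier), ncol(a))
    values[is_outlier, ] <- values[is_outlier, , drop = FALSE] * scram
  }
  missing <- values == 0
  if (noise$miss_lod > 0) {
    p_miss <- plogis((log(noise$miss_lod) - log(pmax(values, .Machine$double.xmin))) /
                       noise$miss_scale)
    missing <- missing | (matrix(runif(length(values)), nrow(values)) < p_miss)
  }
  values[missing] <- NA_real_
  rownames(values) <- pep_ids
  colnames(values) <- colnames(a)
  peptides <- data.frame(peptide_id = pep_ids, protein_id = protein_of,
                         sequence = sequences, is_isoform_specific = TRUE,
                         stringsAsFactors = FALSE)
  pv <- pv_matrix(values, peptides, model$datasets)
  list(pv = pv,
       truth = list(abundance = a,
                    response = setNames(response, pep_ids),
                    is_outlier = setNames(is_outlier, pep_ids),
                    missing = missing,
                    specific = model$specific))
}

#' Standard bait/prey/background AP scenario
#'
#' Builds a [complex_model()] for a specificity experiment: `n_antibodies`
#' target APs, one IgG control and one target-depletion control. The bait
#' and its prey are enriched `enrichment`-fold in the target APs over
#' both controls; background proteins purify bait-independently at
#' log-normally distributed levels identical across all datasets.
#'
#' @param n_prey number of true prey proteins.
#' @param n_background number of nonspecific background proteins.
#' @param n_antibodies number of independent target APs.
#' @param target_abundance bait abundance in target APs (arbitrary units).
#' @param prey_fraction_range range of prey stoichiometric fractions of
#'   the bait (drawn uniformly).
#' @param enrichment fold enrichment of bait/prey over controls.
#' @param background_median,background_sdlog log-normal parameters of
#'   background abundance.
#' @param seed integer seed for the drawn background levels and prey
#'   fractions.
#' @return a [complex_model()] whose `specific` slot names bait + prey.
#' @export
ap_scenario <- function(n_prey = 5, n_background = 200, n_antibodies = 2,
                        target_abundance = 100,
                        prey_fraction_range = c(0.3, 1), enrichment = 50,
                        background_median = 10, background_sdlog = 1,
                        seed = 1) {
  set.seed(as.integer(seed))
  prey_frac <- runif(n_prey, prey_fraction_range[1], prey_fraction_range[2])
  bg <- rlnorm(n_background, log(background_median), background_sdlog)
  proteins <- c("TARGET",
                sprintf("PREY%02d", seq_len(n_prey)),
                sprintf("BG%03d", seq_len(n_background)))
  ap_ids <- paste0("AB", seq_len(n_antibodies))
  ds_ids <- c(ap_ids, "IGG", "DEPL")
  a <- matrix(0, length(proteins), length(ds_ids),
              dimnames = list(proteins, ds_ids))
  spec_levels <- c(target_abundance, prey_frac * target_abundance)
  for (d in ap_ids) a[seq_len(1 + n_prey), d] <- spec_levels
  for (d in c("IGG", "DEPL")) a[seq_len(1 + n_prey), d] <- spec_levels / enrichment
  a[-(seq_len(1 + n_prey)), ] <- bg  # identical in every dataset
  meta <- dataset_meta(
    dataset_id = ds_ids,
    target_proteins = c(rep("TARGET", n_antibodies), "", "TARGET"),
    antibody_id = c(ap_ids, "IgG", "AB1"),
    control_kind = c(rep("none", n_antibodies), "igg", "depletion"))
  complex_model(a, meta, specific = proteins[seq_len(1 + n_prey)])
}

#' Random multi-dataset abundance profiles for recovery tests
#'
#' True abundances drawn log-normally and independently per protein and
#' dataset, giving profiles with realistic dynamic range for testing how
#' well the quantification stage recovers known relative abundances.
#'
#' @param n_proteins,n_datasets dimensions.
#' @param median_abundance median true abundance.
#' @param sdlog_profile spread of abundance across datasets (sdlog).
#' @param seed integer seed.
#' @return a [complex_model()].
#' @export
profile_scenario <- function(n_proteins = 6, n_datasets = 8,
                             median_abundance = 10, sdlog_profile = 1,
                             seed = 1) {
  set.seed(as.integer(seed))
  a <- matrix(rlnorm(n_proteins * n_datasets, log(median_abundance),
                     sdlog_profile),
              n_proteins, n_datasets,
              dimnames = list(sprintf("P%02d", seq_len(n_proteins)),
                              sprintf("AP%02d", seq_len(n_datasets))))
  complex_model(a)
}

#' Simulate a two-step (serial) AP pair
#'
#' The first AP exhaustively captures a fraction `f_true` of each
#' protein's total, the second AP captures the remaining `1 - f_true`
#' (target-depleting serial purification), so the expected sum of the
#' two steps equals the total for every protein. Peptide-level noise is
#' then applied via [simulate_apms()]. A protein with `f_true = 1` is
#' absent (missing) from the second AP.
#'
#' @param totals named vector of total protein amounts (> 0).
#' @param f_true named vector of true first-AP fractions in \[0, 1\]
#'   (recycled names must match `totals`).
#' @param noise a [noise_model()].
#' @param n_replicates number of serial replicate pairs.
#' @param n_peptides_per_protein peptides per protein.
#' @param seed integer seed.
#' @param target_id id of the depleted target (defaults to the first
#'   protein).
#' @return list with `pv` (datasets labeled `first_i` / `second_i` with
#'   matching `serial_position` metadata) and `truth`.
#' @export
simulate_twostep <- function(totals, f_true, noise = noise_model(),
                             n_replicates = 3, n_peptides_per_protein = 6,
                             seed = 1, target_id = names(totals)[1]) {
  if (any(f_true < 0 | f_true > 1)) stop("f_true values must lie in [0, 1]")
  stopifnot(!is.null(names(totals)), length(f_true) == length(totals))
  if (is.null(names(f_true))) names(f_true) <- names(totals)
  f_true <- f_true[names(totals)]
  first_ids <- paste0("first_", seq_len(n_replicates))
  second_ids <- paste0("second_", seq_len(n_replicates))
  a <- cbind(matrix(rep(totals * f_true, n_replicates), ncol = n_replicates,
                    dimnames = list(names(totals), first_ids)),
             matrix(rep(totals * (1 - f_true), n_replicates),
                    ncol = n_replicates,
                    dimnames = list(names(totals), second_ids)))
  meta <- dataset_meta(
    dataset_id = c(first_ids, second_ids),
    target_proteins = target_id,
    replicate_group = rep(paste0("rep", seq_len(n_replicates)), 2),
    serial_position = rep(c("first", "second"), each = n_replicates))
  model <- complex_model(a, meta)
  sim <- simulate_apms(model, noise, n_peptides_per_protein, seed)
  sim$truth$f_true <- f_true
  sim$truth$totals <- totals
  sim
}

#' Parameters for simulated EPSC traces
#'
#' @param amplitude_mean_pA mean event peak amplitude (pA, magnitude).
#' @param amplitude_cv coefficient of variation of event amplitudes
#'   (log-normal; 0 = identical events).
#' @param tau_rise_ms rise time constant (ms, > 0).
#' @param tau_decay_ms decay time constant (ms, > 0).
#' @param rate_hz spontaneous event rate (Hz); ignored when AP markers
#'   are supplied. Rates above 25 Hz (mean interval < 40 ms) make clean,
#'   non-interfered decays unlikely and trigger a warning.
#' @param latency_ms onset delay after each AP marker (evoked events).
#' @param noise_sd_pA Gaussian baseline noise s.d. (pA).
#' @param sampling_khz sampling rate (>= 10 kHz; recordings here assume
#'   20 kHz digitization).
#' @param ap_times_ms optional AP marker times for evoked protocols.
#' @return object of class `epsc_sim_params`.
#' @export
epsc_sim_params <- function(amplitude_mean_pA = 100, amplitude_cv = 0.3,
                            tau_rise_ms = 0.5, tau_decay_ms = 11.3,
                            rate_hz = 1, latency_ms = 0.5, noise_sd_pA = 2,
                            sampling_khz = 20, ap_times_ms = NULL) {
  stopifnot(tau_rise_ms > 0, tau_decay_ms > 0, amplitude_mean_pA >= 0,
            amplitude_cv >= 0, rate_hz >= 0, noise_sd_pA >= 0)
  if (sampling_khz < 10) stop("sampling rate must be >= 10 kHz")
  structure(list(amplitude_mean_pA = amplitude_mean_pA,
                 amplitude_cv = amplitude_cv, tau_rise_ms = tau_rise_ms,
                 tau_decay_ms = tau_decay_ms, rate_hz = rate_hz,
                 latency_ms = latency_ms, noise_sd_pA = noise_sd_pA,
                 sampling_khz = sampling_khz, ap_times_ms = ap_times_ms),
            class = "epsc_sim_params")
}

#' Normalized EPSC waveform
#'
#' Difference-of-exponential kinetics `(1 - exp(-t/tau_rise)) *
#' exp(-t/tau_decay)` scaled to unit peak, so the late decay is
#' mono-exponential with time constant `tau_decay` and the rising phase
#' saturates with `tau_rise`. Zero before onset.
#'
#' @param t_ms time from onset (ms).
#' @param tau_rise_ms,tau_decay_ms time constants (ms).
#' @return waveform values with unit peak amplitude.
#' @export
epsc_waveform <- function(t_ms, tau_rise_ms, tau_decay_ms) {
  w <- ifelse(t_ms < 0, 0,
              (1 - exp(-t_ms / tau_rise_ms)) * exp(-t_ms / tau_decay_ms))
  t_peak <- tau_rise_ms * log(1 + tau_decay_ms / tau_rise_ms)
  peak <- (1 - exp(-t_peak / tau_rise_ms)) * exp(-t_peak / tau_decay_ms)
  w / peak
}

#' Simulate a current trace containing EPSC-like events
#'
#' Inward (negative) synaptic events of [epsc_waveform()] shape are
#' summed onto Gaussian baseline noise. Events occur either at
#' `ap_times_ms + latency_ms` (evoked protocol) or as a Poisson train of
#' the configured rate (spontaneous). Seed-deterministic; the returned
#' ground truth lists each event's onset, peak amplitude and time
#' constants.
#'
#' @param params an [epsc_sim_params()].
#' @param duration_s trace duration in seconds (> 0).
#' @param seed integer seed.
#' @return list with `trace` (an [epsc_trace()]) and `events`
#'   (data.frame: `onset_ms`, `amplitude_pA`, `tau_rise_ms`,
#'   `tau_decay_ms`).
#' @export
simulate_epsc_train <- function(params = epsc_sim_params(), duration_s = 1,
                                seed = 1) {
  stopifnot(inherits(params, "epsc_sim_params"), duration_s > 0)
  set.seed(as.integer(seed))
  dt <- 1 / params$sampling_khz                    # ms per sample
  n <- ceiling(duration_s * 1000 / dt)
  current <- rnorm(n, 0, params$noise_sd_pA)
  t_ms <- (seq_len(n) - 1) * dt
  if (!is.null(params$ap_times_ms)) {
    onsets <- params$ap_times_ms + params$latency_ms
  } else {
    if (params$rate_hz > 25) {
      warning("event rate > 25 Hz: inter-event intervals below 40 ms, ",
              "decays will overlap")
    }
    onsets <- numeric(0)
    t_next <- 0
    while (params$rate_hz > 0) {
      t_next <- t_next + rexp(1, params$rate_hz) * 1000
      if (t_next >= duration_s * 1000) break
      onsets <- c(onsets, t_next)
    }
  }
  n_ev <- length(onsets)
  amps <- if (n_ev == 0) numeric(0) else if (params$amplitude_cv > 0) {
    sdlog <- sqrt(log(1 + params$amplitude_cv^2))
    rlnorm(n_ev, log(params$amplitude_mean_pA) - sdlog^2 / 2, sdlog)
  } else rep(params$amplitude_mean_pA, n_ev)
  for (k in seq_len(n_ev)) {
    idx <- which(t_ms >= onsets[k])
    current[idx] <- current[idx] -
      amps[k] * epsc_waveform(t_ms[idx] - onsets[k],
                              params$tau_rise_ms, params$tau_decay_ms)
  }
  events <- data.frame(onset_ms = onsets, amplitude_pA = amps,
                       tau_rise_ms = rep(params$tau_rise_ms, n_ev),
                       tau_decay_ms = rep(params$tau_decay_ms, n_ev))
  list(trace = epsc_trace(current, dt_ms = dt,
                          ap_times_ms = params$ap_times_ms %||% numeric(0)),
       events = events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
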