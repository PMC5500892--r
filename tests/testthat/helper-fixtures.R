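# Shared builders for small in-code fixtures.

# minimal 3-peptide / 2-dataset PV table written as text, with one
# missing cell (peptide p2 in dataset d2)
write_tiny_pv_fixture <- function(path) {
  writeLines(c(
    "protein_id\tsequence\td1\td2",
    "P1\tACDEFGHIK\t10\t5",
    "P1\tLMNPQRSTV\t20\t",
    "P2\tWYACDEFGH\t7\t7"),
    path)
  path
}

# peptide profile matrix for one protein: n identical copies of `shape`
# plus optional extra rows
profile_block <- function(shape, n, ids = NULL) {
  m <- matrix(rep(shape, each = n), nrow = n)
  rownames(m) <- ids %||% paste0("pep", seq_len(n))
  colnames(m) <- paste0("d", seq_along(shape))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# noiseless constructed EPSC trace: events of given onset/amplitude on a
# flat baseline, difference-of-exponentials kinetics, 20 kHz
constructed_trace <- function(onsets_ms, amps_pA, tau_rise = 0.5,
                              tau_decay = 11.3, duration_ms = 200,
                              dt_ms = 0.05, noise_sd = 0, seed = 1) {
  set.seed(seed)
  t <- seq(0, duration_ms, by = dt_ms)
  cur <- rnorm(length(t), 0, noise_sd)
  for (k in seq_along(onsets_ms)) {
    idx <- which(t >= onsets_ms[k])
    cur[idx] <- cur[idx] - amps_pA[k] *
      epsc_waveform(t[idx] - onsets_ms[k], tau_rise, tau_decay)
  }
  epsc_trace(cur, dt_ms = dt_ms)
}

# mean per-protein Pearson r between estimated profiles and true
# relative abundances for one simulated AP-MS experiment
profile_recovery_r <- function(seed, cv = 0.2, outlier_prob = 0,
                               n_proteins = 6, n_datasets = 8,
                               n_peptides = 6) {
  model <- profile_scenario(n_proteins = n_proteins, n_datasets = n_datasets,
                            seed = seed)
  sim <- simulate_apms(model,
                       noise_model(cv = cv, outlier_prob = outlier_prob,
                                   outlier_sigma = 2),
                       n_peptides_per_protein = n_peptides, seed = seed + 10000)
  est <- protein_profiles(sim$pv)$profiles
  true_rel <- t(apply(model$abundance, 1, function(r) r / max(r)))
  mean(vapply(rownames(est), function(p) {
    stats::cor(est[p, ], true_rel[p, ])
  }, numeric(1)))
}

# run the specificity stage on one simulated bait/prey/background
# experiment; returns called and true specific sets
run_specificity_sim <- function(seed, cv = 0.15, n_prey = 5,
                                n_background = 200) {
  model <- ap_scenario(n_prey = n_prey, n_background = n_background,
                       seed = seed)
  sim <- simulate_apms(model, noise_model(cv = cv),
                       n_peptides_per_protein = 6, seed = seed + 20000)
  prof <- protein_profiles(sim$pv)$profiles
  comparisons <- list()
  for (ab in c("AB1", "AB2")) {
    r <- compute_rpv(prof, ab, "IGG")
    r$threshold <- estimate_threshold(r$rpv)
    comparisons[[paste0(ab, "_vs_igg")]] <- r
  }
  r <- compute_rpv(prof, "AB1", "DEPL")
  r$threshold <- estimate_threshold(r$rpv)
  comparisons[["AB1_vs_depletion"]] <- r
  calls <- call_specific(comparisons, c("AB1_vs_igg", "AB2_vs_igg"),
                         "AB1_vs_depletion")
  list(called = calls$protein_id[calls$is_specific],
       truth = model$specific)
}
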