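make_pv <- function(vals, protein = "P1") {
  n <- nrow(vals)
  pep <- data.frame(peptide_id = rownames(vals),
                    protein_id = rep(protein, length.out = n),
                    sequence = vapply(seq_len(n), function(i) {
                      paste0("ACDEFK", strrep("L", i))
                    }, character(1)))
  pv_matrix(vals, pep)
}

test_that("peptide profiles are max-normalized with missing preserved", {
  vals <- rbind(A = c(10, 5, NA), C = c(7, 7, 7))
  colnames(vals) <- paste0("d", 1:3)
  npv <- normalize_peptide_profiles(make_pv(vals))
  expect_equal(unname(npv$values["A", ]), c(1, 0.5, NA))
  expect_equal(unname(npv$values["C", ]), c(1, 1, 1))
})

test_that("profiles are invariant to per-peptide scale factors", {
  vals <- rbind(A = c(3, 6, 1.5), C = c(2, 4, 1))
  colnames(vals) <- paste0("d", 1:3)
  scaled <- vals
  scaled["A", ] <- scaled["A", ] * 1000
  p1 <- normalize_peptide_profiles(make_pv(vals))$values
  p2 <- normalize_peptide_profiles(make_pv(scaled))$values
  expect_equal(p1, p2)
})

test_that("peptides observed nowhere are dropped with a warning", {
  vals <- rbind(A = c(1, 2), C = c(NA, NA))
  colnames(vals) <- c("d1", "d2")
  expect_warning(npv <- normalize_peptide_profiles(make_pv(vals)), "dropped")
  expect_equal(rownames(npv$values), "A")
})

test_that("correlation ranking excludes an anti-correlated outlier peptide", {
  shape <- c(1, 0.8, 0.6, 0.4, 0.2)
  good <- profile_block(shape, 5, ids = paste0("good", 1:5))
  outlier <- matrix(rev(shape), 1, dimnames = list("zzout", colnames(good)))
  profiles <- rbind(good, outlier)

  # brute-force oracle: mean pairwise Pearson r over all 6 candidates
  oracle <- sapply(rownames(profiles), function(i) {
    mean(sapply(setdiff(rownames(profiles), i), function(j) {
      cor(profiles[i, ], profiles[j, ])
    }))
  })
  expect_lt(oracle["zzout"], 0)
  expect_true(all(oracle[paste0("good", 1:5)] > 0))

  sel <- rank_and_select_peptides(profiles)
  expect_false("zzout" %in% sel$selected)
  expect_false(sel$low_confidence)
  expect_equal(sel$mean_r[order(names(sel$mean_r))],
               oracle[order(names(oracle))])
})

test_that("selection rule arithmetic and degenerate cases", {
  shape <- c(1, 0.5, 0.25, 0.75)
  many <- profile_block(shape, 20)
  jitter <- matrix(rep(seq(0, 0.019, by = 0.001), 4), 20, 4)
  many <- many + jitter  # break exact ties while keeping high correlation
  sel <- rank_and_select_peptides(many)
  expect_length(sel$selected, 10)  # ceiling(0.5 * 20)

  one <- profile_block(shape, 1)
  sel1 <- rank_and_select_peptides(one)
  expect_equal(sel1$selected, rownames(one))
  expect_true(sel1$low_confidence)

  # pairs sharing fewer than 3 datasets: fall back to all peptides
  sparse <- rbind(a = c(1, NA, NA, 0.5), b = c(NA, 1, 0.5, NA))
  colnames(sparse) <- paste0("d", 1:4)
  sel2 <- rank_and_select_peptides(sparse)
  expect_setequal(sel2$selected, c("a", "b"))
  expect_true(sel2$low_confidence)
})

test_that("protein profile is the per-dataset median over selected peptides", {
  sel <- rbind(a = c(1, 0.4), b = c(1, 0.6))
  expect_equal(unname(protein_profile(sel)), c(1, 0.5))
  odd <- rbind(a = c(1, NA, 0.2), b = c(NA, 0.7, 0.4), c = c(0.9, 0.5, NA))
  expect_equal(unname(protein_profile(odd)), c(0.95, 0.6, 0.3))
  allna <- rbind(a = c(1, NA), b = c(0.5, NA))
  expect_equal(unname(protein_profile(allna)), c(0.75, NA))
})

test_that("noiseless profiles equal true relative abundances exactly", {
  model <- profile_scenario(n_proteins = 5, n_datasets = 8, seed = 11)
  sim <- simulate_apms(model, noise_model(cv = 0), 6, seed = 12)
  est <- protein_profiles(sim$pv)$profiles
  true_rel <- t(apply(model$abundance, 1, function(r) r / max(r)))
  expect_equal(est, true_rel[rownames(est), ], tolerance = 1e-12)
})

test_that("one gross outlier among several peptides leaves the profile intact", {
  shape <- c(1, 0.3, 0.6, 0.2, 0.8, 0.5)      # true relative profile
  resp <- c(1, 2, 0.5, 3, 1.5)                # per-peptide response factors
  vals <- outer(resp, shape * 100)
  dimnames(vals) <- list(paste0("pep", 1:5), paste0("d", 1:6))
  est_clean <- protein_profiles(make_pv(vals))$profiles
  expect_equal(unname(est_clean["P1", ]), shape)

  set.seed(42)
  outlier <- matrix(sample(shape) * 1000, 1,
                    dimnames = list("zzz", colnames(vals)))
  est_dirty <- protein_profiles(make_pv(rbind(vals, outlier)))$profiles
  expect_equal(unname(est_dirty["P1", ]), shape)
})

test_that("QconCAT scaling matches the closed-form least squares", {
  prof <- matrix(c(1, 0.5), 1, dimnames = list("P1", c("d1", "d2")))
  one_point <- data.frame(protein_id = "P1", dataset_id = "d1", value = 10)
  res <- calibrate_qconcat(prof, one_point)
  expect_equal(unname(res$abundance["P1", ]), c(10, 5))

  two_points <- data.frame(protein_id = "P1", dataset_id = c("d1", "d2"),
                           value = c(10, 4))
  res2 <- calibrate_qconcat(prof, two_points)
  expect_equal(unname(res2$scale["P1"]), 9.6)  # (1*10 + 0.5*4) / (1 + 0.25)
  # grid-search oracle over candidate scale factors
  grid <- seq(0, 20, by = 1e-3)
  sse <- sapply(grid, function(s) sum((s * c(1, 0.5) - c(10, 4))^2))
  expect_equal(unname(res2$scale["P1"]), grid[which.min(sse)],
               tolerance = 1e-3)
  expect_equal(unname(res2$abundance["P1", ]), c(9.6, 4.8))

  zeros <- data.frame(protein_id = "P1", dataset_id = c("d1", "d2"),
                      value = c(0, 0))
  expect_equal(unname(calibrate_qconcat(prof, zeros)$abundance["P1", ]),
               c(0, 0))
})

test_that("uncalibrated proteins are flagged, not silently scaled", {
  prof <- matrix(c(1, 0.5, 1, 0.2), 2, byrow = TRUE,
                 dimnames = list(c("P1", "P2"), c("d1", "d2")))
  cal <- data.frame(protein_id = "P1", dataset_id = "d1", value = 10)
  expect_message(res <- calibrate_qconcat(prof, cal), "uncalibrated")
  expect_equal(res$uncalibrated, "P2")
  expect_true(all(is.na(res$abundance["P2", ])))
})

test_that("spectral abundance is summed PV per accessible amino acid", {
  vals <- rbind(a = c(100, 50), b = c(300, 150))
  colnames(vals) <- c("d1", "d2")
  pv <- make_pv(vals)
  ab <- abundance_spec(pv, c(P1 = 40))
  expect_equal(unname(ab["P1", ]), c(10, 5))
  # linearity: doubling all PVs doubles the estimate
  pv2 <- make_pv(vals * 2)
  expect_equal(abundance_spec(pv2, c(P1 = 40)), ab * 2)
  expect_error(abundance_spec(pv, c(P1 = 0)), "> 0")
})

test_that("spectral abundance preserves the rank order of true abundance", {
  model <- profile_scenario(n_proteins = 8, n_datasets = 4, seed = 31)
  sim <- simulate_apms(model, noise_model(cv = 0.2), 5, seed = 32)
  aa <- setNames(rep(50L, 8), rownames(model$abundance))
  est <- abundance_spec(sim$pv, aa)
  rho <- mean(sapply(colnames(est), function(d) {
    cor(est[, d], model$abundance[rownames(est), d], method = "spearman")
  }))
  expect_gt(rho, 0.9)
})

test_that("target normalization fixes the target column at 1", {
  ab <- rbind(TGT = c(8, 4), PREY = c(2, 1), GluA1 = c(4, 2),
              GluA2 = c(4, 2), GluA3 = c(2, 1), GluA4 = c(2, 1))
  colnames(ab) <- c("ap1", "ap2")
  meta <- dataset_meta(c("ap1", "ap2"), target_proteins = "TGT")
  res <- normalize_to_target(ab, meta,
                             glua_ids = paste0("GluA", 1:4))
  expect_equal(unname(res$normalized["TGT", ]), c(1, 1))
  expect_equal(unname(res$normalized["PREY", ]), c(0.25, 0.25))
  expect_equal(unname(res$ampar_amount), c(3, 1.5))  # (4+4+2+2)/4
})

test_that("datasets without a usable target are dropped from normalization", {
  ab <- rbind(TGT = c(8, NA), PREY = c(2, 1))
  colnames(ab) <- c("ap1", "ap2")
  meta <- dataset_meta(c("ap1", "ap2"), target_proteins = "TGT")
  expect_message(res <- normalize_to_target(ab, meta), "dropped")
  expect_equal(colnames(res$normalized), "ap1")
  expect_equal(res$dropped, "ap2")
})
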