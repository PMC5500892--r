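abund <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("d", seq_len(ncol(m)))
  m
}

test_that("rPV is abundance in A over mean abundance in B", {
  m <- abund(P1 = c(2, 1), P2 = c(3, 3))
  r <- compute_rpv(m, "d1", "d2")
  expect_equal(r$rpv[r$protein_id == "P1"], 2)
  expect_equal(r$rpv[r$protein_id == "P2"], 1)

  # replicates in A: mean of per-replicate ratios, with s.e.m.
  m2 <- abund(P1 = c(2, 4, 1, 1))
  r2 <- compute_rpv(m2, c("d1", "d2"), c("d3", "d4"))
  expect_equal(r2$rpv, 3)
  expect_equal(r2$sem, sd(c(2, 4)) / sqrt(2))
})

test_that("rPV imputes undetected control abundances at the detection floor", {
  m <- abund(P1 = c(5, NA), P2 = c(1, 0.4), P3 = c(2, 0.8))
  r <- compute_rpv(m, "d1", "d2", impute_factor = 0.5)
  # P1 missing in control: imputed at 0.5 * min(0.4, 0.8) = 0.2
  expect_equal(r$rpv[r$protein_id == "P1"], 25)
  expect_true(r$imputed[r$protein_id == "P1"])
  expect_false(any(r$imputed[r$protein_id != "P1"]))
})

test_that("mean rPV recovers a three-fold enrichment under noise", {
  rpvs <- sapply(1:25, function(seed) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + 0.15^2))
    a <- 3 * rlnorm(4, -sdlog^2 / 2, sdlog)
    b <- 1 * rlnorm(4, -sdlog^2 / 2, sdlog)
    m <- matrix(c(a, b), 1, dimnames = list("P1", paste0("d", 1:8)))
    compute_rpv(m, paste0("d", 1:4), paste0("d", 5:8))$rpv
  })
  expect_gt(mean(rpvs), 2.5)
  expect_lt(mean(rpvs), 3.6)
})

test_that("specificity threshold tracks the background mode of log ratios", {
  set.seed(1)
  bg <- rlnorm(500, 0, 0.2)
  thr <- estimate_threshold(bg)
  expect_gt(thr, 1.6)   # analytic: exp(3 * 0.2) ~ 1.82
  expect_lt(thr, 2.1)

  # 5% strongly enriched proteins do not move the background threshold,
  # and all of them pass it
  enriched <- bg
  enriched[1:25] <- enriched[1:25] * 50
  thr2 <- estimate_threshold(enriched)
  expect_lt(abs(log(thr2) - log(thr)), 0.15)
  expect_true(all(enriched[1:25] / thr2 > 1))
})

test_that("threshold is robust-monotone and guards degenerate input", {
  expect_error(estimate_threshold(rep(2, 10)), "fewer than 20")
  expect_warning(thr <- estimate_threshold(rep(1, 30)), "degenerate")
  expect_equal(thr, 1)

  set.seed(2)
  base <- rlnorm(200, 0, 0.3)
  thr_base <- estimate_threshold(base)
  for (k in c(5, 10, 20)) {
    thr_k <- estimate_threshold(c(base, rep(60, k)))
    expect_gte(thr_k, thr_base)
  }
})

test_that("specificity requires two antibodies plus every control", {
  mk <- function(ids, rpv, thr) {
    d <- data.frame(protein_id = ids, rpv = rpv)
    d$threshold <- thr
    d
  }
  cmp <- list(
    ab1 = mk(c("X", "Y", "Z"), c(10, 10, 10), 2),
    ab2 = mk(c("X", "Y", "Z"), c(10, 1, 10), 2),
    depl = mk(c("X", "Y", "Z"), c(10, 10, 1), 2))
  calls <- call_specific(cmp, c("ab1", "ab2"), "depl")
  got <- setNames(calls$is_specific, calls$protein_id)
  expect_true(got["X"])       # passes both ABs and the depletion control
  expect_false(got["Y"])      # only one antibody
  expect_false(got["Z"])      # fails the required depletion control
  expect_error(call_specific(cmp, c("ab1", "nope")), "unknown")
})

test_that("fraction_first implements F = rPV / (rPV + 1)", {
  expect_equal(fraction_first(1), 0.5)
  expect_equal(fraction_first(0), 0)
  expect_equal(fraction_first(3), 0.75)
  expect_error(fraction_first(-0.1), ">= 0")

  # bijection (0, Inf) -> (0, 1) and the reflection identity
  x <- c(0.01, 0.1, 0.5, 1, 2, 10, 100)
  f <- fraction_first(x)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
  expect_equal(fraction_first(1 / x), 1 - f)
})

test_that("two-step partition fractions and boundary handling", {
  first <- abund(P1 = 0.2, P2 = 0.9, P3 = NA)
  second <- abund(P1 = 0.8, P2 = NA, P3 = 0.4)
  res <- twostep_partition(first, second)
  got <- setNames(res$fraction_first, res$protein_id)
  expect_equal(unname(got["P1"]), 0.2)
  expect_equal(unname(got["P2"]), 1)   # absent from the second AP
  expect_equal(unname(got["P3"]), 0)   # absent from the first AP
  expect_equal(res$fraction_first + res$fraction_second, rep(1, 3))
  expect_equal(unname(res$imputed), c(FALSE, TRUE, TRUE))
})

test_that("group comparison reports ratios, t-tests and stars", {
  m <- abund(SAME = c(1, 2, 3, 1, 2, 3),
             DOWN = c(10, 11, 9, 1, 1.2, 0.9),
             ZERO = c(1, 1, 1, 0, 0, 0))
  ga <- paste0("d", 1:3)
  gb <- paste0("d", 4:6)
  res <- compare_groups(m, ga, gb)
  same <- res[res$protein_id == "SAME", ]
  expect_equal(same$ratio, 1)
  expect_equal(same$p_value, 1)
  down <- res[res$protein_id == "DOWN", ]
  expect_equal(down$ratio, 10 / 1.0333333, tolerance = 1e-5)
  expect_lt(down$p_value, 0.01)
  expect_true(down$stars %in% c("**", "***"))
  zero <- res[res$protein_id == "ZERO", ]
  expect_true(is.infinite(zero$ratio))
  expect_true(is.na(zero$p_value))   # excluded from testing
})

test_that("cross-dataset correlation ranks subunits and set sums", {
  set.seed(3)
  core <- matrix(rlnorm(4 * 8, 0, 0.8), 4, 8,
                 dimnames = list(paste0("C", 1:4), paste0("d", 1:8)))
  focal <- colSums(core)
  m <- rbind(FOCAL = focal, core,
             FLAT = rep(2, 8),
             ANTI = max(focal) + min(focal) - focal)
  res <- cross_dataset_correlation(m, "FOCAL",
                                   list(core = paste0("C", 1:4),
                                        flat = "FLAT"))
  expect_equal(res$r[res$name == "sum_core"], 1)
  expect_true(res$degenerate[res$name == "FLAT"])
  # identical and anti-correlated vectors
  m2 <- rbind(FOCAL = focal, SAMEV = focal, ANTI = -focal, core)
  res2 <- cross_dataset_correlation(m2, "FOCAL",
                                    list(s = "SAMEV", a = "ANTI"))
  expect_equal(res2$r[res2$name == "SAMEV"], 1)
  expect_equal(res2$r[res2$name == "ANTI"], -1)
  expect_error(cross_dataset_correlation(m[, 1:3], "FOCAL", list()), "4 datasets")
})

test_that("a summed core signal correlates better than its members", {
  wins <- sapply(1:30, function(seed) {
    set.seed(seed)
    core <- matrix(rlnorm(4 * 10, 0, 0.8), 4, 10,
                   dimnames = list(paste0("C", 1:4), paste0("d", 1:10)))
    noise <- rlnorm(10, -0.005, 0.1)
    m <- rbind(FOCAL = colSums(core) * noise, core)
    res <- cross_dataset_correlation(m, "FOCAL",
                                     list(core = paste0("C", 1:4)))
    res$r[res$name == "sum_core"] > max(res$r[res$kind == "subunit"])
  })
  expect_gte(mean(wins), 0.9)
})
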