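#' Impute missing abundances with a detection-floor value
#'
#' Proteins undetected in a dataset (typically negative controls) get
#' `factor` times the smallest observed abundance in that dataset, so
#' that finite enrichment ratios can be formed for proteins absent from
#' controls. Imputed cells are reported so downstream calls can be
#' flagged.
#'
#' @param abundance matrix (proteins x datasets).
#' @param factor multiple of the per-dataset minimum used as floor.
#' @return list with `abundance` (imputed matrix) and `imputed` (logical
#'   matrix marking imputed cells).
#' @export
impute_missing_abundance <- function(abundance, factor = 0.5) {
  abundance <- as.matrix(abundance)
  imputed <- is.na(abundance)
  for (j in seq_len(ncol(abundance))) {
    col <- abundance[, j]
    obs <- col[!is.na(col) & col > 0]
    if (length(obs) == 0) next
    floor_val <- factor * min(obs)
    col[is.na(col)] <- floor_val
    abundance[, j] <- col
  }
  list(abundance = abundance, imputed = imputed)
}

#' Protein enrichment ratios (rPV) between two dataset groups
#'
#' For every protein, the ratio of its (target-normalized) abundance in
#' each group-A replicate over the mean abundance across the group-B
#' replicates; ratios are combined across A replicates as mean +/- s.e.m.
#' (n - 1 denominator). Abundances missing in one group are imputed at
#' `impute_factor` times the smallest observed abundance of the dataset
#' (see [impute_missing_abundance()]); proteins absent from both groups
#' are excluded.
#'
#' @param abundance matrix (proteins x datasets).
#' @param group_a,group_b dataset id vectors (non-empty, disjoint).
#' @param impute_factor detection-floor multiple for missing values.
#' @return data.frame with columns `protein_id`, `rpv`, `sem`,
#'   `n_replicates`, `imputed` (any cell of this protein imputed).
#' @export
compute_rpv <- function(abundance, group_a, group_b, impute_factor = 0.5) {
  abundance <- as.matrix(abundance)
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  if (!all(c(group_a, group_b) %in% colnames(abundance))) {
    stop("group dataset ids not all present in the abundance table")
  }
  sub <- abundance[, c(group_a, group_b), drop = FALSE]
  present <- rowSums(!is.na(sub)) > 0
  sub <- sub[present, , drop = FALSE]
  imp <- impute_missing_abundance(sub, factor = impute_factor)
  vals <- imp$abundance
  a <- vals[, group_a, drop = FALSE]
  b_mean <- rowMeans(vals[, group_b, drop = FALSE])
  ratios <- sweep(a, 1, b_mean, "/")
  rpv <- rowMeans(ratios)
  sem <- if (length(group_a) > 1) {
    apply(ratios, 1, sd) / sqrt(length(group_a))
  } else rep(NA_real_, nrow(ratios))
  data.frame(protein_id = rownames(sub),
             rpv = unname(rpv),
             sem = unname(sem),
             n_replicates = length(group_a),
             imputed = unname(rowSums(imp$imputed) > 0),
             stringsAsFactors = FALSE)
}

#' Specificity threshold from the rPV distribution of one comparison
#'
#' Most proteins in an AP-versus-control comparison are nonspecific
#' background whose log ratios cluster around a central mode; specific
#' interactors sit in the far right tail. The threshold is a robust upper
#' bound of that background mode: `exp(m + c * s)` with `m` the median
#' and `s` the scaled MAD (consistency constant 1.4826) of `log(rPV)`.
#' Median and MAD are insensitive to a minority of enriched proteins, so
#' adding high-rPV proteins does not inflate the threshold.
#'
#' @param rpvs numeric vector of rPVs for all proteins detected in the
#'   comparison (at least 20 finite positive values required; with fewer,
#'   an error advises setting a manual threshold).
#' @param multiplier `c` above (default 3).
#' @return threshold ratio (> 0).
#' @export
estimate_threshold <- function(rpvs, multiplier = 3) {
  rpvs <- rpvs[is.finite(rpvs) & rpvs > 0]
  if (length(rpvs) < 20) {
    stop("fewer than 20 finite rPVs: too few for a distribution-based ",
         "threshold, set one manually")
  }
  lr <- log(rpvs)
  m <- median(lr)
  s <- mad(lr)  # scaled by 1.4826
  if (s == 0) {
    warning("degenerate rPV distribution (zero spread); threshold equals the median ratio")
  }
  exp(m + multiplier * s)
}

#' Consensus specificity call across antibodies and controls
#'
#' A protein is called a specific interactor when it exceeds the
#' comparison-specific threshold (rPV / threshold > 1) in at least
#' `n_ab_required` independent antibody-versus-IgG comparisons and in
#' every required depletion/knockout control comparison.
#'
#' @param comparisons named list of data.frames as returned by
#'   [compute_rpv()], each with an attached threshold: either an
#'   attribute `threshold` or a `threshold` column.
#' @param ab_comparisons names of the antibody-vs-IgG comparisons.
#' @param required_comparisons names of comparisons that must all pass
#'   (depletion / knockout controls).
#' @param n_ab_required minimum number of passing antibody comparisons.
#' @return data.frame with `protein_id`, one pass flag per comparison,
#'   `n_ab_pass`, and `is_specific`.
#' @export
call_specific <- function(comparisons, ab_comparisons,
                          required_comparisons = character(0),
                          n_ab_required = 2) {
  all_names <- c(ab_comparisons, required_comparisons)
  missing_cmp <- setdiff(all_names, names(comparisons))
  if (length(missing_cmp) > 0) {
    stop("rule references unknown comparison(s): ",
         paste(missing_cmp, collapse = ", "))
  }
  proteins <- sort(unique(unlist(lapply(comparisons[all_names],
                                        function(d) d$protein_id))))
  passes <- matrix(FALSE, length(proteins), length(all_names),
                   dimnames = list(proteins, all_names))
  for (nm in all_names) {
    d <- comparisons[[nm]]
    thr <- attr(d, "threshold")
    if (is.null(thr)) thr <- d$threshold
    if (is.null(thr)) stop("comparison '", nm, "' carries no threshold")
    ok <- (d$rpv / thr) > 1
    passes[d$protein_id, nm] <- ok
  }
  n_ab_pass <- rowSums(passes[, ab_comparisons, drop = FALSE])
  req_pass <- if (length(required_comparisons) == 0) {
    rep(TRUE, length(proteins))
  } else {
    rowSums(passes[, required_comparisons, drop = FALSE]) ==
      length(required_comparisons)
  }
  out <- data.frame(protein_id = proteins, stringsAsFactors = FALSE)
  for (nm in all_names) out[[paste0("pass_", nm)]] <- unname(passes[, nm])
  out$n_ab_pass <- unname(n_ab_pass)
  out$is_specific <- unname(n_ab_pass >= n_ab_required & req_pass)
  out
}

#' Fraction captured in the first of two serial APs
#'
#' For an exhaustive (target-depleting) first AP followed by a second AP
#' of the flow-through, the fraction of a protein captured in the first
#' step is `F = rPV / (rPV + 1)` where rPV is the first/second abundance
#' ratio; the second step holds `1 - F` exactly. The map is a bijection
#' from ratios (0, Inf) onto fractions (0, 1).
#'
#' @param rpv non-negative ratio(s) first/second.
#' @return fraction(s) in \[0, 1).
#' @export
fraction_first <- function(rpv) {
  if (any(!is.na(rpv) & rpv < 0)) stop("rPV must be >= 0")
  rpv / (rpv + 1)
}

#' Partition fractions from a two-step (serial) AP pair
#'
#' Computes, per protein and replicate, the first/second abundance ratio
#' and the captured fraction `F` (see [fraction_first()]), then averages
#' across replicates (mean +/- s.e.m., n - 1 denominator). A protein
#' missing from one AP but present in the other is treated as fully
#' captured by the step where it was seen (F = 1 or 0, flagged as
#' boundary-imputed); proteins in neither AP are excluded.
#'
#' @param first,second abundance matrices (proteins x replicate datasets)
#'   with replicate columns aligned by position.
#' @return data.frame with `protein_id`, `fraction_first`, `sem`,
#'   `fraction_second`, `n_replicates`, `imputed`.
#' @export
twostep_partition <- function(first, second) {
  first <- as.matrix(first)
  second <- as.matrix(second)
  if (ncol(first) != ncol(second)) {
    stop("first and second AP must have the same number of replicates")
  }
  common <- intersect(rownames(first), rownames(second))
  first <- first[common, , drop = FALSE]
  second <- second[common, , drop = FALSE]
  present <- rowSums(!is.na(first)) + rowSums(!is.na(second)) > 0
  first <- first[present, , drop = FALSE]
  second <- second[present, , drop = FALSE]
  n_rep <- ncol(first)
  fmat <- matrix(NA_real_, nrow(first), n_rep)
  imputed <- rep(FALSE, nrow(first))
  for (j in seq_len(n_rep)) {
    f <- first[, j]
    s <- second[, j]
    one_sided <- xor(is.na(f), is.na(s))
    imputed <- imputed | one_sided
    f[is.na(f) & !is.na(s)] <- 0
    s[is.na(s) & !is.na(f)] <- 0
    both_zero <- !is.na(f) & !is.na(s) & f == 0 & s == 0
    frac <- f / (f + s)             # == fraction_first(f / s), safe at s = 0
    frac[both_zero] <- NA_real_
    fmat[, j] <- frac
  }
  f_mean <- rowMeans(fmat, na.rm = TRUE)
  n_obs <- rowSums(!is.na(fmat))
  sem <- apply(fmat, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) > 1) sd(r) / sqrt(length(r)) else NA_real_
  })
  keep <- n_obs > 0
  data.frame(protein_id = rownames(first)[keep],
             fraction_first = unname(f_mean[keep]),
             sem = unname(sem[keep]),
             fraction_second = unname(1 - f_mean[keep]),
             n_replicates = unname(n_obs[keep]),
             imputed = unname(imputed[keep]),
             stringsAsFactors = FALSE)
}

#' Compare protein abundances between two replicate groups
#'
#' Per protein: the ratio of group means (e.g. knockout over wild type)
#' of normalized abundances, with a two-sided Student's t-test across
#' replicates. Significance stars follow the p < 0.01 (`**`) and
#' p < 0.001 (`***`) convention; no multiple-testing correction is
#' applied, so p-values are per-protein statements only.
#'
#' @param abundance matrix (proteins x datasets) of normalized abundances.
#' @param group_a,group_b dataset id vectors; at least 2 replicates per
#'   group for a p-value (with 1, only the ratio is reported).
#' @return data.frame with `protein_id`, `ratio` (`Inf` flagged when the
#'   reference mean is 0, excluded from testing), `t`, `p_value`,
#'   `stars`.
#' @export
compare_groups <- function(abundance, group_a, group_b) {
  abundance <- as.matrix(abundance)
  stopifnot(all(c(group_a, group_b) %in% colnames(abundance)))
  res <- lapply(rownames(abundance), function(p) {
    a <- abundance[p, group_a]
    b <- abundance[p, group_b]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) {
      return(data.frame(protein_id = p, ratio = NA_real_, t = NA_real_,
                        p_value = NA_real_, stars = "", stringsAsFactors = FALSE))
    }
    ratio <- mean(a) / mean(b)
    tt <- NA_real_
    pp <- NA_real_
    if (is.finite(ratio) && length(a) >= 2 && length(b) >= 2) {
      if (sd(a) == 0 && sd(b) == 0) {
        pp <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
        tt <- if (pp == 1) 0 else Inf
      } else {
        ht <- t.test(a, b, alternative = "two.sided")
        tt <- unname(ht$statistic)
        pp <- ht$p.value
      }
    }
    stars <- if (!is.na(pp) && pp < 0.001) "***" else
      if (!is.na(pp) && pp < 0.01) "**" else ""
    data.frame(protein_id = p, ratio = ratio, t = tt, p_value = pp,
               stars = stars, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Correlation of a focal protein with subunits and subunit-set sums
#'
#' Pearson correlation, across AP datasets, of the focal protein's
#' abundance vector with (a) each individual subunit and (b) the summed
#' abundance of each named subunit set. Used to ask which receptor
#' population a protein tracks: a protein coupled to the whole population
#' correlates better with a subunit-set sum than with any single member.
#'
#' @param abundance matrix (proteins x datasets), >= 4 datasets.
#' @param focal focal protein id.
#' @param subunit_sets named list of protein id vectors.
#' @return data.frame with `name`, `kind` (`"subunit"`/`"set_sum"`), `r`,
#'   sorted by decreasing r; zero-variance vectors yield `NA` r with a
#'   `degenerate` flag.
#' @export
cross_dataset_correlation <- function(abundance, focal, subunit_sets) {
  abundance <- as.matrix(abundance)
  if (ncol(abundance) < 4) stop("at least 4 datasets required")
  if (!focal %in% rownames(abundance)) stop("focal protein not quantified")
  fvec <- abundance[focal, ]
  members <- unique(unlist(subunit_sets))
  missing_m <- setdiff(members, rownames(abundance))
  if (length(missing_m) > 0) {
    stop("subunit(s) not quantified: ", paste(missing_m, collapse = ", "))
  }
  safe_cor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) NA_real_
    else cor(x[ok], y[ok])
  }
  rows <- list()
  for (m in members) {
    rows[[length(rows) + 1]] <- data.frame(
      name = m, kind = "subunit", r = safe_cor(fvec, abundance[m, ]),
      stringsAsFactors = FALSE)
  }
  for (nm in names(subunit_sets)) {
    s <- colSums(abundance[subunit_sets[[nm]], , drop = FALSE], na.rm = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("sum_", nm), kind = "set_sum", r = safe_cor(fvec, s),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$degenerate <- is.na(out$r)
  out[order(-ifelse(is.na(out$r), -Inf, out$r)), , drop = FALSE]
}
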