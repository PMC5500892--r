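#' Max-normalize peptide peak volumes to relative profiles
#'
#' Each peptide's PVs are divided by that peptide's maximum over all AP
#' datasets, yielding a relative peptide profile in \[0, 1\]. The division
#' cancels the peptide-specific response factor (ionization efficiency,
#' detectability), which is why sibling peptides of one protein become
#' directly comparable. Missing values stay missing; peptides observed in
#' no dataset are dropped with a warning.
#'
#' @param pv a [pv_matrix()].
#' @return A `pv_matrix` whose values are relative profiles (per-peptide
#'   maximum = 1).
#' @export
normalize_peptide_profiles <- function(pv) {
  stopifnot(inherits(pv, "pv_matrix"))
  vals <- pv$values
  maxima <- apply(vals, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  all_missing <- is.na(maxima)
  if (any(all_missing)) {
    warning(sum(all_missing), " peptide(s) observed in no dataset were dropped")
    vals <- vals[!all_missing, , drop = FALSE]
    pv$peptides <- pv$peptides[!all_missing, , drop = FALSE]
    maxima <- maxima[!all_missing]
  }
  zero_max <- maxima == 0
  profiles <- sweep(vals, 1, ifelse(zero_max, 1, maxima), "/")
  pv$values <- profiles
  pv
}

#' Rank peptides by mutual correlation and select the best
#'
#' For one protein, every pair of relative peptide profiles is scored by
#' the Pearson correlation over their pairwise-complete datasets (pairs
#' with fewer than `min_shared` shared observations contribute r = 0, so
#' undefined correlations cannot dominate the ranking). Peptides are
#' ranked by mean pairwise r; peptides with mean r below `r_cutoff`
#' (default 0) are excluded first as outliers or false-positive
#' assignments, then the top `k = max(k_min, ceiling(fraction * n))`
#' peptides are kept (`k = n` when `n <= k_min`, so small proteins use
#' everything). Ties in mean r are broken lexicographically by peptide
#' sequence, then id, for determinism.
#'
#' @param profiles numeric matrix (peptides x datasets) of relative
#'   profiles for one protein, rownames = peptide ids.
#' @param sequences character vector of peptide sequences parallel to the
#'   rows (defaults to rownames).
#' @param k_min minimum number of peptides kept (when available).
#' @param fraction fraction of peptides kept for larger proteins.
#' @param r_cutoff peptides with mean pairwise r below this are dropped
#'   before ranking.
#' @param min_shared minimum shared datasets for a defined pairwise r.
#' @return list with `selected` (peptide ids), `mean_r` (named vector),
#'   `low_confidence` (TRUE when no peptide pair had `min_shared` shared
#'   datasets, or only one peptide exists).
#' @export
rank_and_select_peptides <- function(profiles, sequences = rownames(profiles),
                                     k_min = 3, fraction = 0.5,
                                     r_cutoff = 0, min_shared = 3) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n == 0) stop("no peptides to select from")
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(sequences)) sequences <- ids
  if (n == 1) {
    return(list(selected = ids, mean_r = setNames(NA_real_, ids),
                low_confidence = TRUE))
  }
  shared <- crossprod(t(!is.na(profiles)) * 1)   # shared-dataset counts
  suppressWarnings(
    rmat <- cor(t(profiles), use = "pairwise.complete.obs")
  )
  rmat[!is.finite(rmat)] <- 0
  rmat[shared < min_shared] <- 0
  diag(rmat) <- NA
  mean_r <- rowMeans(rmat, na.rm = TRUE)
  names(mean_r) <- ids
  any_defined <- any(shared[upper.tri(shared)] >= min_shared)
  if (!any_defined) {
    # no informative pair at all: fall back to using every peptide
    return(list(selected = ids[order(sequences, ids)], mean_r = mean_r,
                low_confidence = TRUE))
  }
  keep <- mean_r >= r_cutoff
  if (!any(keep)) keep <- rep(TRUE, n)  # degenerate: keep all rather than none
  cand_idx <- which(keep)
  n_cand <- length(cand_idx)
  k <- if (n_cand <= k_min) n_cand else max(k_min, ceiling(fraction * n_cand))
  ord <- cand_idx[order(-mean_r[cand_idx], sequences[cand_idx], ids[cand_idx])]
  list(selected = ids[ord[seq_len(k)]], mean_r = mean_r,
       low_confidence = FALSE)
}

#' Median protein profile from selected peptide profiles
#'
#' The relative abundance of a protein in each dataset is the per-dataset
#' median over its selected peptide profiles, ignoring missing values;
#' datasets where all selected peptides are missing stay missing. The
#' median (rather than a mean) makes the profile robust to a residual
#' outlier peptide.
#'
#' @param selected_profiles numeric matrix (selected peptides x datasets).
#' @return numeric vector of per-dataset relative abundances.
#' @export
protein_profile <- function(selected_profiles) {
  selected_profiles <- as.matrix(selected_profiles)
  if (nrow(selected_profiles) == 0) stop("no peptides selected")
  apply(selected_profiles, 2, function(col) {
    if (all(is.na(col))) NA_real_ else median(col, na.rm = TRUE)
  })
}

#' Relative protein profiles for all proteins of a PV matrix
#'
#' Convenience wrapper chaining [normalize_peptide_profiles()],
#' [rank_and_select_peptides()] and [protein_profile()] per protein.
#' Only isoform-specific peptides are used.
#'
#' @param pv a [pv_matrix()].
#' @inheritParams rank_and_select_peptides
#' @return list with `profiles` (matrix proteins x datasets),
#'   `selection` (per-protein list of selection results), and
#'   `n_peptides` (named vector of isoform-specific peptide counts).
#' @export
protein_profiles <- function(pv, k_min = 3, fraction = 0.5,
                             r_cutoff = 0, min_shared = 3) {
  npv <- normalize_peptide_profiles(pv)
  use <- npv$peptides$is_isoform_specific
  vals <- npv$values[use, , drop = FALSE]
  pep <- npv$peptides[use, , drop = FALSE]
  proteins <- sort(unique(pep$protein_id))
  out <- matrix(NA_real_, length(proteins), ncol(vals),
                dimnames = list(proteins, colnames(vals)))
  selection <- vector("list", length(proteins))
  names(selection) <- proteins
  n_pep <- setNames(integer(length(proteins)), proteins)
  for (p in proteins) {
    rows <- which(pep$protein_id == p)
    n_pep[p] <- length(rows)
    sel <- rank_and_select_peptides(vals[rows, , drop = FALSE],
                                    sequences = pep$sequence[rows],
                                    k_min = k_min, fraction = fraction,
                                    r_cutoff = r_cutoff,
                                    min_shared = min_shared)
    selection[[p]] <- sel
    out[p, ] <- protein_profile(vals[sel$selected, , drop = FALSE])
  }
  list(profiles = out, selection = selection, n_peptides = n_pep)
}

#' Scale a relative protein profile to molecular abundance (QconCAT)
#'
#' A single non-negative scale factor per protein is fitted by least
#' squares so that the scaled relative profile best matches the
#' calibration values obtained from MS analyses of fusion protein
#' standards: `s = sum(profile * cal) / sum(profile^2)` over datasets with
#' a calibration entry. The scaled values are molecular abundances in the
#' (arbitrary) units of the calibration standard.
#'
#' @param profiles matrix (proteins x datasets) of relative profiles.
#' @param calibration data.frame with columns `protein_id`, `dataset_id`,
#'   `value` (see [read_calibration_table()]).
#' @return list with `abundance` (matrix, rows without any overlapping
#'   calibration entry are all-`NA`), `scale` (named vector of fitted
#'   factors, `NA` = uncalibrated), `uncalibrated` (protein ids).
#' @export
calibrate_qconcat <- function(profiles, calibration) {
  profiles <- as.matrix(profiles)
  abundance <- profiles
  abundance[] <- NA_real_
  scale_factors <- setNames(rep(NA_real_, nrow(profiles)), rownames(profiles))
  for (p in rownames(profiles)) {
    cal_p <- calibration[calibration$protein_id == p, , drop = FALSE]
    cal_p <- cal_p[cal_p$dataset_id %in% colnames(profiles), , drop = FALSE]
    prof <- profiles[p, cal_p$dataset_id]
    ok <- !is.na(prof)
    if (nrow(cal_p) == 0 || !any(ok)) next
    num <- sum(prof[ok] * cal_p$value[ok])
    den <- sum(prof[ok]^2)
    s <- if (den == 0) 0 else max(0, num / den)
    scale_factors[p] <- s
    abundance[p, ] <- s * profiles[p, ]
  }
  uncal <- names(scale_factors)[is.na(scale_factors)]
  if (length(uncal) > 0) {
    message(length(uncal), " protein(s) without overlapping calibration left uncalibrated")
  }
  list(abundance = abundance, scale = scale_factors, uncalibrated = uncal)
}

#' Spectral abundance estimate for proteins without calibration standards
#'
#' For each protein and dataset, the sum of all assigned isoform-specific
#' PVs divided by the number of MS-accessible isoform-specific amino
#' acids of that protein. A size-normalized abundance proxy used where no
#' QconCAT standard exists; it is linear in the PVs, so its rank order
#' tracks true abundance.
#'
#' @param pv a [pv_matrix()].
#' @param accessible_aa named integer vector: MS-accessible
#'   isoform-specific amino acids per protein (> 0).
#' @return matrix (proteins x datasets) of abundance values; proteins with
#'   no isoform-specific peptide are excluded with a message.
#' @export
abundance_spec <- function(pv, accessible_aa) {
  stopifnot(inherits(pv, "pv_matrix"))
  use <- pv$peptides$is_isoform_specific
  vals <- pv$values[use, , drop = FALSE]
  pep <- pv$peptides[use, , drop = FALSE]
  proteins <- sort(unique(pv$peptides$protein_id))
  skipped <- setdiff(proteins, unique(pep$protein_id))
  if (length(skipped) > 0) {
    message(length(skipped), " protein(s) without isoform-specific peptides excluded")
  }
  proteins <- sort(unique(pep$protein_id))
  missing_aa <- setdiff(proteins, names(accessible_aa))
  if (length(missing_aa) > 0) {
    stop("no accessible_aa entry for protein(s): ",
         paste(head(missing_aa, 3), collapse = ", "))
  }
  if (any(accessible_aa[proteins] <= 0)) {
    stop("accessible_aa must be > 0 for every quantified protein")
  }
  out <- matrix(NA_real_, length(proteins), ncol(vals),
                dimnames = list(proteins, colnames(vals)))
  for (p in proteins) {
    rows <- vals[pep$protein_id == p, , drop = FALSE]
    sums <- colSums(rows, na.rm = TRUE)
    sums[colSums(!is.na(rows)) == 0] <- NA_real_
    out[p, ] <- sums / accessible_aa[[p]]
  }
  out
}

#' Normalize abundances to the primary target of each AP dataset
#'
#' Each protein's abundance is divided by the abundance of the dataset's
#' primary target protein(s) (their mean when several), so the target
#' column becomes identically 1 and other values read as degree of
#' association with the target. Also returns the amount of co-purified
#' AMPARs per dataset, defined as the sum of GluA1-4 abundances divided
#' by 4 (one tetramer per four pore-forming subunits).
#'
#' @param abundance matrix (proteins x datasets).
#' @param datasets dataset metadata (see [dataset_meta()]); the
#'   `target_proteins` column names each dataset's primary target(s).
#' @param glua_ids ids of the pore-forming GluA1-4 subunits used for
#'   `ampar_amount` (default none -> `NA`).
#' @return list with `normalized` (matrix; datasets whose target
#'   abundance is missing or 0 are dropped with a message, IgG controls
#'   are kept unnormalized as `NA`-target datasets are dropped),
#'   `ampar_amount` (named vector), `dropped` (dataset ids).
#' @export
normalize_to_target <- function(abundance, datasets, glua_ids = character(0)) {
  abundance <- as.matrix(abundance)
  datasets <- validate_dataset_meta(as.data.frame(datasets))
  stopifnot(identical(colnames(abundance), datasets$dataset_id))
  norm <- abundance
  dropped <- character(0)
  for (j in seq_len(ncol(abundance))) {
    targets <- target_ids(datasets$target_proteins[j])
    targets <- intersect(targets, rownames(abundance))
    t_ab <- if (length(targets) == 0) NA_real_ else
      mean(abundance[targets, j], na.rm = TRUE)
    if (!is.finite(t_ab) || t_ab == 0) {
      dropped <- c(dropped, datasets$dataset_id[j])
      norm[, j] <- NA_real_
    } else {
      norm[, j] <- abundance[, j] / t_ab
    }
  }
  if (length(dropped) > 0) {
    message("dataset(s) without usable target abundance dropped from normalization: ",
            paste(dropped, collapse = ", "))
    norm <- norm[, setdiff(colnames(norm), dropped), drop = FALSE]
  }
  ampar <- rep(NA_real_, ncol(abundance))
  names(ampar) <- colnames(abundance)
  glua <- intersect(glua_ids, rownames(abundance))
  if (length(glua) > 0) {
    ampar <- colSums(abundance[glua, , drop = FALSE], na.rm = TRUE) / 4
  }
  list(normalized = norm, ampar_amount = ampar, dropped = dropped)
}
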