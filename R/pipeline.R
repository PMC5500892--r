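#' Pipeline configuration
#'
#' One declarative object carrying every tunable parameter of the
#' quantification and specificity stages; all values are echoed into the
#' run log so a run is fully described by (inputs, config, seed).
#'
#' @param k_min minimum peptides kept per protein (see
#'   [rank_and_select_peptides()]).
#' @param fraction fraction of peptides kept for larger proteins.
#' @param r_cutoff mean-correlation cutoff excluding outlier peptides.
#' @param min_shared minimum shared datasets for a defined pairwise r.
#' @param threshold_multiplier robust-spread multiplier of
#'   [estimate_threshold()].
#' @param impute_factor detection-floor multiple for undetected
#'   abundances (see [impute_missing_abundance()]).
#' @param n_ab_required antibody comparisons required for a specificity
#'   call.
#' @param manual_threshold optional fixed specificity threshold used
#'   when a comparison has too few proteins for estimation.
#' @param glua_ids protein ids of the pore-forming GluA1-4 subunits
#'   (for the co-purified AMPAR amount).
#' @param seed integer random seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(k_min = 3, fraction = 0.5, r_cutoff = 0,
                            min_shared = 3, threshold_multiplier = 3,
                            impute_factor = 0.5, n_ab_required = 2,
                            manual_threshold = NULL,
                            glua_ids = character(0), seed = 0) {
  stopifnot(k_min >= 1, fraction > 0, fraction <= 1, min_shared >= 2,
            threshold_multiplier > 0, impute_factor > 0, impute_factor <= 1,
            n_ab_required >= 1, seed == as.integer(seed))
  structure(list(k_min = k_min, fraction = fraction, r_cutoff = r_cutoff,
                 min_shared = min_shared,
                 threshold_multiplier = threshold_multiplier,
                 impute_factor = impute_factor,
                 n_ab_required = n_ab_required,
                 manual_threshold = manual_threshold,
                 glua_ids = glua_ids, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file of config fields (unknown fields rejected).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

log_line <- function(con, ...) {
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              paste0(...)), file = con, append = TRUE)
}

#' Run the full AP-MS analysis pipeline
#'
#' Orchestrates the stages in order: read the PV table, compute relative
#' protein profiles, calibrate to molecular abundance (when a
#' calibration table is given), normalize to each dataset's primary
#' target, derive rPV specificity calls against the control datasets
#' present in the metadata, and partition any serial (two-step) AP pair.
#' All tables are written to `out_dir` as tab-separated text and every
#' parameter is echoed into `run.log`. Outputs are a pure function of
#' (inputs, config, seed); the quantification itself is deterministic.
#'
#' @param config a [pipeline_config()].
#' @param pv_table path to the peptide PV table (see [read_pv_table()]).
#' @param datasets optional path to a dataset-metadata TSV with the
#'   columns of [dataset_meta()], or a data.frame.
#' @param calibration optional path to a calibration table
#'   (see [read_calibration_table()]) or a data.frame.
#' @param out_dir output directory (created).
#' @return invisible list of the written table paths plus the in-memory
#'   results.
#' @export
run_pipeline <- function(config, pv_table, datasets = NULL,
                         calibration = NULL, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  # validate all inputs before any output is produced
  if (!file.exists(pv_table)) stop("input not found: ", pv_table)
  if (is.character(datasets) && !file.exists(datasets)) {
    stop("input not found: ", datasets)
  }
  if (is.character(calibration) && !file.exists(calibration)) {
    stop("input not found: ", calibration)
  }
  if (is.character(datasets)) {
    datasets <- read.delim(datasets, sep = "\t", stringsAsFactors = FALSE)
  }
  if (is.character(calibration)) {
    calibration <- read_calibration_table(calibration)
  }
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "run.log")
  cat("", file = log_file)
  for (nm in names(config)) {
    log_line(log_file, "config ", nm, " = ",
             paste(format(config[[nm]]), collapse = ","))
  }
  written <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      log_line(log_file, "stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_line(log_file, "stage ", name, " done in ",
             sprintf("%.2f", proc.time()[["elapsed"]] - t0), " s")
    res
  }

  pv <- stage("read", read_pv_table(pv_table, datasets = datasets))
  meta <- pv$datasets

  quant <- stage("quant", protein_profiles(
    pv, k_min = config$k_min, fraction = config$fraction,
    r_cutoff = config$r_cutoff, min_shared = config$min_shared))
  p <- file.path(out_dir, "protein_profiles.tsv")
  write_matrix_tsv(quant$profiles, p)
  written <- c(written, p)

  abundance <- quant$profiles
  if (!is.null(calibration)) {
    cal <- stage("calibrate", calibrate_qconcat(quant$profiles, calibration))
    abundance <- cal$abundance
    p <- file.path(out_dir, "molecular_abundance.tsv")
    write_matrix_tsv(abundance, p)
    written <- c(written, p)
  }

  norm <- stage("normalize", {
    has_target <- any(nzchar(meta$target_proteins))
    if (has_target) normalize_to_target(abundance, meta,
                                        glua_ids = config$glua_ids)
    else list(normalized = abundance,
              ampar_amount = setNames(rep(NA_real_, ncol(abundance)),
                                      colnames(abundance)))
  })
  p <- file.path(out_dir, "normalized_abundance.tsv")
  write_matrix_tsv(norm$normalized, p)
  written <- c(written, p)

  # rPV specificity against control datasets, per antibody
  rpv_tables <- NULL
  calls <- NULL
  controls <- meta$dataset_id[meta$control_kind != "none"]
  ap_sets <- split(meta$dataset_id[meta$control_kind == "none" &
                                     meta$serial_position == "not_serial"],
                   meta$antibody_id[meta$control_kind == "none" &
                                      meta$serial_position == "not_serial"])
  if (length(controls) > 0 && length(ap_sets) > 0) {
    res <- stage("specificity", {
      # profiles (not target-normalized) are used for ratio formation so
      # that IgG controls, which have no target, remain comparable
      comparisons <- list()
      for (ab in names(ap_sets)) {
        for (ctl in controls) {
          kind <- meta$control_kind[meta$dataset_id == ctl]
          cmp_name <- paste0(ab, "_vs_", kind)
          r <- compute_rpv(quant$profiles, ap_sets[[ab]], ctl,
                           impute_factor = config$impute_factor)
          thr <- tryCatch(
            estimate_threshold(r$rpv,
                               multiplier = config$threshold_multiplier),
            error = function(e) {
              if (is.null(config$manual_threshold)) stop(e)
              log_line(log_file, "comparison ", cmp_name,
                       ": manual threshold used (", conditionMessage(e), ")")
              config$manual_threshold
            })
          r$threshold <- thr
          r$passes <- (r$rpv / thr) > 1
          r$comparison <- cmp_name
          comparisons[[cmp_name]] <- r
        }
      }
      ab_cmp <- grep("_vs_igg$", names(comparisons), value = TRUE)
      req_cmp <- grep("_vs_(depletion|knockout)$", names(comparisons),
                      value = TRUE)
      calls <- if (length(ab_cmp) > 0) {
        call_specific(comparisons, ab_cmp, req_cmp,
                      n_ab_required = min(config$n_ab_required,
                                          length(ab_cmp)))
      } else NULL
      list(comparisons = comparisons, calls = calls)
    })
    rpv_tables <- do.call(rbind, res$comparisons)
    p <- file.path(out_dir, "rpv_table.tsv")
    write.table(rpv_tables, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p)
    calls <- res$calls
    if (!is.null(calls)) {
      p <- file.path(out_dir, "specificity_calls.tsv")
      write.table(calls, p, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, p)
    }
  }

  # two-step partition for serial AP pairs
  twostep <- NULL
  firsts <- meta$dataset_id[meta$serial_position == "first"]
  seconds <- meta$dataset_id[meta$serial_position == "second"]
  if (length(firsts) > 0 && length(firsts) == length(seconds)) {
    twostep <- stage("twostep", {
      ord_f <- firsts[order(meta$replicate_group[match(firsts, meta$dataset_id)])]
      ord_s <- seconds[order(meta$replicate_group[match(seconds, meta$dataset_id)])]
      twostep_partition(quant$profiles[, ord_f, drop = FALSE],
                        quant$profiles[, ord_s, drop = FALSE])
    })
    p <- file.path(out_dir, "twostep_fractions.tsv")
    write.table(twostep, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p)
  }

  log_line(log_file, "pipeline complete; ", length(written), " table(s) written")
  invisible(list(written = written, profiles = quant$profiles,
                 abundance = abundance, normalized = norm$normalized,
                 ampar_amount = norm$ampar_amount, rpv = rpv_tables,
                 specificity = calls, twostep = twostep))
}
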