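#' Peak-volume matrix
#'
#' Container for peptide-level peak volumes (PVs): a peptide's m/z signal
#' intensity integrated over chromatographic time, the elementary unit of
#' label-free quantification. Rows are peptides, columns are AP datasets;
#' `NA` marks a peptide not detected in a dataset and is distinct from 0.
#'
#' @param values numeric matrix (peptides x datasets) of PVs; all finite
#'   values must be >= 0, `NA` = missing.
#' @param peptides data.frame with columns `peptide_id`, `protein_id`,
#'   `sequence` and optionally `is_isoform_specific` (default `TRUE`).
#'   Peptides shared between isoforms should be flagged `FALSE`; they are
#'   excluded from isoform-specific quantification.
#' @param datasets data.frame of per-dataset metadata as produced by
#'   [dataset_meta()]; defaults to minimal metadata built from the column
#'   names of `values`.
#' @return An object of class `pv_matrix`: a list with elements `values`,
#'   `peptides`, `datasets`.
#' @seealso [read_pv_table()], [simulate_apms()]
#' @export
pv_matrix <- function(values, peptides, datasets = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("PV values must be numeric")
  }
  peptides <- as.data.frame(peptides, stringsAsFactors = FALSE)
  required <- c("peptide_id", "protein_id", "sequence")
  missing_cols <- setdiff(required, names(peptides))
  if (length(missing_cols) > 0) {
    stop("peptides table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(peptides$is_isoform_specific)) {
    peptides$is_isoform_specific <- TRUE
  }
  if (anyDuplicated(peptides$peptide_id)) {
    stop("peptide ids must be unique")
  }
  if (any(!nzchar(peptides$sequence))) {
    stop("peptide sequences must be non-empty")
  }
  bad_seq <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", peptides$sequence)
  if (any(bad_seq)) {
    stop("peptide sequence outside the 20-amino-acid uppercase alphabet: ",
         peptides$sequence[which(bad_seq)[1]])
  }
  if (nrow(values) != nrow(peptides)) {
    stop("values and peptides disagree on the number of peptides")
  }
  if (is.null(rownames(values))) rownames(values) <- peptides$peptide_id
  if (is.null(datasets)) {
    if (is.null(colnames(values))) {
      colnames(values) <- paste0("dataset", seq_len(ncol(values)))
    }
    datasets <- dataset_meta(dataset_id = colnames(values))
  } else {
    datasets <- as.data.frame(datasets, stringsAsFactors = FALSE)
    datasets <- validate_dataset_meta(datasets)
    if (is.null(colnames(values))) colnames(values) <- datasets$dataset_id
  }
  if (!identical(colnames(values), datasets$dataset_id)) {
    stop("dataset metadata does not match the PV matrix columns")
  }
  finite_bad <- !is.na(values) & (!is.finite(values) | values < 0)
  if (any(finite_bad)) {
    idx <- which(finite_bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid PV (negative or non-finite) for peptide '%s' in dataset '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  structure(list(values = values, peptides = peptides, datasets = datasets),
            class = "pv_matrix")
}

#' Per-dataset metadata for AP-MS experiments
#'
#' @param dataset_id character vector of unique dataset identifiers.
#' @param target_proteins character vector of `;`-separated accessions of
#'   the primary target protein(s) of each AP (empty for IgG controls).
#' @param antibody_id antibody identifier per dataset.
#' @param control_kind one of `"none"` (target AP), `"igg"`
#'   (preimmunization IgG control), `"depletion"` (target-depleted
#'   solubilisate), `"knockout"`, `"sh_control"`.
#' @param replicate_group label grouping replicate APs.
#' @param serial_position `"first"`/`"second"` for the two steps of a
#'   serial (two-step) AP, `"not_serial"` otherwise.
#' @return data.frame with one row per dataset.
#' @export
dataset_meta <- function(dataset_id,
                         target_proteins = "",
                         antibody_id = NA_character_,
                         control_kind = "none",
                         replicate_group = dataset_id,
                         serial_position = "not_serial") {
  meta <- data.frame(dataset_id = as.character(dataset_id),
                     target_proteins = target_proteins,
                     antibody_id = antibody_id,
                     control_kind = control_kind,
                     replicate_group = replicate_group,
                     serial_position = serial_position,
                     stringsAsFactors = FALSE)
  validate_dataset_meta(meta)
}

validate_dataset_meta <- function(meta) {
  needed <- c("dataset_id", "target_proteins", "antibody_id",
              "control_kind", "replicate_group", "serial_position")
  for (col in setdiff(needed, names(meta))) {
    meta[[col]] <- switch(col,
                          target_proteins = "",
                          control_kind = "none",
                          serial_position = "not_serial",
                          replicate_group = meta$dataset_id,
                          NA_character_)
  }
  if (anyDuplicated(meta$dataset_id)) stop("dataset ids must be unique")
  kinds <- c("none", "igg", "depletion", "knockout", "sh_control")
  if (!all(meta$control_kind %in% kinds)) {
    stop("control_kind must be one of: ", paste(kinds, collapse = ", "))
  }
  pos <- c("first", "second", "not_serial")
  if (!all(meta$serial_position %in% pos)) {
    stop("serial_position must be one of: ", paste(pos, collapse = ", "))
  }
  meta$target_proteins[is.na(meta$target_proteins)] <- ""
  empty_target <- !nzchar(meta$target_proteins)
  bad <- empty_target & meta$control_kind %in% c("depletion", "knockout",
                                                 "sh_control")
  if (any(bad)) {
    stop("control dataset '", meta$dataset_id[which(bad)[1]],
         "' must name the depleted/knocked-out target; only IgG controls ",
         "have no target")
  }
  meta[needed]
}

target_ids <- function(meta_row) {
  x <- strsplit(meta_row, ";", fixed = TRUE)[[1]]
  x[nzchar(x)]
}

#' @export
print.pv_matrix <- function(x, ...) {
  cat(sprintf("pv_matrix: %d peptides (%d proteins) x %d datasets, %.1f%% missing\n",
              nrow(x$values), length(unique(x$peptides$protein_id)),
              ncol(x$values), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.pv_matrix <- function(x) dim(x$values)

#' Read and write peptide peak-volume tables
#'
#' Tab-separated UTF-8 text with `.` decimal separator, one header row and
#' columns `protein_id`, `sequence`, optionally `is_isoform_specific`,
#' followed by one PV column per dataset (the minimal MaxQuant-style
#' evidence schema consumed here). Empty cells are missing values; PVs are
#' serialized with 6 significant digits, below measurement precision.
#'
#' @param path file path.
#' @param datasets optional dataset metadata (see [dataset_meta()]).
#' @return `read_pv_table()` returns a [pv_matrix()];
#'   `write_pv_table()` returns `path` invisibly.
#' @export
read_pv_table <- function(path, datasets = NULL) {
  if (!file.exists(path)) stop("PV table not found: ", path)
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = "")
  required <- c("protein_id", "sequence")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("malformed PV table header, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  has_flag <- "is_isoform_specific" %in% names(tab)
  value_cols <- setdiff(names(tab), c(required, "is_isoform_specific", "peptide_id"))
  if (length(value_cols) == 0) stop("PV table has no dataset columns")
  values <- matrix(NA_real_, nrow(tab), length(value_cols),
                   dimnames = list(NULL, value_cols))
  for (j in seq_along(value_cols)) {
    raw <- tab[[value_cols[j]]]
    num <- suppressWarnings(as.numeric(raw))
    bad_parse <- !is.na(raw) & is.na(num)
    if (any(bad_parse)) {
      stop(sprintf("non-numeric PV '%s' in column '%s', row %d",
                   raw[which(bad_parse)[1]], value_cols[j], which(bad_parse)[1]))
    }
    neg <- !is.na(num) & num < 0
    if (any(neg)) {
      stop(sprintf("negative PV in column '%s', row %d",
                   value_cols[j], which(neg)[1]))
    }
    values[, j] <- num
  }
  peptides <- data.frame(
    peptide_id = if ("peptide_id" %in% names(tab)) tab$peptide_id else tab$sequence,
    protein_id = tab$protein_id,
    sequence = tab$sequence,
    is_isoform_specific = if (has_flag) as.logical(tab$is_isoform_specific) else TRUE,
    stringsAsFactors = FALSE)
  rownames(values) <- peptides$peptide_id
  pv_matrix(values, peptides, datasets)
}

#' @rdname read_pv_table
#' @param x a `pv_matrix`.
#' @export
write_pv_table <- function(x, path) {
  stopifnot(inherits(x, "pv_matrix"))
  vals <- apply(x$values, 2, function(col) {
    out <- ifelse(is.na(col), "", formatC(signif(col, 6), format = "g",
                                          digits = 6))
    trimws(out)
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(NULL, colnames(x$values)))
  out <- cbind(data.frame(protein_id = x$peptides$protein_id,
                          sequence = x$peptides$sequence,
                          is_isoform_specific = x$peptides$is_isoform_specific,
                          stringsAsFactors = FALSE),
               as.data.frame(vals, stringsAsFactors = FALSE, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write QconCAT-style calibration tables
#'
#' Calibration values (arbitrary units, > 0) from MS analyses of fusion
#' protein standards, keyed by protein and dataset. Tab-separated with
#' columns `protein_id`, `dataset_id`, `value`.
#'
#' @param path file path.
#' @return data.frame with columns `protein_id`, `dataset_id`, `value`.
#' @export
read_calibration_table <- function(path) {
  if (!file.exists(path)) stop("calibration table not found: ", path)
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  missing_cols <- setdiff(c("protein_id", "dataset_id", "value"), names(tab))
  if (length(missing_cols) > 0) {
    stop("malformed calibration table, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(tab$value) | tab$value < 0)) {
    stop("calibration values must be finite and >= 0")
  }
  tab[c("protein_id", "dataset_id", "value")]
}

#' @rdname read_calibration_table
#' @param cal calibration data.frame.
#' @export
write_calibration_table <- function(cal, path) {
  write.table(cal, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a numeric matrix as a tab-separated table
#'
#' Used for all derived protein-level tables (profiles, abundances,
#' heat-map matrices). Row names go into a leading `protein_id` column;
#' values are serialized with 6 significant digits, empty string = missing.
#'
#' @param m numeric matrix with row and column names.
#' @param path file path.
#' @param id_col name for the row-identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "protein_id") {
  vals <- apply(m, 2, function(col) {
    ifelse(is.na(col), "", trimws(formatC(signif(col, 6), format = "g",
                                          digits = 6)))
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(NULL, colnames(m)))
  out <- cbind(setNames(data.frame(rownames(m), stringsAsFactors = FALSE), id_col),
               as.data.frame(vals, stringsAsFactors = FALSE, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, id_col = "protein_id") {
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    na.strings = "")
  if (!id_col %in% names(tab)) stop("missing id column '", id_col, "' in ", path)
  m <- as.matrix(tab[setdiff(names(tab), id_col)])
  rownames(m) <- tab[[id_col]]
  storage.mode(m) <- "double"
  m
}
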