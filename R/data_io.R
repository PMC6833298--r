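# PSM table schema and interchange format.
#
# One row per identified, quantified peptide-spectrum match (PSM). The
# light and heavy isotope clusters each carry four peaks (mono-isotopic
# + three isotopologues); the scan triplet carries the first and second
# light/heavy peak intensities for the identification scan (scan 0) and
# its two retention-time neighbors (scans 1, 2), following the extracted
# ion chromatogram.

#' Column names of the PSM interchange table
#'
#' @param with_tp Include the optional theoretical-pattern columns
#'   `TP_0..TP_3`.
#' @return Character vector of column names, in schema order.
#' @export
psm_schema <- function(with_tp = FALSE) {
  cols <- c(
    "spectrum_id", "peptide", "protein_id", "charge", "M_t", "M_e",
    "asap_ratio",
    paste0("EP_L", 0:3), paste0("EP_H", 0:3),
    "M_pp", "noise_peaks",
    paste0("L1_", 0:2), paste0("L2_", 0:2),
    paste0("H1_", 0:2), paste0("H2_", 0:2)
  )
  if (with_tp) cols <- c(cols, paste0("TP_", 0:3))
  cols
}

psm_numeric_cols <- function(with_tp = FALSE) {
  setdiff(psm_schema(with_tp), c("spectrum_id", "peptide", "protein_id", "noise_peaks"))
}

#' Construct a PSM dataset
#'
#' Validates the record invariants and attaches dataset-level metadata.
#' `noise_peaks` must be a list column of numeric vectors (detected peak
#' intensities in the precursor's spectrum region, used for noise
#' estimation).
#'
#' @param records A data frame with the columns of [psm_schema()]
#'   (optionally plus `TP_0..TP_3` and a logical `ground_truth_good`).
#' @param sample_label Optional label for the mix, e.g. `"1:1"`.
#' @param true_log2_ratio Optional known log2 heavy:light ratio of the mix.
#' @return A `psm_dataset`, a data frame subclass.
#' @export
new_psm_dataset <- function(records, sample_label = NULL, true_log2_ratio = NULL) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(psm_schema(), names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records$spectrum_id)) {
    stop("spectrum_id values must be unique", call. = FALSE)
  }
  if (!is.list(records$noise_peaks)) {
    stop("noise_peaks must be a list column of numeric vectors", call. = FALSE)
  }
  if (any(!is.na(records$M_t) & records$M_t <= 0)) {
    stop("M_t must be > 0", call. = FALSE)
  }
  if (any(!is.na(records$charge) & records$charge < 1)) {
    stop("charge must be >= 1", call. = FALSE)
  }
  intens <- c(paste0("EP_L", 0:3), paste0("EP_H", 0:3), "M_pp",
              paste0("L1_", 0:2), paste0("L2_", 0:2),
              paste0("H1_", 0:2), paste0("H2_", 0:2))
  for (cl in intens) {
    if (any(!is.na(records[[cl]]) & records[[cl]] < 0)) {
      stop("negative intensity in column ", cl, call. = FALSE)
    }
  }
  structure(records,
            class = c("psm_dataset", "data.frame"),
            sample_label = sample_label,
            true_log2_ratio = true_log2_ratio)
}

#' @export
print.psm_dataset <- function(x, ...) {
  lab <- attr(x, "sample_label")
  cat("PSM dataset: ", nrow(x), " spectra",
      if (!is.null(lab)) paste0(" [", lab, "]"), "\n", sep = "")
  cat("  quantified (asap_ratio present): ", sum(!is.na(x$asap_ratio)), "\n", sep = "")
  invisible(x)
}

parse_numeric_column <- function(x, col) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("non-numeric value '%s' in column %s, row %d",
                 x[bad[1]], col, bad[1]), call. = FALSE)
  }
  out
}

#' Read a PSM table from CSV/TSV
#'
#' Missing values are encoded as empty fields; for `asap_ratio` the
#' sentinel `-1` is additionally accepted as "missing" (an unquantified
#' spectrum). The `noise_peaks` field holds semicolon-joined intensities.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"tsv"`.
#' @param sample_label,true_log2_ratio Optional dataset metadata.
#' @return A [new_psm_dataset()] with rows in file order.
#' @export
read_psm_table <- function(path, dialect = c("csv", "tsv"),
                           sample_label = NULL, true_log2_ratio = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(psm_schema(), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  has_tp <- all(paste0("TP_", 0:3) %in% names(raw))
  df <- data.frame(spectrum_id = raw$spectrum_id,
                   peptide = raw$peptide,
                   protein_id = raw$protein_id,
                   stringsAsFactors = FALSE)
  for (cl in psm_numeric_cols(has_tp)) df[[cl]] <- parse_numeric_column(raw[[cl]], cl)
  df$asap_ratio[!is.na(df$asap_ratio) & df$asap_ratio == -1] <- NA_real_
  df$noise_peaks <- lapply(raw$noise_peaks, function(s) {
    s <- trimws(s)
    if (is.na(s) || s == "") return(numeric(0))
    parse_numeric_column(strsplit(s, ";", fixed = TRUE)[[1]], "noise_peaks")
  })
  df <- df[, psm_schema(has_tp)[psm_schema(has_tp) %in% names(df)], drop = FALSE]
  if (has_tp) df <- df[, c(psm_schema(), paste0("TP_", 0:3))]
  new_psm_dataset(df, sample_label = sample_label, true_log2_ratio = true_log2_ratio)
}

#' Write a PSM table to CSV/TSV
#'
#' Numeric fields are written with 15 significant digits so that a
#' read/write round trip is the identity up to floating-point formatting.
#' Missing values become empty fields.
#'
#' @param dataset A `psm_dataset`.
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(dataset, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!is.data.frame(dataset) || nrow(dataset) == 0) {
    stop("dataset must be a non-empty data frame", call. = FALSE)
  }
  has_tp <- all(paste0("TP_", 0:3) %in% names(dataset))
  out <- data.frame(spectrum_id = dataset$spectrum_id,
                    peptide = dataset$peptide,
                    protein_id = dataset$protein_id,
                    stringsAsFactors = FALSE)
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 15, trim = TRUE,
                                                 scientific = FALSE))
  for (cl in psm_numeric_cols(has_tp)) out[[cl]] <- fmt(dataset[[cl]])
  out$noise_peaks <- vapply(dataset$noise_peaks, function(v) {
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE), collapse = ";")
  }, character(1))
  out <- out[, psm_schema(has_tp)]
  tryCatch(
    utils::write.table(out, path, sep = if (dialect == "csv") "," else "\t",
                       row.names = FALSE, quote = TRUE, na = ""),
    error = function(e) {
      stop("cannot write PSM table to ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  invisible(path)
}

#' Theoretical isotope pattern from peptide mass
#'
#' Poisson approximation to the averagine isotope distribution: the
#' relative abundance of the i-th isotopologue is
#' `lambda^i / i!` with `lambda = c * M_t`, normalized so the
#' mono-isotopic abundance `TP_0` is 1. The default `c` makes
#' `TP_1/TP_0` match the expected number of heavy-atom substitutions per
#' dalton of averagine-like peptide.
#'
#' @param M_t Theoretical neutral peptide mass in Da (scalar or vector).
#' @param c_per_da Averagine-derived rate constant per Da.
#' @return For scalar input, a named numeric vector `TP_0..TP_3`; for
#'   vector input a matrix with those columns.
#' @export
compute_theoretical_pattern <- function(M_t, c_per_da = 4.938e-4) {
  if (any(is.na(M_t)) || any(M_t <= 0)) stop("M_t must be > 0", call. = FALSE)
  lambda <- c_per_da * M_t
  tp <- cbind(1, lambda, lambda^2 / 2, lambda^3 / 6)
  colnames(tp) <- paste0("TP_", 0:3)
  if (length(M_t) == 1) tp[1, ] else tp
}

# Per-record theoretical patterns: TP columns in the table take
# precedence over the Poisson/averagine approximation.
theoretical_patterns <- function(dataset, c_per_da = 4.938e-4) {
  tp_cols <- paste0("TP_", 0:3)
  if (all(tp_cols %in% names(dataset))) {
    tp <- as.matrix(as.data.frame(dataset)[, tp_cols])
  } else {
    tp <- compute_theoretical_pattern(dataset$M_t, c_per_da)
    if (is.null(dim(tp))) tp <- matrix(tp, nrow = 1, dimnames = list(NULL, tp_cols))
  }
  tp
}
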