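# Evaluation of ratio concentration before and after filtering.
#
# For log-scale ratio data the ordinary CV = sd/mean is meaningless; the
# appropriate coefficient of variation for base-2 logarithmic data is
#   CV = sqrt(2^((ln 2) * sigma^2) - 1)
# with sigma the SD of the log2 ratios — the exact CV of a log-normal
# variable 2^X, X ~ N(mu, sigma^2).

#' Coefficient of variation for base-2 logarithmic ratio data
#'
#' @param log2_ratios Numeric vector of log2 ratios (>= 2 values).
#' @return `sqrt(2^((ln 2) * sigma^2) - 1)` with `sigma` the sample SD.
#' @export
log_ratio_cv <- function(log2_ratios) {
  log2_ratios <- log2_ratios[!is.na(log2_ratios)]
  if (length(log2_ratios) < 2) stop("need at least 2 values", call. = FALSE)
  s2 <- var(log2_ratios)
  sqrt(2^(log(2) * s2) - 1)
}

#' Summarize a set of quantitative ratios
#'
#' Valid (present, positive) ratios are log2-transformed; the summary
#' reports their count, mean, KDE mode (same estimator as the mass-tag
#' rule) and log-scale CV.
#'
#' @param ratios Heavy-light ratios; `NA`/non-positive entries are
#'   excluded and counted.
#' @param config A [tag_config()] (KDE settings for the mode).
#' @return One-row data frame: `n`, `mean`, `mode`, `cv`, `n_invalid`.
#' @export
summarize_ratios <- function(ratios, config = tag_config()) {
  valid <- !is.na(ratios) & ratios > 0
  if (sum(valid) < 2) stop("need at least 2 valid ratios", call. = FALSE)
  x <- log2(ratios[valid])
  data.frame(n = sum(valid),
             mean = mean(x),
             mode = estimate_mode(x, config),
             cv = log_ratio_cv(x),
             n_invalid = sum(!valid))
}

#' CV as a function of the fraction of spectra filtered out
#'
#' For each fraction f, the `floor(f * n)` lowest-scoring records are
#' dropped (ties broken by record order) and the remainder summarized.
#' f = 0 reproduces the unfiltered summary.
#'
#' @param scores Quality scores, aligned with `ratios`.
#' @param ratios Heavy-light ratios.
#' @param fractions Fractions in `[0, 1)`.
#' @param config A [tag_config()].
#' @return Data frame with one row per fraction: `fraction`,
#'   `n_retained`, and the [summarize_ratios()] columns.
#' @export
filter_sweep <- function(scores, ratios, fractions = seq(0, 0.5, by = 0.05),
                         config = tag_config()) {
  if (length(scores) != length(ratios)) {
    stop("scores and ratios must be aligned", call. = FALSE)
  }
  stopifnot(all(fractions >= 0), all(fractions < 1))
  n <- length(scores)
  ord <- order(scores, seq_len(n)) # lowest first, ties by record order
  rows <- lapply(fractions, function(f) {
    drop_n <- floor(f * n)
    keep <- if (drop_n > 0) ord[-seq_len(drop_n)] else seq_len(n)
    cbind(data.frame(fraction = f, n_retained = length(keep)),
          summarize_ratios(ratios[keep], config))
  })
  do.call(rbind, rows)
}

#' Protein-level ratio summaries
#'
#' Groups kept records by protein and reports peptide count, mean and SD
#' of the raw (untransformed) ratios. Proteins with no kept peptide are
#' omitted with a message.
#'
#' @param records A `psm_dataset` (needs `protein_id` and `asap_ratio`).
#' @param keep_flags Logical vector: which records survive filtering
#'   (default: all).
#' @return Data frame: `protein_id`, `n_peptides`, `ratio_mean`,
#'   `ratio_sd` (0 when a single peptide).
#' @export
protein_level_summary <- function(records, keep_flags = rep(TRUE, nrow(records))) {
  stopifnot(length(keep_flags) == nrow(records))
  all_prot <- unique(records$protein_id)
  kept <- records[keep_flags & !is.na(records$asap_ratio), , drop = FALSE]
  dropped <- setdiff(all_prot, unique(kept$protein_id))
  if (length(dropped) > 0) {
    message(length(dropped), " protein(s) with no kept quantified peptide omitted")
  }
  if (nrow(kept) == 0) {
    return(data.frame(protein_id = character(0), n_peptides = integer(0),
                      ratio_mean = numeric(0), ratio_sd = numeric(0)))
  }
  groups <- split(kept$asap_ratio, kept$protein_id)
  out <- data.frame(protein_id = names(groups),
                    n_peptides = vapply(groups, length, integer(1)),
                    ratio_mean = vapply(groups, mean, numeric(1)),
                    ratio_sd = vapply(groups, function(v) {
                      if (length(v) < 2) 0 else sd(v)
                    }, numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$protein_id), , drop = FALSE]
}

#' Fraction of a sample within k sample-SDs of the sample mean
#'
#' Chebyshev's inequality guarantees this is at least `1 - 1/k^2` for
#' any distribution (8/9 at k = 3). A constant sample has coverage 1.
#'
#' @param values Numeric vector (>= 2 values).
#' @param k Number of SDs.
#' @return Fraction in `[0, 1]`.
#' @export
chebyshev_coverage <- function(values, k = 3) {
  stopifnot(length(values) >= 2, k > 0)
  s <- sd(values)
  if (s == 0) return(1)
  mean(abs(values - mean(values)) <= k * s)
}
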