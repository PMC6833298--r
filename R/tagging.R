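# Automatic training-tag generation.
#
# Two rules, combined by AND:
#  * ratio-tag: a spectrum's log2 quantitative ratio must fall within
#    mean +/- 3 SD of the sample's log2 ratios (Chebyshev's inequality
#    guarantees this keeps at least 8/9 of the data);
#  * mass-tag: the standardized mass deviation must fall within a fixed
#    window (default +/- 0.5 standardized units) around the KDE mode of
#    the standardized deviations — the mode, not zero, because mass
#    measurement carries a systematic bias.

#' Tagging configuration
#'
#' @param sigma_multiplier Half-width of the ratio-tag window in SDs.
#' @param mass_threshold Half-width of the mass-tag window, in
#'   standardized units.
#' @param kde_bandwidth_rule Bandwidth rule for the KDE mode estimator:
#'   `"scott"` ([stats::bw.nrd()]) or `"silverman"` ([stats::bw.nrd0()]).
#' @param kde_grid_points Number of KDE evaluation points.
#' @return A `tag_config` list.
#' @export
tag_config <- function(sigma_multiplier = 3, mass_threshold = 0.5,
                       kde_bandwidth_rule = c("scott", "silverman"),
                       kde_grid_points = 512L) {
  kde_bandwidth_rule <- match.arg(kde_bandwidth_rule)
  stopifnot(sigma_multiplier > 0, mass_threshold > 0, kde_grid_points >= 16)
  structure(list(sigma_multiplier = sigma_multiplier,
                 mass_threshold = mass_threshold,
                 kde_bandwidth_rule = kde_bandwidth_rule,
                 kde_grid_points = as.integer(kde_grid_points)),
            class = "tag_config")
}

#' Ratio-tag: 3-sigma window on log2 quantitative ratios
#'
#' Records with a missing or non-positive ratio are tagged `FALSE` and
#' excluded from the mean/SD estimation. If the valid log2 ratios have
#' zero spread, every valid record is tagged `TRUE`.
#'
#' @param ratios Per-record heavy-light ratios (`NA` = missing).
#' @param config A [tag_config()].
#' @return Logical vector, one tag per record.
#' @export
ratio_tag <- function(ratios, config = tag_config()) {
  valid <- !is.na(ratios) & ratios > 0
  if (sum(valid) < 2) stop("need at least 2 valid ratios to tag", call. = FALSE)
  x <- log2(ratios[valid])
  mu <- mean(x)
  s <- sd(x)
  k <- config$sigma_multiplier
  tags <- rep(FALSE, length(ratios))
  tags[valid] <- if (s == 0) TRUE else x >= mu - k * s & x <= mu + k * s
  tags
}

#' Mode of a sample via Gaussian kernel density estimation
#'
#' Argmax of a Gaussian KDE evaluated on a regular grid spanning the
#' data range. Constant input returns that constant.
#'
#' @param values Numeric vector (>= 2 values).
#' @param config A [tag_config()] (bandwidth rule and grid size).
#' @return The estimated mode (a single number).
#' @export
estimate_mode <- function(values, config = tag_config()) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (length(unique(values)) == 1) return(values[1])
  bw <- switch(config$kde_bandwidth_rule,
               scott = bw.nrd(values),
               silverman = bw.nrd0(values))
  d <- density(values, bw = bw, n = config$kde_grid_points,
               from = min(values), to = max(values))
  d$x[which.max(d$y)]
}

#' Mass-tag: window around the mode of standardized mass deviations
#'
#' Mass deviations are standardized (`z = (x - mean)/SD`), the KDE mode
#' `m` of the z-scores is located, and a record is tagged `TRUE` iff its
#' z-score lies in the closed interval `[m - t, m + t]` with `t` the
#' configured threshold. Zero spread degenerates to all-`TRUE` with a
#' warning.
#'
#' @param mass_devs Per-record mass deviations, ppm.
#' @param config A [tag_config()].
#' @return Logical vector of tags.
#' @export
mass_tag <- function(mass_devs, config = tag_config()) {
  if (length(mass_devs) < 2) stop("need at least 2 records", call. = FALSE)
  s <- sd(mass_devs)
  if (is.na(s) || s == 0) {
    warning("zero spread in mass deviations; all records mass-tagged TRUE")
    return(rep(TRUE, length(mass_devs)))
  }
  z <- (mass_devs - mean(mass_devs)) / s
  m <- estimate_mode(z, config)
  z >= m - config$mass_threshold & z <= m + config$mass_threshold
}

#' Combine ratio- and mass-tags
#'
#' The final training tag is the elementwise AND: a spectrum is a
#' positive example only if both rules hold.
#'
#' @param ratio_tags,mass_tags Logical vectors of equal length.
#' @param ground_truth Optional logical vector (synthetic data only).
#' @return A data frame with columns `ratio_tag`, `mass_tag`, `final_tag`
#'   (and `ground_truth` if supplied).
#' @export
combine_tags <- function(ratio_tags, mass_tags, ground_truth = NULL) {
  if (length(ratio_tags) != length(mass_tags)) {
    stop("ratio_tags and mass_tags must have equal length", call. = FALSE)
  }
  out <- data.frame(ratio_tag = ratio_tags, mass_tag = mass_tags,
                    final_tag = ratio_tags & mass_tags)
  if (!is.null(ground_truth)) {
    stopifnot(length(ground_truth) == length(ratio_tags))
    out$ground_truth <- ground_truth
  }
  out
}

#' Tag a PSM dataset for classifier training
#'
#' Convenience wrapper: applies [ratio_tag()] to the dataset's
#' `asap_ratio` column and [mass_tag()] to its mass deviations, and
#' combines them.
#'
#' @param dataset A `psm_dataset`.
#' @param config A [tag_config()].
#' @return [combine_tags()] output with a leading `spectrum_id` column.
#' @export
quality_tags <- function(dataset, config = tag_config()) {
  rt <- ratio_tag(dataset$asap_ratio, config)
  mt <- mass_tag(mass_deviation(dataset$M_t, dataset$M_e), config)
  gt <- if ("ground_truth_good" %in% names(dataset)) dataset$ground_truth_good
  cbind(data.frame(spectrum_id = dataset$spectrum_id, stringsAsFactors = FALSE),
        combine_tags(rt, mt, gt))
}
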