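# Synthetic SILAC PSM generator with known ground-truth quality.
#
# Emulates the statistical structure of a SILAC mix analyzed by LC-MS:
# Poisson/averagine isotope patterns for the light cluster and a
# K (+8.014199 Da) or R (+10.008269 Da) shifted heavy cluster, a 3-scan
# elution profile, mass deviations with a small systematic bias, and a
# log-normal quantitative-ratio error. A configurable fraction of
# spectra is corrupted by one of four mechanisms, each aimed at the
# feature meant to detect it:
#   pattern    -> isotope/scan pattern distortion (IsoDev, SID)
#   preceding  -> co-eluting contaminant just before the mono peak
#                 (PPR near 1)
#   noise      -> raised noise floor (low S/N)
#   ratio      -> quantification blow-up plus scan-profile distortion
# Corrupted spectra also draw heavy-tailed mass deviations and inflated
# ratio noise, so the auto-tagging rules can discover them.

#' Synthetic-data configuration
#'
#' @param n_spectra Number of spectra to generate.
#' @param true_ratio True heavy:light mix ratio (1 for a 1:1 mix).
#' @param bad_fraction Fraction of corrupted (low-quality) spectra.
#' @param mass_bias Systematic offset of good spectra's mass deviation,
#'   in units of `ppm_sd` (the standardized mode of the mass-deviation
#'   distribution sits near this value).
#' @param ppm_sd SD of good spectra's mass deviation, ppm.
#' @param bad_ppm_scale Scale multiplier of the heavy-tailed (Student-t,
#'   3 df) mass deviation of corrupted spectra, in units of `ppm_sd`.
#' @param intensity_scale Median mono-isotopic peak intensity,
#'   arbitrary units.
#' @param elution_shape Relative XIC apex intensities of scans 0..2.
#' @param corruption_weights Named sampling weights for the corruption
#'   menu (`pattern`, `preceding`, `noise`, `ratio`).
#' @param ratio_noise_sd_good,ratio_noise_sd_bad SD of the log2
#'   quantification error for good / corrupted spectra.
#' @param snr_good,snr_bad Typical signal-to-noise of good spectra and
#'   of noise-corrupted spectra.
#' @param seed Integer seed; the dataset is a deterministic function of
#'   the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_spectra = 3000L, true_ratio = 1, bad_fraction = 0.15,
                       mass_bias = -0.13, ppm_sd = 2, bad_ppm_scale = 8,
                       intensity_scale = 1e6,
                       elution_shape = c(1, 0.75, 0.5),
                       corruption_weights = c(pattern = 1, preceding = 1,
                                              noise = 1, ratio = 1),
                       ratio_noise_sd_good = 0.3, ratio_noise_sd_bad = 1.2,
                       snr_good = 20, snr_bad = 1.5, seed = 1L) {
  stopifnot(n_spectra >= 1, true_ratio > 0,
            bad_fraction >= 0, bad_fraction < 1,
            ppm_sd >= 0, ratio_noise_sd_good >= 0, ratio_noise_sd_bad >= 0,
            length(elution_shape) == 3, all(elution_shape > 0),
            all(corruption_weights >= 0), sum(corruption_weights) > 0)
  structure(as.list(environment()), class = "sim_config")
}

# Tryptic-like peptides: the C-terminal residue is the labeled amino
# acid, lysine (K, +8.014199 Da) or arginine (R, +10.008269 Da).
silac_label_shifts <- c(K = 8.014199, R = 10.008269)

random_peptides <- function(n, terminal) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste0(paste(sample(aa, sample(7:19, 1), replace = TRUE), collapse = ""),
           terminal[i])
  }, character(1))
}

#' Generate a synthetic SILAC PSM dataset
#'
#' @param config A [sim_config()].
#' @return A `psm_dataset` in the standard schema, with `TP_0..TP_3`
#'   columns and an extra logical column `ground_truth_good`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_spectra
  n_bad <- round(config$bad_fraction * n)
  bad <- rep(FALSE, n)
  if (n_bad > 0) bad[sample.int(n, n_bad)] <- TRUE

  M_t <- runif(n, 700, 3500)
  charge <- sample(2:3, n, replace = TRUE)
  tp <- compute_theoretical_pattern(M_t)
  if (is.null(dim(tp))) tp <- matrix(tp, nrow = 1,
                                     dimnames = list(NULL, paste0("TP_", 0:3)))
  tp_ratio <- tp / tp[, 1]

  n_prot <- max(1L, round(n / 8))
  protein_id <- sample(sprintf("P%04d", seq_len(n_prot)), n, replace = TRUE)

  # cluster intensities proportional to the theoretical pattern
  a_light <- rlnorm(n, log(config$intensity_scale), 0.8)
  a_heavy <- a_light * config$true_ratio
  obs_noise <- function() exp(matrix(rnorm(n * 4, 0, 0.05), n, 4))
  ep_l <- a_light * tp_ratio * obs_noise()
  ep_h <- a_heavy * tp_ratio * obs_noise()

  which_corrupt <- rep(NA_character_, n)
  if (n_bad > 0) {
    menu <- names(config$corruption_weights)
    which_corrupt[bad] <- sample(menu, n_bad, replace = TRUE,
                                 prob = config$corruption_weights)
  }

  # pattern distortion: isotopologue peaks wander off the theoretical
  # pattern (the mono peaks stay, so the record still parses)
  pat <- bad & which_corrupt == "pattern"
  if (any(pat)) {
    ep_l[pat, 2:4] <- ep_l[pat, 2:4] * exp(matrix(rnorm(sum(pat) * 3, 0, 0.7),
                                                  sum(pat), 3))
    ep_h[pat, 2:4] <- ep_h[pat, 2:4] * exp(matrix(rnorm(sum(pat) * 3, 0, 0.7),
                                                  sum(pat), 3))
  }

  # scan triplet: scan 0 is the identification scan and repeats the
  # cluster's first two peaks exactly; neighbors follow the elution
  # shape with mild jitter
  scan_noise <- function(m) exp(matrix(rnorm(n * m, 0, 0.08), n, m))
  L1 <- cbind(ep_l[, 1], ep_l[, 1] %o% config$elution_shape[2:3] * scan_noise(2))
  L2 <- cbind(ep_l[, 2], ep_l[, 2] %o% config$elution_shape[2:3] * scan_noise(2))
  H1 <- cbind(ep_h[, 1], ep_h[, 1] %o% config$elution_shape[2:3] * scan_noise(2))
  H2 <- cbind(ep_h[, 2], ep_h[, 2] %o% config$elution_shape[2:3] * scan_noise(2))

  # ratio blow-up corruption also disturbs the neighboring scans' XIC
  rat <- bad & which_corrupt == "ratio"
  if (any(rat)) {
    m <- sum(rat)
    L2[rat, 2:3] <- L2[rat, 2:3] * exp(matrix(rnorm(m * 2, 0, 0.8), m, 2))
    H2[rat, 2:3] <- H2[rat, 2:3] * exp(matrix(rnorm(m * 2, 0, 0.8), m, 2))
  }

  # occasionally a neighbor scan is simply not found in corrupted data
  miss_scan <- bad & runif(n) < 0.15
  if (any(miss_scan)) {
    for (i in which(miss_scan)) {
      j <- sample(2:3, 1)
      L1[i, j] <- L2[i, j] <- H1[i, j] <- H2[i, j] <- NA_real_
    }
  }

  # noise floor: good spectra sit well above it, noise-corrupted ones
  # barely clear it
  snr <- rlnorm(n, log(config$snr_good), 0.3)
  noi <- bad & which_corrupt == "noise"
  snr[noi] <- rlnorm(sum(noi), log(config$snr_bad), 0.3)
  noise_peaks <- lapply(seq_len(n), function(i) {
    rlnorm(25, log(ep_l[i, 1] / snr[i]), 0.5)
  })

  # preceding peak: usually absent or tiny; contamination puts a peak of
  # comparable size right before the mono peak
  M_pp <- ifelse(runif(n) < 0.7, NA_real_, runif(n, 0.01, 0.15) * ep_l[, 1])
  pre <- bad & which_corrupt == "preceding"
  M_pp[pre] <- ep_l[pre, 1] * runif(sum(pre), 0.7, 1.3)

  # mass deviation: tight and slightly biased for good spectra,
  # heavy-tailed for corrupted ones
  ppm <- config$mass_bias * config$ppm_sd + rnorm(n, 0, config$ppm_sd)
  ppm[bad] <- config$mass_bias * config$ppm_sd +
    config$bad_ppm_scale * config$ppm_sd * rt(sum(bad), df = 3)
  M_e <- M_t * (1 - ppm / 1e6)

  # estimated quantitative ratio
  eps <- rnorm(n, 0, config$ratio_noise_sd_good)
  eps[bad] <- rnorm(sum(bad), 0, config$ratio_noise_sd_bad)
  asap <- config$true_ratio * 2^eps
  if (any(rat)) {
    asap[rat] <- asap[rat] *
      2^(sample(c(-1, 1), sum(rat), replace = TRUE) * runif(sum(rat), 1.5, 3))
  }

  label <- sample(names(silac_label_shifts), n, replace = TRUE)
  df <- data.frame(spectrum_id = sprintf("S%06d", seq_len(n)),
                   peptide = random_peptides(n, label),
                   protein_id = protein_id,
                   charge = charge, M_t = M_t, M_e = M_e,
                   asap_ratio = asap,
                   stringsAsFactors = FALSE)
  colnames(ep_l) <- paste0("EP_L", 0:3)
  colnames(ep_h) <- paste0("EP_H", 0:3)
  df <- cbind(df, ep_l, ep_h)
  df$M_pp <- M_pp
  df$noise_peaks <- noise_peaks
  colnames(L1) <- paste0("L1_", 0:2); colnames(L2) <- paste0("L2_", 0:2)
  colnames(H1) <- paste0("H1_", 0:2); colnames(H2) <- paste0("H2_", 0:2)
  df <- cbind(df, L1, L2, H1, H2, tp)
  df$ground_truth_good <- !bad
  df$corruption <- which_corrupt

  new_psm_dataset(df,
                  sample_label = paste0(format(config$true_ratio), ":1 (heavy:light)"),
                  true_log2_ratio = log2(config$true_ratio))
}
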