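# The thirteen spectrum quality features.
#
# Feature order is fixed: MassDev, PPR, S/N, IsoDev_Light1..3,
# IsoDev_Heavy1..3, SID_sum_, SID_0_, SID_1_, SID_2_. SID features use
# -1 as the "missing scan" convention, so -1 is never a valid SID value
# of a present scan in the classifier's eyes.

#' Names of the thirteen quality features, in canonical order
#' @export
silac_feature_names <- function() {
  c("MassDev", "PPR", "S/N",
    paste0("IsoDev_Light", 1:3), paste0("IsoDev_Heavy", 1:3),
    "SID_sum_", "SID_0_", "SID_1_", "SID_2_")
}

# Sentinel for isotope deviations when a cluster's mono peak is missing:
# a deliberately large deviation, semantically "as bad as it gets".
ISODEV_MISSING_SENTINEL <- 9.99

#' Mass deviation in parts per million
#'
#' Relative deviation of the experimental (precursor mono-isotopic)
#' neutral mass from the theoretical peptide mass:
#' `(M_t - M_e) / M_t * 1e6`. The sign is preserved.
#'
#' @param M_t Theoretical neutral mass, Da.
#' @param M_e Experimental neutral mass, Da.
#' @return Deviation in ppm (vectorized).
#' @export
mass_deviation <- function(M_t, M_e) {
  if (any(is.na(M_t)) || any(M_t <= 0)) stop("M_t must be > 0", call. = FALSE)
  (M_t - M_e) / M_t * 1e6
}

#' Preceding peak ratio
#'
#' Intensity of the peak immediately before the light mono-isotopic peak
#' divided by the mono-isotopic intensity. A PPR close to one signals a
#' co-eluting contaminant; when no preceding peak was identified the
#' ratio is defined as zero.
#'
#' @param M_pp Preceding-peak intensity, `NA` when unidentified.
#' @param M_mp Mono-isotopic peak intensity (> 0).
#' @return PPR (vectorized).
#' @export
preceding_peak_ratio <- function(M_pp, M_mp) {
  if (any(is.na(M_mp)) || any(M_mp <= 0)) {
    stop("mono-isotopic intensity M_mp must be > 0", call. = FALSE)
  }
  out <- M_pp / M_mp
  out[is.na(M_pp)] <- 0
  out
}

#' Signal-to-noise ratio
#'
#' Mono-isotopic peak intensity over the noise level, where the noise
#' level is the median of the detected peak intensities in the
#' precursor's spectrum region.
#'
#' @param M_mp Mono-isotopic peak intensity.
#' @param spectrum_intensities Numeric vector of detected peak intensities.
#' @return S/N, a single number.
#' @export
signal_to_noise <- function(M_mp, spectrum_intensities) {
  if (length(spectrum_intensities) == 0) {
    stop("degenerate noise: empty spectrum intensity list", call. = FALSE)
  }
  noise <- median(spectrum_intensities)
  if (is.na(noise) || noise <= 0) {
    stop("degenerate noise: median intensity is not positive", call. = FALSE)
  }
  M_mp / noise
}

#' Isotope pattern deviations of one cluster
#'
#' For i = 1, 2, 3, the difference between the theoretical and
#' experimental isotopologue abundances relative to the mono peak:
#' `TP_i/TP_0 - EP_i/EP_0`. Applied to the light and heavy clusters
#' separately this yields the six IsoDev features.
#'
#' @param TP Theoretical pattern, length-4 (`TP_0 > 0`).
#' @param EP Experimental cluster intensities, length-4 (`EP_0 > 0`).
#' @return Numeric length-3 vector of deviations.
#' @export
isotope_deviations <- function(TP, EP) {
  stopifnot(length(TP) == 4, length(EP) == 4)
  if (is.na(TP[1]) || TP[1] <= 0) stop("TP_0 must be > 0", call. = FALSE)
  if (is.na(EP[1]) || EP[1] <= 0) {
    stop(structure(class = c("silacqc_missing_mono", "error", "condition"),
                   list(message = "missing mono-isotopic peak (EP_0 <= 0)",
                        call = sys.call(-1))))
  }
  ep <- EP
  ep[is.na(ep)] <- 0
  TP[2:4] / TP[1] - ep[2:4] / ep[1]
}

#' Scan isotope pattern deviations
#'
#' For the identification scan (0) and its two neighboring LC scans
#' (1, 2), the pooled second-to-first peak ratio
#' `E_i = (L2_i + H2_i) / (L1_i + H1_i)` is compared with the reference
#' ratio `M_0`: `SID_i = (E_i - M_0) / M_0`. `SID_sum` uses the ratio of
#' the summed second peaks to the summed first peaks over the scans that
#' are present. A scan with any missing peak, or a non-positive
#' denominator, contributes `-1` and is excluded from the sums.
#'
#' @param L1,L2,H1,H2 Length-3 vectors: first/second light and heavy peak
#'   intensities for scans 0..2; `NA` marks a missing peak.
#' @param M_0 Reference second-to-first abundance ratio (> 0); the
#'   theoretical `TP_1/TP_0` of the identified peptide.
#' @return Named vector `(SID_0_, SID_1_, SID_2_, SID_sum_)`.
#' @export
scan_isotope_pattern_deviations <- function(L1, L2, H1, H2, M_0) {
  stopifnot(length(L1) == 3, length(L2) == 3, length(H1) == 3, length(H2) == 3)
  if (is.na(M_0) || M_0 <= 0) stop("M_0 must be > 0", call. = FALSE)
  M_0 <- unname(M_0)
  L1 <- unname(L1); L2 <- unname(L2); H1 <- unname(H1); H2 <- unname(H2)
  first <- L1 + H1
  second <- L2 + H2
  present <- !is.na(first) & !is.na(second) & first > 0
  sid <- rep(-1, 3)
  sid[present] <- (second[present] / first[present] - M_0) / M_0
  if (any(present)) {
    e_sum <- sum(second[present]) / sum(first[present])
    sid_sum <- (e_sum - M_0) / M_0
  } else {
    sid_sum <- -1
  }
  c(SID_0_ = sid[1], SID_1_ = sid[2], SID_2_ = sid[3], SID_sum_ = sid_sum)
}

#' Extract the thirteen quality features for every record
#'
#' Orchestrates [mass_deviation()], [preceding_peak_ratio()],
#' [signal_to_noise()], [isotope_deviations()] (light and heavy) and
#' [scan_isotope_pattern_deviations()]. The SID reference ratio `M_0` is
#' the theoretical `TP_1/TP_0` of each peptide. A record whose light or
#' heavy mono peak is missing receives the sentinel value 9.99 for the
#' three corresponding IsoDev features and is flagged low-confidence
#' rather than dropped.
#'
#' @param dataset A `psm_dataset`.
#' @param c_per_da Averagine rate constant for
#'   [compute_theoretical_pattern()], used when the table carries no
#'   `TP_0..TP_3` columns.
#' @return A data frame `spectrum_id` + the 13 feature columns (names
#'   from [silac_feature_names()]), with a logical attribute
#'   `low_confidence` marking flagged records.
#' @export
extract_features <- function(dataset, c_per_da = 4.938e-4) {
  stopifnot(is.data.frame(dataset), nrow(dataset) > 0)
  n <- nrow(dataset)
  tp <- theoretical_patterns(dataset, c_per_da)
  feats <- matrix(NA_real_, n, 13, dimnames = list(NULL, silac_feature_names()))
  low_conf <- logical(n)

  feats[, "MassDev"] <- mass_deviation(dataset$M_t, dataset$M_e)
  feats[, "PPR"] <- preceding_peak_ratio(dataset$M_pp, dataset$EP_L0)
  ep_l <- as.matrix(as.data.frame(dataset)[, paste0("EP_L", 0:3)])
  ep_h <- as.matrix(as.data.frame(dataset)[, paste0("EP_H", 0:3)])
  l1 <- as.matrix(as.data.frame(dataset)[, paste0("L1_", 0:2)])
  l2 <- as.matrix(as.data.frame(dataset)[, paste0("L2_", 0:2)])
  h1 <- as.matrix(as.data.frame(dataset)[, paste0("H1_", 0:2)])
  h2 <- as.matrix(as.data.frame(dataset)[, paste0("H2_", 0:2)])

  for (i in seq_len(n)) {
    feats[i, "S/N"] <- signal_to_noise(ep_l[i, 1], dataset$noise_peaks[[i]])
    for (side in c("Light", "Heavy")) {
      ep <- if (side == "Light") ep_l[i, ] else ep_h[i, ]
      cols <- paste0("IsoDev_", side, 1:3)
      dev <- tryCatch(isotope_deviations(tp[i, ], ep),
                      silacqc_missing_mono = function(e) NULL)
      if (is.null(dev)) {
        dev <- rep(ISODEV_MISSING_SENTINEL, 3)
        low_conf[i] <- TRUE
      }
      feats[i, cols] <- dev
    }
    m0 <- tp[i, 2] / tp[i, 1]
    feats[i, c("SID_0_", "SID_1_", "SID_2_", "SID_sum_")] <-
      scan_isotope_pattern_deviations(l1[i, ], l2[i, ], h1[i, ], h2[i, ], m0)[
        c("SID_0_", "SID_1_", "SID_2_", "SID_sum_")]
  }
  out <- data.frame(spectrum_id = dataset$spectrum_id, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (cl in silac_feature_names()) out[[cl]] <- feats[, cl]
  attr(out, "low_confidence") <- low_conf
  out
}

#' Feature data frame to numeric matrix in canonical order
#'
#' @param features Output of [extract_features()] (or any data frame with
#'   the 13 feature columns).
#' @return Numeric matrix, columns in [silac_feature_names()] order.
#' @export
feature_matrix <- function(features) {
  missing_cols <- setdiff(silac_feature_names(), names(features))
  if (length(missing_cols) > 0) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(as.data.frame(features, check.names = FALSE)[, silac_feature_names()])
  storage.mode(m) <- "double"
  m
}
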