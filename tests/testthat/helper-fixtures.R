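# Fixtures built in code.

# A perfectly clean dataset: experimental patterns exactly proportional
# to the theoretical ones, scan ratios exactly at M_0, no mass error,
# no preceding peak, flat noise floor of 50 (so S/N = EP_L0 / 50).
make_clean_dataset <- function(n = 5, M_t = seq(900, by = 150, length.out = n),
                               ratio = 1, base_intensity = 1000) {
  tp <- compute_theoretical_pattern(M_t)
  if (is.null(dim(tp))) tp <- matrix(tp, nrow = 1,
                                     dimnames = list(NULL, paste0("TP_", 0:3)))
  tpr <- tp / tp[, 1]
  ep_l <- base_intensity * tpr
  ep_h <- base_intensity * ratio * tpr
  shape <- c(1, 0.8, 0.6)
  df <- data.frame(spectrum_id = paste0("spec", seq_len(n)),
                   peptide = "SAMPLEPEPTIDEK", protein_id = "P1",
                   charge = 2, M_t = M_t, M_e = M_t, asap_ratio = ratio,
                   stringsAsFactors = FALSE)
  colnames(ep_l) <- paste0("EP_L", 0:3)
  colnames(ep_h) <- paste0("EP_H", 0:3)
  df <- cbind(df, ep_l, ep_h)
  df$M_pp <- NA_real_
  df$noise_peaks <- replicate(n, c(50, 50, 50), simplify = FALSE)
  for (i in 0:2) {
    df[[paste0("L1_", i)]] <- ep_l[, 1] * shape[i + 1]
    df[[paste0("L2_", i)]] <- ep_l[, 2] * shape[i + 1]
    df[[paste0("H1_", i)]] <- ep_h[, 1] * shape[i + 1]
    df[[paste0("H2_", i)]] <- ep_h[, 2] * shape[i + 1]
  }
  new_psm_dataset(df)
}

# Independent mode oracle: argmax of a fixed-width histogram.
hist_mode <- function(x, binwidth = 0.05) {
  breaks <- seq(min(x) - binwidth, max(x) + binwidth, by = binwidth)
  h <- hist(x, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

# A separable feature matrix with the canonical 13 columns: the class
# is a threshold on MassDev alone, which takes only two well-separated
# levels so that separability is unambiguous in every subsample.
make_separable <- function(n = 400, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n * 13), n, 13, dimnames = list(NULL, silac_feature_names()))
  x[, "MassDev"] <- ifelse(x[, "MassDev"] > 0.5, 0.9, 0.1)
  list(x = x, tags = x[, "MassDev"] > 0.5)
}

auc_of <- function(truth, score) {
  as.numeric(pROC::auc(pROC::roc(response = truth, predictor = score,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}
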