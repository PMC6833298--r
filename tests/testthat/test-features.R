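test_that("mass deviation is signed ppm relative to theoretical mass", {
  expect_equal(mass_deviation(1000, 1000), 0)
  expect_equal(mass_deviation(1000, 999.999), 1, tolerance = 1e-9)
  expect_equal(mass_deviation(500, 500.005), -10, tolerance = 1e-9)
  expect_error(mass_deviation(0, 1), "M_t")
  # ppm round trip: M_e = M_t * (1 - x ppm) recovers x
  for (x in c(-7.5, 0.1, 3, 25)) {
    expect_equal(mass_deviation(1234.5, 1234.5 * (1 - x * 1e-6)), x,
                 tolerance = 1e-8)
  }
})

test_that("preceding peak ratio handles missing preceding peaks as zero", {
  expect_equal(preceding_peak_ratio(NA, 100), 0)
  expect_equal(preceding_peak_ratio(100, 100), 1)
  expect_equal(preceding_peak_ratio(50, 200), 0.25)
  expect_equal(preceding_peak_ratio(c(NA, 10), c(100, 100)), c(0, 0.1))
  expect_error(preceding_peak_ratio(10, 0), "M_mp")
})

test_that("signal-to-noise uses the median as the noise level", {
  expect_equal(signal_to_noise(100, c(100, 100, 100)), 1)
  expect_equal(signal_to_noise(100, c(10, 20, 30, 40, 100)), 100 / 30)
  # even-length median is the mean of the two central values
  expect_equal(signal_to_noise(40, c(10, 20, 30, 40)), 1.6)
  expect_error(signal_to_noise(10, numeric(0)), "noise")
  expect_error(signal_to_noise(10, c(0, 0, 0)), "noise")
})

test_that("isotope deviations compare mono-relative abundances", {
  expect_equal(isotope_deviations(c(100, 50, 20, 5), c(1000, 500, 200, 50)),
               c(0, 0, 0))
  expect_equal(isotope_deviations(c(100, 50, 20, 5), c(1000, 400, 200, 50)),
               c(0.1, 0, 0))
  # invariant under rescaling of EP (and of TP) separately
  expect_equal(isotope_deviations(c(1, 0.5, 0.2, 0.05), c(2, 0.8, 0.4, 0.1)),
               c(0.1, 0, 0))
  tp <- c(2, 1, 0.3, 0.05); ep <- c(800, 350, 90, 20)
  expect_equal(isotope_deviations(tp * 3, ep), isotope_deviations(tp, ep * 7))
  expect_error(isotope_deviations(c(2, 1, 0.3, 0.05), c(0, 1, 1, 1)), "mono")
})

test_that("scan isotope pattern deviations follow the pooled ratio rule", {
  # all scans exactly at the reference ratio
  z <- scan_isotope_pattern_deviations(c(100, 80, 60), c(50, 40, 30),
                                       c(100, 80, 60), c(50, 40, 30), 0.5)
  expect_equal(unname(z), c(0, 0, 0, 0))
  # every scan at E_i = 0.25 against M_0 = 0.5
  z <- scan_isotope_pattern_deviations(rep(200, 3), rep(50, 3),
                                       rep(200, 3), rep(50, 3), 0.5)
  expect_equal(unname(z), rep(-0.5, 4))
  # a missing scan contributes -1 and drops out of the pooled sum
  z <- scan_isotope_pattern_deviations(c(200, 200, NA), c(50, 50, 50),
                                       c(200, 200, 200), c(50, 50, 50), 0.5)
  expect_equal(z[["SID_2_"]], -1)
  expect_equal(z[["SID_sum_"]], -0.5)
  # all scans missing
  z <- scan_isotope_pattern_deviations(rep(NA_real_, 3), rep(NA_real_, 3),
                                       rep(NA_real_, 3), rep(NA_real_, 3), 0.5)
  expect_equal(unname(z), rep(-1, 4))
  expect_error(scan_isotope_pattern_deviations(rep(1, 3), rep(1, 3),
                                               rep(1, 3), rep(1, 3), 0), "M_0")
  # invariant under joint rescaling of all scan intensities
  a <- scan_isotope_pattern_deviations(c(10, 8, 6), c(4, 3, 2),
                                       c(9, 7, 5), c(3, 2, 1), 0.4)
  b <- scan_isotope_pattern_deviations(c(10, 8, 6) * 50, c(4, 3, 2) * 50,
                                       c(9, 7, 5) * 50, c(3, 2, 1) * 50, 0.4)
  expect_equal(a, b)
})

test_that("a clean record yields zero deviations and the fixed order", {
  ds <- make_clean_dataset(4)
  f <- extract_features(ds)
  expect_identical(names(f), c("spectrum_id", silac_feature_names()))
  expect_equal(f$MassDev, rep(0, 4))
  expect_equal(f$PPR, rep(0, 4))
  expect_equal(f[["S/N"]], rep(20, 4))
  for (cl in c(paste0("IsoDev_Light", 1:3), paste0("IsoDev_Heavy", 1:3),
               "SID_sum_", "SID_0_", "SID_1_", "SID_2_")) {
    expect_equal(f[[cl]], rep(0, 4), tolerance = 1e-12, label = cl)
  }
  expect_false(any(attr(f, "low_confidence")))
})

test_that("extract_features equals the component operations applied independently", {
  ds <- generate_dataset(sim_config(n_spectra = 25, seed = 9))
  f <- extract_features(ds)
  tp <- cbind(ds$TP_0, ds$TP_1, ds$TP_2, ds$TP_3)
  i <- 17
  expect_equal(f$MassDev[i], mass_deviation(ds$M_t[i], ds$M_e[i]))
  expect_equal(f$PPR[i], preceding_peak_ratio(ds$M_pp[i], ds$EP_L0[i]))
  expect_equal(f[["S/N"]][i], signal_to_noise(ds$EP_L0[i], ds$noise_peaks[[i]]))
  expect_equal(unname(unlist(f[i, paste0("IsoDev_Light", 1:3)])),
               isotope_deviations(tp[i, ],
                                  c(ds$EP_L0[i], ds$EP_L1[i], ds$EP_L2[i], ds$EP_L3[i])))
  sid <- scan_isotope_pattern_deviations(
    c(ds$L1_0[i], ds$L1_1[i], ds$L1_2[i]), c(ds$L2_0[i], ds$L2_1[i], ds$L2_2[i]),
    c(ds$H1_0[i], ds$H1_1[i], ds$H1_2[i]), c(ds$H2_0[i], ds$H2_1[i], ds$H2_2[i]),
    tp[i, 2] / tp[i, 1])
  expect_equal(f$SID_0_[i], sid[["SID_0_"]])
  expect_equal(f$SID_sum_[i], sid[["SID_sum_"]])
  # determinism: a second pass is identical
  expect_identical(f, extract_features(ds))
})

test_that("missing conventions: no preceding peak, missing scan, missing heavy mono", {
  ds <- make_clean_dataset(3)
  ds$L1_1[2] <- ds$L2_1[2] <- ds$H1_1[2] <- ds$H2_1[2] <- NA
  ds$EP_H0[3] <- 0
  f <- extract_features(ds)
  expect_equal(f$PPR, rep(0, 3))      # preceding peak absent everywhere
  expect_equal(f$SID_1_[2], -1)
  expect_equal(unname(unlist(f[3, paste0("IsoDev_Heavy", 1:3)])), rep(9.99, 3))
  expect_equal(attr(f, "low_confidence"), c(FALSE, FALSE, TRUE))
})

test_that("feature_matrix enforces the canonical column order", {
  ds <- make_clean_dataset(2)
  f <- extract_features(ds)
  shuffled <- f[, c(1, sample(2:14))]
  expect_identical(colnames(feature_matrix(shuffled)), silac_feature_names())
  expect_error(feature_matrix(f[, -3]), "missing feature")
})
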