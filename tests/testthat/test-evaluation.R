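test_that("log-scale CV follows the closed form", {
  expect_equal(log_ratio_cv(rep(1.3, 10)), 0)
  # sigma = 1: sqrt(exp((ln 2)^2) - 1)
  set.seed(71)
  x <- rnorm(2e5)
  x <- (x - mean(x)) / sd(x)   # exact unit sample SD
  expect_equal(log_ratio_cv(x), sqrt(exp(log(2)^2) - 1), tolerance = 1e-12)
  expect_equal(log_ratio_cv(x), 0.785383, tolerance = 1e-4)
  # strictly increasing in sigma
  sigmas <- c(0.1, 0.25, 0.5, 1, 2)
  cvs <- vapply(sigmas, function(s) log_ratio_cv(x * s), numeric(1))
  expect_true(all(diff(cvs) > 0))
  expect_error(log_ratio_cv(1), "at least 2")
})

test_that("closed-form CV matches the empirical CV of exponentiated normals", {
  set.seed(72)
  for (s in c(0.25, 0.5, 1)) {
    x <- rnorm(2e5, 0, s)
    y <- 2^x
    expect_equal(log_ratio_cv(x), sd(y) / mean(y), tolerance = 0.02)
  }
})

test_that("ratio summaries report n, mean, mode and CV on the log2 scale", {
  s <- summarize_ratios(rep(2, 10))
  expect_equal(s$n, 10)
  expect_equal(s$mean, 1)
  expect_equal(s$mode, 1)
  expect_equal(s$cv, 0)
  # known-parameter simulation: 2^X, X ~ N(0.5, 0.7^2)
  set.seed(73)
  r <- 2^rnorm(50000, 0.5, 0.7)
  s <- summarize_ratios(r)
  expect_equal(s$mean, 0.5, tolerance = 0.02)
  expect_equal(s$cv, sqrt(2^(log(2) * 0.49) - 1), tolerance = 0.02)
  # invalid ratios are excluded and counted
  s2 <- summarize_ratios(c(r[1:100], NA, -2, 0))
  expect_equal(s2$n, 100)
  expect_equal(s2$n_invalid, 3)
  # invariant to record order
  expect_equal(summarize_ratios(rev(r)), summarize_ratios(r))
  expect_error(summarize_ratios(c(NA, 2)), "valid")
})

test_that("filter sweep drops the lowest-scoring fraction with stable ties", {
  set.seed(74)
  n <- 2114
  scores <- runif(n)
  ratios <- 2^rnorm(n, 0, 0.5)
  sw <- filter_sweep(scores, ratios, c(0, 0.1, 0.3))
  expect_equal(sw$n_retained, c(2114, 2114 - 211, 1480))
  # f = 0 reproduces the unfiltered summary
  expect_equal(sw$cv[1], summarize_ratios(ratios)$cv)
  # nesting: survivors at a larger fraction are survivors at a smaller one
  keep_at <- function(f) {
    ord <- order(scores, seq_along(scores))
    sort(ord[-seq_len(floor(f * n))])
  }
  expect_true(all(keep_at(0.3) %in% keep_at(0.1)))
  expect_true(all(diff(sw$n_retained) <= 0))
  # ties broken by record order
  tied <- rep(0.5, 10)
  sw_t <- filter_sweep(tied, 2^rnorm(10), 0.3)
  expect_equal(sw_t$n_retained, 7)
  expect_error(filter_sweep(scores[1:5], ratios), "aligned")
})

test_that("protein summaries aggregate kept peptides per protein", {
  ds <- make_clean_dataset(3)
  ds$asap_ratio <- c(1, 1, 1)
  ps <- protein_level_summary(ds)
  expect_equal(ps$n_peptides, 3)
  expect_equal(ps$ratio_mean, 1)
  expect_equal(ps$ratio_sd, 0)
  # filtering corrupted peptides shrinks the protein SD
  good <- rnorm(20, 1.5, 0.1)
  badr <- rnorm(5, 8, 0.5)
  ds2 <- make_clean_dataset(25)
  ds2$asap_ratio <- c(good, badr)
  before <- protein_level_summary(ds2)
  after <- protein_level_summary(ds2, keep_flags = c(rep(TRUE, 20), rep(FALSE, 5)))
  expect_lt(after$ratio_sd, before$ratio_sd)
  expect_equal(after$ratio_mean, mean(good))
  # totals over proteins equal total kept records
  ds3 <- generate_dataset(sim_config(n_spectra = 300, seed = 75))
  keep <- runif(300) > 0.3
  ps3 <- suppressMessages(protein_level_summary(ds3, keep))
  expect_equal(sum(ps3$n_peptides), sum(keep & !is.na(ds3$asap_ratio)))
})

test_that("Chebyshev coverage is bounded below by 1 - 1/k^2", {
  set.seed(76)
  x <- rnorm(50000)
  expect_equal(chebyshev_coverage(x, 3), 0.9973, tolerance = 0.002)
  expect_gte(chebyshev_coverage(rt(1000, df = 1.5), 3), 8 / 9)
  expect_equal(chebyshev_coverage(rep(4, 10), 3), 1)
})
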