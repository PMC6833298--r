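test_that("train/test split has the exact sizes and is seed-stable", {
  df <- data.frame(i = seq_len(2114))
  sp <- split_train_test(df, 0.75, seed = 3)
  expect_equal(nrow(sp$train), 1585)
  expect_equal(nrow(sp$test), 529)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(2114))
  sp2 <- split_train_test(df, 0.75, seed = 3)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_error(split_train_test(df[1, , drop = FALSE]), "degenerate")
})

test_that("training parameters are validated against the search bounds", {
  p <- train_params()
  expect_equal(p$learning_rate, 0.197)
  expect_equal(p$n_estimators, 11L)
  expect_equal(p$max_depth, 10L)
  expect_error(train_params(learning_rate = 0.5), "learning_rate")
  expect_error(train_params(n_estimators = 5), "n_estimators")
})

test_that("separable data is learned perfectly and reproducibly", {
  sep <- make_separable(300, seed = 61)
  m <- train_quality_model(sep$x, sep$tags, seed = 7)
  pred <- predict_quality(m, sep$x)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_identical(pred$keep, sep$tags)       # training accuracy 1.0
  m2 <- train_quality_model(sep$x, sep$tags, seed = 7)
  expect_identical(predict_quality(m2, sep$x)$score, pred$score)
  expect_error(train_quality_model(sep$x, rep(TRUE, 300)), "both classes")
})

test_that("predictions are record-order equivariant and dimension-checked", {
  sep <- make_separable(120, seed = 62)
  m <- train_quality_model(sep$x, sep$tags, seed = 1)
  perm <- sample(120)
  expect_equal(predict_quality(m, sep$x[perm, ])$score,
               predict_quality(m, sep$x)$score[perm])
  expect_error(predict_quality(m, sep$x[, 1:5]), "dimension")
})

test_that("gain importances are non-negative and single out the informative feature", {
  sep <- make_separable(300, seed = 63)
  m <- train_quality_model(sep$x, sep$tags, seed = 2)
  g <- feature_importance(m)
  expect_named(g, silac_feature_names())
  expect_true(all(g >= 0))
  expect_gt(max(g), 0)
  expect_equal(names(which.max(g)), "MassDev")
  expect_error(feature_importance(list()), "silac_model")
})

test_that("oversampled CV evaluates untouched folds: high AUC when separable, null at chance", {
  sep <- make_separable(300, seed = 64)
  cv <- cross_validate_oversampled(sep$x, sep$tags, folds = 5, seed = 5)
  expect_length(cv$fold_auc, 5)
  expect_true(all(cv$fold_auc >= 0.99))
  # permutation null: mean AUC near 0.5 over repeats
  set.seed(65)
  x <- matrix(rnorm(240 * 13), 240, 13,
              dimnames = list(NULL, silac_feature_names()))
  tags <- rep(c(TRUE, FALSE), c(200, 40))
  null_auc <- vapply(1:10, function(r) {
    cross_validate_oversampled(x, sample(tags), folds = 4, seed = r)$mean_auc
  }, numeric(1))
  expect_lt(abs(mean(null_auc) - 0.5), 0.1)
  # a class too small to appear in every fold is a folding error
  bad_tags <- rep(c(TRUE, FALSE), c(237, 3))
  suppressWarnings(  # the tiny minority also triggers SMOTE k-reduction
    expect_error(cross_validate_oversampled(x, bad_tags, folds = 5, seed = 1),
                 "class"))
})

test_that("hyperparameter search returns integral, in-bounds parameters", {
  sep <- make_separable(150, seed = 66)
  bounds <- default_param_bounds()
  bounds$n_estimators <- c(10, 40)   # small trees keep the search quick
  for (method in c("bayes", "random")) {
    p <- tune_hyperparameters(sep$x, sep$tags, bounds = bounds,
                              iterations = 3, seed = 8, folds = 3,
                              method = method, n_init = 2)
    expect_s3_class(p, "train_params")
    expect_identical(p$n_estimators, as.integer(p$n_estimators))
    expect_identical(p$max_depth, as.integer(p$max_depth))
    for (nm in names(bounds)) {
      expect_gte(p[[nm]], bounds[[nm]][1])
      expect_lte(p[[nm]], bounds[[nm]][2])
    }
    expect_gte(attr(p, "score"), 0.9)  # separable data: near-perfect CV AUC
  }
  expect_error(tune_hyperparameters(sep$x, sep$tags, iterations = 0), "iterations")
  expect_error(tune_hyperparameters(sep$x, sep$tags, bounds = bounds[1:3],
                                    iterations = 1), "bounds")
})

test_that("the class-weighted SVM baseline favors minority recall", {
  set.seed(67)
  n_maj <- 300; n_min <- 50
  x <- rbind(matrix(rnorm(n_maj * 13, 0, 1), n_maj, 13),
             matrix(rnorm(n_min * 13, 1.2, 1), n_min, 13))
  colnames(x) <- silac_feature_names()
  tags <- rep(c(TRUE, FALSE), c(n_maj, n_min))
  m1 <- train_svm_baseline(x, tags, class_weight = 1, seed = 1)
  m6 <- train_svm_baseline(x, tags, class_weight = 6, seed = 1)
  p1 <- predict_quality(m1, x); p6 <- predict_quality(m6, x)
  expect_true(all(p6$score >= 0 & p6$score <= 1))
  recall_min <- function(p) mean(!p$keep[!tags])
  expect_gte(recall_min(p6), recall_min(p1))
  expect_error(train_svm_baseline(x, rep(TRUE, 350)), "both classes")
})

test_that("separable data is perfectly fit by the SVM baseline", {
  sep <- make_separable(200, seed = 68)
  m <- train_svm_baseline(sep$x, sep$tags, class_weight = 6, seed = 1)
  pred <- predict(m$fit, sep$x)
  expect_equal(as.logical(as.character(pred)), sep$tags)
})

test_that("model persistence round-trips predictions and metadata", {
  sep <- make_separable(150, seed = 69)
  m <- train_quality_model(sep$x, sep$tags, seed = 4)
  dir <- withr::local_tempdir()
  save_quality_model(m, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  back <- load_quality_model(dir)
  expect_identical(back$feature_names, silac_feature_names())
  expect_identical(unclass(back$params), unclass(m$params))
  expect_equal(predict_quality(back, sep$x)$score,
               predict_quality(m, sep$x)$score, tolerance = 1e-7)
})
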