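# Boosted-tree quality classifier and class-weighted SVM baseline.
#
# The classifier consumes exactly the 13 quality features — never the
# quantitative ratio itself — so filtering cannot trivially favor
# ratios near the expected mix.

#' Boosted-tree training parameters
#'
#' Defaults are the tuned operating point of the quality classifier;
#' each value must lie within the hyperparameter search box of
#' [default_param_bounds()].
#'
#' @param learning_rate Shrinkage per boosting round.
#' @param n_estimators Number of boosting rounds (integer).
#' @param max_depth Maximum tree depth (integer).
#' @param gamma Minimum loss reduction to split.
#' @param colsample_bytree Column subsample ratio per tree.
#' @param subsample Row subsample ratio per tree.
#' @return A `train_params` list.
#' @export
train_params <- function(learning_rate = 0.197, n_estimators = 11L,
                         max_depth = 10L, gamma = 0.04,
                         colsample_bytree = 0.97, subsample = 0.96) {
  p <- list(learning_rate = learning_rate,
            n_estimators = as.integer(round(n_estimators)),
            max_depth = as.integer(round(max_depth)),
            gamma = gamma, colsample_bytree = colsample_bytree,
            subsample = subsample)
  b <- default_param_bounds()
  for (nm in names(b)) {
    if (p[[nm]] < b[[nm]][1] || p[[nm]] > b[[nm]][2]) {
      stop(nm, " = ", p[[nm]], " outside bounds [",
           b[[nm]][1], ", ", b[[nm]][2], "]", call. = FALSE)
    }
  }
  structure(p, class = "train_params")
}

#' Hyperparameter search bounds
#'
#' The box searched by [tune_hyperparameters()]: learning_rate
#' (0.01–0.3), n_estimators (10–2000), max_depth (3–10), gamma (0–0.05),
#' colsample_bytree (0.7–1), subsample (0.7–1).
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_param_bounds <- function() {
  list(learning_rate = c(0.01, 0.3),
       n_estimators = c(10, 2000),
       max_depth = c(3, 10),
       gamma = c(0, 0.05),
       colsample_bytree = c(0.7, 1),
       subsample = c(0.7, 1))
}

#' Random 75/25 train/test split
#'
#' Uniform split without stratification; the training part has
#' `floor(fraction * n)` rows.
#'
#' @param dataset A data frame (or matrix) of records.
#' @param fraction Training fraction, strictly between 0 and 1.
#' @param seed Integer seed making the split reproducible.
#' @return List with elements `train` and `test` (disjoint, exhaustive)
#'   plus the integer index vectors `train_idx` and `test_idx`.
#' @export
split_train_test <- function(dataset, fraction = 0.75, seed = 1L) {
  n <- nrow(dataset)
  stopifnot(fraction > 0, fraction < 1)
  n_train <- floor(fraction * n)
  if (n < 2 || n_train < 1 || n_train >= n) {
    stop("degenerate split sizes for n = ", n, call. = FALSE)
  }
  set.seed(seed)
  train_idx <- sort(sample.int(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = dataset[train_idx, , drop = FALSE],
       test = dataset[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

# Stratified fold assignment: both classes spread evenly over folds.
stratified_folds <- function(tags, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assign <- integer(length(tags))
  for (lv in unique(tags)) {
    idx <- which(tags == lv)
    assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assign
}

xgb_params_list <- function(params, seed) {
  list(objective = "binary:logistic",
       eta = params$learning_rate,
       max_depth = params$max_depth,
       gamma = params$gamma,
       colsample_bytree = params$colsample_bytree,
       subsample = params$subsample,
       nthread = 1,
       seed = seed)
}

#' Train the boosted-tree quality classifier
#'
#' @param x Feature matrix (13 columns, [silac_feature_names()] order;
#'   use [feature_matrix()]).
#' @param tags Logical training tags (`TRUE` = high quality).
#' @param params A [train_params()].
#' @param seed Integer seed; with a single thread the fit is
#'   deterministic.
#' @return A `silac_model` holding the fitted booster and training
#'   metadata.
#' @export
train_quality_model <- function(x, tags, params = train_params(), seed = 1L) {
  x <- as.matrix(x)
  tags <- as.logical(tags)
  if (length(unique(tags)) < 2) stop("both classes must be present", call. = FALSE)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(tags))
  booster <- xgboost::xgb.train(params = xgb_params_list(params, seed),
                                data = dtrain,
                                nrounds = params$n_estimators,
                                verbose = 0)
  structure(list(booster = booster, params = params, seed = seed,
                 feature_names = colnames(x)),
            class = "silac_model")
}

#' Predict spectrum quality
#'
#' @param model A `silac_model` or `silac_svm`.
#' @param x Feature matrix with the same 13 columns used in training.
#' @param threshold Score cut for the boolean decision.
#' @return Data frame with `score` (in `[0, 1]`) and `keep`
#'   (`score >= threshold`).
#' @export
predict_quality <- function(model, x, threshold = 0.5) {
  UseMethod("predict_quality")
}

check_predict_input <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$feature_names)) {
    stop("feature dimension mismatch: model expects ",
         length(model$feature_names), " features, got ", ncol(x), call. = FALSE)
  }
  x
}

#' @export
predict_quality.silac_model <- function(model, x, threshold = 0.5) {
  x <- check_predict_input(model, x)
  score <- predict(model$booster, x)
  data.frame(score = score, keep = score >= threshold)
}

#' Per-feature gain importances of a fitted model
#'
#' Gain — the summed loss reduction contributed by all splits on a
#' feature, reported as each feature's share of the total — for all 13
#' features. Features never used by any split report 0.
#'
#' @param model A fitted `silac_model`.
#' @return Named non-negative numeric vector, one entry per feature.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "silac_model")) stop("need a fitted silac_model", call. = FALSE)
  imp <- xgboost::xgb.importance(model = model$booster)
  gains <- setNames(rep(0, length(model$feature_names)), model$feature_names)
  gains[imp$Feature] <- imp$Gain
  gains
}

#' Cross-validation with oversampling of the training folds only
#'
#' Stratified k-fold cross-validation in which SMOTE is applied to the
#' k-1 training folds of each round; the held-out testing fold is never
#' over-sampled, so every evaluation happens at the original class
#' ratio.
#'
#' @param x Feature matrix.
#' @param tags Logical tags.
#' @param folds Number of folds.
#' @param params A [train_params()].
#' @param smote_cfg An [smote_config()]; `NULL` disables oversampling.
#' @param seed Integer seed (folding, SMOTE, fits).
#' @return List with `fold_auc` (per-fold ROC AUC) and `mean_auc`.
#' @export
cross_validate_oversampled <- function(x, tags, folds = 10L,
                                       params = train_params(),
                                       smote_cfg = smote_config(),
                                       seed = 1L) {
  x <- as.matrix(x)
  tags <- as.logical(tags)
  stopifnot(folds >= 2)
  assign <- stratified_folds(tags, folds, seed = derive_seed(seed, "folds"))
  fold_auc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- assign != f
    te <- !tr
    if (length(unique(tags[te])) < 2 || length(unique(tags[tr])) < 2) {
      stop("fold ", f, " lost a class; use fewer folds", call. = FALSE)
    }
    xtr <- x[tr, , drop = FALSE]
    ttr <- tags[tr]
    if (!is.null(smote_cfg)) {
      cfg <- smote_cfg
      cfg$seed <- derive_seed(seed, paste0("smote_fold", f))
      res <- smote(xtr, ttr, cfg)
      xtr <- res$x
      ttr <- res$tags
    }
    fit <- train_quality_model(xtr, ttr, params,
                               seed = derive_seed(seed, paste0("fit_fold", f)))
    sc <- predict_quality(fit, x[te, , drop = FALSE])$score
    fold_auc[f] <- as.numeric(pROC::auc(pROC::roc(
      response = tags[te], predictor = sc,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
  }
  list(fold_auc = fold_auc, mean_auc = mean(fold_auc))
}

#' Tune hyperparameters by Bayesian (Gaussian-process) search
#'
#' Maximizes the mean oversampled-CV AUC over the search box.
#' `n_estimators` and `max_depth` are rounded to integers before every
#' evaluation. A pure random search over the same box is selectable via
#' `method = "random"` and satisfies the same contract.
#'
#' @param x Feature matrix.
#' @param tags Logical tags.
#' @param bounds Search box, as [default_param_bounds()].
#' @param iterations Total number of objective evaluations.
#' @param seed Integer seed.
#' @param folds,smote_cfg Passed to [cross_validate_oversampled()].
#' @param method `"bayes"` (GP expected improvement) or `"random"`.
#' @param n_init Random initialization points before the GP takes over.
#' @return The best [train_params()] found; its CV score is attached as
#'   attribute `score`.
#' @export
tune_hyperparameters <- function(x, tags, bounds = default_param_bounds(),
                                 iterations = 30L, seed = 1L, folds = 10L,
                                 smote_cfg = smote_config(),
                                 method = c("bayes", "random"),
                                 n_init = 5L) {
  method <- match.arg(method)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  needed <- names(default_param_bounds())
  if (!all(needed %in% names(bounds))) {
    stop("bounds must cover: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  bounds <- bounds[needed]
  objective <- function(v) {
    p <- as.list(v)
    names(p) <- needed
    params <- train_params(p$learning_rate, round(p$n_estimators),
                           round(p$max_depth), p$gamma,
                           p$colsample_bytree, p$subsample)
    cross_validate_oversampled(x, tags, folds = folds, params = params,
                               smote_cfg = smote_cfg,
                               seed = derive_seed(seed, "cv"))$mean_auc
  }
  res <- gp_ei_optimize(objective, bounds, iterations = iterations,
                        seed = derive_seed(seed, "tune"),
                        n_init = n_init,
                        random_only = method == "random")
  v <- as.list(res$best_x)
  names(v) <- needed
  out <- train_params(v$learning_rate, round(v$n_estimators), round(v$max_depth),
                      v$gamma, v$colsample_bytree, v$subsample)
  attr(out, "score") <- res$best_y
  out
}

#' Class-weighted SVM baseline
#'
#' RBF-kernel support vector machine with the minority class up-weighted
#' (default weight 6, matching an imbalance ratio of about 6:1), used as
#' the comparison quality controller. Shares the [predict_quality()]
#' contract with the boosted model.
#'
#' @param x Feature matrix.
#' @param tags Logical tags.
#' @param class_weight Weight of the minority class (majority gets 1).
#' @param seed Integer seed (probability calibration is stochastic).
#' @param ... Passed to [e1071::svm()].
#' @return A `silac_svm` model.
#' @export
train_svm_baseline <- function(x, tags, class_weight = 6, seed = 1L, ...) {
  x <- as.matrix(x)
  tags <- as.logical(tags)
  if (length(unique(tags)) < 2) stop("both classes must be present", call. = FALSE)
  counts <- table(factor(tags, levels = c(FALSE, TRUE)))
  minority <- names(counts)[which.min(counts)]
  w <- c("FALSE" = 1, "TRUE" = 1)
  w[minority] <- class_weight
  set.seed(seed)
  fit <- e1071::svm(x = x, y = factor(tags, levels = c(FALSE, TRUE)),
                    kernel = "radial", class.weights = w,
                    probability = TRUE, ...)
  structure(list(fit = fit, class_weight = class_weight,
                 feature_names = colnames(x), seed = seed),
            class = "silac_svm")
}

#' @export
predict_quality.silac_svm <- function(model, x, threshold = 0.5) {
  x <- check_predict_input(model, x)
  pr <- attr(predict(model$fit, x, probability = TRUE), "probabilities")
  score <- pr[, "TRUE"]
  data.frame(score = as.numeric(score), keep = as.numeric(score) >= threshold)
}

#' Save / load a fitted quality model
#'
#' The booster is stored in the boosting library's native JSON model
#' format; training metadata (parameters, seed, feature order, schema
#' version) goes to a plain-text sidecar.
#'
#' @param model A `silac_model`.
#' @param dir Directory to write into (created if needed).
#' @return `dir` (save) or the restored `silac_model` (load).
#' @export
save_quality_model <- function(model, dir) {
  stopifnot(inherits(model, "silac_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "model.json"))
  meta <- c(schema_version = "1",
            seed = as.character(model$seed),
            feature_names = paste(model$feature_names, collapse = "|"),
            vapply(unclass(model$params), function(v) format(v, digits = 15),
                   character(1)))
  writeLines(paste0(names(meta), ": ", meta), file.path(dir, "metadata.txt"))
  invisible(dir)
}

#' @rdname save_quality_model
#' @export
load_quality_model <- function(dir) {
  booster <- xgboost::xgb.load(file.path(dir, "model.json"))
  lines <- readLines(file.path(dir, "metadata.txt"))
  kv <- strsplit(lines, ": ", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, character(1), 2), vapply(kv, `[`, character(1), 1))
  params <- train_params(as.numeric(meta[["learning_rate"]]),
                         as.integer(meta[["n_estimators"]]),
                         as.integer(meta[["max_depth"]]),
                         as.numeric(meta[["gamma"]]),
                         as.numeric(meta[["colsample_bytree"]]),
                         as.numeric(meta[["subsample"]]))
  structure(list(booster = booster, params = params,
                 seed = as.integer(meta[["seed"]]),
                 feature_names = strsplit(meta[["feature_names"]], "|",
                                          fixed = TRUE)[[1]]),
            class = "silac_model")
}
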