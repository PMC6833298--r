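# End-to-end orchestration: extract -> tag -> split -> SMOTE -> train
# (-> tune) -> assess -> evaluate, with one master seed driving every
# stochastic stage.

#' Pipeline configuration
#'
#' @param input Path of the input PSM table (CSV/TSV).
#' @param out_dir Output directory for artifacts.
#' @param master_seed Single integer seed from which every stage seed is
#'   derived.
#' @param dialect Input table dialect.
#' @param tag A [tag_config()].
#' @param smote An [smote_config()] or `NULL` to disable re-balancing.
#' @param params A [train_params()]; ignored when `tune = TRUE`.
#' @param tune Run the hyperparameter search instead of using `params`.
#' @param tune_iterations,tune_folds Search budget and CV folds.
#' @param split_fraction Training fraction of the 75/25 split.
#' @param fractions Filtered-out fractions for the evaluation sweep.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir, master_seed = 1L,
                            dialect = c("csv", "tsv"),
                            tag = tag_config(), smote = smote_config(),
                            params = train_params(), tune = FALSE,
                            tune_iterations = 30L, tune_folds = 10L,
                            split_fraction = 0.75,
                            fractions = seq(0, 0.5, by = 0.05)) {
  dialect <- match.arg(dialect)
  structure(list(input = input, out_dir = out_dir,
                 master_seed = as.integer(master_seed), dialect = dialect,
                 tag = tag, smote = smote, params = params, tune = tune,
                 tune_iterations = as.integer(tune_iterations),
                 tune_folds = as.integer(tune_folds),
                 split_fraction = split_fraction, fractions = fractions),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' Plain-text key-value format; `read_pipeline_config` inverts
#' `write_pipeline_config` exactly.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `path` (write) or the restored `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  num <- function(v) paste(format(v, digits = 15), collapse = ",")
  lines <- c(
    paste0("input: ", config$input),
    paste0("out_dir: ", config$out_dir),
    paste0("master_seed: ", config$master_seed),
    paste0("dialect: ", config$dialect),
    paste0("tag.sigma_multiplier: ", num(config$tag$sigma_multiplier)),
    paste0("tag.mass_threshold: ", num(config$tag$mass_threshold)),
    paste0("tag.kde_bandwidth_rule: ", config$tag$kde_bandwidth_rule),
    paste0("tag.kde_grid_points: ", config$tag$kde_grid_points),
    paste0("smote.enabled: ", !is.null(config$smote)),
    paste0("smote.k_neighbors: ",
           if (is.null(config$smote)) "" else config$smote$k_neighbors),
    paste0("params.", names(unclass(config$params)), ": ",
           vapply(unclass(config$params), num, character(1))),
    paste0("tune: ", config$tune),
    paste0("tune_iterations: ", config$tune_iterations),
    paste0("tune_folds: ", config$tune_folds),
    paste0("split_fraction: ", num(config$split_fraction)),
    paste0("fractions: ", num(config$fractions))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  kv <- strsplit(readLines(path), ": ", fixed = TRUE)
  val <- setNames(vapply(kv, function(p) if (length(p) > 1) p[2] else "",
                         character(1)),
                  vapply(kv, `[`, character(1), 1))
  smote <- if (identical(val[["smote.enabled"]], "TRUE")) {
    smote_config(k_neighbors = as.integer(val[["smote.k_neighbors"]]))
  }
  pipeline_config(
    input = val[["input"]], out_dir = val[["out_dir"]],
    master_seed = as.integer(val[["master_seed"]]),
    dialect = val[["dialect"]],
    tag = tag_config(as.numeric(val[["tag.sigma_multiplier"]]),
                     as.numeric(val[["tag.mass_threshold"]]),
                     val[["tag.kde_bandwidth_rule"]],
                     as.integer(val[["tag.kde_grid_points"]])),
    smote = smote,
    params = train_params(as.numeric(val[["params.learning_rate"]]),
                          as.integer(val[["params.n_estimators"]]),
                          as.integer(val[["params.max_depth"]]),
                          as.numeric(val[["params.gamma"]]),
                          as.numeric(val[["params.colsample_bytree"]]),
                          as.numeric(val[["params.subsample"]])),
    tune = identical(val[["tune"]], "TRUE"),
    tune_iterations = as.integer(val[["tune_iterations"]]),
    tune_folds = as.integer(val[["tune_folds"]]),
    split_fraction = as.numeric(val[["split_fraction"]]),
    fractions = as.numeric(strsplit(val[["fractions"]], ",", fixed = TRUE)[[1]])
  )
}

pipeline_log <- function(stage, ...) {
  message("[silacqc] ", stage, ": ", ...)
}

#' Run the full quality-control pipeline
#'
#' Reads (or takes) a PSM table, extracts the 13 features, derives
#' training tags, splits 75/25, re-balances the training part with SMOTE,
#' trains the boosted-tree classifier (optionally tuning it first),
#' scores every spectrum, and writes the evaluation artifacts: feature
#' table, tag table, model directory, score table, a ratio-summary table
#' (before/after filtering) and a CV-vs-filtered-fraction sweep.
#'
#' @param config A [pipeline_config()].
#' @param dataset Optional pre-loaded `psm_dataset`; when supplied,
#'   `config$input` is not read.
#' @return Invisibly, a list with the in-memory artifacts (`features`,
#'   `tags`, `split`, `model`, `scores`, `summary`, `sweep`, `proteins`).
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pipeline_config(config, file.path(config$out_dir, "config.txt"))
  ms <- config$master_seed

  if (is.null(dataset)) {
    pipeline_log("read", config$input)
    dataset <- read_psm_table(config$input, config$dialect)
  }

  pipeline_log("extract", nrow(dataset), " spectra")
  features <- extract_features(dataset)
  write.csv(features, file.path(config$out_dir, "features.csv"),
            row.names = FALSE)

  pipeline_log("tag", "ratio + mass rules")
  tags <- quality_tags(dataset, config$tag)
  write.csv(data.frame(spectrum_id = tags$spectrum_id,
                       ratio_tag = as.integer(tags$ratio_tag),
                       mass_tag = as.integer(tags$mass_tag),
                       final_tag = as.integer(tags$final_tag)),
            file.path(config$out_dir, "tags.csv"), row.names = FALSE)

  x <- feature_matrix(features)
  y <- tags$final_tag
  split <- split_train_test(data.frame(idx = seq_len(nrow(x))),
                            fraction = config$split_fraction,
                            seed = derive_seed(ms, "split"))
  tr <- split$train_idx

  params <- config$params
  if (config$tune) {
    pipeline_log("tune", config$tune_iterations, " iterations")
    params <- tune_hyperparameters(x[tr, , drop = FALSE], y[tr],
                                   iterations = config$tune_iterations,
                                   folds = config$tune_folds,
                                   smote_cfg = config$smote,
                                   seed = derive_seed(ms, "tune"))
  }

  xtr <- x[tr, , drop = FALSE]
  ytr <- y[tr]
  if (!is.null(config$smote)) {
    cfg <- config$smote
    cfg$seed <- derive_seed(ms, "smote")
    pipeline_log("smote", "re-balancing ", sum(!ytr), " minority records")
    res <- smote(xtr, ytr, cfg)
    xtr <- res$x
    ytr <- res$tags
  } else {
    pipeline_log("smote", "disabled")
  }

  pipeline_log("train", "boosted trees on ", nrow(xtr), " rows")
  model <- train_quality_model(xtr, ytr, params, seed = derive_seed(ms, "fit"))
  save_quality_model(model, file.path(config$out_dir, "model"))

  pipeline_log("assess", "scoring all spectra")
  scores <- predict_quality(model, x)
  score_table <- data.frame(spectrum_id = dataset$spectrum_id,
                            score = scores$score, keep = scores$keep)
  write.csv(score_table, file.path(config$out_dir, "scores.csv"),
            row.names = FALSE)

  pipeline_log("evaluate", "ratio summaries and filter sweep")
  sweep <- filter_sweep(scores$score, dataset$asap_ratio, config$fractions,
                        config$tag)
  write.csv(sweep, file.path(config$out_dir, "sweep.csv"), row.names = FALSE)
  summary_tbl <- cbind(stage = c("before", "after_30pct"),
                       rbind(sweep[which.min(abs(sweep$fraction - 0)), -1],
                             filter_sweep(scores$score, dataset$asap_ratio,
                                          0.30, config$tag)[, -1]))
  write.csv(summary_tbl, file.path(config$out_dir, "summary.csv"),
            row.names = FALSE)
  proteins <- protein_level_summary(dataset, scores$keep)
  write.csv(proteins, file.path(config$out_dir, "proteins.csv"),
            row.names = FALSE)

  invisible(list(features = features, tags = tags, split = split,
                 params = params, model = model, scores = score_table,
                 summary = summary_tbl, sweep = sweep, proteins = proteins))
}
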