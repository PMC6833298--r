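# SMOTE: synthetic minority over-sampling.
#
# New minority points are linear interpolations x + u * (xhat - x) with
# u ~ Uniform(0, 1) and xhat one of x's k nearest minority neighbors
# (Euclidean). The majority class passes through untouched; synthetic
# rows are appended after the originals until the classes are equal.

#' SMOTE configuration
#'
#' @param k_neighbors Number of minority nearest neighbors considered.
#' @param seed Optional integer seed; fixing it makes [smote()]
#'   deterministic.
#' @param standardize If `TRUE`, neighbors are found on column-scaled
#'   features (interpolation still happens on the raw values). Off by
#'   default: plain Euclidean distance on raw feature values.
#' @return An `smote_config` list.
#' @export
smote_config <- function(k_neighbors = 5L, seed = NULL, standardize = FALSE) {
  stopifnot(k_neighbors >= 1)
  structure(list(k_neighbors = as.integer(k_neighbors), seed = seed,
                 standardize = isTRUE(standardize)),
            class = "smote_config")
}

#' Over-sample the minority class with SMOTE
#'
#' @param x Numeric feature matrix (rows = records).
#' @param tags Logical (or two-level) class vector aligned with `x`.
#' @param config An [smote_config()].
#' @return A list with `x` (original rows first, synthetic rows
#'   appended), `tags`, and `n_synthetic`. After SMOTE the minority count
#'   equals the majority count.
#' @export
smote <- function(x, tags, config = smote_config()) {
  x <- as.matrix(x)
  tags <- as.logical(tags)
  stopifnot(nrow(x) == length(tags), !anyNA(tags))
  counts <- table(factor(tags, levels = c(FALSE, TRUE)))
  if (any(counts == 0)) stop("both classes must be present", call. = FALSE)
  minority_level <- as.logical(names(counts)[which.min(counts)])
  n_min <- min(counts)
  n_maj <- max(counts)
  if (n_min == n_maj) {
    return(list(x = x, tags = tags, n_synthetic = 0L))
  }
  if (n_min < 2) stop("minority class needs at least 2 members", call. = FALSE)
  k <- config$k_neighbors
  if (n_min <= k) {
    k <- n_min - 1L
    warning("k_neighbors reduced to ", k, " (minority class has ", n_min,
            " members)")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  idx_min <- which(tags == minority_level)
  xm <- x[idx_min, , drop = FALSE]
  xd <- if (config$standardize) {
    sds <- apply(xm, 2, sd)
    sds[sds == 0] <- 1
    sweep(xm, 2, sds, "/")
  } else xm
  dmat <- as.matrix(dist(xd))
  diag(dmat) <- Inf
  # k nearest minority neighbors of every minority point
  nn <- matrix(0L, n_min, k)
  for (i in seq_len(n_min)) nn[i, ] <- order(dmat[i, ])[seq_len(k)]

  n_syn <- n_maj - n_min
  base <- sample.int(n_min, n_syn, replace = TRUE)
  pick <- sample.int(k, n_syn, replace = TRUE)
  u <- runif(n_syn)
  neigh <- nn[cbind(base, pick)]
  synth <- xm[base, , drop = FALSE] +
    u * (xm[neigh, , drop = FALSE] - xm[base, , drop = FALSE])
  rownames(synth) <- NULL
  list(x = rbind(x, synth),
       tags = c(tags, rep(minority_level, n_syn)),
       n_synthetic = n_syn)
}
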