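# Lightweight Gaussian-process expected-improvement optimizer.
#
# Parameters are scaled to the unit cube; the surrogate is a GP with a
# squared-exponential kernel (fixed length-scale 0.2, signal variance
# from the observed scores, small nugget for numerical stability).
# Candidates are random draws in the cube; each round the candidate with
# maximal expected improvement is evaluated. Ties are broken first-found
# (which.max). A pure random search is available for comparison.

gp_ei_optimize <- function(objective, bounds, iterations = 30L, seed = 1L,
                           n_init = 5L, n_candidates = 500L,
                           lengthscale = 0.2, random_only = FALSE) {
  stopifnot(iterations >= 1)
  set.seed(seed)
  d <- length(bounds)
  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  to_raw <- function(u) lower + u * (upper - lower)

  n_init <- min(n_init, iterations)
  U <- matrix(runif(n_init * d), n_init, d)
  y <- apply(U, 1, function(u) objective(to_raw(u)))

  sqexp <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exp(-0.5 * pmax(d2, 0) / lengthscale^2)
  }

  while (length(y) < iterations) {
    if (random_only) {
      u_next <- runif(d)
    } else {
      sf2 <- max(var(y), 1e-8)
      K <- sf2 * sqexp(U, U) + diag(1e-6 * sf2, nrow(U))
      Kinv_y <- solve(K, y - mean(y))
      cand <- matrix(runif(n_candidates * d), n_candidates, d)
      ks <- sf2 * sqexp(cand, U)
      mu <- mean(y) + as.numeric(ks %*% Kinv_y)
      # posterior variance; clamp tiny negatives from round-off
      v <- pmax(sf2 - rowSums((ks %*% solve(K)) * ks), 1e-12)
      s <- sqrt(v)
      best <- max(y)
      z <- (mu - best) / s
      ei <- (mu - best) * pnorm(z) + s * dnorm(z)
      u_next <- cand[which.max(ei), ]
    }
    U <- rbind(U, u_next)
    y <- c(y, objective(to_raw(u_next)))
  }
  i_best <- which.max(y)
  list(best_x = to_raw(U[i_best, ]), best_y = y[i_best],
       X = t(apply(U, 1, to_raw)), y = y)
}
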