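#' Fit a Gaussian mixture to spine lengths by EM
#'
#' Maximum-likelihood fit of a `k`-component univariate Gaussian mixture
#' (the conventional parametrisation of the spine-length distribution,
#' whose three modes are often read as thin/stubby vs mushroom vs
#' filopodial spines). Plain expectation-maximisation with a moment-based
#' quantile initialisation; the log-likelihood trace is returned so
#' monotone convergence can be audited.
#'
#' @param lengths Numeric vector, at least `10 * k` values.
#' @param k Number of components (default 3).
#' @param max_iter Iteration cap; exceeding it without meeting `tol`
#'   raises a diagnostic error whose condition carries the best-so-far fit
#'   in `$fit`.
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @return A `spine_mixture` list: `weights`, `means`, `sds` (components
#'   sorted by mean), `loglik` (per-iteration trace), `n_iter`,
#'   `converged`.
#' @export
fit_length_mixture <- function(lengths, k = 3L, max_iter = 500L,
                               tol = 1e-8) {
  x <- as.numeric(lengths)
  k <- as.integer(k)
  if (k < 1L) .config_error("`k` must be >= 1")
  if (length(x) < 10L * k || anyNA(x)) {
    .config_error("need at least ", 10L * k, " non-missing values")
  }
  n <- length(x)
  # quantile init: centres at interior quantiles, common spread
  qs <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  mu <- qs
  sigma <- rep(stats::sd(x) / k, k)
  sd_floor <- 1e-8 * stats::sd(x) + .Machine$double.eps
  w <- rep(1 / k, k)
  loglik <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dnorm(x, mu[j], sigma[j]),
                   numeric(n))
    if (k == 1L) dens <- matrix(dens, ncol = 1L)
    rowsums <- rowSums(dens)
    rowsums[rowsums == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsums))
    loglik <- c(loglik, ll)
    if (iter > 1L && ll - loglik[iter - 1L] < tol) {
      converged <- TRUE
      break
    }
    resp <- dens / rowsums
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    sigma <- pmax(sigma, sd_floor)
  }
  ord <- order(mu)
  fit <- structure(list(weights = w[ord], means = mu[ord], sds = sigma[ord],
                        loglik = loglik, n_iter = length(loglik),
                        converged = converged),
                   class = "spine_mixture")
  if (!converged) {
    stop(errorCondition(
      sprintf("EM did not converge within %d iterations (last increment %.3g)",
              max_iter, diff(utils::tail(loglik, 2L))),
      class = c("spinesim_convergence_error", "error", "condition"),
      fit = fit))
  }
  fit
}

#' @export
print.spine_mixture <- function(x, ...) {
  cat(sprintf("<spine_mixture> %d components, loglik %.3f (%d EM iterations)\n",
              length(x$means), utils::tail(x$loglik, 1L), x$n_iter))
  print(data.frame(weight = round(x$weights, 4),
                   mean = round(x$means, 4),
                   sd = round(x$sds, 4)))
  invisible(x)
}
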