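#' Classic two-sample Student t-test (pooled variance, two-tailed)
#'
#' The equal-variance Student form, computed in closed form. Degenerate
#' inputs follow fixed conventions: zero pooled variance with equal means
#' gives p = 1; zero pooled variance with unequal means gives the
#' smallest representable positive p (certain rejection).
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return List with `statistic` (t), `df` and `p.value`.
#' @export
students_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) .config_error("each input needs >= 2 values")
  mx <- mean(x); my <- mean(y)
  df <- nx + ny - 2
  pooled <- (sum((x - mx)^2) + sum((y - my)^2)) / df
  if (pooled <= 0) {
    if (mx == my) {
      return(list(statistic = 0, df = df, p.value = 1))
    }
    return(list(statistic = sign(mx - my) * Inf, df = df,
                p.value = .Machine$double.xmin))
  }
  tstat <- (mx - my) / sqrt(pooled * (1 / nx + 1 / ny))
  list(statistic = tstat, df = df, p.value = 2 * pt(-abs(tstat), df))
}

# ---- exact Mann-Whitney ----------------------------------------------------

# Null distribution of the rank-sum W of the first group (sizes n1, n2,
# no ties): counts of subsets of {1..N} of size n1 by rank sum, computed
# by the standard shift-add dynamic programme. Counts stay below 2^53 for
# N <= 40, so doubles hold them exactly.
.ranksum_null_counts <- function(n1, n2) {
  N <- n1 + n2
  smax <- sum((N - n1 + 1):N)
  dp <- vector("list", n1 + 1L)
  dp[[1L]] <- c(1, numeric(smax))        # counts over sums 0..smax
  for (k in seq_len(n1)) dp[[k + 1L]] <- numeric(smax + 1L)
  for (j in seq_len(N)) {
    for (k in seq(min(j, n1), 1L)) {
      src <- dp[[k]]
      shifted <- c(numeric(j), src[seq_len(smax + 1L - j)])
      dp[[k + 1L]] <- dp[[k + 1L]] + shifted
    }
  }
  dp[[n1 + 1L]]                          # index s+1 holds count of sum s
}

#' Exact two-tailed Mann-Whitney-Wilcoxon u-test
#'
#' Two-tailed p from the exact permutation null distribution of the
#' rank-sum statistic, enumerated by dynamic programming, for
#' `min(n1, n2) <= 15` and `n1 + n2 <= 40` on tie-free data. Beyond those
#' sizes, or when ties are present (midranks), a continuity-corrected
#' normal approximation with tie correction is used. The exact two-sided
#' p is `2 * min(P(W <= w), P(W >= w))` capped at 1, which for the
#' symmetric null equals the summed probability of both tails.
#'
#' @param x,y Numeric vectors (>= 1 value each).
#' @return List with `statistic` (U of the first sample), `p.value`,
#'   and `exact` flag.
#' @export
exact_mann_whitney_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) .config_error("each input needs >= 1 value")
  r <- rank(c(x, y))
  ties <- anyDuplicated(c(x, y)) > 0L
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  if (!ties && min(n1, n2) <= 15L && n1 + n2 <= 40L) {
    counts <- .ranksum_null_counts(n1, n2)   # index s+1 = count of sum s
    total <- sum(counts)
    p_le <- sum(counts[seq_len(W + 1)]) / total
    p_ge <- sum(counts[(W + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = U, p.value = p, exact = TRUE))
  }
  # normal approximation, midranks, tie correction, continuity correction
  N <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(tie_tab^3 - tie_tab) /
                                (N * (N - 1)))
  if (sigma2 <= 0) return(list(statistic = U, p.value = 1, exact = FALSE))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  if (U == mu) z <- 0
  list(statistic = U, p.value = min(1, 2 * pnorm(-abs(z))), exact = FALSE)
}

#' Smallest attainable two-tailed p of the exact u-test
#'
#' The exact test's p-values form a discrete spectrum; the most extreme
#' ordering attains `2 / choose(n1 + n2, n1)`. At significance level
#' 0.001 this exceeds the level for equal groups up to n = 6, so no
#' positive outcome is possible there, and first drops below it at n = 7.
#'
#' @param n1,n2 Group sizes (>= 1).
#' @return The minimal two-tailed p (1 when both groups have one value).
#' @export
min_attainable_p_u_test <- function(n1, n2) {
  if (n1 < 1L || n2 < 1L) .config_error("group sizes must be >= 1")
  min(1, 2 / choose(n1 + n2, n1))
}

# ---- Kolmogorov-Smirnov ----------------------------------------------------

# Survival function of the Kolmogorov distribution, series form.
.kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- seq_len(100L)
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
}

#' Two-sample Kolmogorov-Smirnov test on pooled spine values
#'
#' Computes the supremum distance D between the two empirical CDFs and a
#' two-sided p-value: the exact small-sample distribution (via
#' [stats::psmirnov()]) when the effective size `n1 n2 / (n1 + n2)` is
#' below 35, and the asymptotic Kolmogorov distribution at or above that
#' fixed switchover. With ties the asymptotic form is always used (exact
#' p-values are defined only for continuous data).
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return List with `statistic` (D), `p.value`, `exact` flag.
#' @export
ks_two_sample <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) .config_error("each input needs >= 2 values")
  pooled <- c(a, b)
  o <- order(pooled)
  steps <- ifelse(o <= na, 1 / na, -1 / nb)
  cdf_diff <- cumsum(steps)
  sorted <- pooled[o]
  # at tied values only the difference after the full tie block counts
  last_of_run <- c(sorted[-1L] != sorted[-length(sorted)], TRUE)
  D <- max(abs(cdf_diff[last_of_run]))
  ne <- na * nb / (na + nb)
  ties <- anyDuplicated(pooled) > 0L
  if (ne < 35 && !ties) {
    p <- 1 - psmirnov(D, sizes = c(na, nb), two.sided = TRUE, exact = TRUE)
    return(list(statistic = D, p.value = min(1, max(0, p)), exact = TRUE))
  }
  list(statistic = D, p.value = .kolmogorov_sf(sqrt(ne) * D),
       exact = FALSE)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,trials Counts.
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
wilson_interval <- function(successes, trials, conf = 0.95) {
  if (trials < 1L) .config_error("`trials` must be >= 1")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (phat + z^2 / (2 * trials)) / denom
  half <- z * sqrt(phat * (1 - phat) / trials + z^2 / (4 * trials^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}
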