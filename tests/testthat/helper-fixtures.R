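# Shared fixtures, generated in code at test time.

# Small deterministic population built directly from values (no RNG).
tiny_pop <- function() {
  spine_population(
    length = c(1.2, 0.8, 2.5, 5.1, 1.0, 0.6),
    head_width = c(0.5, 0.4, 0.6, 0.3, 0.55, 0.35),
    neck_width = c(0.3, 0.35, 0.25, 0.28, 0.4, 0.3),
    area = c(0.5, 0.3, 0.9, 1.1, 0.45, 0.2),
    cell_id = c("a", "a", "b", "b", "c", "c")
  )
}

# Medium synthetic pool from the frozen default model, cached per session.
default_pool <- local({
  pool <- NULL
  function(n = 50000L, seed = 424242L) {
    if (is.null(pool)) pool <<- generate_population(default_spine_model(),
                                                    n = n, seed = seed)
    pool
  }
})

write_pop_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Brute-force two-tailed Mann-Whitney p by enumerating all assignments of
# the pooled values to the first group (tie-free data only). Independent
# of the package's dynamic-programming path.
brute_mann_whitney_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  w_all <- apply(sets, 2L, function(ix) sum(r[ix]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact size of the two-tailed exact u-test at level alpha: probability,
# under the enumerated null, of a rank ordering whose two-sided p is
# below alpha.
exact_u_test_size <- function(n1, n2, alpha) {
  counts <- spinesim:::.ranksum_null_counts(n1, n2)
  total <- sum(counts)
  cum <- cumsum(counts)
  rev_cum <- rev(cumsum(rev(counts)))
  p_two <- pmin(1, 2 * pmin(cum, rev_cum) / total)
  sum(counts[p_two < alpha]) / total
}
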