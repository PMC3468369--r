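#' Full specification of one simulated experiment
#'
#' @param population A [spine_population()] serving as the sampling
#'   substrate.
#' @param n Samples (cells/animals) per group (>= 2).
#' @param m Spines per sample (>= 1).
#' @param variable Morphometric variable under study.
#' @param change A [change_model()]; applied to the treatment group only
#'   (false-positive experiments use `none` or a symmetric
#'   `systematic_perturbation`, see [estimate_fpr()]).
#' @param test A [test_spec()]. A `binary_fraction` spec with no explicit
#'   area threshold gets the population's median area filled in here.
#' @param seed Default master seed for estimators run on this config.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(population, n, m, variable,
                              change = change_model("none"),
                              test = test_spec("t_test"), seed = NULL) {
  if (!inherits(population, "spine_pop")) {
    .config_error("`population` must be a spine_pop")
  }
  if (nrow(population) == 0L) .config_error("population has no records")
  if (!is.numeric(n) || n < 2) .config_error("`n` must be >= 2")
  if (!is.numeric(m) || m < 1) .config_error("`m` must be >= 1")
  .check_variable(variable)
  stopifnot(inherits(change, "change_model"), inherits(test, "test_spec"))
  if (test$test == "binary_fraction" &&
      is.null(test$thresholds$binary_area_threshold)) {
    test$thresholds$binary_area_threshold <- median(population$area)
  }
  structure(list(population = population, n = as.integer(n),
                 m = as.integer(m), variable = variable, change = change,
                 test = test, seed = seed),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> n = %d, m = %d, variable = %s, change = %s, test = %s (alpha %g)\n",
              x$n, x$m, x$variable, x$change$kind, x$test$test,
              x$test$alpha))
  invisible(x)
}

# Deterministic per-run seed stream: run r of cell c under master seed s
# uses seed (s * 48271 + c * 100003 + r) mod (2^31 - 1). Exact in double
# arithmetic for s < 2^31, and independent of execution order, so grids
# can be evaluated cell-by-cell (or in parallel) bit-reproducibly.
.run_seed <- function(master, cell, r) {
  as.integer(((as.double(master) %% 2147483647) * 48271 +
                cell * 100003 + r) %% 2147483647)
}

# One simulation run; assumes the RNG is already seeded.
.single_run <- function(config, perturb_both = FALSE) {
  pop <- config$population
  n <- config$n; m <- config$m
  idx <- sample.int(nrow(pop), 2L * n * m, replace = TRUE)
  control <- .group_from_indices(pop, idx[seq_len(n * m)], n, m, "control")
  treatment <- .group_from_indices(pop, idx[n * m + seq_len(n * m)], n, m,
                                   "treatment")
  if (perturb_both) {
    control <- apply_change(config$change, control, pop)
  }
  treatment <- apply_change(config$change, treatment, pop)
  run_test(config$test, control, treatment, config$variable)
}

#' Run a single simulated experiment
#'
#' Draws both groups from the population, applies the change model to the
#' treatment group, runs the configured test and returns the outcome.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed; the run is bit-reproducible given
#'   (config, seed).
#' @return List with `p.value` and `reject`.
#' @export
run_single_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(seed)) return(.single_run(config))
  withr::with_seed(seed, .single_run(config))
}

.error_rate_estimate <- function(events, runs) {
  ci <- wilson_interval(events, runs)
  structure(list(rate = events / runs, n_runs = runs, events = events,
                 ci95 = ci),
            class = "error_rate_estimate")
}

#' @export
print.error_rate_estimate <- function(x, ...) {
  cat(sprintf("rate %.4f  [%.4f, %.4f] Wilson 95%%  (%d/%d runs)\n",
              x$rate, x$ci95[1], x$ci95[2], x$events, x$n_runs))
  invisible(x)
}

# Shared Monte Carlo loop. counts "failures to reject" when count_fnr,
# rejections otherwise; stops early once `stop_after` events are seen
# (the remaining runs cannot change the decision the caller is making).
.mc_rate <- function(config, runs, seed, cell = 0L, perturb_both = FALSE,
                     count_fnr = TRUE, stop_after = Inf) {
  events <- 0L
  for (r in seq_len(runs)) {
    res <- withr::with_seed(.run_seed(seed, cell, r),
                            .single_run(config, perturb_both))
    hit <- if (count_fnr) !res$reject else res$reject
    if (hit) {
      events <- events + 1L
      if (events > stop_after) {
        return(list(events = events, runs_done = r, early = TRUE))
      }
    }
  }
  list(events = events, runs_done = runs, early = FALSE)
}

#' Monte Carlo estimate of the false negative rate
#'
#' Fraction of simulation runs in which the configured test fails to
#' reject although the change model was applied to the treatment group.
#'
#' @param config An [experiment_config()] with a non-`none` change.
#' @param runs Number of simulation runs (default 2000).
#' @param seed Master seed; per-run seeds are derived deterministically.
#' @return An `error_rate_estimate` (rate, run count, Wilson 95% CI).
#' @export
estimate_fnr <- function(config, runs = 2000L, seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$change$kind == "none") {
    .config_error("false-negative estimation needs a non-`none` change")
  }
  if (is.null(seed)) .config_error("a master `seed` is required")
  res <- .mc_rate(config, runs, seed, count_fnr = TRUE)
  .error_rate_estimate(res$events, runs)
}

#' Monte Carlo estimate of the false positive rate
#'
#' Both groups are drawn from the same population and compared; a
#' rejection is a Type I error. The change model must be `none` or a
#' `systematic_perturbation`, which is applied independently to *both*
#' groups (a one-sided perturbation would constitute a treatment effect).
#'
#' @inheritParams estimate_fnr
#' @param runs Default 10000.
#' @export
estimate_fpr <- function(config, runs = 10000L, seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  if (!config$change$kind %in% c("none", "systematic_perturbation")) {
    .config_error("false-positive estimation allows only `none` or ",
                  "`systematic_perturbation` changes")
  }
  if (is.null(seed)) .config_error("a master `seed` is required")
  res <- .mc_rate(config, runs, seed, perturb_both = TRUE,
                  count_fnr = FALSE)
  .error_rate_estimate(res$events, runs)
}

#' Smallest group size keeping the false negative rate at a target
#'
#' Scans `n` upward and returns the first value whose estimated false
#' negative rate is at or below `max_fnr`. The default decision uses the
#' point estimate at the configured run count (with an exact early-stop:
#' a value of `n` is abandoned as soon as its failure count can no longer
#' meet the target); `mode = "wilson"` instead requires the upper Wilson
#' bound to meet the target.
#'
#' @param config An [experiment_config()]; its `n` is ignored.
#' @param max_fnr Target false negative rate (default 0.05).
#' @param runs Runs per candidate `n` (default 2000).
#' @param n_max Scan bound.
#' @param mode `"point"` (default) or `"wilson"`.
#' @param seed Master seed.
#' @return List with `n` (integer, `NA` if `n_max` was exhausted), `fnr`
#'   (the `error_rate_estimate` at the returned `n`, or at `n_max`), and
#'   `scanned` (failure counts per candidate).
#' @export
find_min_samples <- function(config, max_fnr = 0.05, runs = 2000L,
                             n_max = 200L, mode = c("point", "wilson"),
                             seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  mode <- match.arg(mode)
  if (config$change$kind == "none") {
    .config_error("minimal-n search needs a non-`none` change")
  }
  if (is.null(seed)) .config_error("a master `seed` is required")
  max_events <- floor(max_fnr * runs)
  scanned <- list()
  last <- NULL
  for (n in 2:n_max) {
    cfg <- config
    cfg$n <- as.integer(n)
    res <- .mc_rate(cfg, runs, seed, cell = n, count_fnr = TRUE,
                    stop_after = if (mode == "point") max_events else Inf)
    scanned[[as.character(n)]] <- res$events
    if (!res$early) {
      est <- .error_rate_estimate(res$events, runs)
      last <- est
      ok <- if (mode == "point") est$rate <= max_fnr
            else est$ci95["high"] <= max_fnr
      if (ok) {
        return(list(n = n, fnr = est, scanned = unlist(scanned)))
      }
    }
  }
  list(n = NA_integer_, fnr = last, scanned = unlist(scanned))
}

#' Minimal sample sizes over an experiment grid
#'
#' One [find_min_samples()] search per grid cell (change magnitude x
#' significance level x variable x spines-per-sample), reproducing the
#' structure of a minimal-cells-per-group table.
#'
#' @param population Base [spine_population()].
#' @param magnitudes Multiplicative growth factors (default
#'   `c(1.1, 1.2, 1.5)` for 10/20/50% growth).
#' @param alphas Significance levels (default `c(0.001, 0.01)`).
#' @param variables Variables studied (default area, length, head width).
#' @param m Spines per sample (default `c(15, 30, 60)`).
#' @param test Test name (default `t_test`).
#' @param max_fnr Target false negative rate (default 0.05).
#' @param runs Runs per candidate `n`.
#' @param n_max Scan bound per cell.
#' @param seed Master seed; each cell derives its own stream.
#' @return Data frame with columns `magnitude`, `alpha`, `variable`, `m`,
#'   `min_n`, `fnr_at_min_n`, `runs`, plus a `manifest` attribute.
#' @export
power_table <- function(population, magnitudes = c(1.1, 1.2, 1.5),
                        alphas = c(0.001, 0.01),
                        variables = c("area", "length", "head_width"),
                        m = c(15, 30, 60), test = "t_test",
                        max_fnr = 0.05, runs = 2000L, n_max = 200L,
                        seed = 1L) {
  grid <- expand.grid(magnitude = magnitudes, alpha = alphas,
                      variable = variables, m = m,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$magnitude, grid$alpha, grid$variable, grid$m), ]
  rownames(grid) <- NULL
  out <- grid
  out$min_n <- NA_integer_
  out$fnr_at_min_n <- NA_real_
  out$runs <- as.integer(runs)
  for (i in seq_len(nrow(grid))) {
    cfg <- experiment_config(
      population, n = 2L, m = grid$m[i], variable = grid$variable[i],
      change = change_model("linear_growth", variable = grid$variable[i],
                            factor = grid$magnitude[i]),
      test = test_spec(test, alpha = grid$alpha[i]))
    cell_seed <- .run_seed(seed, i, 0L)
    res <- find_min_samples(cfg, max_fnr = max_fnr, runs = runs,
                            n_max = n_max, seed = cell_seed)
    out$min_n[i] <- res$n
    if (!is.null(res$fnr)) out$fnr_at_min_n[i] <- res$fnr$rate
    message(sprintf("power_table cell %d/%d: %g%% %s alpha=%g m=%d -> n=%s",
                    i, nrow(grid), 100 * (grid$magnitude[i] - 1),
                    grid$variable[i], grid$alpha[i], grid$m[i],
                    ifelse(is.na(res$n), ">n_max", res$n)))
  }
  attr(out, "manifest") <- run_manifest(seed = seed, runs = runs,
                                        cells = nrow(grid))
  out
}

#' False-negative inflation from dichotomising the area into large/small
#'
#' Compares, over a grid of growth magnitudes and spines-per-sample, the
#' false negative rate of the binary "large spine" fraction test (area
#' above the base-population median) with that of the direct per-sample
#' mean-area t-test, at matched settings. For each setting, `n` is
#' scanned upward and every value whose direct-test FNR falls in
#' `fnr_window` (the informative range: the change is neither almost
#' always nor almost never detected) contributes one paired fold
#' `FNR(fraction) / FNR(direct)`; both estimates reuse the same simulated
#' groups. The largest fold over the grid summarises how much sensitivity
#' the dichotomisation can cost.
#'
#' @param population Base [spine_population()].
#' @param magnitudes Area growth factors (default `c(1.2, 1.5)`).
#' @param m Spines per sample (default `c(15, 30, 60)`).
#' @param alpha Significance level (default 0.01).
#' @param runs Runs per estimate (default 2000).
#' @param seed Master seed.
#' @param fnr_window Admissible direct-test FNR range (default 1-50%).
#' @param n_max Scan bound.
#' @return Data frame `magnitude`, `m`, `n`, `fnr_direct`, `fnr_binary`,
#'   `fold`, one row per admissible setting.
#' @export
binary_fraction_folds <- function(population, magnitudes = c(1.2, 1.5),
                                  m = c(15, 30, 60), alpha = 0.01,
                                  runs = 2000L, seed = 1L,
                                  fnr_window = c(0.01, 0.5), n_max = 80L) {
  rows <- list()
  cell <- 0L
  for (mag in magnitudes) {
    for (mm in m) {
      cell <- cell + 1L
      change <- change_model("linear_growth", variable = "area",
                             factor = mag)
      for (n in 3:n_max) {
        dir_cfg <- experiment_config(population, n = n, m = mm,
                                     variable = "area", change = change,
                                     test = test_spec("t_test",
                                                      alpha = alpha))
        cell_seed <- .run_seed(seed, cell * 1000L + n, 0L)
        fnr_dir <- estimate_fnr(dir_cfg, runs = runs, seed = cell_seed)
        if (fnr_dir$rate < fnr_window[1]) break     # window passed
        if (fnr_dir$rate >= fnr_window[2]) next     # not yet informative
        bin_cfg <- dir_cfg
        bin_cfg$test <- test_spec("binary_fraction", alpha = alpha)
        bin_cfg <- experiment_config(population, n = n, m = mm,
                                     variable = "area", change = change,
                                     test = bin_cfg$test)
        fnr_bin <- estimate_fnr(bin_cfg, runs = runs, seed = cell_seed)
        rows[[length(rows) + 1L]] <- data.frame(
          magnitude = mag, m = mm, n = n, fnr_direct = fnr_dir$rate,
          fnr_binary = fnr_bin$rate, fold = fnr_bin$rate / fnr_dir$rate)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(magnitude = numeric(0), m = numeric(0),
                      n = integer(0), fnr_direct = numeric(0),
                      fnr_binary = numeric(0), fold = numeric(0)))
  }
  do.call(rbind, rows)
}

#' False-positive rate of the K-S test under per-sample perturbation
#'
#' Sweeps the per-sample systematic factor spread `sigma` and estimates
#' the false positive rate of the pooled two-sample K-S comparison for
#' each requested spines-per-sample `m`. Both groups receive independent
#' perturbations.
#'
#' @param population Base [spine_population()].
#' @param sigmas Non-negative factor spreads (e.g. `seq(0, 0.15, 0.025)`).
#' @param n Samples per group (default 4).
#' @param m Spines per sample (default `c(15, 30, 60)`).
#' @param variable Perturbed/measured variable (default area).
#' @param alpha Significance level (default 0.001).
#' @param runs Runs per point (default 10000).
#' @param seed Master seed.
#' @return Data frame `sigma`, `m`, `rate`, `ci_low`, `ci_high`, `runs`
#'   with a `manifest` attribute.
#' @export
fpr_sigma_sweep <- function(population, sigmas, n = 4L, m = c(15, 30, 60),
                            variable = "area", alpha = 0.001,
                            runs = 10000L, seed = 1L) {
  if (any(sigmas < 0)) .config_error("`sigmas` must be >= 0")
  grid <- expand.grid(sigma = sigmas, m = m)
  out <- grid
  out$rate <- NA_real_; out$ci_low <- NA_real_; out$ci_high <- NA_real_
  out$runs <- as.integer(runs)
  for (i in seq_len(nrow(grid))) {
    cfg <- experiment_config(
      population, n = n, m = grid$m[i], variable = variable,
      change = change_model("systematic_perturbation", variable = variable,
                            sigma = grid$sigma[i]),
      test = test_spec("ks_test", alpha = alpha))
    est <- estimate_fpr(cfg, runs = runs, seed = .run_seed(seed, i, 0L))
    out$rate[i] <- est$rate
    out$ci_low[i] <- est$ci95["low"]
    out$ci_high[i] <- est$ci95["high"]
  }
  attr(out, "manifest") <- run_manifest(seed = seed, runs = runs,
                                        cells = nrow(grid))
  out
}
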