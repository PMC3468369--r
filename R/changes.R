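#' Treatment-effect (change) models
#'
#' A `change_model` tags one of the simulated treatment effects together
#' with its parameters:
#'
#' * `none` — identity (used for false-positive experiments),
#' * `linear_growth` — one variable of every spine multiplied by `factor`,
#' * `head_swelling` — alias of `linear_growth` on the head width,
#' * `filopodia_elimination` — each spine longer than `length_threshold`
#'   is removed with probability `elimination_probability` and replaced by
#'   a fresh draw from the base population (itself refiltered), keeping
#'   the spine count per sample fixed,
#' * `small_spine_growth` — the area of each spine below `area_threshold`
#'   (decided on the pre-change area) multiplied by `factor`,
#' * `systematic_perturbation` — one Gaussian factor (mean 1, standard
#'   deviation `sigma`, redrawn until positive) per sample multiplies the
#'   chosen variable of every spine in that sample.
#'
#' @param kind One of the kinds above.
#' @param variable Target variable for `linear_growth` and
#'   `systematic_perturbation`.
#' @param factor Multiplicative effect size (e.g. 1.1, 1.2, 1.5).
#' @param length_threshold um; spines longer than this are candidates for
#'   elimination (default 2).
#' @param elimination_probability Default 0.5.
#' @param area_threshold um^2; spines below it count as "small"
#'   (default 0.8).
#' @param sigma Relative standard deviation of the per-sample factor.
#' @param replacement_from `"population"` (default: replacements drawn
#'   from the whole base table and passed through the same elimination
#'   filter) or `"below_threshold"` (replacements drawn only from spines
#'   at or below the threshold).
#' @return A `change_model` object.
#' @export
change_model <- function(kind = c("none", "linear_growth", "head_swelling",
                                  "filopodia_elimination",
                                  "small_spine_growth",
                                  "systematic_perturbation"),
                         variable = NULL, factor = 1.5,
                         length_threshold = 2, elimination_probability = 0.5,
                         area_threshold = 0.8, sigma = 0,
                         replacement_from = c("population",
                                              "below_threshold")) {
  kind <- match.arg(kind)
  replacement_from <- match.arg(replacement_from)
  if (kind %in% c("linear_growth", "systematic_perturbation")) {
    if (is.null(variable)) .config_error("`variable` required for ", kind)
    .check_variable(variable)
  }
  if (kind == "head_swelling") variable <- "head_width"
  if (!is.numeric(factor) || factor <= 0) .config_error("`factor` must be > 0")
  if (elimination_probability < 0 || elimination_probability > 1) {
    .config_error("`elimination_probability` must be in [0, 1]")
  }
  if (sigma < 0) .config_error("`sigma` must be >= 0")
  if (length_threshold <= 0 || area_threshold <= 0) {
    .config_error("thresholds must be > 0")
  }
  structure(list(kind = kind, variable = variable, factor = factor,
                 length_threshold = length_threshold,
                 elimination_probability = elimination_probability,
                 area_threshold = area_threshold, sigma = sigma,
                 replacement_from = replacement_from),
            class = "change_model")
}

#' @export
print.change_model <- function(x, ...) {
  cat("<change_model>", x$kind,
      if (!is.null(x$variable)) paste0("on ", x$variable), "\n")
  invisible(x)
}

#' Uniform linear growth of one variable
#'
#' Multiplies the chosen variable of every spine by `factor`; all other
#' variables are untouched and the spine count is unchanged.
#'
#' @param group A `spine_group`.
#' @inheritParams per_sample_means
#' @param factor Multiplier (> 0).
#' @return The modified group.
#' @export
apply_linear_growth <- function(group, variable, factor) {
  .check_variable(variable)
  if (!is.numeric(factor) || factor <= 0) .config_error("`factor` must be > 0")
  group[[variable]] <- group[[variable]] * factor
  group
}

#' Head swelling: linear growth restricted to the head width
#'
#' @inheritParams apply_linear_growth
#' @export
apply_head_swelling <- function(group, factor) {
  apply_linear_growth(group, "head_width", factor)
}

#' Growth of the small-spine subpopulation
#'
#' Multiplies the area of each spine whose *pre-change* area is below
#' `area_threshold`; membership is decided before any modification, so a
#' spine crossing the threshold is still modified exactly once.
#'
#' @param group A `spine_group`.
#' @param area_threshold um^2 (default 0.8).
#' @param factor Multiplier (default 1.5, i.e. 50% growth).
#' @export
apply_small_spine_growth <- function(group, area_threshold = 0.8,
                                     factor = 1.5) {
  if (!is.numeric(factor) || factor <= 0) .config_error("`factor` must be > 0")
  small <- group$area < area_threshold
  group$area[small] <- group$area[small] * factor
  group
}

#' Elimination of long spines (filopodia) with resampled replacements
#'
#' Each spine with length above `length_threshold` is independently
#' removed with probability `p_elim`. Removed spines are replaced by fresh
#' draws (with replacement) from the base population, each replacement
#' being subject to the same elimination rule, until every sample again
#' holds its original `m` spines. The result is a shift of the length
#' spectrum away from filopodia at constant sample size: the stationary
#' fraction of spines above the threshold is
#' `q (1 - p) / (1 - p q)` for a base-population tail fraction `q`.
#'
#' @param group A `spine_group`.
#' @param pop The base [spine_population()] replacements are drawn from.
#' @param length_threshold um (default 2).
#' @param p_elim Elimination probability (default 0.5).
#' @param seed Optional integer seed.
#' @param replacement_from `"population"` (refiltered, default) or
#'   `"below_threshold"`.
#' @export
apply_filopodia_elimination <- function(group, pop, length_threshold = 2,
                                        p_elim = 0.5, seed = NULL,
                                        replacement_from = c("population",
                                                             "below_threshold")) {
  replacement_from <- match.arg(replacement_from)
  if (!inherits(pop, "spine_pop") || nrow(pop) == 0L) {
    .config_error("`pop` must be a non-empty spine_pop")
  }
  if (p_elim < 0 || p_elim > 1) .config_error("`p_elim` must be in [0, 1]")
  run <- function() {
    total <- group$n * group$m
    elim <- group$length > length_threshold & runif(total) < p_elim
    slots <- which(elim)
    if (replacement_from == "below_threshold") {
      keep_idx <- which(pop$length <= length_threshold)
      if (!length(keep_idx)) {
        stop("no spines at or below the length threshold to draw from",
             call. = FALSE)
      }
      repl <- keep_idx[sample.int(length(keep_idx), length(slots),
                                  replace = TRUE)]
      for (v in .variables) group[[v]][slots] <- pop[[v]][repl]
      return(group)
    }
    # whole-population replacements, refiltered by the same rule
    while (length(slots)) {
      cand <- sample.int(nrow(pop), length(slots), replace = TRUE)
      keep <- pop$length[cand] <= length_threshold |
        runif(length(slots)) >= p_elim
      filled <- slots[keep]
      src <- cand[keep]
      for (v in .variables) group[[v]][filled] <- pop[[v]][src]
      slots <- slots[!keep]
    }
    group
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Per-sample systematic perturbation
#'
#' Models cell/animal/preparation effects that act on a whole sample: one
#' factor per sample is drawn from a Gaussian with mean 1 and standard
#' deviation `sigma` (redrawn until positive), and the chosen variable of
#' every spine in that sample is multiplied by it. `sigma` is the relative
#' spread of the factor, i.e. `sigma = 0.1` perturbs samples by about
#' +/-10%.
#'
#' @param group A `spine_group`.
#' @inheritParams per_sample_means
#' @param sigma Standard deviation of the per-sample factor (>= 0).
#' @param seed Optional integer seed.
#' @export
apply_systematic_perturbation <- function(group, variable, sigma,
                                          seed = NULL) {
  .check_variable(variable)
  if (sigma < 0) .config_error("`sigma` must be >= 0")
  if (sigma == 0) return(group)
  run <- function() {
    f <- rnorm(group$n, 1, sigma)
    while (any(f <= 0)) f[f <= 0] <- rnorm(sum(f <= 0), 1, sigma)
    group[[variable]] <- group[[variable]] * rep(f, each = group$m)
    group
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Apply a tagged change model to a group
#'
#' Dispatcher used by the simulator; `pop` is only needed for
#' `filopodia_elimination`.
#'
#' @param change A [change_model()].
#' @param group A `spine_group`.
#' @param pop Base population (for elimination replacements).
#' @param seed Optional integer seed for the stochastic kinds.
#' @export
apply_change <- function(change, group, pop = NULL, seed = NULL) {
  stopifnot(inherits(change, "change_model"))
  switch(change$kind,
    none = group,
    linear_growth = apply_linear_growth(group, change$variable,
                                        change$factor),
    head_swelling = apply_head_swelling(group, change$factor),
    small_spine_growth = apply_small_spine_growth(group,
                                                  change$area_threshold,
                                                  change$factor),
    filopodia_elimination = apply_filopodia_elimination(
      group, pop, change$length_threshold, change$elimination_probability,
      seed = seed, replacement_from = change$replacement_from),
    systematic_perturbation = apply_systematic_perturbation(
      group, change$variable, change$sigma, seed = seed)
  )
}
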