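#' Specification of a statistical comparison
#'
#' Pairs a test with its significance level and the datum it consumes:
#' the t- and u-tests compare per-sample means, the K-S test pools all
#' `n * m` spine values of each group, and the fraction tests compare
#' per-sample subclass fractions with a Student t-test.
#'
#' @param test One of `t_test`, `u_test`, `ks_test`, `subclass_fraction`,
#'   `binary_fraction`.
#' @param alpha Significance level in (0, 1); 0.01 and 0.001 are the
#'   conventional choices in this setting.
#' @param datum Datum convention; defaults to the convention implied by
#'   `test` and must stay consistent with it (the K-S test only ever sees
#'   pooled spines).
#' @param class Subclass compared by `subclass_fraction` (default
#'   mushroom).
#' @param thresholds [classification_thresholds()] used by the fraction
#'   tests; the binary threshold may be left `NULL` to be filled from the
#'   population median at experiment setup.
#' @export
test_spec <- function(test = c("t_test", "u_test", "ks_test",
                               "subclass_fraction", "binary_fraction"),
                      alpha = 0.01, datum = NULL, class = "mushroom",
                      thresholds = classification_thresholds()) {
  test <- match.arg(test)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    .config_error("test.alpha must be in (0, 1)")
  }
  implied <- switch(test,
                    t_test = "per_sample_mean", u_test = "per_sample_mean",
                    ks_test = "pooled_spines",
                    subclass_fraction = "per_sample_fraction",
                    binary_fraction = "per_sample_fraction")
  if (is.null(datum)) datum <- implied
  if (!identical(datum, implied)) {
    .config_error("datum `", datum, "` inconsistent with test `", test, "`")
  }
  structure(list(test = test, alpha = alpha, datum = datum,
                 class = match.arg(class, .spine_classes),
                 thresholds = thresholds),
            class = "test_spec")
}

#' @export
print.test_spec <- function(x, ...) {
  cat(sprintf("<test_spec> %s at alpha = %g (%s datum)\n", x$test, x$alpha,
              x$datum))
  invisible(x)
}

#' Run a specified test on a control/treatment pair
#'
#' Dispatches to the matching engine with the matching datum and applies
#' the rejection rule `p < alpha`.
#'
#' @param spec A [test_spec()].
#' @param control,treatment `spine_group` objects.
#' @inheritParams per_sample_means
#' @return List with `p.value` and logical `reject`.
#' @export
run_test <- function(spec, control, treatment, variable) {
  stopifnot(inherits(spec, "test_spec"))
  p <- switch(spec$test,
    t_test = students_t_test(per_sample_means(control, variable),
                             per_sample_means(treatment, variable))$p.value,
    u_test = exact_mann_whitney_test(
      per_sample_means(control, variable),
      per_sample_means(treatment, variable))$p.value,
    ks_test = ks_two_sample(control[[variable]],
                            treatment[[variable]])$p.value,
    subclass_fraction = students_t_test(
      subclass_fractions(control, class = spec$class,
                         thresholds = spec$thresholds),
      subclass_fractions(treatment, class = spec$class,
                         thresholds = spec$thresholds))$p.value,
    binary_fraction = {
      thr <- spec$thresholds$binary_area_threshold
      if (is.null(thr)) {
        .config_error("binary_fraction needs `binary_area_threshold` ",
                      "(set it, or let experiment_config() fill it from ",
                      "the population median)")
      }
      students_t_test(
        subclass_fractions(control, large_area = thr),
        subclass_fractions(treatment, large_area = thr))$p.value
    })
  list(p.value = p, reject = p < spec$alpha)
}
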