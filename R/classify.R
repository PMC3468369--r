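#' Classification thresholds for spine subclasses
#'
#' The conventional ratio-based division into filopodium / stubby /
#' mushroom / thin, applied in fixed order: a spine is a filopodium when
#' `L > filopodium_min_length`; otherwise stubby when
#' `L / N > stubby_min_ln_ratio`; the remainder are mushroom when
#' `H / N >= mushroom_min_hn_ratio`, else thin. Boundary handling: the
#' filopodium and stubby rules are strict inequalities; a spine exactly at
#' the head/neck boundary counts as mushroom (the dichotomy leaves that
#' point unassigned, and assigning it makes the rule total).
#'
#' @param filopodium_min_length um, default 4.
#' @param stubby_min_ln_ratio Default 2.
#' @param mushroom_min_hn_ratio Default 1.3.
#' @param binary_area_threshold um^2 threshold splitting "large" vs
#'   "small" spines; `NULL` (default) means: compute it as the median area
#'   of the base population at experiment setup.
#' @export
classification_thresholds <- function(filopodium_min_length = 4,
                                      stubby_min_ln_ratio = 2,
                                      mushroom_min_hn_ratio = 1.3,
                                      binary_area_threshold = NULL) {
  vals <- c(filopodium_min_length, stubby_min_ln_ratio,
            mushroom_min_hn_ratio, binary_area_threshold)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    .config_error("all thresholds must be positive")
  }
  structure(list(filopodium_min_length = filopodium_min_length,
                 stubby_min_ln_ratio = stubby_min_ln_ratio,
                 mushroom_min_hn_ratio = mushroom_min_hn_ratio,
                 binary_area_threshold = binary_area_threshold),
            class = "classification_thresholds")
}

.spine_classes <- c("filopodium", "stubby", "mushroom", "thin")

#' Classify spines into filopodium / stubby / mushroom / thin
#'
#' Vectorised and total: every spine receives exactly one class.
#'
#' @param x A `spine_group`, [spine_population()], or any list/data frame
#'   with `length`, `head_width` and `neck_width` components.
#' @param thresholds A [classification_thresholds()].
#' @return Factor with levels filopodium, stubby, mushroom, thin.
#' @export
classify_spines <- function(x, thresholds = classification_thresholds()) {
  L <- x$length; H <- x$head_width; N <- x$neck_width
  cls <- ifelse(L > thresholds$filopodium_min_length, 1L,
                ifelse(L / N > thresholds$stubby_min_ln_ratio, 2L,
                       ifelse(H / N >= thresholds$mushroom_min_hn_ratio,
                              3L, 4L)))
  factor(.spine_classes[cls], levels = .spine_classes)
}

#' Per-sample fractions of spines satisfying a predicate
#'
#' For each sample of the group, the fraction of its spines that fall in
#' a morphological subclass (`class = "mushroom"` etc.), or above an area
#' threshold (`large_area = <um^2>`), the two per-sample data used by the
#' subclass-comparison pathways.
#'
#' @param group A `spine_group`.
#' @param class One of filopodium, stubby, mushroom, thin; or `NULL`.
#' @param large_area Area threshold (um^2) defining "large" spines; used
#'   when `class` is `NULL`.
#' @param thresholds A [classification_thresholds()].
#' @return Numeric vector of length `n`, fractions in `[0, 1]`.
#' @export
subclass_fractions <- function(group, class = NULL, large_area = NULL,
                               thresholds = classification_thresholds()) {
  if (group$m < 1L) .config_error("samples must be non-empty")
  if (!is.null(class)) {
    class <- match.arg(class, .spine_classes)
    ind <- as.numeric(classify_spines(group, thresholds) == class)
  } else if (!is.null(large_area)) {
    ind <- as.numeric(group$area > large_area)
  } else {
    .config_error("give either `class` or `large_area`")
  }
  .colMeans(ind, group$m, group$n)
}
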