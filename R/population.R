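#' Construct a spine population table
#'
#' A spine population is a data frame with one row per spine and the four
#' morphometric variables used throughout the package: curvilinear spine
#' `length` (um), `head_width` (um), `neck_width` (um) and projected
#' cross-sectional `area` (um^2), plus a `cell_id` giving the cell (or
#' animal) each spine was measured on. All four variables must be finite
#' and strictly positive.
#'
#' @param length,head_width,neck_width,area Numeric vectors of equal
#'   length, in um (um^2 for `area`).
#' @param cell_id Vector of cell labels, recycled if scalar.
#' @param spine_id Optional per-spine identifier; defaults to row number.
#' @return A `spine_pop` data frame.
#' @export
spine_population <- function(length, head_width, neck_width, area,
                             cell_id = "cell1", spine_id = NULL) {
  n <- base::length(length)
  vars <- list(length = length, head_width = head_width,
               neck_width = neck_width, area = area)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (!is.numeric(v) || base::length(v) != n) {
      .config_error("`", nm, "` must be numeric with length ", n)
    }
    bad <- which(!is.finite(v) | v <= 0)
    if (base::length(bad)) {
      .config_error("non-positive or non-finite `", nm, "` at row ", bad[1L])
    }
  }
  pop <- data.frame(
    cell_id = rep_len(as.character(cell_id), n),
    spine_id = if (is.null(spine_id)) seq_len(n) else spine_id,
    length = as.numeric(length),
    head_width = as.numeric(head_width),
    neck_width = as.numeric(neck_width),
    area = as.numeric(area),
    stringsAsFactors = FALSE
  )
  class(pop) <- c("spine_pop", "data.frame")
  pop
}

#' Load a spine morphometry database from CSV
#'
#' Reads a table in the package's population schema: a UTF-8 CSV with
#' header columns `cell_id, spine_id, length_um, head_width_um,
#' neck_width_um, area_um2`, one spine per row, decimal-point numbers.
#'
#' A file with the header but no rows is accepted and returns an empty
#' population; sampling operations refuse to use it.
#'
#' @param path Path to the CSV file.
#' @return A [spine_population()] data frame.
#' @export
load_spine_database <- function(path) {
  if (!file.exists(path)) .config_error("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "spine_id", "length_um", "head_width_um",
                "neck_width_um", "area_um2")
  missing <- setdiff(required, names(raw))
  if (base::length(missing)) {
    .config_error("missing column(s) in ", path, ": ",
                  paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    pop <- spine_population(numeric(0), numeric(0), numeric(0), numeric(0),
                            cell_id = character(0), spine_id = integer(0))
    return(pop)
  }
  for (col in c("length_um", "head_width_um", "neck_width_um", "area_um2")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v) | v <= 0)
    if (base::length(bad)) {
      .config_error("invalid value in column `", col, "` at data row ",
                    bad[1L], " of ", path)
    }
    raw[[col]] <- v
  }
  spine_population(raw$length_um, raw$head_width_um, raw$neck_width_um,
                   raw$area_um2, cell_id = raw$cell_id,
                   spine_id = raw$spine_id)
}

#' @export
print.spine_pop <- function(x, ...) {
  cat(sprintf("<spine_pop> %d spines from %d cell(s)\n",
              nrow(x), base::length(unique(x$cell_id))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

# ---- groups ----------------------------------------------------------------

# A spine_group holds n samples of m spines each as flat vectors ordered
# sample-by-sample (spines of sample i occupy rows (i-1)*m + 1:m). The
# regular layout lets per-sample summaries reduce to .colMeans.
new_spine_group <- function(n, m, length, head_width, neck_width, area,
                            label = "control") {
  structure(list(n = as.integer(n), m = as.integer(m),
                 sample_id = rep(seq_len(n), each = m),
                 length = length, head_width = head_width,
                 neck_width = neck_width, area = area, label = label),
            class = "spine_group")
}

#' @export
print.spine_group <- function(x, ...) {
  cat(sprintf("<spine_group '%s'> n = %d samples x m = %d spines\n",
              x$label, x$n, x$m))
  invisible(x)
}

.group_from_indices <- function(pop, idx, n, m, label) {
  new_spine_group(n, m,
                  length = pop$length[idx],
                  head_width = pop$head_width[idx],
                  neck_width = pop$neck_width[idx],
                  area = pop$area[idx],
                  label = label)
}

#' Draw a control and a treatment group from a population
#'
#' Assembles two groups of `n` samples with `m` spines each by sampling
#' spines with replacement from the pooled population table. Both groups
#' are drawn from the identical source; treatment effects are applied
#' afterwards (see [apply_change()]).
#'
#' @param pop A [spine_population()].
#' @param n Samples (cells/animals) per group; at least 2.
#' @param m Spines per sample; at least 1.
#' @param seed Optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A list with elements `control` and `treatment`, each a
#'   `spine_group`.
#' @export
draw_groups <- function(pop, n, m, seed = NULL) {
  if (!inherits(pop, "spine_pop")) .config_error("`pop` must be a spine_pop")
  if (nrow(pop) == 0L) .config_error("population has no records; cannot sample")
  if (!is.numeric(n) || n < 2) .config_error("`n` must be >= 2")
  if (!is.numeric(m) || m < 1) .config_error("`m` must be >= 1")
  n <- as.integer(n); m <- as.integer(m)
  draw <- function() {
    idx <- sample.int(nrow(pop), 2L * n * m, replace = TRUE)
    list(control = .group_from_indices(pop, idx[seq_len(n * m)], n, m,
                                       "control"),
         treatment = .group_from_indices(pop, idx[n * m + seq_len(n * m)],
                                         n, m, "treatment"))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Per-sample means of a morphometric variable
#'
#' The statistical unit ("datum") of the t- and u-test pathways: the chosen
#' variable averaged over all spines of one sample.
#'
#' @param group A `spine_group`.
#' @param variable One of `"length"`, `"head_width"`, `"neck_width"`,
#'   `"area"`.
#' @return Numeric vector of length `n` (one mean per sample, in sample
#'   order).
#' @export
per_sample_means <- function(group, variable) {
  .check_variable(variable)
  if (!inherits(group, "spine_group")) {
    .config_error("`group` must be a spine_group")
  }
  if (group$m < 1L) .config_error("samples must be non-empty")
  v <- group[[variable]]
  .colMeans(v, group$m, group$n)
}

# ---- excess kurtosis -------------------------------------------------------

#' Sample excess kurtosis
#'
#' Fourth standardized central moment minus 3, using the bias-uncorrected
#' ("population") moment estimator. Zero for Gaussian data, positive for
#' heavy tails (about -1.2 for uniform data).
#'
#' @param x Numeric vector with at least 4 values and nonzero variance.
#' @return The excess kurtosis.
#' @export
excess_kurtosis <- function(x) {
  x <- as.numeric(x)
  if (base::length(x) < 4L || anyNA(x)) {
    stop("need at least 4 non-missing values", call. = FALSE)
  }
  m <- mean(x)
  d <- x - m
  s2 <- mean(d^2)
  if (s2 <= 0) stop("zero variance: kurtosis undefined", call. = FALSE)
  mean(d^4) / s2^2 - 3
}
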