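#' Run manifest
#'
#' Light provenance record attached to result tables so any emitted file
#' can be traced to the package version, master seed and run counts that
#' produced it (and regenerated bit-identically from them).
#'
#' @param seed Master seed.
#' @param runs Runs per cell.
#' @param cells Number of grid cells.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(seed, runs, cells = 1L) {
  structure(list(package = "spinesim",
                 version = as.character(packageVersion("spinesim")),
                 seed = seed, runs = runs, cells = cells,
                 created = format(Sys.time(), tz = "UTC",
                                  "%Y-%m-%dT%H:%M:%SZ")),
            class = "run_manifest")
}

#' Parse an experiment configuration file
#'
#' Reads a JSON or YAML experiment description and returns a validated
#' [experiment_config()] (or a list of them when a `grid` block is
#' present). Recognised keys:
#'
#' ```yaml
#' population: synthetic-default   # or a path to a population CSV
#' population_size: 200000         # synthetic pool size
#' n: 8
#' m: 60
#' variable: head_width
#' change: {kind: linear_growth, factor: 1.2}
#' test: {name: t_test, alpha: 0.01}
#' runs: 2000                      # default 2000 (FNR) / 10000 (FPR)
#' seed: 1
#' grid: {factor: [1.1, 1.2], alpha: [0.01, 0.001]}   # optional
#' ```
#'
#' Unknown keys and out-of-range values raise configuration errors naming
#' the key path.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An `experiment_config`, or a list of them (class
#'   `experiment_grid`) when `grid` is present.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) .config_error("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML 1.1 reads a bare `n:` key as the boolean FALSE; map it back.
  names(raw)[names(raw) == "FALSE"] <- "n"
  names(raw)[names(raw) == "n_samples"] <- "n"
  names(raw)[names(raw) == "m_spines"] <- "m"
  known <- c("population", "population_size", "n", "m", "variable",
             "change", "test", "runs", "seed", "grid")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    .config_error("unknown configuration key(s): ",
                  paste(unknown, collapse = ", "))
  }
  for (key in c("n", "m", "variable")) {
    if (is.null(raw[[key]])) .config_error("missing key `", key, "`")
  }
  pop_ref <- raw[["population"]] %||% "synthetic-default"
  population <- if (identical(pop_ref, "synthetic-default")) {
    generate_population(default_spine_model(),
                        n = raw[["population_size"]] %||% 200000L,
                        seed = raw[["seed"]] %||% 1L)
  } else {
    load_spine_database(pop_ref)
  }
  build_one <- function(factor = NULL, alpha = NULL, m = NULL,
                        variable = NULL) {
    ch <- raw[["change"]] %||% list(kind = "none")
    if (!is.null(factor)) ch$factor <- factor
    te <- raw[["test"]] %||% list(name = "t_test")
    if (!is.null(alpha)) te$alpha <- alpha
    if (!is.null(te$alpha) && (!is.numeric(te$alpha) || te$alpha <= 0 ||
                               te$alpha >= 1)) {
      .config_error("test.alpha must be in (0, 1), got ", te$alpha)
    }
    if (!is.null(ch$sigma) && ch$sigma < 0) {
      .config_error("change.sigma must be >= 0")
    }
    change <- change_model(
      kind = ch$kind %||% "none", variable = ch$variable %||% raw[["variable"]],
      factor = ch$factor %||% 1.5,
      length_threshold = ch$length_threshold %||% 2,
      elimination_probability = ch$elimination_probability %||% 0.5,
      area_threshold = ch$area_threshold %||% 0.8,
      sigma = ch$sigma %||% 0)
    test <- test_spec(te$name %||% "t_test", alpha = te$alpha %||% 0.01,
                      class = te$class %||% "mushroom")
    cfg <- experiment_config(population, n = raw[["n"]], m = m %||% raw[["m"]],
                             variable = variable %||% raw[["variable"]],
                             change = change, test = test,
                             seed = raw[["seed"]] %||% 1L)
    cfg$runs <- raw[["runs"]] %||%
      if (change$kind %in% c("none", "systematic_perturbation")) 10000L
      else 2000L
    cfg
  }
  if (is.null(raw[["grid"]])) return(build_one())
  g <- raw[["grid"]]
  axes <- list(factor = g$factor %||% NA, alpha = g$alpha %||% NA,
               m = g$m %||% NA, variable = g$variable %||% NA)
  cells <- expand.grid(axes, stringsAsFactors = FALSE)
  configs <- lapply(seq_len(nrow(cells)), function(i) {
    build_one(
      factor = if (!is.na(cells$factor[i])) cells$factor[i],
      alpha = if (!is.na(cells$alpha[i])) cells$alpha[i],
      m = if (!is.na(cells$m[i])) cells$m[i],
      variable = if (!is.na(cells$variable[i])) cells$variable[i])
  })
  structure(configs, class = "experiment_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic fixture population to CSV
#'
#' Generates `n` spines from the frozen default model, spread over
#' `cells` cell labels, and writes them in the package's population
#' schema; the file round-trips losslessly through
#' [load_spine_database()] and is byte-identical for a fixed seed.
#'
#' @param path Output CSV path.
#' @param n Spines (default 2499).
#' @param cells Cell labels (default 34).
#' @param seed Integer seed (default 1).
#' @return The path, invisibly.
#' @export
write_fixture_population <- function(path, n = 2499L, cells = 34L,
                                     seed = 1L) {
  pop <- generate_population(default_spine_model(), n = n, seed = seed,
                             cells = cells)
  out <- data.frame(cell_id = pop$cell_id, spine_id = pop$spine_id,
                    length_um = sprintf("%.6f", pop$length),
                    head_width_um = sprintf("%.6f", pop$head_width),
                    neck_width_um = sprintf("%.6f", pop$neck_width),
                    area_um2 = sprintf("%.6f", pop$area))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a result table to disk
#'
#' Deterministic column order; rate-like columns rendered with fixed
#' 4-decimal precision so files diff cleanly.
#'
#' @param table A data frame (e.g. from [power_table()] or
#'   [fpr_sigma_sweep()]).
#' @param path Output path.
#' @param format `"csv"`, `"tsv"` or `"markdown"`.
#' @return The path, invisibly.
#' @export
write_table <- function(table, path, format = c("csv", "tsv", "markdown")) {
  format <- match.arg(format)
  df <- as.data.frame(table)
  for (col in intersect(c("fnr_at_min_n", "rate", "ci_low", "ci_high"),
                        names(df))) {
    df[[col]] <- sprintf("%.4f", df[[col]])
  }
  if (format == "markdown") {
    cells <- vapply(df, as.character, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    lines <- c(paste0("| ", paste(names(df), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(df)), collapse = "|"),
                      "|"),
               apply(cells, 1L, function(r) {
                 paste0("| ", paste(r, collapse = " | "), " |")
               }))
    writeLines(lines, path)
  } else {
    write.table(df, path, sep = if (format == "csv") "," else "\t",
                row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
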