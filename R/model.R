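#' Hierarchical synthetic spine-population model
#'
#' The generator draws each spine in two stages. First an archetype
#' (stubby, thin, mushroom or filopodium) is picked with the model's
#' weights. Conditional on the archetype, spine length `L` and neck width
#' `N` are lognormal, the head/neck ratio `r = H/N` is lognormal (so the
#' head width is `H = N * r`), and the cross-sectional area couples the
#' linear measures through `A = kappa * L * H * eps` with a mean-one
#' lognormal noise factor `eps`. The construction induces realistic
#' correlation among `L`, `H` and `A` and a heavy area tail while keeping
#' every marginal a lognormal mixture, so all moments are available in
#' closed form (see [model_moments()]).
#'
#' @param weights Archetype probabilities (stubby, thin, mushroom,
#'   filopodium); must sum to 1.
#' @param length_meanlog,length_sdlog Lognormal log-scale location/spread
#'   of `L` per archetype (um).
#' @param neck_meanlog,neck_sdlog Same for the neck width `N` (um).
#' @param ratio_meanlog,ratio_sdlog Same for the head/neck ratio `r`.
#' @param area_coupling Scalar `kappa` in `A = kappa * L * H * eps`.
#' @param area_noise_sdlog Log-scale spread of the mean-one area noise
#'   `eps`.
#' @param calibration Optional list recording how the parameters were
#'   fixed (kept for provenance; not used in computation).
#' @return A `spine_model` object.
#' @seealso [default_spine_model()], [calibrate_spine_model()],
#'   [generate_population()]
#' @export
spine_model <- function(weights,
                        length_meanlog, length_sdlog,
                        neck_meanlog, neck_sdlog,
                        ratio_meanlog, ratio_sdlog,
                        area_coupling = 0.7,
                        area_noise_sdlog = 0.25,
                        calibration = NULL) {
  k <- 4L
  num4 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != k || anyNA(v)) {
      .config_error("`", nm, "` must be numeric of length ", k)
    }
    as.numeric(v)
  }
  weights <- num4(weights, "weights")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    .config_error("`weights` must be non-negative and sum to 1")
  }
  for (nm in c("length_sdlog", "neck_sdlog", "ratio_sdlog")) {
    v <- get(nm)
    if (any(num4(v, nm) <= 0)) .config_error("`", nm, "` must be > 0")
  }
  if (!is.numeric(area_coupling) || area_coupling <= 0) {
    .config_error("`area_coupling` must be > 0")
  }
  if (!is.numeric(area_noise_sdlog) || area_noise_sdlog <= 0) {
    .config_error("`area_noise_sdlog` must be > 0")
  }
  structure(list(
    archetypes = c("stubby", "thin", "mushroom", "filopodium"),
    weights = weights,
    length_meanlog = num4(length_meanlog, "length_meanlog"),
    length_sdlog = num4(length_sdlog, "length_sdlog"),
    neck_meanlog = num4(neck_meanlog, "neck_meanlog"),
    neck_sdlog = num4(neck_sdlog, "neck_sdlog"),
    ratio_meanlog = num4(ratio_meanlog, "ratio_meanlog"),
    ratio_sdlog = num4(ratio_sdlog, "ratio_sdlog"),
    area_coupling = as.numeric(area_coupling),
    area_noise_sdlog = as.numeric(area_noise_sdlog),
    calibration = calibration
  ), class = "spine_model")
}

#' @export
print.spine_model <- function(x, ...) {
  cat("<spine_model> archetype weights:",
      paste(sprintf("%s %.3f", x$archetypes, x$weights), collapse = ", "),
      "\n")
  mom <- model_moments(x)
  cat(sprintf("  population excess kurtosis: length %.2f, head-width %.2f, area %.2f\n",
              mom["length", "exkurt"], mom["head_width", "exkurt"],
              mom["area", "exkurt"]))
  invisible(x)
}

#' Starting-point model used by the calibration search
#'
#' Archetype weights 0.25/0.40/0.25/0.10 with a filopodium length scale of
#' 5 um, head-width modes at 0.45/0.38/0.60/0.30 um, and head/neck ratio
#' modes separated around the mushroom/thin boundary (thin near 1,
#' mushroom near 1.6). [calibrate_spine_model()] adjusts the filopodium
#' weight, the length spread and the neck spread from here.
#'
#' @return A `spine_model`.
#' @export
starting_spine_model <- function() {
  head_mu <- log(c(0.45, 0.38, 0.60, 0.30))
  ratio_mu <- log(c(0.95, 1.00, 1.60, 0.90))
  spine_model(
    weights = c(0.25, 0.40, 0.25, 0.10),
    length_meanlog = log(c(0.7, 1.4, 1.2, 5.0)),
    length_sdlog = c(0.30, 0.30, 0.30, 0.25),
    neck_meanlog = head_mu - ratio_mu,
    neck_sdlog = rep(0.15, 4),
    ratio_meanlog = ratio_mu,
    ratio_sdlog = c(0.22, 0.22, 0.25, 0.22)
  )
}

# ---- closed-form moments ---------------------------------------------------

# Raw k-th moment of a lognormal mixture.
.mix_raw_moment <- function(k, w, mu, sdlog) {
  sum(w * exp(k * mu + k^2 * sdlog^2 / 2))
}

.mix_summary <- function(w, mu, sdlog) {
  M <- vapply(1:4, .mix_raw_moment, numeric(1), w = w, mu = mu,
              sdlog = sdlog)
  v <- M[2] - M[1]^2
  mu4 <- M[4] - 4 * M[1] * M[3] + 6 * M[1]^2 * M[2] - 3 * M[1]^4
  c(mean = M[1], sd = sqrt(v), exkurt = mu4 / v^2 - 3)
}

#' Closed-form population moments of a synthetic model
#'
#' Every marginal of the hierarchical generator is a four-component
#' lognormal mixture, so mean, standard deviation and excess kurtosis are
#' exact weighted sums of lognormal raw moments. The calibration search
#' optimises these analytic values; Monte Carlo enters only when samples
#' are generated.
#'
#' @param model A [spine_model()].
#' @return Matrix with rows `length`, `head_width`, `neck_width`, `area`
#'   and columns `mean`, `sd`, `exkurt`.
#' @export
model_moments <- function(model) {
  stopifnot(inherits(model, "spine_model"))
  w <- model$weights
  head_mu <- model$neck_meanlog + model$ratio_meanlog
  head_sd <- sqrt(model$neck_sdlog^2 + model$ratio_sdlog^2)
  eps_mu <- -model$area_noise_sdlog^2 / 2  # mean-one noise
  area_mu <- log(model$area_coupling) + model$length_meanlog + head_mu +
    eps_mu
  area_sd <- sqrt(model$length_sdlog^2 + head_sd^2 +
                    model$area_noise_sdlog^2)
  out <- rbind(
    length = .mix_summary(w, model$length_meanlog, model$length_sdlog),
    head_width = .mix_summary(w, head_mu, head_sd),
    neck_width = .mix_summary(w, model$neck_meanlog, model$neck_sdlog),
    area = .mix_summary(w, area_mu, area_sd)
  )
  out
}

# ---- generation ------------------------------------------------------------

#' Generate a synthetic spine population
#'
#' @param model A [spine_model()]; defaults to the frozen calibrated model
#'   shipped with the package.
#' @param n Number of spines to generate (>= 1).
#' @param seed Optional integer seed (bit-reproducible draws; caller RNG
#'   state preserved).
#' @param cells Number of synthetic cell labels to spread the spines over
#'   (balanced assignment); purely a labelling device, sampling pools all
#'   spines.
#' @return A [spine_population()] with an `archetype` attribute giving the
#'   latent archetype of each spine.
#' @export
generate_population <- function(model = default_spine_model(), n,
                                seed = NULL, cells = 1L) {
  stopifnot(inherits(model, "spine_model"))
  if (!is.numeric(n) || n < 1) .config_error("`n` must be >= 1")
  n <- as.integer(n)
  gen <- function() {
    a <- sample.int(4L, n, replace = TRUE, prob = model$weights)
    L <- rlnorm(n, model$length_meanlog[a], model$length_sdlog[a])
    N <- rlnorm(n, model$neck_meanlog[a], model$neck_sdlog[a])
    H <- N * rlnorm(n, model$ratio_meanlog[a], model$ratio_sdlog[a])
    A <- model$area_coupling * L * H *
      rlnorm(n, -model$area_noise_sdlog^2 / 2, model$area_noise_sdlog)
    cell <- sprintf("cell%02d", rep_len(seq_len(max(1L, as.integer(cells))),
                                        n))
    pop <- spine_population(L, H, N, A, cell_id = sort(cell))
    attr(pop, "archetype") <- model$archetypes[a]
    pop
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# ---- calibration -----------------------------------------------------------

#' Calibrate the synthetic model against distribution-shape targets
#'
#' Adjusts three knobs of the starting-point model -- the filopodium
#' weight (the other weights are rescaled proportionally), a common scale
#' on the archetype length spreads, and the shared neck-width spread --
#' so that the population excess kurtosis of spine length and head width
#' match the requested targets. The objective uses the closed-form mixture
#' moments of [model_moments()], so the search is deterministic and fast:
#' a coarse grid pass followed by box-constrained quasi-Newton refinement.
#'
#' @param target_length_kurtosis,target_head_kurtosis Excess-kurtosis
#'   targets for spine length and head width.
#' @param start Starting model; see [starting_spine_model()].
#' @param tolerance Maximum relative deviation per target before the
#'   calibration is declared failed (default 10%).
#' @return A calibrated `spine_model` whose `calibration` field records
#'   targets, achieved values and knob settings.
#' @export
calibrate_spine_model <- function(target_length_kurtosis = 7.97,
                                  target_head_kurtosis = 2.02,
                                  start = starting_spine_model(),
                                  tolerance = 0.10) {
  stopifnot(inherits(start, "spine_model"))
  base_w <- start$weights
  apply_knobs <- function(p) {
    wf <- p[1]; s_len <- p[2]; neck_sd <- p[3]
    w <- c(base_w[1:3] / sum(base_w[1:3]) * (1 - wf), wf)
    m <- start
    m$weights <- w
    m$length_sdlog <- start$length_sdlog * s_len
    m$neck_sdlog <- rep(neck_sd, 4L)
    m
  }
  objective <- function(p) {
    mom <- model_moments(apply_knobs(p))
    (mom["length", "exkurt"] / target_length_kurtosis - 1)^2 +
      (mom["head_width", "exkurt"] / target_head_kurtosis - 1)^2
  }
  lower <- c(0.005, 0.4, 0.03)
  upper <- c(0.20, 1.5, 0.35)
  best <- NULL; best_val <- Inf
  for (wf in seq(0.02, 0.18, by = 0.01)) {
    for (s_len in seq(0.5, 1.4, by = 0.1)) {
      for (neck_sd in seq(0.05, 0.30, by = 0.05)) {
        v <- objective(c(wf, s_len, neck_sd))
        if (v < best_val) { best_val <- v; best <- c(wf, s_len, neck_sd) }
      }
    }
  }
  opt <- stats::optim(best, objective, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 1e3))
  model <- apply_knobs(opt$par)
  mom <- model_moments(model)
  achieved <- c(length = unname(mom["length", "exkurt"]),
                head_width = unname(mom["head_width", "exkurt"]))
  rel <- abs(achieved / c(target_length_kurtosis, target_head_kurtosis) - 1)
  model$calibration <- list(
    targets = c(length = target_length_kurtosis,
                head_width = target_head_kurtosis),
    achieved = achieved,
    knobs = c(filopodium_weight = opt$par[1],
              length_sdlog_scale = opt$par[2],
              neck_sdlog = opt$par[3]),
    objective = opt$value
  )
  if (any(rel > tolerance)) {
    stop(errorCondition(
      sprintf(paste0("calibration failed: achieved kurtosis (length %.3f, ",
                     "head-width %.3f) outside +/-%.0f%% of targets"),
              achieved[1], achieved[2], 100 * tolerance),
      class = c("spinesim_calibration_error", "error", "condition"),
      model = model))
  }
  model
}

#' The frozen default population model
#'
#' Parameters fixed once by running [calibrate_spine_model()] with the
#' shipped targets and stored in `inst/extdata/default_model.json`; loaded
#' lazily and cached for the session.
#'
#' @return A `spine_model`.
#' @export
default_spine_model <- function() {
  if (!is.null(.spinesim_env$default_model)) return(.spinesim_env$default_model)
  path <- system.file("extdata", "default_model.json", package = "spinesim",
                      mustWork = TRUE)
  pars <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- spine_model(
    weights = pars$weights,
    length_meanlog = pars$length_meanlog,
    length_sdlog = pars$length_sdlog,
    neck_meanlog = pars$neck_meanlog,
    neck_sdlog = pars$neck_sdlog,
    ratio_meanlog = pars$ratio_meanlog,
    ratio_sdlog = pars$ratio_sdlog,
    area_coupling = pars$area_coupling,
    area_noise_sdlog = pars$area_noise_sdlog,
    calibration = pars$calibration
  )
  .spinesim_env$default_model <- model
  model
}
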