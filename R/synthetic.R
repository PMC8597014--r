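# Synthetic time-course generator: emulates 1H-NMR-derived species
# fractions sampled over ~4 weeks with a drifting pH and additive
# integration noise, so the whole fitting pipeline is testable without
# external data.

#' pH drift model
#'
#' Describes how the solution pH evolves over an experiment: constant,
#' linear decay from `ph_start` to `ph_end` over the horizon, or an
#' exponential approach `ph_end + (ph_start - ph_end) * exp(-t /
#' timescale)`. The defaults emulate a four-week migration experiment in
#' which the pH settles at 7.95 on dissolution and drifts to about 7.75
#' as hydrolysis releases acetic acid.
#'
#' @param kind `"constant"`, `"linear"` or `"exponential_approach"`.
#' @param ph_start Starting pH (used alone for `"constant"`).
#' @param ph_end Final pH (drift kinds); must satisfy
#'   `0 <= ph_end <= ph_start <= 14`.
#' @param horizon Experiment length in hours (default 672 h = 4 weeks).
#' @param timescale Approach timescale in hours
#'   (`"exponential_approach"` only).
#' @return An object of class `ph_drift_model`.
#' @export
ph_drift_model <- function(kind = c("linear", "constant",
                                    "exponential_approach"),
                           ph_start = 7.95, ph_end = 7.75, horizon = 672,
                           timescale = NULL) {
  kind <- match.arg(kind)
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  if (ph_start < 0 || ph_start > 14) {
    stop("ph_start must lie in [0, 14]", call. = FALSE)
  }
  if (kind != "constant") {
    if (ph_end < 0 || ph_end > ph_start) {
      stop("drift requires 0 <= ph_end <= ph_start <= 14", call. = FALSE)
    }
    if (kind == "exponential_approach") {
      if (is.null(timescale) || timescale <= 0) {
        stop("exponential_approach requires a positive timescale",
             call. = FALSE)
      }
    }
  }
  structure(list(kind = kind, ph_start = ph_start, ph_end = ph_end,
                 horizon = horizon, timescale = timescale),
            class = "ph_drift_model")
}

#' Sample a pH drift model onto a profile
#'
#' @param model A [ph_drift_model()].
#' @param n_points Number of uniformly spaced readings (>= 2 for the
#'   drift kinds). Endpoints hit `ph_start`/`ph_end` exactly for the
#'   linear kind.
#' @return A [ph_profile()].
#' @export
#' @examples
#' ph_drift_profile(ph_drift_model("linear", 7.95, 7.75, 672), 5)
ph_drift_profile <- function(model, n_points = 25) {
  stopifnot(inherits(model, "ph_drift_model"))
  if (model$kind == "constant") {
    return(constant_ph_profile(model$ph_start))
  }
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  t <- seq(0, model$horizon, length.out = n_points)
  ph <- switch(model$kind,
    linear = model$ph_start +
      (model$ph_end - model$ph_start) * t / model$horizon,
    exponential_approach = model$ph_end +
      (model$ph_start - model$ph_end) * exp(-t / model$timescale))
  ph_profile(t, ph)
}

#' Measurement noise model
#'
#' Additive Gaussian noise on mole fractions, emulating the precision of
#' 1H-NMR acetyl-peak integration. The default sigma of 0.005 absolute
#' fraction is a plausible integral precision for well-separated
#' singlets; it is a synthetic choice, not a measured value.
#'
#' @param kind `"gaussian"` or `"none"`.
#' @param sigma Noise standard deviation (absolute mole fraction, >= 0).
#' @param clip_to_simplex If `TRUE` (default), noisy fractions are
#'   clipped to \[0, 1\] and rows summing above 1 are renormalized.
#' @param seed Integer seed making generation deterministic.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("gaussian", "none"), sigma = 0.005,
                        clip_to_simplex = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(kind = kind, sigma = sigma,
                 clip_to_simplex = isTRUE(clip_to_simplex),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Generator configuration
#'
#' Full description of one synthetic experiment: which network, which
#' constants, the starting composition, the sampling design, the pH
#' drift and the noise.
#'
#' Starting presets: `"from_1a"` puts all mass in species 1a (optionally
#' redistributing `initial_hydrolyzed_fraction` into 1d/1e at the O2:O3
#' equilibrium split, mirroring the ~10 % hydrolysis already present at
#' a first NMR measurement); `"from_1b"` puts all mass in 1b;
#' `"ggm_default"` starts GGM at (A, B, C, D) = (0.39, 0.61, 0, 0) — the
#' acetyl-bearing units normalized to 1 and split by the observed 61:39
#' O2:O3 equilibrium, with no O6 acetylation at the start.
#'
#' The default sampling design is 25 points geometrically spaced from
#' 1 h to 672 h: dense early sampling resolves the fast O2/O3
#' equilibration, the four-week tail identifies migration and
#' hydrolysis.
#'
#' @param model_kind `"trisaccharide"` or `"ggm"`.
#' @param constants A [rate_constants()] object; default the
#'   trisaccharide preset.
#' @param start `"from_1a"`, `"from_1b"` or `"ggm_default"` (ignored if
#'   `initial_state` is given).
#' @param initial_state Optional explicit starting state.
#' @param initial_hydrolyzed_fraction Fraction already hydrolyzed at
#'   time 0 (default 0; the `"from_1a"` preset accepts e.g. 0.10).
#' @param sample_times Sampling times (hours); default geometric design.
#' @param ph_model A [ph_drift_model()]; default linear 7.95 -> 7.75
#'   over 672 h.
#' @param noise A [noise_model()].
#' @param label Dataset label.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(model_kind = c("trisaccharide", "ggm"),
                             constants = NULL,
                             start = c("from_1a", "from_1b", "ggm_default"),
                             initial_state = NULL,
                             initial_hydrolyzed_fraction = 0,
                             sample_times = NULL,
                             ph_model = ph_drift_model(),
                             noise = noise_model(),
                             label = NULL) {
  model_kind <- match.arg(model_kind)
  start <- match.arg(start)
  if (is.null(constants)) {
    constants <- rate_constants_preset(
      if (model_kind == "trisaccharide") "trisaccharide" else "ggm-2mg")
  }
  constants <- as_rate_constants(constants)
  if (model_kind == "ggm" && start %in% c("from_1a", "from_1b")) {
    start <- "ggm_default"
  }
  if (initial_hydrolyzed_fraction < 0 || initial_hydrolyzed_fraction >= 1) {
    stop("initial_hydrolyzed_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(sample_times)) {
    sample_times <- 10^seq(0, log10(672), length.out = 25)
  }
  sample_times <- check_times(sample_times)
  stopifnot(inherits(ph_model, "ph_drift_model"),
            inherits(noise, "noise_model"))
  if (ph_model$kind != "constant" &&
      max(sample_times) > ph_model$horizon + 1e-9) {
    stop("sample_times must lie within [0, ph_model$horizon]",
         call. = FALSE)
  }
  if (is.null(label)) label <- paste(model_kind, start)
  structure(list(model_kind = model_kind, constants = constants,
                 start = start, initial_state = initial_state,
                 initial_hydrolyzed_fraction = initial_hydrolyzed_fraction,
                 sample_times = sample_times, ph_model = ph_model,
                 noise = noise, label = label),
            class = "generator_config")
}

generator_initial_state <- function(config) {
  if (!is.null(config$initial_state)) {
    return(as_state(config$initial_state, config$model_kind))
  }
  sp <- species_names(config$model_kind)
  state <- setNames(numeric(length(sp)), sp)
  h <- config$initial_hydrolyzed_fraction
  if (config$start == "ggm_default") {
    state[c("c_A", "c_B")] <- c(0.39, 0.61)
  } else if (config$start == "from_1a") {
    state["c_1a"] <- 1 - h
    if (h > 0) {
      fO2 <- equilibrium_O2_fraction(config$constants)
      state["c_1e"] <- h * fO2
      state["c_1d"] <- h * (1 - fO2)
    }
  } else {
    state["c_1b"] <- 1 - h
    if (h > 0) state["c_1f"] <- h
  }
  state
}

#' Generate a synthetic time-course dataset
#'
#' Simulates the exact trajectory under the configured pH drift, then
#' applies the noise model. Deterministic given the noise seed; the
#' caller's RNG state is left untouched.
#'
#' @param config A [generator_config()].
#' @return A [timecourse_dataset()] whose `ph_profile` is the sampled
#'   drift profile and whose `initial_state` is the exact (noise-free)
#'   starting state.
#' @export
#' @examples
#' cfg <- generator_config(noise = noise_model("none"))
#' generate_dataset(cfg)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  y0 <- generator_initial_state(config)
  profile <- ph_drift_profile(config$ph_model)
  tr <- simulate_closed_form(config$constants, y0, profile,
                             config$sample_times, config$model_kind)
  obs <- tr$states
  value_tol <- 1e-9
  if (config$noise$kind == "gaussian" && config$noise$sigma > 0) {
    if (!config$noise$clip_to_simplex) {
      value_tol <- 6 * config$noise$sigma
    }
    rng <- get_rng_state()
    on.exit(restore_rng_state(rng), add = TRUE)
    set.seed(config$noise$seed)
    obs <- obs + matrix(rnorm(length(obs), 0, config$noise$sigma),
                        nrow(obs), ncol(obs))
    if (config$noise$clip_to_simplex) {
      obs <- pmin(pmax(obs, 0), 1)
      sums <- rowSums(obs)
      over <- sums > 1
      obs[over, ] <- obs[over, , drop = FALSE] / sums[over]
    }
  }
  timecourse_dataset(model_kind = config$model_kind,
                     sample_times = config$sample_times,
                     observations = obs,
                     ph_profile = profile,
                     initial_state = y0,
                     label = config$label,
                     value_tol = value_tol)
}

#' Parameter-recovery simulation study
#'
#' Generates `n_replicates` noisy datasets from known constants, refits
#' each, and summarizes how well the generating constants are recovered:
#' per-parameter relative bias, relative RMSE, and the coverage of the
#' +/- 2 standard-error interval. Replicate fit failures are recorded
#' and counted, not fatal.
#'
#' @param config A [generator_config()] or list of them (the latter are
#'   fitted jointly, e.g. paired 1a-/1b-start experiments).
#' @param fit_config A [fit_config()]; `NULL` uses the defaults.
#' @param n_replicates Number of replicates (>= 1).
#' @param seed Base seed; replicate `i` uses noise seed
#'   `seed * 1000 + i`.
#' @return An object of class `recovery_report`: `per_parameter` data
#'   frame (`parameter`, `true`, `mean_estimate`, `rel_bias`,
#'   `rel_rmse`, `coverage_2se`), `n_replicates`, `n_failed`,
#'   `estimates` matrix.
#' @export
recovery_experiment <- function(config, fit_config = NULL,
                                n_replicates = 20, seed = 1) {
  if (inherits(config, "generator_config")) config <- list(config)
  stopifnot(all(vapply(config, inherits, logical(1), "generator_config")),
            n_replicates >= 1)
  if (is.null(fit_config)) fit_config <- acmig::fit_config()
  stopifnot(inherits(fit_config, "fit_config"))
  truth <- unclass(config[[1]]$constants)
  free <- fit_config$free_parameters
  est <- matrix(NA_real_, n_replicates, length(free),
                dimnames = list(NULL, free))
  covered <- matrix(NA, n_replicates, length(free),
                    dimnames = list(NULL, free))
  n_failed <- 0L
  for (i in seq_len(n_replicates)) {
    rep_cfgs <- lapply(config, function(cf) {
      cf$noise$seed <- as.integer(seed * 1000 + i)
      cf
    })
    fit <- tryCatch({
      ds <- lapply(rep_cfgs, generate_dataset)
      fit_rate_constants(ds, fit_config)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    k_hat <- unclass(fit$estimates)[free]
    se <- fit$standard_errors[free]
    est[i, ] <- k_hat
    covered[i, ] <- abs(k_hat - truth[free]) <= 2 * se
  }
  ok <- !is.na(est[, 1])
  per_parameter <- data.frame(
    parameter = free,
    true = unname(truth[free]),
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    rel_bias = (colMeans(est[ok, , drop = FALSE]) - truth[free]) /
      truth[free],
    rel_rmse = sqrt(colMeans((t(t(est[ok, , drop = FALSE]) - truth[free]) /
                                rep(truth[free],
                                    each = sum(ok)))^2)),
    coverage_2se = colMeans(covered[ok, , drop = FALSE], na.rm = TRUE),
    row.names = NULL)
  structure(list(per_parameter = per_parameter,
                 n_replicates = n_replicates,
                 n_failed = n_failed,
                 estimates = est,
                 seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicates (%d failed):\n",
              x$n_replicates, x$n_failed))
  print(transform(x$per_parameter,
                  rel_bias = signif(rel_bias, 3),
                  rel_rmse = signif(rel_rmse, 3)))
  invisible(x)
}

#' Serialize a recovery report to JSON
#'
#' @param report A `recovery_report`.
#' @param path Optional output path; if `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
write_recovery_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "recovery_report"))
  payload <- list(per_parameter = report$per_parameter,
                  n_replicates = report$n_replicates,
                  n_failed = report$n_failed,
                  seed = report$seed)
  if (is.null(path)) {
    return(jsonlite::toJSON(payload, dataframe = "rows", digits = NA,
                            auto_unbox = TRUE, na = "null"))
  }
  jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}
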