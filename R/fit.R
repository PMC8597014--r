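#' Fit configuration
#'
#' Controls which of the five tied constants are estimated, how the
#' optimizer stages run, and how multistarts are seeded. Optimization is
#' carried out in log10-parameter space (the constants span roughly
#' three decades) inside box bounds.
#'
#' @param free_parameters Names of constants to estimate (subset of
#'   `k_O2_O6`, `k_O3_O2`, `k_O2_O3`, `k_prim_hydr`, `k_sec_hydr`).
#' @param locked_values Named numeric of constants held fixed; together
#'   with `free_parameters` this must cover all five names disjointly.
#' @param initial_guess Named numeric starting values (h^-1) for the free
#'   parameters; defaults to 1 h^-1 for the O3/O2 exchange pair and
#'   1e-2 h^-1 for the slow constants.
#' @param bounds Named list of `c(lo, hi)` per free parameter; default
#'   `c(1e-8, 1e2)` h^-1 for all.
#' @param optimizer_stages Ordered subset of `"simplex"` (Nelder-Mead,
#'   robust far from the optimum) and `"levenberg_marquardt"`
#'   (refinement); default both, in that order.
#' @param max_iterations Per-stage iteration cap.
#' @param multistart_count Number of starts; the first is
#'   `initial_guess`, the rest are log-uniform perturbations of it within
#'   +/- half a decade, deterministic from `seed`.
#' @param seed Integer seed for multistart perturbations.
#' @param sim_method `"closed_form"` (exact matrix exponential, default)
#'   or `"bdf"` (stiff integrator) for the nested forward simulations.
#' @param doe_center `"global"` (grand mean over all pooled observations,
#'   default) or `"per_species"` centering for the degree of explanation.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(free_parameters = PARAM_NAMES,
                       locked_values = NULL,
                       initial_guess = NULL,
                       bounds = NULL,
                       optimizer_stages = c("simplex", "levenberg_marquardt"),
                       max_iterations = 500,
                       multistart_count = 5,
                       seed = 1,
                       sim_method = c("closed_form", "bdf"),
                       doe_center = c("global", "per_species")) {
  sim_method <- match.arg(sim_method)
  doe_center <- match.arg(doe_center)
  optimizer_stages <- match.arg(optimizer_stages,
                                c("simplex", "levenberg_marquardt"),
                                several.ok = TRUE)
  if (!length(free_parameters)) {
    stop("at least one free parameter is required", call. = FALSE)
  }
  if (!all(free_parameters %in% PARAM_NAMES)) {
    stop("unknown parameter name(s): ",
         paste(setdiff(free_parameters, PARAM_NAMES), collapse = ", "),
         call. = FALSE)
  }
  locked_values <- unlist(locked_values)
  locked_names <- names(locked_values)
  if (length(intersect(free_parameters, locked_names))) {
    stop("free and locked parameter sets must be disjoint", call. = FALSE)
  }
  if (!setequal(c(free_parameters, locked_names), PARAM_NAMES)) {
    stop("free + locked parameters must cover all five constants; missing: ",
         paste(setdiff(PARAM_NAMES, c(free_parameters, locked_names)),
               collapse = ", "), call. = FALSE)
  }
  if (any(locked_values < 0)) {
    stop("locked values must be >= 0", call. = FALSE)
  }
  default_guess <- c(k_O2_O6 = 1e-2, k_O3_O2 = 1, k_O2_O3 = 1,
                     k_prim_hydr = 1e-2, k_sec_hydr = 1e-2)
  guess <- default_guess[free_parameters]
  if (!is.null(initial_guess)) {
    initial_guess <- unlist(initial_guess)
    guess[intersect(names(initial_guess), free_parameters)] <-
      initial_guess[intersect(names(initial_guess), free_parameters)]
  }
  default_bounds <- rep(list(c(1e-8, 1e2)), length(free_parameters))
  names(default_bounds) <- free_parameters
  if (!is.null(bounds)) default_bounds[names(bounds)] <- bounds
  lo <- vapply(default_bounds, `[`, numeric(1), 1)
  hi <- vapply(default_bounds, `[`, numeric(1), 2)
  if (any(lo <= 0) || any(hi <= lo)) {
    stop("bounds must satisfy 0 < lo < hi", call. = FALSE)
  }
  if (any(guess < lo) || any(guess > hi)) {
    stop("initial guess must lie inside the bounds", call. = FALSE)
  }
  structure(list(free_parameters = free_parameters,
                 locked_values = locked_values,
                 initial_guess = guess,
                 lower = lo, upper = hi,
                 optimizer_stages = optimizer_stages,
                 max_iterations = max_iterations,
                 multistart_count = as.integer(multistart_count),
                 seed = as.integer(seed),
                 sim_method = sim_method,
                 doe_center = doe_center),
            class = "fit_config")
}

# Assemble a full rate_constants object from free (named) + locked values.
constants_from_free <- function(free, config) {
  k <- setNames(numeric(5), PARAM_NAMES)
  k[names(free)] <- free
  if (length(config$locked_values)) {
    k[names(config$locked_values)] <- config$locked_values
  }
  as_rate_constants(k)
}

simulate_dataset <- function(constants, ds, method = "closed_form") {
  fun <- if (method == "bdf") simulate_kinetics else simulate_closed_form
  fun(constants, ds$initial_state, ds$ph_profile, ds$sample_times,
      ds$model_kind)
}

# Pooled residual vector (model - observed) over datasets, times and
# observed species; NA observations dropped. Attributes carry the pooled
# observed values and species ids for the degree of explanation.
fit_residuals <- function(constants, datasets, method = "closed_form") {
  res <- obs <- numeric(0)
  species <- character(0)
  for (ds in datasets) {
    tr <- tryCatch(simulate_dataset(constants, ds, method),
                   error = function(e) {
                     stop("simulation failed for dataset '", ds$label,
                          "': ", conditionMessage(e), call. = FALSE)
                   })
    pred <- tr$states[, ds$observed_species, drop = FALSE]
    o <- ds$observations
    keep <- !is.na(o)
    sp_mat <- matrix(colnames(o), nrow = nrow(o), ncol = ncol(o),
                     byrow = TRUE)
    res <- c(res, (pred - o)[keep])
    obs <- c(obs, o[keep])
    species <- c(species, sp_mat[keep])
  }
  structure(res, observed = obs, species = species)
}

#' Sum-of-squares objective of a kinetic fit
#'
#' The unweighted sum over datasets, sampling times and observed species
#' of squared differences between simulated and observed mole fractions.
#' Each dataset is simulated from its own initial state under its own pH
#' profile.
#'
#' @param constants A [rate_constants()] object.
#' @param datasets A [timecourse_dataset()] or list of them.
#' @param sim_method `"closed_form"` or `"bdf"`.
#' @return The scalar SSQ (dimensionless, `>= 0`).
#' @export
ssq_objective <- function(constants, datasets,
                          sim_method = c("closed_form", "bdf")) {
  sim_method <- match.arg(sim_method)
  datasets <- as_dataset_list(datasets)
  r <- fit_residuals(as_rate_constants(constants), datasets, sim_method)
  sum(r^2)
}

#' Degree of explanation
#'
#' The R-squared-style goodness-of-fit statistic
#' `100 * (1 - SSQ / sum((y - center)^2))` in percent, where `y` pools
#' every observed value. With `center = "global"` the grand mean of the
#' pooled observations is used; `"per_species"` centers each observed
#' species at its own mean.
#'
#' @param observed Observed values (pooled numeric vector).
#' @param predicted Model values, same length.
#' @param center `"global"` or `"per_species"`.
#' @param species Species id per observation (required for
#'   `"per_species"`).
#' @return Percent in `(-Inf, 100]`; `NA` (with a warning) if the
#'   observations have zero total variance.
#' @export
#' @examples
#' degree_of_explanation(c(0, 1), c(0.1, 0.9)) # 96
degree_of_explanation <- function(observed, predicted,
                                  center = c("global", "per_species"),
                                  species = NULL) {
  center <- match.arg(center)
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop("observed and predicted must be equal-length, n >= 2",
         call. = FALSE)
  }
  ssq <- sum((predicted - observed)^2)
  if (center == "global") {
    tss <- sum((observed - mean(observed))^2)
  } else {
    if (is.null(species)) {
      stop("species ids required for per-species centering", call. = FALSE)
    }
    tss <- sum(unlist(tapply(observed, species,
                             function(y) (y - mean(y))^2)))
  }
  if (tss == 0) {
    warning("zero total variance: degree of explanation undefined")
    return(NA_real_)
  }
  100 * (1 - ssq / tss)
}

#' Linearized standard errors from a residual Jacobian
#'
#' Gauss-Newton (linearized) covariance `s^2 * (J'J)^-1` with
#' `s^2 = SSQ / (n - p)`; standard errors are the square roots of its
#' diagonal. Rank-deficient Jacobians trigger an identifiability warning
#' and `NA` errors.
#'
#' @param jacobian `n x p` matrix of residual derivatives w.r.t. the
#'   parameters (in whatever parameterization the errors are wanted).
#' @param residuals Residual vector of length `n` at the optimum.
#' @return Numeric vector of `p` standard errors.
#' @export
linearized_standard_errors <- function(jacobian, residuals) {
  jacobian <- as.matrix(jacobian)
  n <- length(residuals)
  p <- ncol(jacobian)
  if (nrow(jacobian) != n) stop("jacobian/residual size mismatch",
                                call. = FALSE)
  if (n <= p) stop("need more observations than parameters", call. = FALSE)
  s2 <- sum(residuals^2) / (n - p)
  qrj <- qr(jacobian)
  if (qrj$rank < p) {
    warning("rank-deficient sensitivity matrix: some parameters are not ",
            "identifiable; their standard errors are undefined")
    se <- rep(NA_real_, p)
    return(se)
  }
  cov <- s2 * chol2inv(qr.R(qrj))
  sqrt(pmax(diag(cov), 0))
}

# Central-difference Jacobian of the residual vector w.r.t. log10 of the
# free parameters, step 1e-4 in log10 space.
residual_jacobian_log10 <- function(free, config, datasets, h = 1e-4) {
  p <- length(free)
  lg <- log10(free)
  J <- NULL
  for (j in seq_len(p)) {
    up <- lg; up[j] <- up[j] + h
    dn <- lg; dn[j] <- dn[j] - h
    r_up <- fit_residuals(constants_from_free(setNames(10^up, names(free)),
                                              config),
                          datasets, config$sim_method)
    r_dn <- fit_residuals(constants_from_free(setNames(10^dn, names(free)),
                                              config),
                          datasets, config$sim_method)
    col <- (as.numeric(r_up) - as.numeric(r_dn)) / (2 * h)
    if (is.null(J)) J <- matrix(0, length(col), p)
    J[, j] <- col
  }
  colnames(J) <- names(free)
  J
}

#' Estimate rate constants from time-course data
#'
#' ODE-constrained nonlinear least squares: each candidate constant set
#' is forward-simulated through every dataset and scored by
#' [ssq_objective()]. The configured optimizer stages run in order
#' (default Nelder-Mead simplex, then Levenberg-Marquardt) in
#' log10-parameter space, from `multistart_count` deterministic starts;
#' the best converged result is returned with linearized standard errors
#' and the degree of explanation.
#'
#' Fitting a single trisaccharide experiment leaves the slow constants
#' weakly identified; joint fitting of complementary starting points
#' (e.g. one experiment started from 1a and one from 1b) in a single SSQ
#' is recommended.
#'
#' @param datasets A [timecourse_dataset()] or list of them, fitted
#'   jointly under one shared constant set.
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: `estimates`
#'   ([rate_constants()]), `standard_errors` (h^-1, `NA` for locked
#'   parameters), `ssq`, `degree_of_explanation`, `n_observations`, and
#'   `convergence` (`converged`, `iterations`, `stage_log`).
#' @export
fit_rate_constants <- function(datasets, config = fit_config()) {
  datasets <- as_dataset_list(datasets)
  stopifnot(inherits(config, "fit_config"))
  free_names <- config$free_parameters
  lo <- log10(config$lower)
  hi <- log10(config$upper)
  ssq_of_log10 <- function(lg) {
    lgc <- pmin(pmax(lg, lo), hi)
    free <- setNames(10^lgc, free_names)
    r <- fit_residuals(constants_from_free(free, config), datasets,
                       config$sim_method)
    # quadratic penalty keeps the simplex inside the box
    sum(r^2) + 1e3 * sum((lg - lgc)^2)
  }
  resid_of_log10 <- function(lg) {
    free <- setNames(10^lg, free_names)
    as.numeric(fit_residuals(constants_from_free(free, config), datasets,
                             config$sim_method))
  }

  starts <- list(log10(config$initial_guess))
  if (config$multistart_count > 1) {
    rng <- get_rng_state()
    on.exit(restore_rng_state(rng), add = TRUE)
    set.seed(config$seed)
    for (i in seq_len(config$multistart_count - 1)) {
      pert <- starts[[1]] + runif(length(free_names), -0.5, 0.5)
      starts[[i + 1]] <- pmin(pmax(pert, lo), hi)
    }
  }

  best <- NULL
  stage_log <- list()
  for (s in seq_along(starts)) {
    lg <- starts[[s]]
    converged <- TRUE
    iterations <- 0L
    for (stage in config$optimizer_stages) {
      if (stage == "simplex") {
        opt <- optim(lg, ssq_of_log10, method = "Nelder-Mead",
                     control = list(maxit = config$max_iterations,
                                    reltol = 1e-12))
        lg <- pmin(pmax(opt$par, lo), hi)
        iterations <- iterations + opt$counts[["function"]]
        stage_log[[length(stage_log) + 1]] <-
          list(start = s, stage = "simplex", ssq = ssq_of_log10(lg),
               evaluations = unname(opt$counts[["function"]]))
      } else {
        lm <- minpack.lm::nls.lm(par = lg, lower = lo, upper = hi,
                                 fn = resid_of_log10,
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = min(config$max_iterations, 1024),
                                   ftol = 1e-12, ptol = 1e-12))
        lg <- pmin(pmax(lm$par, lo), hi)
        iterations <- iterations + lm$niter
        ok <- lm$info %in% 1:4
        converged <- converged && ok
        stage_log[[length(stage_log) + 1]] <-
          list(start = s, stage = "levenberg_marquardt",
               ssq = lm$deviance, iterations = lm$niter,
               info = lm$info, message = lm$message)
      }
    }
    ssq <- sum(resid_of_log10(lg)^2)
    if (is.null(best) || ssq < best$ssq) {
      best <- list(lg = lg, ssq = ssq, converged = converged,
                   iterations = iterations)
    }
  }
  if (is.null(best) || !is.finite(best$ssq)) {
    stop("all multistarts failed; stage log attached",
         call. = FALSE)
  }

  free <- setNames(10^best$lg, free_names)
  estimates <- constants_from_free(free, config)
  r <- fit_residuals(estimates, datasets, config$sim_method)
  n_obs <- length(r)

  se <- setNames(rep(NA_real_, 5), PARAM_NAMES)
  if (n_obs > length(free_names)) {
    J_log <- residual_jacobian_log10(free, config, datasets)
    se_log <- suppressWarnings(
      tryCatch(linearized_standard_errors(J_log, as.numeric(r)),
               error = function(e) rep(NA_real_, length(free_names))))
    # chain rule: dk = k * ln(10) * d(log10 k)
    se[free_names] <- free * log(10) * se_log
  }

  doe <- degree_of_explanation(attr(r, "observed"),
                               attr(r, "observed") + as.numeric(r),
                               center = config$doe_center,
                               species = attr(r, "species"))
  structure(list(estimates = estimates,
                 standard_errors = se,
                 ssq = best$ssq,
                 degree_of_explanation = doe,
                 n_observations = n_obs,
                 convergence = list(converged = best$converged,
                                    iterations = best$iterations,
                                    stage_log = stage_log),
                 config = config),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Kinetic fit result\n")
  est <- unclass(x$estimates)
  for (nm in PARAM_NAMES) {
    locked <- nm %in% names(x$config$locked_values)
    cat(sprintf("  %-12s %.4g h^-1 %s\n", nm, est[[nm]],
                if (locked) "(locked)"
                else sprintf("+/- %.3g", x$standard_errors[[nm]])))
  }
  cat(sprintf("  SSQ = %.4g over %d observations\n", x$ssq,
              x$n_observations))
  cat(sprintf("  degree of explanation = %.2f %%\n",
              x$degree_of_explanation))
  cat(sprintf("  converged: %s (%d iterations)\n",
              x$convergence$converged, x$convergence$iterations))
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param result A `fit_result` from [fit_rate_constants()].
#' @param path Optional output path; if `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
write_fit_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "fit_result"))
  payload <- list(
    estimates = as.list(unclass(result$estimates)),
    standard_errors = as.list(result$standard_errors),
    ssq = result$ssq,
    degree_of_explanation = result$degree_of_explanation,
    n_observations = result$n_observations,
    converged = result$convergence$converged,
    iterations = result$convergence$iterations,
    config = list(
      free_parameters = result$config$free_parameters,
      locked_values = as.list(result$config$locked_values %||% list()),
      optimizer_stages = result$config$optimizer_stages,
      multistart_count = result$config$multistart_count,
      seed = result$config$seed,
      sim_method = result$config$sim_method))
  if (is.null(path)) {
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                            na = "null"))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
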