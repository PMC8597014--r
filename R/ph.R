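#' Hydroxide correction factor for a given pH
#'
#' All reactions in the networks are first-order in hydroxide, so every
#' pseudo-first-order rate is the pH-8 constant times
#' `[OH-](pH) / [OH-](reference)` = `10^(pH - reference_ph)`. With the
#' default reference pH 8 the factor is exactly 1 at pH 8 and, e.g.,
#' drops by 37 % when the pH falls from 7.95 to 7.75.
#'
#' @param ph pH value(s) in \[0, 14\].
#' @param reference_ph Reference pH at which the rate constants are
#'   quoted (default 8). Set to the starting pH of an experiment for a
#'   start-referenced correction.
#' @return `10^(ph - reference_ph)`, vectorized over `ph`.
#' @export
#' @examples
#' oh_correction_factor(8)                            # 1
#' oh_correction_factor(7.75) / oh_correction_factor(7.95) # ~0.63
oh_correction_factor <- function(ph, reference_ph = 8) {
  if (!is.numeric(ph) || any(!is.finite(ph))) {
    stop("ph must be finite numeric", call. = FALSE)
  }
  if (any(ph < 0 | ph > 14)) stop("ph must lie in [0, 14]", call. = FALSE)
  if (!is.numeric(reference_ph) || length(reference_ph) != 1L ||
      !is.finite(reference_ph) || reference_ph < 0 || reference_ph > 14) {
    stop("reference_ph must be a single pH in [0, 14]", call. = FALSE)
  }
  10^(ph - reference_ph)
}

#' Time-stamped pH profile
#'
#' An ordered log of pH-meter readings defining the hydroxide correction
#' over the course of an experiment. Between readings the pH is linearly
#' interpolated; outside the logged span the nearest reading is held.
#'
#' @param time_h Strictly increasing sampling times in hours.
#' @param ph pH readings in \[0, 14\], one per time.
#' @return An object of class `ph_profile` (data frame with columns
#'   `time_h`, `ph`).
#' @export
#' @examples
#' ph_profile(c(0, 672), c(7.95, 7.75))
ph_profile <- function(time_h, ph) {
  if (length(time_h) != length(ph) || length(ph) < 1L) {
    stop("time_h and ph must have equal, positive length", call. = FALSE)
  }
  if (any(!is.finite(time_h)) || any(!is.finite(ph))) {
    stop("pH profile must be finite", call. = FALSE)
  }
  if (any(diff(time_h) <= 0)) {
    stop("pH profile times must be strictly increasing", call. = FALSE)
  }
  if (any(ph < 0 | ph > 14)) {
    stop("pH values must lie in [0, 14]", call. = FALSE)
  }
  structure(data.frame(time_h = as.numeric(time_h), ph = as.numeric(ph)),
            class = c("ph_profile", "data.frame"))
}

#' Constant-pH profile
#'
#' @param ph The constant pH (default 8, where the correction factor is 1).
#' @return A single-reading [ph_profile()], interpreted as constant pH.
#' @export
constant_ph_profile <- function(ph = 8) ph_profile(0, ph)

as_ph_profile <- function(x) {
  if (inherits(x, "ph_profile")) return(x)
  if (is.null(x)) return(constant_ph_profile())
  if (is.numeric(x) && length(x) == 1L) return(constant_ph_profile(x))
  if (is.data.frame(x) && all(c("time_h", "ph") %in% names(x))) {
    return(ph_profile(x$time_h, x$ph))
  }
  stop("cannot interpret object as a pH profile", call. = FALSE)
}

#' Interpolated pH at arbitrary times
#'
#' @param profile A [ph_profile()].
#' @param t Times in hours (vectorized).
#' @return pH at `t`: linear interpolation between readings, nearest
#'   reading held outside the logged span.
#' @export
ph_at <- function(profile, t) {
  profile <- as_ph_profile(profile)
  if (nrow(profile) == 1L) return(rep(profile$ph, length(t)))
  approx(profile$time_h, profile$ph, xout = t, rule = 2)$y
}

#' Hydroxide-transformed time
#'
#' Because every rate shares the common factor `10^(pH(t) - reference)`,
#' the time-varying linear system is the constant-coefficient system run
#' on the transformed clock
#' `tau(t) = integral_0^t 10^(pH(s) - reference) ds`. The integral is
#' evaluated exactly on each linear-in-pH segment of the profile
#' (the integrand is exponential in `s` there).
#'
#' @param profile A [ph_profile()].
#' @param t Times in hours (vectorized, `>= 0`).
#' @param reference_ph Reference pH of the rate constants (default 8).
#' @return `tau(t)` in hours; `tau(0) = 0`, monotone non-decreasing, and
#'   equal to `t` for a constant profile at the reference pH.
#' @export
#' @examples
#' transformed_time(constant_ph_profile(7), 10) # 1
transformed_time <- function(profile, t, reference_ph = 8) {
  profile <- as_ph_profile(profile)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be finite and >= 0", call. = FALSE)
  }
  vapply(t, function(ti) {
    .tau_segmented(profile$time_h, profile$ph, ti, reference_ph)
  }, numeric(1))
}

# Exact integral of 10^(pH(s) - ref) from 0 to t for a piecewise-linear
# pH(s) with nearest-value extrapolation.
.tau_segmented <- function(times, phs, t, ref) {
  seg <- function(t0, t1, ph0, ph1) {
    if (t1 <= t0) return(0)
    b <- (ph1 - ph0) / (t1 - t0)
    if (abs(b) < 1e-14) {
      10^(ph0 - ref) * (t1 - t0)
    } else {
      (10^(ph1 - ref) - 10^(ph0 - ref)) / (b * log(10))
    }
  }
  tau <- 0
  # portion before the first reading: hold the first pH
  t_first <- times[1]
  if (t_first > 0) {
    upper <- min(t, t_first)
    tau <- tau + seg(0, upper, phs[1], phs[1])
    if (t <= t_first) return(tau)
  }
  start <- max(t_first, 0)
  n <- length(times)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      t0 <- times[i]; t1 <- times[i + 1]
      if (t1 <= start) next
      lo <- max(t0, start)
      hi <- min(t1, t)
      if (hi <= lo) next
      ph_lo <- phs[i] + (phs[i + 1] - phs[i]) * (lo - t0) / (t1 - t0)
      ph_hi <- phs[i] + (phs[i + 1] - phs[i]) * (hi - t0) / (t1 - t0)
      tau <- tau + seg(lo, hi, ph_lo, ph_hi)
      if (hi >= t) return(tau)
    }
  }
  # beyond the last reading: hold the last pH
  t_last <- times[n]
  from <- max(t_last, start)
  if (t > from) tau <- tau + seg(from, t, phs[n], phs[n])
  tau
}
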