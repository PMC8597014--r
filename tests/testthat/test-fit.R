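test_that("SSQ is zero for data generated by the same constants", {
  ds <- noise_free_ggm()
  expect_lt(ssq_objective(ggm2_constants(), ds), 1e-10)
})

test_that("SSQ sums squared residuals and ignores dataset order", {
  # 2-point, single-observed-species toy dataset with residuals 0.1, -0.2
  kk <- rate_constants(0, 0, 0, 0, 0) # model constant at the initial state
  y0 <- pure_state("c_1a", "trisaccharide")
  obs <- matrix(c(1 - 0.1, 1 + (-0.2) + 0.2), ncol = 1,
                dimnames = list(NULL, "c_1a"))
  obs[2, 1] <- 0.8 # model 1.0, observed 0.8 -> residual +0.2
  ds <- timecourse_dataset("trisaccharide", c(0, 5), obs,
                           initial_state = y0)
  expect_equal(ssq_objective(kk, ds), 0.1^2 + 0.2^2)
  ds2 <- noise_free_ggm()
  both <- ssq_objective(ggm2_constants(), list(ds2, ds2))
  expect_equal(both, 2 * ssq_objective(ggm2_constants(), ds2))
})

test_that("degree of explanation matches hand arithmetic", {
  expect_equal(degree_of_explanation(c(0, 1), c(0.1, 0.9)), 96)
  expect_equal(degree_of_explanation(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8)),
               100)
  y <- c(0.1, 0.4, 0.7)
  expect_equal(degree_of_explanation(y, rep(mean(y), 3)), 0)
  expect_warning(out <- degree_of_explanation(c(0.5, 0.5), c(0.4, 0.6)),
                 "zero total variance")
  expect_true(is.na(out))
  # per-species centering uses each species' own mean
  y2 <- c(0, 1, 10, 12)
  sp <- c("a", "a", "b", "b")
  expect_equal(degree_of_explanation(y2, y2 + 0.1, center = "per_species",
                                     species = sp),
               100 * (1 - 4 * 0.01 / (0.5 + 2)))
})

test_that("linearized standard errors match the textbook closed form", {
  # one-parameter linear model y = k * t: SE = s / sqrt(sum(t^2))
  t <- c(1, 2, 3)
  r <- c(0.1, -0.1, 0.05)
  s <- sqrt(sum(r^2) / (length(r) - 1))
  expect_equal(linearized_standard_errors(matrix(t, ncol = 1), r),
               s / sqrt(sum(t^2)))
  # zero residuals -> zero error
  expect_equal(linearized_standard_errors(matrix(t, ncol = 1), rep(0, 3)),
               0)
  # rank-deficient sensitivities -> identifiability warning, NA errors
  J <- cbind(t, 2 * t)
  expect_warning(se <- linearized_standard_errors(J, c(r, 0)[1:3]),
                 "identifiab")
  expect_true(all(is.na(se)))
})

test_that("fit configuration enforces the parameter partition", {
  expect_error(fit_config(free_parameters = c("k_O2_O6", "bogus")),
               "unknown parameter")
  expect_error(fit_config(free_parameters = "k_O2_O6"), "cover all five")
  expect_error(fit_config(free_parameters = c("k_O2_O6", "k_O3_O2",
                                              "k_O2_O3", "k_prim_hydr",
                                              "k_sec_hydr"),
                          locked_values = c(k_O2_O6 = 1)),
               "disjoint")
  expect_error(fit_config(bounds = list(k_O2_O6 = c(-1, 10))), "bounds")
})

test_that("noise-free GGM data with the lock recovers the constants", {
  ds <- noise_free_ggm()
  truth <- unclass(ggm2_constants())
  cfg <- fit_config(
    free_parameters = c("k_O2_O6", "k_O3_O2", "k_prim_hydr", "k_sec_hydr"),
    locked_values = c(k_O2_O3 = 1.00),
    initial_guess = truth[-3] * 1.4,
    multistart_count = 1)
  fit <- fit_rate_constants(ds, cfg)
  est <- unclass(fit$estimates)
  expect_lt(abs(est[["k_O3_O2"]] / truth[["k_O3_O2"]] - 1), 0.01)
  expect_lt(abs(est[["k_O2_O6"]] / truth[["k_O2_O6"]] - 1), 0.01)
  # locked parameter is bit-identical in the estimates
  expect_identical(est[["k_O2_O3"]], 1.00)
  expect_true(is.na(fit$standard_errors[["k_O2_O3"]]))
  expect_true(fit$convergence$converged)
  expect_gt(fit$degree_of_explanation, 99.99)
  # restarting at the optimum does not increase the SSQ
  cfg2 <- fit_config(free_parameters = names(truth[-3]),
                     locked_values = c(k_O2_O3 = 1.00),
                     initial_guess = est[-3], multistart_count = 1,
                     optimizer_stages = "levenberg_marquardt")
  expect_lte(fit_rate_constants(ds, cfg2)$ssq, fit$ssq + 1e-12)
})

test_that("pH drift in generation is removed by the correction in fitting", {
  # data generated under a drifting pH, fitted with the same profile
  # attached, recover the pH-8 constants
  gcfg <- generator_config(
    model_kind = "ggm", constants = ggm2_constants(), start = "ggm_default",
    ph_model = ph_drift_model("linear", 7.95, 7.75, 672),
    noise = noise_model("none"))
  ds <- generate_dataset(gcfg)
  truth <- unclass(ggm2_constants())
  cfg <- fit_config(free_parameters = c("k_O3_O2", "k_O2_O6"),
                    locked_values = truth[c("k_O2_O3", "k_prim_hydr",
                                            "k_sec_hydr")],
                    initial_guess = truth[c("k_O3_O2", "k_O2_O6")] * 0.7,
                    multistart_count = 1)
  fit <- fit_rate_constants(ds, cfg)
  est <- unclass(fit$estimates)
  expect_lt(abs(est[["k_O3_O2"]] / truth[["k_O3_O2"]] - 1), 0.01)
  expect_lt(abs(est[["k_O2_O6"]] / truth[["k_O2_O6"]] - 1), 0.01)
})

test_that("doubling the noise doubles the standard errors", {
  # identical normal draws scaled by sigma: the noise vector itself
  # doubles, so the linearized errors should double within fit noise
  fits <- lapply(c(0.004, 0.008), function(sig) {
    gcfg <- generator_config(
      model_kind = "ggm", constants = ggm2_constants(),
      start = "ggm_default",
      ph_model = ph_drift_model("constant", ph_start = 8),
      noise = noise_model("gaussian", sigma = sig, seed = 99,
                          clip_to_simplex = FALSE))
    cfg <- fit_config(free_parameters = c("k_O3_O2", "k_O2_O6"),
                      locked_values = unclass(ggm2_constants())[
                        c("k_O2_O3", "k_prim_hydr", "k_sec_hydr")],
                      initial_guess = unclass(ggm2_constants())[
                        c("k_O3_O2", "k_O2_O6")],
                      multistart_count = 1)
    fit_rate_constants(generate_dataset(gcfg), cfg)
  })
  ratio <- fits[[2]]$standard_errors[c("k_O3_O2", "k_O2_O6")] /
    fits[[1]]$standard_errors[c("k_O3_O2", "k_O2_O6")]
  expect_equal(unname(ratio), c(2, 2), tolerance = 0.25)
})
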