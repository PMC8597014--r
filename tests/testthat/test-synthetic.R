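test_that("pH drift profiles hit their endpoints", {
  const <- ph_drift_profile(ph_drift_model("constant", ph_start = 8))
  expect_true(all(ph_at(const, c(0, 300, 672)) == 8))
  lin <- ph_drift_profile(ph_drift_model("linear", 7.95, 7.75, 672), 25)
  expect_identical(lin$ph[1], 7.95)
  expect_identical(lin$ph[25], 7.75)
  expect_equal(ph_at(lin, 336), 7.85)
  slow <- ph_drift_profile(ph_drift_model("exponential_approach", 7.95,
                                          7.75, 672, timescale = 1e12), 10)
  expect_equal(slow$ph, rep(7.95, 10), tolerance = 1e-6)
  expect_error(ph_drift_model("linear", ph_start = 7.5, ph_end = 7.9),
               "ph_end <= ph_start")
  expect_error(ph_drift_profile(ph_drift_model("linear"), n_points = 1),
               ">= 2")
})

test_that("noise-free generation equals the exact trajectory", {
  cfg <- generator_config(constants = tri_constants(),
                          noise = noise_model("none"))
  ds <- generate_dataset(cfg)
  tr <- simulate_closed_form(tri_constants(),
                             pure_state("c_1a", "trisaccharide"),
                             ph_drift_profile(cfg$ph_model),
                             cfg$sample_times, "trisaccharide")
  expect_equal(ds$observations, tr$states)
})

test_that("generation is deterministic given the noise seed", {
  cfg <- function(seed) generator_config(
    constants = tri_constants(),
    noise = noise_model("gaussian", 0.005, seed = seed))
  a <- generate_dataset(cfg(7))
  b <- generate_dataset(cfg(7))
  c_ <- generate_dataset(cfg(8))
  expect_identical(a$observations, b$observations)
  expect_false(identical(a$observations, c_$observations))
  # the caller's RNG stream is untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_dataset(cfg(7))); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("empirical noise matches the configured sigma", {
  times <- seq(1, 672, length.out = 100)
  cfg <- generator_config(constants = tri_constants(),
                          sample_times = times,
                          noise = noise_model("gaussian", 0.005, seed = 4,
                                              clip_to_simplex = FALSE))
  ds <- generate_dataset(cfg)
  exact <- simulate_closed_form(tri_constants(),
                                pure_state("c_1a", "trisaccharide"),
                                ph_drift_profile(cfg$ph_model),
                                times, "trisaccharide")
  resid <- ds$observations - exact$states
  expect_gt(sd(resid), 0.004)
  expect_lt(sd(resid), 0.006)
})

test_that("starting presets encode the documented compositions", {
  ds_b <- generate_dataset(generator_config(start = "from_1b",
                                            noise = noise_model("none")))
  expect_equal(unname(ds_b$initial_state["c_1b"]), 1)
  # ~10 % pre-hydrolysis redistributes into 1d/1e at the O2:O3 split
  cfg <- generator_config(start = "from_1a",
                          initial_hydrolyzed_fraction = 0.10,
                          noise = noise_model("none"))
  y0 <- generate_dataset(cfg)$initial_state
  f <- equilibrium_O2_fraction(tri_constants())
  expect_equal(unname(y0["c_1a"]), 0.90)
  expect_equal(unname(y0["c_1e"]), 0.10 * f)
  expect_equal(unname(y0["c_1d"]), 0.10 * (1 - f))
  ds_g <- generate_dataset(generator_config("ggm",
                                            noise = noise_model("none")))
  expect_equal(unname(ds_g$initial_state),
               c(0.39, 0.61, 0, 0))
})

test_that("GGM generation holds the O2:O3 split through the early phase", {
  ds <- generate_dataset(generator_config(
    "ggm", constants = ggm2_constants(),
    sample_times = seq(0, 48, by = 4), noise = noise_model("none")))
  ab <- ds$observations[, c("c_A", "c_B")]
  split <- ab[, "c_B"] / rowSums(ab)
  expect_equal(split, rep(0.61, length(split)), tolerance = 0.015,
               ignore_attr = TRUE)
})

test_that("generated datasets survive the CSV validators", {
  cfg <- generator_config(constants = tri_constants(),
                          noise = noise_model("gaussian", 0.005, seed = 2))
  ds <- generate_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse_csv(ds, path)
  expect_s3_class(read_timecourse_csv(path), "timecourse_dataset")
})

test_that("a zero-noise replicate recovers the truth with < 1 % bias", {
  gcfg <- generator_config(
    "ggm", constants = ggm2_constants(),
    ph_model = ph_drift_model("constant", ph_start = 8),
    noise = noise_model("none"))
  truth <- unclass(ggm2_constants())
  fcfg <- fit_config(free_parameters = c("k_O3_O2", "k_O2_O6"),
                     locked_values = truth[c("k_O2_O3", "k_prim_hydr",
                                             "k_sec_hydr")],
                     initial_guess = truth[c("k_O3_O2", "k_O2_O6")] * 1.3,
                     multistart_count = 1)
  rep1 <- recovery_experiment(gcfg, fcfg, n_replicates = 1, seed = 3)
  expect_identical(rep1$n_failed, 0L)
  expect_true(all(abs(rep1$per_parameter$rel_bias) < 0.01))
})

test_that("recovery error grows with the noise level", {
  truth <- unclass(ggm2_constants())
  fcfg <- fit_config(free_parameters = c("k_O3_O2", "k_O2_O6"),
                     locked_values = truth[c("k_O2_O3", "k_prim_hydr",
                                             "k_sec_hydr")],
                     initial_guess = truth[c("k_O3_O2", "k_O2_O6")],
                     multistart_count = 1)
  rmse_at <- function(sig) {
    gcfg <- generator_config(
      "ggm", constants = ggm2_constants(),
      ph_model = ph_drift_model("constant", ph_start = 8),
      noise = noise_model("gaussian", sigma = sig))
    rep <- recovery_experiment(gcfg, fcfg, n_replicates = 5, seed = 17)
    mean(rep$per_parameter$rel_rmse)
  }
  expect_lt(rmse_at(0.002), rmse_at(0.008))
})
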