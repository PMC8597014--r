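# Shared fixtures: everything is generated in code at test time.

tri_constants <- function() rate_constants_preset("trisaccharide")
ggm2_constants <- function() rate_constants_preset("ggm-2mg")

pure_state <- function(species, model_kind) {
  sp <- species_names(model_kind)
  setNames(as.numeric(sp == species), sp)
}

random_constants <- function(max_rate = 2) {
  k <- runif(5, 0, max_rate)
  rate_constants(k[1], k[2], k[3], k[4], k[5])
}

random_simplex_state <- function(model_kind) {
  sp <- species_names(model_kind)
  x <- runif(length(sp))
  setNames(x / sum(x), sp)
}

random_two_point_profile <- function(horizon = 700) {
  ph_profile(c(0, horizon), c(runif(1, 7.4, 8.2), runif(1, 7.2, 8.0)))
}

# Joint noise-free trisaccharide design: experiments started from 1a and
# from 1b at constant pH 8, 25 samples over 700 h.
noise_free_tri_pair <- function(constants = tri_constants(),
                                n_times = 25, horizon = 700) {
  times <- c(0, 10^seq(0, log10(horizon), length.out = n_times - 1))
  lapply(c("from_1a", "from_1b"), function(s) {
    generate_dataset(generator_config(
      model_kind = "trisaccharide", constants = constants, start = s,
      sample_times = times,
      ph_model = ph_drift_model("constant", ph_start = 8),
      noise = noise_model("none")))
  })
}

noise_free_ggm <- function(constants = ggm2_constants()) {
  generate_dataset(generator_config(
    model_kind = "ggm", constants = constants, start = "ggm_default",
    ph_model = ph_drift_model("constant", ph_start = 8),
    noise = noise_model("none")))
}
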