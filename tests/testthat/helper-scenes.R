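# Shared fixture builders (everything is generated in code).

# a clean, well-separated multi-spot scene with known truth
clean_scene <- function(n_spots = 10, seed = 42, noise_sd = 0,
                        shape = c(64L, 64L), min_separation = 10) {
  generate_scene(scene_params(shape = shape, n_spots = n_spots,
                              noise_sd = noise_sd,
                              min_separation = min_separation),
                 seed = seed)
}

# permissive detection parameters for clean (noiseless) scenes: an
# absolute background just above the flat 500-count background so even
# the faintest spots stay in the foreground
permissive_params <- function() {
  foci_params(background = 550, min_size = 4,
              min_height_above_saddle = 50)
}

# the default training grid used by optimiser-level tests: one Otsu
# background, two smoothing levels, and merge/filter ranges around the
# scales of the default synthetic scenes
training_grid <- function() {
  foci_grid(background = list(background_spec("otsu")),
            blur_sigma = c(0.5, 1),
            search_fraction = 0,
            min_size = c(3, 5),
            min_height_above_saddle = c(100, 200, 400),
            min_height = c(0, 300),
            metric = "f1")
}

expect_same_peaks <- function(res, oracle_peaks, info = NULL) {
  expect_identical(result_canonical(res), oracle_peaks, info = info)
}
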