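# Shared fixture builders: everything is generated in code at test time.

random_rgb <- function(h = 8, w = 8, seed = 1) {
  set.seed(seed)
  rgb_image(array(runif(h * w * 3), c(h, w, 3)))
}

random_cube <- function(h = 4, w = 4, b = 10, seed = 1, max_val = 1) {
  set.seed(seed)
  spectral_cube(array(runif(h * w * b, max = max_val), c(h, w, b)))
}

# a small paired synthetic dataset for training-based tests
tiny_pairs <- function(n = 6, hw = 16, seed = 3) {
  set <- generate_training_set(
    n, scene_params(height = hw, width = hw, seed = seed))
  lapply(set, `[[`, "pair")
}

write_test_png <- function(px, path = tempfile(fileext = ".png")) {
  png::writePNG(px, path)
  path
}
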