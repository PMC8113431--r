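# Small in-code fixtures shared across test files.

tiny_calib <- function(sensitivity = 100) {
  scanner_calib(sensitivity = sensitivity, psf_fwhm_mm = 4,
                beta_fwhm = function(beta) 2 + beta / 250)
}

# small uniform activity volume (no liver, no lesions)
uniform_activity <- function(level = 1, shape = c(24, 24, 12),
                             voxel_size = c(2.7, 2.7, 2.8)) {
  pet_volume(array(level, shape), voxel_size)
}

# phantom spec small enough for fast unit tests but with a real liver
small_phantom_spec <- function(lesions = list(), shape = c(48L, 48L, 31L)) {
  phantom_spec(shape = shape,
               background_suv = 0.7,
               liver = list(center = c(20, 24, 16),
                            semi_axes_mm = c(40, 35, 30), suv = 2.0),
               lesions = lesions)
}

# deterministic pseudo-volume for geometry tests (values = linear index)
index_volume <- function(shape = c(6, 6, 71)) {
  pet_volume(array(seq_len(prod(shape)), shape))
}

# a fast model config for training tests
tiny_cnn_config <- function(...) {
  cnn_config(n_layers = 3L, n_filters = 4L, epochs = 5L,
             learning_rate = 0.02, batch_size = 4L, seed = 11L, ...)
}

# tiny noisy/clean pair set: smooth blobs plus noise at two levels
make_toy_pairs <- function(n = 12, shape = c(12L, 12L, 5L), seed = 5,
                           identical_pair = FALSE) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      base <- smooth_gaussian(array(stats::rpois(prod(shape), 40), shape),
                              c(2.7, 2.7, 2.8), 8) / 40
      clean <- base + 0.05 * array(stats::rnorm(prod(shape)), shape)
      noisy <- if (identical_pair) clean
               else clean + 0.3 * array(stats::rnorm(prod(shape)), shape)
      list(noisy = noisy, clean = clean)
    })
  })
}
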