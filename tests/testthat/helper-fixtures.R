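# Shared fixtures: tiny phantoms and networks sized for fast unit tests.

tiny_phantom_spec <- function(seed = 1L, ...) {
  args <- list(volume_shape = c(32, 32, 8), liver_axes = c(13, 12, 3.2),
               n_lesions = 1, lesion_radius_range = c(3, 4),
               deformation_amplitude = 0, noise_sigma = 0.01, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

tiny_dcnn <- function(seed = 1L, input = 8, base = 2) {
  build_dcnn(dcnn_config(input, base_channels = base), seed = seed)
}

random_slice_pair <- function(seed, n = 16, case_id = "c1", slice = 1L) {
  dfnseg:::with_seed(seed, {
    m <- matrix(0, n, n)
    m[(n / 2 - 2):(n / 2 + 2), (n / 2 - 2):(n / 2 + 2)] <- 1
    list(phase1 = matrix(runif(n * n), n),
         phase2 = matrix(runif(n * n), n),
         mask = m, case_id = case_id, slice = slice)
  })
}

random_mask <- function(seed, dims = c(16, 16, 16), p = 0.2) {
  dfnseg:::with_seed(seed, array(rbinom(prod(dims), 1, p), dims))
}
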