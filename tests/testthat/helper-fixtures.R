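# Shared fixtures: small constant-field decompositions and desk-scale
# texture parameters. Everything is generated in code; no binary fixtures.

const_decomp <- function(a = 1, b = 0.5, dphi = 0, shape = c(6, 8)) {
  field_decomposition(matrix(a, shape[1], shape[2]),
                      matrix(b, shape[1], shape[2]),
                      matrix(dphi, shape[1], shape[2]))
}

random_dphi <- function(shape = c(6, 8), seed = 1) {
  set.seed(seed)
  d <- matrix(runif(prod(shape), -pi, pi), shape[1], shape[2])
  d[d == -pi] <- pi
  d
}

# independent forward oracle: two-beam interference via complex arithmetic
oracle_frames <- function(a, b, dphi) {
  lapply(c(0, pi / 2, pi, 3 * pi / 2), function(pm) {
    Mod(a + b * exp(1i * (dphi - pm)))^2
  })
}

# small fiber world used across classifier tests: image area scaled down
# 16x from the 192 x 256 default, fiber count scaled with it
tiny_params <- function(...) {
  fiber_texture_params(image_shape = c(48, 64), fiber_count = 12,
                       fiber_length_px = 30, ...)
}
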