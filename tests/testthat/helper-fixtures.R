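# Shared fixture builders: everything is generated in code at test time.

# short grid for fast unit tests (20 channels, 500-595 nm)
short_grid <- function(n = 20L) seq(500, by = 5, length.out = n)

# seeded random cube with values in [lo, hi]
random_cube <- function(H, W, wavelengths, lo = 0.1, hi = 1,
                        role = "raw", seed = 1L) {
  set.seed(seed)
  hypercube(array(runif(H * W * length(wavelengths), lo, hi),
                  c(H, W, length(wavelengths))),
            wavelengths, role = role)
}

# cube from an explicit C-vector per pixel (1 x 1 x C)
pixel_cube <- function(spectrum, wavelengths, role = "raw") {
  hypercube(array(spectrum, c(1, 1, length(spectrum))), wavelengths,
            role = role)
}

# tiny model configuration for fast structural tests
tiny_config <- function(mode = "resolved", normalize = TRUE) {
  model_config(mode, channels = c(2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 5L),
               normalize = normalize)
}

expect_cube_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$values, b$values, tolerance = tol)
  expect_equal(a$wavelengths, b$wavelengths)
}
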