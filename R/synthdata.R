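# Seeded generators emulating the statistical structure of surgical HSI
# data: halogen- and LED-type camera spectra, stray-light white references
# with controllable spatial non-uniformity, tissue-like multi-class scenes
# and a colorchecker board. Everything is bit-reproducible under a fixed
# seed, so the whole calibration pipeline is testable without measured
# data.

#' Stray-light scenario specification
#'
#' Describes one lighting setup: the kind of stray-light source, its
#' intensity relative to the camera light, and the spatial-field
#' parameters. The five named default scenarios (`none`, `ceiling`,
#' `side_spot`, `direct_spot`, `ceiling_plus_direct`) are ordered by
#' strictly increasing spatial non-uniformity of the resulting white
#' reference.
#'
#' @param name Scenario name.
#' @param stray_source One of `"none"`, `"ceiling"`, `"side_spot"`,
#'   `"direct_spot"`, `"ceiling_plus_direct"`.
#' @param intensity Stray-light intensity relative to the camera light
#'   (>= 0).
#' @param center Spot center as fractions of (row, column) extent.
#' @param width Spot width as a fraction of `min(H, W)`.
#' @param gradient_direction Unit-direction angle (radians) of the ceiling
#'   gradient.
#' @param seed Seed associated with the scenario.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, stray_source = c("none", "ceiling",
                                                 "side_spot", "direct_spot",
                                                 "ceiling_plus_direct"),
                          intensity = 0.5, center = c(0.5, 0.5),
                          width = 0.3, gradient_direction = pi / 4,
                          seed = 1L) {
  stray_source <- match.arg(stray_source)
  if (!is.numeric(intensity) || intensity < 0)
    stop("intensity must be >= 0")
  structure(list(name = name, stray_source = stray_source,
                 intensity = intensity, center = center, width = width,
                 gradient_direction = gradient_direction, seed = seed),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @export
default_scenarios <- function() {
  list(
    scenario_spec("none", "none", intensity = 0),
    scenario_spec("ceiling", "ceiling", intensity = 0.3),
    scenario_spec("side_spot", "side_spot", intensity = 0.6,
                  center = c(0.5, 1), width = 0.45),
    scenario_spec("direct_spot", "direct_spot", intensity = 0.9,
                  center = c(0.5, 0.5), width = 0.25),
    scenario_spec("ceiling_plus_direct", "ceiling_plus_direct",
                  intensity = 1.2, center = c(0.5, 0.5), width = 0.3)
  )
}

#' Synthesize a camera light spectrum
#'
#' `"halogen"` draws the four parameters of the Planck-like parametric
#' spectrum from a canonical box chosen so the curve is smooth, strictly
#' positive and has exactly one interior maximum on the default grid.
#' `"led"` builds a positive mixture of 3-6 separated Gaussian peaks, so
#' the spectrum has at least two interior local maxima. Both are
#' normalized to peak 1 and are deterministic under a fixed seed.
#'
#' @param system `"halogen"` or `"led"`.
#' @param wavelengths Wavelength grid in nm.
#' @param seed RNG seed.
#' @return Positive spectrum of length `length(wavelengths)`. For
#'   `"halogen"` the generating [spectrum_params()] are attached as
#'   attribute `"params"`.
#' @export
make_camera_spectrum <- function(system = c("halogen", "led"),
                                 wavelengths = default_grid(), seed = 1L) {
  system <- match.arg(system)
  wavelengths <- validate_grid(wavelengths)
  lam_min <- min(grid_um(wavelengths))
  with_seed(seed, {
    if (system == "halogen") {
      p1 <- stats::runif(1, 0.9, 1.1)
      p2 <- p1 * lam_min * stats::runif(1, 0.76, 0.90)
      p3 <- stats::runif(1, 8, 12)
      p4 <- p3 * lam_min * stats::runif(1, 0.5, 0.7)
      params <- spectrum_params(p1, p2, p3, p4)
      f <- parametric_spectrum(params, wavelengths)
      out <- f / max(f)
      attr(out, "params") <- params
      out
    } else {
      n_peaks <- sample(3:6, 1L)
      span <- range(wavelengths)
      anchors <- seq(span[1] + 40, span[2] - 40, length.out = n_peaks)
      centers <- anchors + stats::runif(n_peaks, -15, 15)
      sigmas <- stats::runif(n_peaks, 15, 30)
      weights <- stats::runif(n_peaks, 0.5, 1)
      f <- rep(0.08, length(wavelengths))
      for (k in seq_len(n_peaks))
        f <- f + weights[k] *
          exp(-(wavelengths - centers[k])^2 / (2 * sigmas[k]^2))
      f / max(f)
    }
  })
}

#' Spatial stray-light field
#'
#' A smooth, strictly positive `H x W` map with mean exactly 1 describing
#' how the stray light is distributed over the scene. `"none"` is constant;
#' `"ceiling"` is a gentle linear gradient; the spotlight kinds are
#' Gaussian spots of increasing amplitude/concentration, so their spatial
#' standard deviation exceeds the ceiling gradient's under the default
#' parameters.
#'
#' @param spec A [scenario_spec()].
#' @param H,W Spatial extents (>= 1).
#' @return `H x W` positive matrix with `mean(field) == 1`.
#' @export
make_spatial_field <- function(spec, H, W) {
  if (!inherits(spec, "scenario_spec")) stop("spec must be a scenario_spec")
  if (H < 1 || W < 1) stop("H and W must be >= 1")
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  gauss <- function(center, width, amp) {
    cy <- 1 + center[1] * (H - 1); cx <- 1 + center[2] * (W - 1)
    s <- max(width * min(H, W), 1e-8)
    amp * exp(-((rows - cy)^2 + (cols - cx)^2) / (2 * s^2))
  }
  gradient <- function(angle, amp) {
    u <- cos(angle) * (rows - (H + 1) / 2) + sin(angle) * (cols - (W + 1) / 2)
    span <- max(u) - min(u)
    if (span == 0) 0 * u else amp * (u - min(u)) / span - amp / 2
  }
  field <- switch(spec$stray_source,
    none = matrix(1, H, W),
    ceiling = 1 + gradient(spec$gradient_direction, 0.35),
    side_spot = 1 + gauss(spec$center, spec$width, 1.2),
    direct_spot = 1 + gauss(spec$center, spec$width, 2.2),
    ceiling_plus_direct = 1 + gradient(spec$gradient_direction, 0.35) +
      gauss(spec$center, spec$width, 3.0)
  )
  field / mean(field)
}

truncated_noise <- function(n, noise_sd) {
  if (noise_sd == 0) return(rep(1, n))
  1 + noise_sd * pmin(pmax(stats::rnorm(n), -3), 3)
}

#' Synthesize a white-reference cube
#'
#' `cube(i,j,c) = camera(c) + intensity * field(i,j) * stray(c)`, then a
#' multiplicative truncated-Gaussian noise term (`1 + noise_sd * z`,
#' `|z| <= 3`) keeps values strictly positive for `noise_sd < 1/3`.
#'
#' @param camera_spectrum,stray_spectrum Positive spectra of length `C`.
#' @param field `H x W` positive spatial map (see [make_spatial_field()]).
#' @param stray_intensity Stray intensity relative to camera light (>= 0).
#' @param wavelengths Wavelength grid in nm.
#' @param noise_sd Multiplicative noise sd (0 <= noise_sd < 1/3).
#' @param seed RNG seed.
#' @return A white-reference [hypercube].
#' @export
make_white_reference <- function(camera_spectrum, stray_spectrum, field,
                                 stray_intensity, wavelengths = default_grid(),
                                 noise_sd = 0, seed = 1L) {
  wavelengths <- validate_grid(wavelengths)
  C <- length(wavelengths)
  if (length(camera_spectrum) != C || length(stray_spectrum) != C)
    stop("spectra must match the wavelength grid length")
  if (!is.matrix(field) || any(field <= 0))
    stop("field must be a strictly positive matrix")
  if (!is.numeric(stray_intensity) || stray_intensity < 0)
    stop("stray_intensity must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd < 0 || noise_sd >= 1 / 3)
    stop("noise_sd must be in [0, 1/3)")
  H <- nrow(field); W <- ncol(field)
  base <- outer(rep(1, H * W), as.numeric(camera_spectrum)) +
    stray_intensity * outer(as.vector(field), as.numeric(stray_spectrum))
  vals <- with_seed(seed, base * truncated_noise(length(base), noise_sd))
  hypercube(array(vals, c(H, W, C)), wavelengths, role = "white_reference")
}

# Smooth absorber basis used to build tissue-like reflectance spectra:
# a short-wavelength absorption edge, a NIR absorption band and a
# long-wavelength ramp. Purely phenomenological stand-ins.
absorber_basis <- function(wavelengths) {
  span <- (wavelengths - min(wavelengths)) /
    (max(wavelengths) - min(wavelengths))
  cbind(edge = 1 / (1 + exp((wavelengths - 600) / 30)),
        band = exp(-(wavelengths - 760)^2 / (2 * 40^2)),
        ramp = span^2)
}

#' Synthesize a calibrated tissue-like scene
#'
#' The scene is a seeded Voronoi partition into `n_classes` contiguous
#' regions. Each class gets a smooth reflectance spectrum in `(0, 1]`
#' built as `exp(-)` of a nonnegative mixture of three smooth absorber
#' basis functions, plus multiplicative truncated-Gaussian pixel noise.
#'
#' @param H,W Spatial extents.
#' @param wavelengths Wavelength grid in nm.
#' @param n_classes Number of tissue classes (>= 1).
#' @param seed RNG seed.
#' @param noise_sd Multiplicative within-class noise sd.
#' @return List with `cube` (calibrated [hypercube]), `labels`
#'   (`H x W` integer matrix, values `1..n_classes`) and `class_spectra`
#'   (`n_classes x C` matrix).
#' @export
make_tissue_cube <- function(H, W, wavelengths = default_grid(),
                             n_classes = 4L, seed = 1L, noise_sd = 0.01) {
  wavelengths <- validate_grid(wavelengths)
  if (n_classes < 1L) stop("n_classes must be >= 1")
  if (noise_sd < 0 || noise_sd >= 1 / 3) stop("noise_sd must be in [0, 1/3)")
  C <- length(wavelengths)
  basis <- absorber_basis(wavelengths)
  with_seed(seed, {
    cy <- stats::runif(n_classes, 1, H)
    cx <- stats::runif(n_classes, 1, W)
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    d2 <- vapply(seq_len(n_classes),
                 function(k) as.vector((rows - cy[k])^2 + (cols - cx[k])^2),
                 numeric(H * W))
    labels <- matrix(max.col(-d2, ties.method = "first"), H, W)
    coef <- cbind(stats::runif(n_classes, 0.1, 0.6),
                  stats::runif(n_classes, 0.5, 2.5),
                  stats::runif(n_classes, 0.0, 1.5),
                  stats::runif(n_classes, 0.0, 1.0))
    class_spectra <- t(vapply(seq_len(n_classes), function(k)
      exp(-(coef[k, 1] + basis %*% coef[k, 2:4]))[, 1], numeric(C)))
    vals <- class_spectra[as.vector(labels), , drop = FALSE]
    vals <- vals * truncated_noise(length(vals), noise_sd)
    list(cube = hypercube(array(vals, c(H, W, C)), wavelengths,
                          role = "calibrated"),
         labels = labels, class_spectra = class_spectra)
  })
}

#' Synthesize a calibrated colorchecker board
#'
#' A rectangular grid of flat patches, each with a constant smooth known
#' reflectance spectrum, serving as a high-fidelity reference target.
#'
#' @param wavelengths Wavelength grid in nm.
#' @param n_patches_per_side Patches per board side (total
#'   `n_patches_per_side^2`).
#' @param patch_px Pixels per patch side.
#' @param seed RNG seed.
#' @param noise_sd Multiplicative pixel noise sd (default 0: exact
#'   patches).
#' @return List with `cube` (calibrated [hypercube]), `labels` (`H x W`
#'   patch index matrix) and `patch_spectra` (`n_patches^2 x C` matrix of
#'   ground-truth reflectances).
#' @export
make_colorchecker_cube <- function(wavelengths = default_grid(),
                                   n_patches_per_side = 4L, patch_px = 8L,
                                   seed = 1L, noise_sd = 0) {
  wavelengths <- validate_grid(wavelengths)
  if (n_patches_per_side < 1L) stop("n_patches_per_side must be >= 1")
  if (noise_sd < 0 || noise_sd >= 1 / 3) stop("noise_sd must be in [0, 1/3)")
  C <- length(wavelengths)
  n_patches <- n_patches_per_side^2
  H <- W <- n_patches_per_side * patch_px
  with_seed(seed, {
    knots <- seq(min(wavelengths), max(wavelengths), length.out = 8L)
    patch_spectra <- t(vapply(seq_len(n_patches), function(k) {
      y <- stats::runif(length(knots), 0.05, 0.95)
      s <- stats::spline(knots, y, xout = wavelengths)$y
      pmin(pmax(s, 0.02), 1)
    }, numeric(C)))
    block <- matrix(seq_len(n_patches), n_patches_per_side,
                    n_patches_per_side, byrow = TRUE)
    labels <- block[rep(seq_len(n_patches_per_side), each = patch_px),
                    rep(seq_len(n_patches_per_side), each = patch_px)]
    vals <- patch_spectra[as.vector(labels), , drop = FALSE]
    vals <- vals * truncated_noise(length(vals), noise_sd)
    list(cube = hypercube(array(vals, c(H, W, C)), wavelengths,
                          role = "calibrated"),
         labels = labels, patch_spectra = patch_spectra)
  })
}

#' Generate the default stray-light scenario suite
#'
#' The four stray-light lighting setups (ceiling-only, side spot, direct
#' spot, ceiling plus direct spot) plus a stray-free reference, each as a
#' white-reference cube built from one halogen camera spectrum and one
#' LED-like stray spectrum. Under the default parameters, the spatial
#' standard deviation of the white references increases strictly from
#' `none` to `ceiling_plus_direct`.
#'
#' @param wavelengths Wavelength grid in nm.
#' @param H,W Spatial extents.
#' @param seed RNG seed.
#' @param noise_sd Multiplicative noise sd applied to the white references
#'   (default 0).
#' @return Named list of 5 entries, each `list(spec, white)`.
#' @export
make_scenario_suite <- function(wavelengths = default_grid(), H = 32L,
                                W = 32L, seed = 1L, noise_sd = 0) {
  wavelengths <- validate_grid(wavelengths)
  scenarios <- default_scenarios()
  camera <- make_camera_spectrum("halogen", wavelengths, seed = seed)
  stray <- make_camera_spectrum("led", wavelengths, seed = seed + 1L)
  out <- lapply(seq_along(scenarios), function(i) {
    sp <- scenarios[[i]]
    field <- make_spatial_field(sp, H, W)
    white <- make_white_reference(camera, stray, field, sp$intensity,
                                  wavelengths, noise_sd = noise_sd,
                                  seed = seed + 10L + i)
    list(spec = sp, white = white)
  })
  names(out) <- vapply(scenarios, `[[`, character(1), "name")
  out
}

#' Generate a synthetic illumination acquisition set
#'
#' A stand-in for a measured white-reference library: `n` cubes built from
#' per-cube camera spectra (halogen or LED system) combined with LED-like
#' stray light over cycled stray-light scenarios with jittered
#' intensities.
#'
#' @param n Number of cubes.
#' @param wavelengths Wavelength grid in nm.
#' @param H,W Spatial extents.
#' @param system `"halogen"` or `"led"` camera system.
#' @param seed RNG seed.
#' @param noise_sd Multiplicative noise sd.
#' @return List of `n` white-reference [hypercube]s.
#' @export
make_illumination_cubes <- function(n, wavelengths = default_grid(),
                                    H = 16L, W = 16L,
                                    system = c("halogen", "led"),
                                    seed = 1L, noise_sd = 0.01) {
  system <- match.arg(system)
  wavelengths <- validate_grid(wavelengths)
  scenarios <- default_scenarios()
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      camera <- make_camera_spectrum(system, wavelengths,
                                     seed = seed + 100L + i)
      stray <- make_camera_spectrum("led", wavelengths,
                                    seed = seed + 200L + i)
      sp <- scenarios[[((i - 1L) %% length(scenarios)) + 1L]]
      intensity <- sp$intensity * stats::runif(1, 0.7, 1.3)
      field <- make_spatial_field(sp, H, W)
      make_white_reference(camera, stray, field, intensity, wavelengths,
                           noise_sd = noise_sd, seed = seed + 300L + i)
    })
  })
}
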