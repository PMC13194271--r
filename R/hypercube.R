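#' Default wavelength grid
#'
#' Channel center wavelengths of a Tivita-class hyperspectral camera:
#' 100 channels from 500 to 995 nm at 5 nm spacing.
#'
#' @return Numeric vector of 100 wavelengths in nanometres.
#' @export
default_grid <- function() {
  seq(500, 995, by = 5)
}

validate_grid <- function(wavelengths) {
  if (!is.numeric(wavelengths) || length(wavelengths) < 2L)
    stop("wavelength grid must be numeric with at least 2 channels")
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stop("wavelength grid must be finite")
  if (any(wavelengths <= 0))
    stop("wavelength grid must be strictly positive")
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  invisible(as.numeric(wavelengths))
}

CUBE_ROLES <- c("raw", "calibrated", "white_reference")

#' Construct a hyperspectral cube
#'
#' A hypercube is an `H x W x C` array of nonnegative radiometric values on
#' a shared wavelength grid, tagged with the role it plays in the
#' calibration workflow: `"raw"` (uncalibrated acquisition), `"calibrated"`
#' (reflectance-like, after white-reference division) or
#' `"white_reference"` (an image of the scene illumination). Axis order is
#' (row, column, channel).
#'
#' @param values Numeric `H x W x C` array, finite and nonnegative.
#' @param wavelengths Strictly increasing positive channel wavelengths (nm);
#'   length must equal `dim(values)[3]`.
#' @param role One of `"raw"`, `"calibrated"`, `"white_reference"`.
#' @param metadata Free-form named list carried through I/O round trips.
#' @return An object of class `hypercube`.
#' @examples
#' cube <- hypercube(array(1, c(4, 4, length(default_grid()))))
#' dim(cube)
#' @export
hypercube <- function(values, wavelengths = default_grid(),
                      role = c("raw", "calibrated", "white_reference"),
                      metadata = list()) {
  role <- match.arg(role)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-dimensional H x W x C array")
  storage.mode(values) <- "double"
  d <- dim(values)
  if (d[1] < 1L || d[2] < 1L)
    stop("spatial extents H and W must both be >= 1")
  if (anyNA(values) || any(!is.finite(values)))
    stop("cube values must be finite")
  if (any(values < 0))
    stop("cube values must be nonnegative")
  wavelengths <- validate_grid(wavelengths)
  if (length(wavelengths) != d[3])
    stop(sprintf("channel count mismatch: cube has %d channels, grid has %d",
                 d[3], length(wavelengths)))
  if (!is.list(metadata)) stop("metadata must be a list")
  structure(list(values = values, wavelengths = wavelengths,
                 role = role, metadata = metadata),
            class = "hypercube")
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d pixels, %d channels (%g-%g nm), role: %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$role))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

is_hypercube <- function(x) inherits(x, "hypercube")

stop_if_not_cube <- function(x, arg = "cube") {
  if (!is_hypercube(x)) stop(sprintf("%s must be a hypercube", arg))
  invisible(x)
}

# Shared-geometry contract used by all binary cube operations.
check_same_geometry <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("cube shape mismatch: %s vs %s",
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")))
  if (!isTRUE(all.equal(a$wavelengths, b$wavelengths, tolerance = 1e-12)))
    stop("wavelength grid mismatch between cubes")
  invisible(TRUE)
}

#' Calibrate a raw cube with a white reference
#'
#' Element-wise division of a raw acquisition by a white-reference cube of
#' the same geometry, the standard reflectance calibration
#' `I_cal = I / I_white`. White values are clamped to a small positive
#' floor before division so dark pixels yield large finite values rather
#' than infinities. No upper clipping is applied: calibrated values above 1
#' are legitimate (specular or reference-mismatch effects).
#'
#' @param raw Raw [hypercube].
#' @param white White-reference [hypercube], same shape and grid.
#' @param floor Positive clamp applied to `white` before dividing. Default
#'   `1e-6 * max(white)`.
#' @return Calibrated [hypercube].
#' @seealso [relight()] for the inverse operation.
#' @export
calibrate <- function(raw, white, floor = NULL) {
  stop_if_not_cube(raw, "raw"); stop_if_not_cube(white, "white")
  check_same_geometry(raw, white)
  if (is.null(floor)) floor <- 1e-6 * max(white$values)
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor) ||
      floor <= 0)
    stop("floor must be a single positive number")
  vals <- raw$values / pmax(white$values, floor)
  hypercube(vals, raw$wavelengths, role = "calibrated",
            metadata = raw$metadata)
}

#' Relight a calibrated cube with an illuminant cube
#'
#' Element-wise multiplication of a calibrated cube by a white-reference
#' cube, synthesizing a raw acquisition of the same scene under that
#' illumination. This is the augmentation primitive of the two-dataset
#' training paradigm: sample cubes and illumination cubes combine into
#' training inputs.
#'
#' @param calibrated Calibrated [hypercube].
#' @param white White-reference [hypercube], same shape and grid.
#' @return Raw [hypercube].
#' @export
relight <- function(calibrated, white) {
  stop_if_not_cube(calibrated, "calibrated"); stop_if_not_cube(white, "white")
  check_same_geometry(calibrated, white)
  hypercube(calibrated$values * white$values, calibrated$wavelengths,
            role = "raw", metadata = calibrated$metadata)
}

#' Spatially averaged spectrum of a cube
#'
#' Per-channel arithmetic mean over all `H * W` pixels. Used for K-means
#' clustering of illumination libraries and as the spatially uniform
#' illuminant estimate.
#'
#' @param cube A [hypercube].
#' @return Numeric vector of length `C`.
#' @export
spatial_mean_spectrum <- function(cube) {
  stop_if_not_cube(cube)
  d <- dim(cube$values)
  colMeans(matrix(cube$values, d[1] * d[2], d[3]))
}

#' Flag oversaturated pixels
#'
#' White-reference acquisitions are susceptible to oversaturation; this
#' flags every pixel with at least one channel at or above a ceiling.
#'
#' @param cube A [hypercube].
#' @param ceiling Positive saturation level.
#' @return `H x W` logical matrix; `TRUE` marks saturated pixels.
#' @export
saturation_mask <- function(cube, ceiling) {
  stop_if_not_cube(cube)
  if (!is.numeric(ceiling) || length(ceiling) != 1L || !is.finite(ceiling) ||
      ceiling <= 0)
    stop("ceiling must be a single positive number")
  d <- dim(cube$values)
  m <- matrix(cube$values, d[1] * d[2], d[3])
  matrix(apply(m, 1L, function(px) any(px >= ceiling)), d[1], d[2])
}

# Build a cube whose every pixel carries the same spectrum.
constant_cube <- function(spectrum, H, W, wavelengths,
                          role = "white_reference") {
  vals <- aperm(array(spectrum, c(length(spectrum), H, W)), c(2, 3, 1))
  hypercube(vals, wavelengths, role = role)
}
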