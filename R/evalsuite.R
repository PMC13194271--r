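# Metrics, classical illuminant-estimation baselines and the analysis
# procedures: the spatial-uniformity study, cosine-similarity validation,
# latent PCA density diagnostics and scenario benchmarking.

#' Mean spectral cosine similarity between two cubes
#'
#' Mean over pixels of the cosine between corresponding C-length spectra;
#' scale-invariant per pixel, equal to 1 iff every pixel pair is positively
#' proportional. Pixels whose spectrum is all-zero in either cube are
#' excluded and counted (attribute `"n_excluded"`).
#'
#' @param a,b [hypercube]s of equal shape.
#' @return Scalar in `[-1, 1]`.
#' @export
spectral_cosine_similarity <- function(a, b) {
  stop_if_not_cube(a, "a"); stop_if_not_cube(b, "b")
  if (!identical(dim(a$values), dim(b$values)))
    stop("cube shape mismatch")
  d <- dim(a$values)
  ma <- matrix(a$values, d[1] * d[2], d[3])
  mb <- matrix(b$values, d[1] * d[2], d[3])
  na <- sqrt(rowSums(ma^2)); nb <- sqrt(rowSums(mb^2))
  ok <- na > 0 & nb > 0
  if (!any(ok)) stop("all pixel spectra are zero; cosine undefined")
  cosines <- rowSums(ma[ok, , drop = FALSE] * mb[ok, , drop = FALSE]) /
    (na[ok] * nb[ok])
  out <- mean(cosines)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Spatial standard deviation of a cube
#'
#' Per-channel population standard deviation over the `H*W` pixels,
#' averaged over channels. Zero iff the cube is spatially constant;
#' quantifies illumination non-uniformity of white references.
#'
#' @param white A [hypercube].
#' @return Nonnegative scalar.
#' @export
spatial_std <- function(white) {
  stop_if_not_cube(white, "white")
  d <- dim(white$values)
  m <- matrix(white$values, d[1] * d[2], d[3])
  mu <- colMeans(m)
  mean(sqrt(colMeans(sweep(m, 2, mu)^2)))
}

normalize_unit_mean <- function(spectrum) {
  m <- mean(spectrum)
  if (m <= 0) rep(1, length(spectrum)) else spectrum / m
}

#' Gray-world illuminant estimate
#'
#' Assumes the scene-average reflectance is achromatic: the per-channel
#' spatial mean estimates the illuminant, returned normalized to unit mean
#' (scale is unidentifiable).
#'
#' @param cube A [hypercube].
#' @return Unit-mean spectrum of length `C`.
#' @export
gray_world_illuminant <- function(cube) {
  normalize_unit_mean(spatial_mean_spectrum(cube))
}

#' Max-RGB illuminant estimate (per channel)
#'
#' Assumes a perfect reflector is visible somewhere in the scene: the
#' per-channel spatial maximum estimates the illuminant, unit-mean
#' normalized.
#'
#' @param cube A [hypercube].
#' @return Unit-mean spectrum of length `C`.
#' @export
max_channel_illuminant <- function(cube) {
  stop_if_not_cube(cube)
  d <- dim(cube$values)
  m <- matrix(cube$values, d[1] * d[2], d[3])
  normalize_unit_mean(apply(m, 2L, max))
}

# Separable Gaussian smoothing of an H x W image (replicated edges).
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(m) {
    n <- nrow(m)
    idx <- pmin(pmax(outer(seq_len(n), -r:r, `+`), 1L), n)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(img))))
}

#' First-order Gray-edge illuminant estimate
#'
#' Per channel, the Minkowski `p`-norm of the spatial gradient magnitude of
#' the (optionally Gaussian-smoothed) channel image, unit-mean normalized.
#' A spatially constant cube has no gradients; a flagged uniform spectrum
#' (attribute `"degenerate"`) is returned instead of dividing by zero.
#'
#' @param cube A [hypercube].
#' @param minkowski_p Norm order `p >= 1` (default 5).
#' @param smoothing_sigma Gaussian smoothing sd in pixels (default 1).
#' @return Unit-mean spectrum of length `C`.
#' @export
gray_edge_illuminant <- function(cube, minkowski_p = 5, smoothing_sigma = 1) {
  stop_if_not_cube(cube)
  if (minkowski_p < 1) stop("minkowski_p must be >= 1")
  d <- dim(cube$values)
  est <- vapply(seq_len(d[3]), function(c) {
    img <- gaussian_smooth(cube$values[, , c], smoothing_sigma)
    gy <- img[c(2:d[1], d[1]), , drop = FALSE] -
      img[c(1, 1:(d[1] - 1)), , drop = FALSE]
    gx <- img[, c(2:d[2], d[2]), drop = FALSE] -
      img[, c(1, 1:(d[2] - 1)), drop = FALSE]
    g <- sqrt(gx^2 + gy^2)
    mean(g^minkowski_p)^(1 / minkowski_p)
  }, numeric(1))
  if (all(est == 0)) {
    out <- rep(1, d[3])
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  normalize_unit_mean(est)
}

#' Calibrate with a spatially uniform illuminant
#'
#' Divides every pixel by the same spectrum (floor-guarded), the reduction
#' whose adequacy the spatial-uniformity study quantifies.
#'
#' @param cube A [hypercube].
#' @param illuminant Spectrum of length `C`.
#' @param floor Division floor; default `1e-6 * max(illuminant)`.
#' @return Calibrated [hypercube].
#' @export
calibrate_uniform <- function(cube, illuminant, floor = NULL) {
  stop_if_not_cube(cube)
  d <- dim(cube$values)
  if (length(illuminant) != d[3])
    stop(sprintf("illuminant length %d does not match %d channels",
                 length(illuminant), d[3]))
  white <- constant_cube(as.numeric(illuminant), d[1], d[2],
                         cube$wavelengths)
  calibrate(cube, white, floor = floor)
}

# Resolve a calibration method to a predicted white-reference cube.
# `true_white` is available only to the oracle tags.
predict_white_for <- function(method, input, true_white, floor = NULL) {
  d <- dim(input$values)
  if (inherits(method, "whiteref_model"))
    return(predict_white_reference(method, input))
  if (is.function(method))
    return(method(input))
  if (is.character(method) && length(method) == 1L) {
    return(switch(method,
      resolved_oracle = true_white,
      uniform_oracle = constant_cube(spatial_mean_spectrum(true_white),
                                     d[1], d[2], input$wavelengths),
      none = constant_cube(rep(1, d[3]), d[1], d[2], input$wavelengths),
      gray_world = constant_cube(gray_world_illuminant(input), d[1], d[2],
                                 input$wavelengths),
      max_channel = constant_cube(max_channel_illuminant(input), d[1], d[2],
                                  input$wavelengths),
      gray_edge = constant_cube(as.numeric(gray_edge_illuminant(input)),
                                d[1], d[2], input$wavelengths),
      stop(sprintf("unknown method tag: %s", method))
    ))
  }
  stop("method must be a whiteref_model, a function, or a method tag")
}

#' Spatial-uniformity study
#'
#' For each stray-light scenario: relight the samples with the scenario's
#' white reference, recalibrate with (a) the spatially averaged spectrum as
#' a spatially uniform illuminant and (b) the true spatially resolved white
#' reference, and report the mean spectral cosine similarity to the
#' original together with the scenario's spatial standard deviation. As
#' illumination non-uniformity grows, the uniform reduction degrades while
#' the resolved calibration stays essentially exact.
#'
#' @param samples List of calibrated [hypercube]s.
#' @param scenario_suite Output of [make_scenario_suite()].
#' @param floor Division floor.
#' @param seed RNG seed (bootstrap).
#' @param n_boot Bootstrap resamples.
#' @return Data frame of class `eval_report`: scenario, method
#'   (`uniform`/`resolved`), n, mean_cosine, ci_low, ci_high,
#'   scenario_spatial_std.
#' @export
uniformity_study <- function(samples, scenario_suite, floor = NULL,
                             seed = 1L, n_boot = 1000L) {
  if (!length(samples) || !length(scenario_suite))
    stop("samples and scenario_suite must be non-empty")
  with_seed(seed, {
    rows <- list()
    for (nm in names(scenario_suite)) {
      white <- scenario_suite[[nm]]$white
      sstd <- spatial_std(white)
      scores_u <- numeric(length(samples))
      scores_r <- numeric(length(samples))
      for (i in seq_along(samples)) {
        input <- relight(samples[[i]], white)
        cal_u <- calibrate_uniform(input, spatial_mean_spectrum(white),
                                   floor = floor)
        cal_r <- calibrate(input, white, floor = floor)
        scores_u[i] <- spectral_cosine_similarity(cal_u, samples[[i]])
        scores_r[i] <- spectral_cosine_similarity(cal_r, samples[[i]])
      }
      for (meth in c("uniform", "resolved")) {
        sc <- if (meth == "uniform") scores_u else scores_r
        ci <- bootstrap_ci(sc, n_boot)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = nm, method = meth, n = length(sc),
          mean_cosine = mean(sc), ci_low = ci[1], ci_high = ci[2],
          scenario_spatial_std = sstd)
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("eval_report", "data.frame")
    out
  })
}

#' Latent PCA density diagnostics
#'
#' Fits a PCA on pooled latent feature vectors (see [encode_pooled()]),
#' projects each group onto the first two components (sign-canonicalized:
#' the largest-magnitude loading of each component is positive) and
#' summarizes each group with a 2D kernel density estimate.
#'
#' @param feature_vectors Numeric matrix (vectors in rows) or list of
#'   vectors.
#' @param groups Group label per vector.
#' @param kde_n Grid size of the kernel density estimate.
#' @return List with `scores` (n x 2), `groups`, `explained` (variance
#'   fractions), `densities` (per-group `MASS::kde2d` fits, `NULL` when
#'   degenerate) and `degenerate` flag.
#' @export
latent_pca_density <- function(feature_vectors, groups, kde_n = 25L) {
  X <- if (is.list(feature_vectors)) do.call(rbind, feature_vectors)
       else as.matrix(feature_vectors)
  if (nrow(X) < 3L) stop("need at least 3 feature vectors")
  if (length(groups) != nrow(X))
    stop("groups must have one label per vector")
  groups <- as.factor(groups)
  total_var <- sum(apply(X, 2L, stats::var))
  if (total_var == 0) {
    return(list(scores = matrix(0, nrow(X), 2L), groups = groups,
                explained = c(NA_real_, NA_real_), densities = NULL,
                degenerate = TRUE))
  }
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 2L)
  rot <- pca$rotation
  for (k in seq_len(ncol(rot))) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) {
      rot[, k] <- -rot[, k]
      pca$x[, k] <- -pca$x[, k]
    }
  }
  scores <- pca$x[, 1:2, drop = FALSE]
  if (ncol(scores) < 2L) scores <- cbind(scores, 0)
  densities <- lapply(levels(groups), function(g) {
    pts <- scores[groups == g, , drop = FALSE]
    if (nrow(pts) < 3L || any(apply(pts, 2L, stats::sd) == 0)) return(NULL)
    MASS::kde2d(pts[, 1], pts[, 2], n = kde_n)
  })
  names(densities) <- levels(groups)
  list(scores = scores, groups = groups,
       explained = (pca$sdev^2 / sum(pca$sdev^2))[1:2],
       densities = densities, degenerate = FALSE)
}

#' Benchmark calibration methods across stray-light scenarios
#'
#' Cross product of methods and scenarios: for each cell, relight every
#' sample with the scenario's white reference, recalibrate with the
#' method, and report the mean spectral cosine similarity to the original
#' sample with a 95% bootstrap percentile interval (resampling over
#' samples).
#'
#' @param methods Character vector of method tags (`"none"`,
#'   `"gray_world"`, `"max_channel"`, `"gray_edge"`, `"uniform_oracle"`,
#'   `"resolved_oracle"`), and/or a named list mixing tags, trained
#'   `whiteref_model`s and functions.
#' @param samples List of calibrated [hypercube]s.
#' @param scenario_suite Output of [make_scenario_suite()].
#' @param floor Division floor.
#' @param seed RNG seed (bootstrap).
#' @param n_boot Bootstrap resamples (default 1000).
#' @return Data frame of class `eval_report`: method, scenario, n,
#'   mean_cosine, ci_low, ci_high, scenario_spatial_std.
#' @export
benchmark_methods <- function(methods, samples, scenario_suite, floor = NULL,
                              seed = 1L, n_boot = 1000L) {
  if (is.character(methods)) methods <- stats::setNames(as.list(methods),
                                                        methods)
  if (is.null(names(methods)) || any(names(methods) == ""))
    stop("methods must be named")
  with_seed(seed, {
    rows <- list()
    for (mi in seq_along(methods)) {
      for (nm in names(scenario_suite)) {
        white <- scenario_suite[[nm]]$white
        scores <- vapply(samples, function(s) {
          input <- relight(s, white)
          what <- predict_white_for(methods[[mi]], input, white, floor)
          spectral_cosine_similarity(calibrate(input, what, floor = floor), s)
        }, numeric(1))
        ci <- bootstrap_ci(scores, n_boot)
        rows[[length(rows) + 1L]] <- data.frame(
          method = names(methods)[mi], scenario = nm, n = length(scores),
          mean_cosine = mean(scores), ci_low = ci[1], ci_high = ci[2],
          scenario_spatial_std = spatial_std(white))
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("eval_report", "data.frame")
    out
  })
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
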