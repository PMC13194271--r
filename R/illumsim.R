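# Physics-inspired simulation of plausible white-reference cubes.
#
# One-dimensional light spectra are modeled by a four-parameter function
# inspired by Planck's radiation law,
#     f(lambda) = (p1*lambda - p2)^3 / (exp(p3*lambda - p4) - 1),
# fitted to observed illumination spectra by least squares. Per-parameter
# intervals mu_k +/- n_sigma * sigma_k are sampled to synthesize new
# spectra, which are then spatialized onto measured white-reference
# templates so the simulated cubes keep realistic spatial variation.
# Wavelengths are rescaled to micrometres before evaluating f so that
# p1..p4 are O(1), which conditions the least-squares problem.

# Run code with a temporarily fixed RNG state; NULL seed = ambient RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

grid_um <- function(wavelengths) wavelengths / 1000

#' Parameters of the parametric light spectrum
#'
#' @param p1,p2,p3,p4 Real parameters of the spectrum
#'   `f(lambda) = (p1*lambda - p2)^3 / (exp(p3*lambda - p4) - 1)`, with
#'   `lambda` in micrometres.
#' @return An object of class `spectrum_params`.
#' @export
spectrum_params <- function(p1, p2, p3, p4) {
  p <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
  if (anyNA(p) || any(!is.finite(p))) stop("spectrum parameters must be finite")
  structure(as.list(p), class = "spectrum_params")
}

#' @export
print.spectrum_params <- function(x, ...) {
  cat(sprintf("<spectrum_params> p1=%.4g p2=%.4g p3=%.4g p4=%.4g\n",
              x$p1, x$p2, x$p3, x$p4))
  invisible(x)
}

params_vec <- function(params) {
  if (inherits(params, "spectrum_params"))
    return(c(params$p1, params$p2, params$p3, params$p4))
  if (is.numeric(params) && length(params) == 4L) return(as.numeric(params))
  stop("expected spectrum_params or a numeric vector of length 4")
}

# Validity of Planck-like spectrum parameters on a grid: denominator bounded away from
# its pole and a nonnegative finite spectrum.
params_valid <- function(params, wavelengths, eps = 1e-3) {
  p <- params_vec(params)
  lam <- grid_um(wavelengths)
  den_arg <- p[3] * lam - p[4]
  if (any(den_arg < eps)) return(FALSE)
  f <- (p[1] * lam - p[2])^3 / expm1(den_arg)
  all(is.finite(f)) && all(f >= 0)
}

#' Evaluate the parametric light spectrum on a wavelength grid
#'
#' Computes `f(lambda) = (p1*lambda - p2)^3 / (exp(p3*lambda - p4) - 1)`
#' channel-wise, with `lambda` the grid wavelengths converted to
#' micrometres. Parameters must keep the denominator positive (at least
#' `eps`) and the spectrum nonnegative over the whole grid.
#'
#' @param params [spectrum_params()] or numeric vector `c(p1, p2, p3, p4)`.
#' @param wavelengths Wavelength grid in nm.
#' @param eps Lower bound enforced on `p3*lambda - p4`.
#' @return Numeric spectrum of length `length(wavelengths)`.
#' @export
parametric_spectrum <- function(params, wavelengths, eps = 1e-3) {
  p <- params_vec(params)
  wavelengths <- validate_grid(wavelengths)
  lam <- grid_um(wavelengths)
  den_arg <- p[3] * lam - p[4]
  bad <- den_arg < eps
  if (any(bad))
    stop(sprintf(
      "invalid spectrum parameters: denominator below eps at wavelengths %s nm",
      paste(utils::head(wavelengths[bad], 5L), collapse = ", ")))
  f <- (p[1] * lam - p[2])^3 / expm1(den_arg)
  neg <- f < 0
  if (any(neg))
    stop(sprintf(
      "invalid spectrum parameters: negative spectrum at wavelengths %s nm",
      paste(utils::head(wavelengths[neg], 5L), collapse = ", ")))
  f
}

#' Fit the parametric spectrum to an observed spectrum
#'
#' Levenberg-Marquardt least squares (via \pkg{minpack.lm}) with a
#' moment-based initialization and seeded multi-starts, keeping the best
#' residual. The fit is non-convex, so a local optimum is accepted.
#' Non-convergence is flagged on the returned object rather than raised.
#'
#' @param target Nonnegative observed spectrum, same length as the grid.
#' @param wavelengths Wavelength grid in nm.
#' @param init Optional [spectrum_params()] initialization; when `NULL` a
#'   moment-based heuristic (amplitude-matched canonical halogen shape) is
#'   used.
#' @param n_starts Number of jittered restarts (the first start is `init`).
#' @param seed Optional seed for the restart jitter.
#' @param eps Validity margin for the denominator.
#' @return List with elements `params` ([spectrum_params()]), `residual`
#'   (sum of squared residuals), `rel_rmse` (residual RMSE relative to the
#'   RMS of the target) and `converged`.
#' @export
fit_spectrum <- function(target, wavelengths, init = NULL, n_starts = 10L,
                         seed = NULL, eps = 1e-3) {
  wavelengths <- validate_grid(wavelengths)
  if (!is.numeric(target) || length(target) != length(wavelengths))
    stop("target must be numeric with one value per grid channel")
  if (any(!is.finite(target)) || any(target < 0))
    stop("target spectrum must be finite and nonnegative")
  lam <- grid_um(wavelengths)

  resid_fn <- function(p) {
    den_arg <- p[3] * lam - p[4]
    ok <- den_arg >= eps
    f <- numeric(length(lam))
    f[ok] <- (p[1] * lam[ok] - p[2])^3 / expm1(den_arg[ok])
    # soft barrier keeps the optimizer away from the denominator pole
    barrier <- 1e3 * pmax(0, eps - den_arg)
    c(f - target, barrier)
  }

  starts <- with_seed(seed, make_starts(target, lam, init, n_starts))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(resid_fn(fit$par)[seq_along(lam)]^2)
    if (!params_valid(fit$par, wavelengths, eps)) next
    if (is.null(best) || ssr < best$ssr)
      best <- list(par = fit$par, ssr = ssr, info = fit$info)
  }
  if (is.null(best)) {
    # no start yielded a valid iterate: return the flagged initial guess
    s0 <- starts[[1]]
    return(list(params = spectrum_params(s0[1], s0[2], s0[3], s0[4]),
                residual = sum(resid_fn(s0)[seq_along(lam)]^2),
                rel_rmse = NA_real_, converged = FALSE))
  }
  denom <- sqrt(mean(target^2))
  rel <- if (denom > 0) sqrt(best$ssr / length(lam)) / denom else NA_real_
  list(params = spectrum_params(best$par[1], best$par[2], best$par[3],
                                best$par[4]),
       residual = best$ssr, rel_rmse = rel,
       converged = best$info %in% 1:4)
}

# Canonical halogen-like start, amplitude-matched to the target, plus
# multiplicative jitters of the shape parameters.
make_starts <- function(target, lam, init, n_starts) {
  if (!is.null(init)) {
    base <- params_vec(init)
  } else {
    lmin <- min(lam)
    base <- c(1, 0.83 * lmin, 10, 3)
    f0 <- (base[1] * lam - base[2])^3 / expm1(base[3] * lam - base[4])
    amp <- max(target) / max(f0)
    if (is.finite(amp) && amp > 0) {
      a <- amp^(1 / 3)
      base[1] <- base[1] * a
      base[2] <- base[2] * a
    }
  }
  starts <- list(base)
  if (n_starts > 1L) {
    for (i in seq_len(n_starts - 1L)) {
      jit <- stats::runif(4, 0.85, 1.15)
      starts[[i + 1L]] <- base * jit
    }
  }
  starts
}

#' Per-parameter statistics across fitted instances
#'
#' Mean and population standard deviation of each of the four spectrum
#' parameters across a set of fitted instances.
#'
#' @param param_sets List of [spectrum_params()] (or length-4 numeric
#'   vectors).
#' @return Object of class `param_stats` with fields `mu`, `sigma`
#'   (length-4 vectors) and `n_instances`.
#' @export
compute_param_stats <- function(param_sets) {
  if (!is.list(param_sets) || length(param_sets) < 1L)
    stop("param_sets must be a non-empty list")
  m <- t(vapply(param_sets, params_vec, numeric(4)))
  mu <- colMeans(m)
  sigma <- sqrt(colMeans(sweep(m, 2, mu)^2))  # population sd
  structure(list(mu = mu, sigma = sigma, n_instances = nrow(m)),
            class = "param_stats")
}

#' Sampling intervals for the spectrum parameters
#'
#' Builds per-parameter intervals `[mu_k - n_sigma*sigma_k,
#' mu_k + n_sigma*sigma_k]`. `n_sigma` controls the realism-diversity
#' trade-off of the simulated spectra; the default 0.25 gave the best
#' validation similarity in the sweep reproduced by the evaluation suite.
#'
#' @param stats A `param_stats` object from [compute_param_stats()].
#' @param n_sigma Nonnegative interval half-width in standard deviations.
#' @return Object of class `param_intervals` with `lower`, `upper`,
#'   `n_sigma`.
#' @export
build_intervals <- function(stats, n_sigma = 0.25) {
  if (!inherits(stats, "param_stats")) stop("stats must be a param_stats")
  if (!is.numeric(n_sigma) || length(n_sigma) != 1L || !is.finite(n_sigma) ||
      n_sigma < 0)
    stop("n_sigma must be a single nonnegative number")
  structure(list(lower = stats$mu - n_sigma * stats$sigma,
                 upper = stats$mu + n_sigma * stats$sigma,
                 n_sigma = n_sigma),
            class = "param_intervals")
}

#' Sample valid spectrum parameters from intervals
#'
#' Draws each parameter independently and uniformly within its interval
#' (or, with `mode = "grid"`, from a regular discretization of the
#' interval product) and rejects draws that are invalid on the grid
#' (denominator pole or negative spectrum), up to `max_tries` attempts.
#'
#' @param intervals A `param_intervals` object.
#' @param wavelengths Wavelength grid in nm used for the validity check.
#' @param seed Optional RNG seed.
#' @param mode `"continuous"` (default) or `"grid"`.
#' @param grid_resolution Points per parameter in `"grid"` mode.
#' @param max_tries Rejection-sampling cap.
#' @param eps Validity margin for the denominator.
#' @return A valid [spectrum_params()]; attribute `"tries"` records the
#'   number of draws used.
#' @export
sample_params <- function(intervals, wavelengths, seed = NULL,
                          mode = c("continuous", "grid"),
                          grid_resolution = 10L, max_tries = 1000L,
                          eps = 1e-3) {
  if (!inherits(intervals, "param_intervals"))
    stop("intervals must be a param_intervals")
  mode <- match.arg(mode)
  wavelengths <- validate_grid(wavelengths)
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      p <- if (mode == "continuous") {
        stats::runif(4, intervals$lower, intervals$upper)
      } else {
        vapply(1:4, function(k) {
          pts <- seq(intervals$lower[k], intervals$upper[k],
                     length.out = max(2L, grid_resolution))
          pts[sample.int(length(pts), 1L)]
        }, numeric(1))
      }
      if (params_valid(p, wavelengths, eps)) {
        out <- spectrum_params(p[1], p[2], p[3], p[4])
        attr(out, "tries") <- i
        return(out)
      }
    }
    stop(sprintf(
      "sampling failure: no valid parameters in %d draws (rejection rate 100%%)",
      max_tries))
  })
}

#' Spatialize a spectrum onto a white-reference template
#'
#' Synthesizes a white-reference cube whose spatially averaged spectrum is
#' the given spectrum while keeping the template's spatial variation:
#' `out(i,j,c) = spectrum(c) * template(i,j,c) / mean_spectrum(c)`.
#'
#' @param spectrum Nonnegative target spectrum (length `C`).
#' @param template White-reference [hypercube] with strictly positive
#'   spatial mean spectrum.
#' @return A white-reference [hypercube].
#' @export
spatialize <- function(spectrum, template) {
  stop_if_not_cube(template, "template")
  d <- dim(template$values)
  if (!is.numeric(spectrum) || length(spectrum) != d[3])
    stop("spectrum length must equal the template channel count")
  if (any(!is.finite(spectrum)) || any(spectrum < 0))
    stop("spectrum must be finite and nonnegative")
  ms <- spatial_mean_spectrum(template)
  if (any(ms <= 0))
    stop("template has a zero channel mean; cannot spatialize")
  scale <- spectrum / ms
  vals <- template$values * array(rep(scale, each = d[1] * d[2]), d)
  hypercube(vals, template$wavelengths, role = "white_reference")
}

new_illumination_library <- function(white_refs, labels, K, provenance,
                                     seed = NULL) {
  structure(list(white_refs = white_refs, labels = labels, K = K,
                 provenance = provenance, seed = seed),
            class = "illumination_library")
}

#' @export
print.illumination_library <- function(x, ...) {
  cat(sprintf("<illumination_library> %d white references, K = %d clusters\n",
              length(x$white_refs), x$K))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$K), collapse = ", "), "\n")
  cat("  provenance:", paste(names(table(x$provenance)),
                             table(x$provenance), collapse = "; "), "\n")
  invisible(x)
}

#' Cluster white-reference cubes into an illumination library
#'
#' K-means (squared-Euclidean, 10 restarts) on the spatially averaged
#' spectra of the cubes. Spectra are not normalized before clustering:
#' intensity differences are themselves illumination information. Each
#' cube receives a cluster label 1..K.
#'
#' @param white_refs List of white-reference [hypercube]s on a common grid.
#' @param K Number of clusters (default 4).
#' @param seed RNG seed making the clustering deterministic.
#' @return An `illumination_library`.
#' @export
cluster_library <- function(white_refs, K = 4L, seed = 1L) {
  if (!is.list(white_refs) || !length(white_refs))
    stop("white_refs must be a non-empty list of hypercubes")
  lapply(white_refs, stop_if_not_cube, arg = "white_refs element")
  for (w in white_refs[-1]) check_same_geometry(white_refs[[1]], w)
  if (length(white_refs) < K)
    stop(sprintf("need at least K = %d cubes, got %d", K, length(white_refs)))
  spectra <- t(vapply(white_refs, spatial_mean_spectrum,
                      numeric(dim(white_refs[[1]]$values)[3])))
  labels <- with_seed(seed, {
    if (nrow(unique(spectra)) < K) {
      # degenerate library (duplicated spectra): assign by duplicate group
      grp <- match(apply(spectra, 1, paste, collapse = ","),
                   unique(apply(spectra, 1, paste, collapse = ",")))
      ((grp - 1L) %% K) + 1L
    } else {
      stats::kmeans(spectra, centers = K, nstart = 10L,
                    iter.max = 100L)$cluster
    }
  })
  new_illumination_library(white_refs, as.integer(labels), as.integer(K),
                           rep("measured-synthetic", length(white_refs)),
                           seed)
}

#' Convex interpolation of two white-reference cubes
#'
#' `alpha * a + (1 - alpha) * b`, element-wise. Interpolation preserves
#' positivity and the local extrema shared by both parents, matching the
#' approximately constructive interference of LED camera light with LED
#' surgical lights.
#'
#' @param a,b White-reference [hypercube]s of matching geometry.
#' @param alpha Interpolation weight in `[0, 1]` (1 returns `a`).
#' @return A white-reference [hypercube].
#' @export
interpolate_pair <- function(a, b, alpha) {
  stop_if_not_cube(a, "a"); stop_if_not_cube(b, "b")
  check_same_geometry(a, b)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single number in [0, 1]")
  hypercube(alpha * a$values + (1 - alpha) * b$values, a$wavelengths,
            role = "white_reference")
}

#' Generate LED-system illumination cubes by inter-cluster interpolation
#'
#' Each output interpolates two randomly selected members of two distinct
#' clusters with a uniform random weight (pairwise mixtures only).
#'
#' @param library An `illumination_library` with at least two non-empty
#'   clusters.
#' @param count Number of cubes to generate.
#' @param alpha_sampler Function of no arguments returning one weight in
#'   `[0, 1]`; defaults to `runif(1)`.
#' @param seed RNG seed.
#' @return List of white-reference [hypercube]s; attribute `"parents"` is a
#'   data frame (indices and weights).
#' @export
generate_led_set <- function(library, count, alpha_sampler = NULL,
                             seed = 1L) {
  if (!inherits(library, "illumination_library"))
    stop("library must be an illumination_library")
  present <- sort(unique(library$labels))
  if (length(present) < 2L)
    stop("library has a single cluster; inter-cluster interpolation needs >= 2")
  if (!is.numeric(count) || count < 0) stop("count must be >= 0")
  if (is.null(alpha_sampler)) alpha_sampler <- function() stats::runif(1)
  with_seed(seed, {
    out <- vector("list", count)
    parents <- data.frame(i = integer(count), j = integer(count),
                          alpha = numeric(count))
    for (k in seq_len(count)) {
      cl <- sample(present, 2L)
      i <- sample(which(library$labels == cl[1]), 1L)
      j <- sample(which(library$labels == cl[2]), 1L)
      alpha <- alpha_sampler()
      out[[k]] <- interpolate_pair(library$white_refs[[i]],
                                   library$white_refs[[j]], alpha)
      parents[k, ] <- list(i, j, alpha)
    }
    attr(out, "parents") <- parents
    out
  })
}

#' Generate halogen-system illumination cubes by simulation + interpolation
#'
#' The halogen pipeline: fit the parametric spectrum to every library
#' cube's spatially averaged spectrum, compute per-parameter statistics,
#' build `mu +/- n_sigma*sigma` intervals, then repeatedly sample valid
#' parameters, evaluate the spectrum and spatialize it onto a randomly
#' chosen library template. Unlike interpolation, sampled spectra can shift
#' the positions of spectral extrema, which is required for halogen camera
#' light interfering destructively with LED surgical lights. The simulated
#' set is then augmented with random pairwise interpolations drawn from the
#' union of acquisitions and simulations.
#'
#' @param library An `illumination_library`.
#' @param n_sigma Interval half-width (default 0.25).
#' @param count_sim Number of simulated cubes.
#' @param count_interp Number of additional interpolated cubes.
#' @param seed RNG seed.
#' @param eps Validity margin for the spectrum denominator.
#' @param max_tries Rejection cap per sampled parameter set.
#' @return List of white-reference [hypercube]s (simulations first).
#'   Attributes: `"provenance"` (`"simulated"`/`"interpolated"`),
#'   `"target_spectra"` (`count_sim x C` matrix of the sampled spectra),
#'   `"params"` (list of sampled [spectrum_params()]), `"rejection_rate"`.
#' @export
generate_halogen_set <- function(library, n_sigma = 0.25, count_sim = 10L,
                                 count_interp = 0L, seed = 1L, eps = 1e-3,
                                 max_tries = 1000L) {
  if (!inherits(library, "illumination_library"))
    stop("library must be an illumination_library")
  if (!length(library$white_refs)) stop("library is empty")
  wl <- library$white_refs[[1]]$wavelengths
  with_seed(seed, {
    fits <- lapply(library$white_refs, function(w)
      fit_spectrum(spatial_mean_spectrum(w), wl, eps = eps))
    stats <- compute_param_stats(lapply(fits, `[[`, "params"))
    intervals <- build_intervals(stats, n_sigma)
    sims <- vector("list", count_sim)
    params <- vector("list", count_sim)
    targets <- matrix(NA_real_, count_sim, length(wl))
    total_tries <- 0L
    for (k in seq_len(count_sim)) {
      p <- sample_params(intervals, wl, eps = eps, max_tries = max_tries)
      total_tries <- total_tries + attr(p, "tries")
      spec <- parametric_spectrum(p, wl, eps = eps)
      template <- library$white_refs[[sample.int(length(library$white_refs),
                                                 1L)]]
      sims[[k]] <- spatialize(spec, template)
      params[[k]] <- p
      targets[k, ] <- spec
    }
    pool <- c(library$white_refs, sims)
    interps <- vector("list", count_interp)
    for (k in seq_len(count_interp)) {
      ij <- sample.int(length(pool), 2L)
      interps[[k]] <- interpolate_pair(pool[[ij[1]]], pool[[ij[2]]],
                                       stats::runif(1))
    }
    out <- c(sims, interps)
    attr(out, "provenance") <- c(rep("simulated", count_sim),
                                 rep("interpolated", count_interp))
    attr(out, "target_spectra") <- targets
    attr(out, "params") <- params
    attr(out, "rejection_rate") <-
      if (count_sim > 0) 1 - count_sim / total_tries else 0
    attr(out, "fit_stats") <- stats
    out
  })
}
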