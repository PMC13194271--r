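test_that("parametric_spectrum evaluates the Planck-like form exactly", {
  g <- c(500, 600, 700, 800, 900)
  p <- spectrum_params(1.0, 0.42, 10, 3.2)
  f <- parametric_spectrum(p, g)
  # independent re-evaluation of the formula (micrometre scaling)
  lam <- g / 1000
  expect_equal(f, (1.0 * lam - 0.42)^3 / (exp(10 * lam - 3.2) - 1),
               tolerance = 1e-14)

  # numerator root: f(lambda*) = 0 exactly where p1*lambda = p2; for a
  # nonnegative spectrum the root sits at the grid minimum
  g2 <- c(500, 600, 700)
  p2 <- spectrum_params(1.0, 0.5, 10, 3.0)
  expect_equal(parametric_spectrum(p2, g2)[1], 0)

  # numerator scaling: (a p1, a p2) multiplies f by a^3
  a <- 1.7
  pa <- spectrum_params(a * 1.0, a * 0.42, 10, 3.2)
  expect_equal(parametric_spectrum(pa, g), a^3 * f, tolerance = 1e-12)

  # denominator pole -> validity error listing wavelengths
  expect_error(parametric_spectrum(spectrum_params(1, 0.4, 1, 2), g),
               "denominator.*500")
})

test_that("fit_spectrum recovers generating parameters in function space", {
  g <- default_grid()
  p_true <- attr(make_camera_spectrum("halogen", g, seed = 11), "params")
  target <- parametric_spectrum(p_true, g)

  # init at the truth: essentially zero residual
  fit0 <- fit_spectrum(target, g, init = p_true, n_starts = 1)
  expect_lt(fit0$residual / sum(target^2), 1e-10)
  expect_true(fit0$converged)

  # init perturbed by 5%: recovery to rel RMSE <= 1e-3
  p_init <- spectrum_params(p_true$p1 * 1.05, p_true$p2 * 0.95,
                            p_true$p3 * 1.05, p_true$p4 * 0.95)
  fit1 <- fit_spectrum(target, g, init = p_init, n_starts = 1)
  fhat <- parametric_spectrum(fit1$params, g)
  expect_lt(sqrt(mean((fhat - target)^2)) / sqrt(mean(target^2)), 1e-3)

  # default moment-based multi-start init also recovers
  fit2 <- fit_spectrum(target, g, seed = 1)
  fhat2 <- parametric_spectrum(fit2$params, g)
  expect_lt(sqrt(mean((fhat2 - target)^2)) / sqrt(mean(target^2)), 1e-3)

  expect_error(fit_spectrum(c(-1, target[-1]), g), "nonnegative")
})

test_that("parameter statistics use the population standard deviation", {
  p1 <- spectrum_params(1, 2, 3, 4)
  p3 <- spectrum_params(3, 2, 3, 4)
  single <- compute_param_stats(list(p1))
  expect_equal(single$mu, c(1, 2, 3, 4))
  expect_equal(single$sigma, c(0, 0, 0, 0))

  st <- compute_param_stats(list(p1, p3))
  expect_equal(st$mu[1], 2)
  expect_equal(st$sigma[1], 1)  # population sd of {1, 3}
  expect_equal(st$n_instances, 2L)

  # permutation invariance
  st2 <- compute_param_stats(list(p3, p1))
  expect_equal(st$mu, st2$mu)
  expect_equal(st$sigma, st2$sigma)
  expect_error(compute_param_stats(list()), "non-empty")
})

test_that("build_intervals forms mu +/- n_sigma*sigma with monotone width", {
  st <- compute_param_stats(list(spectrum_params(1, 2, 3, 4),
                                 spectrum_params(3, 2, 5, 4)))
  iv0 <- build_intervals(st, 0)
  expect_equal(iv0$lower, iv0$upper)
  expect_equal(iv0$lower, st$mu)

  iv1 <- build_intervals(st, 1)
  expect_equal(iv1$lower[1], 1)  # mu 2, sigma 1
  expect_equal(iv1$upper[1], 3)

  iv25 <- build_intervals(st)    # default n_sigma = 0.25
  expect_equal(iv25$n_sigma, 0.25)
  expect_true(all(iv1$upper - iv1$lower >= iv25$upper - iv25$lower))
  expect_error(build_intervals(st, -0.1), "nonnegative")
})

test_that("sample_params draws valid parameters inside the intervals", {
  g <- default_grid()
  p <- attr(make_camera_spectrum("halogen", g, seed = 4), "params")
  st <- compute_param_stats(list(p))
  iv_point <- build_intervals(st, 0)
  drawn <- sample_params(iv_point, g, seed = 1)
  expect_equal(unlist(drawn[c("p1", "p2", "p3", "p4")], use.names = FALSE),
               unlist(p[c("p1", "p2", "p3", "p4")], use.names = FALSE))

  # many draws from a widened library: all in bounds and valid on the grid
  ps <- lapply(1:8, function(i)
    attr(make_camera_spectrum("halogen", g, seed = i), "params"))
  iv <- build_intervals(compute_param_stats(ps), 0.25)
  draws <- lapply(1:200, function(i) sample_params(iv, g))
  ok <- vapply(draws, function(d) {
    v <- c(d$p1, d$p2, d$p3, d$p4)
    all(v >= iv$lower - 1e-12) && all(v <= iv$upper + 1e-12) &&
      all(parametric_spectrum(d, g) >= 0)
  }, logical(1))
  expect_true(all(ok))

  # determinism and grid mode
  expect_equal(sample_params(iv, g, seed = 9)$p3,
               sample_params(iv, g, seed = 9)$p3)
  dg <- sample_params(iv, g, seed = 2, mode = "grid", grid_resolution = 5)
  expect_true(dg$p1 >= iv$lower[1] && dg$p1 <= iv$upper[1])
})

test_that("spatialize imposes the target mean spectrum on the template", {
  g <- short_grid(2)
  # 2 x 1 x 2 template carrying the spatial pattern (1, 3) in each channel,
  # spatialized to the flat target spectrum (4, 4): per-pixel (2, 6)
  tpl <- hypercube(array(c(1, 3, 1, 3), c(2, 1, 2)), g,
                   role = "white_reference")
  out <- spatialize(c(4, 4), tpl)
  expect_equal(as.vector(out$values), c(2, 6, 2, 6))

  # mean-spectrum identity and spatial-pattern preservation
  r <- random_cube(5, 4, g, lo = 0.2, hi = 2, role = "white_reference",
                   seed = 8)
  spec <- c(3, 0.5)
  out2 <- spatialize(spec, r)
  expect_equal(spatial_mean_spectrum(out2), spec, tolerance = 1e-12)
  ratio_in <- r$values[, , 1] / mean(r$values[, , 1])
  ratio_out <- out2$values[, , 1] / mean(out2$values[, , 1])
  expect_equal(ratio_out, ratio_in, tolerance = 1e-12)

  zero_tpl <- hypercube(array(c(0, 0, 1, 1), c(2, 1, 2)), g,
                        role = "white_reference")
  expect_error(spatialize(c(1, 1), zero_tpl), "zero channel mean")
})

test_that("cluster_library recovers well-separated groups deterministically", {
  g <- short_grid(4)
  specs <- list(c(1, 1, 1, 1), c(5, 5, 5, 5), c(1, 5, 1, 5), c(10, 1, 10, 1))
  cubes <- list()
  truth <- integer(0)
  set.seed(3)
  for (k in seq_along(specs)) {
    for (r in 1:3) {
      jit <- specs[[k]] * (1 + rnorm(4, 0, 0.01))
      cubes[[length(cubes) + 1L]] <-
        hypercube(aperm(array(jit, c(4, 2, 2)), c(2, 3, 1)), g,
                  role = "white_reference")
      truth <- c(truth, k)
    }
  }
  lib <- cluster_library(cubes, K = 4, seed = 5)
  # co-membership agrees with the planted groups
  co_truth <- outer(truth, truth, `==`)
  co_fit <- outer(lib$labels, lib$labels, `==`)
  expect_identical(co_fit, co_truth)

  expect_identical(cluster_library(cubes, K = 4, seed = 5)$labels, lib$labels)
  expect_error(cluster_library(cubes[1:3], K = 4), "at least K")

  # degenerate: all cubes identical still succeeds
  same <- lapply(1:4, function(i) cubes[[1]])
  expect_s3_class(cluster_library(same, K = 2, seed = 1),
                  "illumination_library")
})

test_that("interpolate_pair is a convex combination preserving positivity", {
  g <- short_grid(3)
  a <- hypercube(aperm(array(c(1, 2, 3), c(3, 2, 2)), c(2, 3, 1)), g,
                 role = "white_reference")
  b <- hypercube(aperm(array(c(3, 4, 5), c(3, 2, 2)), c(2, 3, 1)), g,
                 role = "white_reference")
  expect_cube_equal(interpolate_pair(a, b, 1), a)
  mid <- interpolate_pair(a, b, 0.5)
  expect_equal(spatial_mean_spectrum(mid), c(2, 3, 4))
  # commutes with spatial averaging
  al <- 0.3
  expect_equal(spatial_mean_spectrum(interpolate_pair(a, b, al)),
               al * spatial_mean_spectrum(a) +
                 (1 - al) * spatial_mean_spectrum(b))
  expect_error(interpolate_pair(a, b, 1.2), "alpha")
  expect_error(interpolate_pair(a, b, -0.1), "alpha")
})

test_that("generate_led_set interpolates across distinct clusters", {
  g <- short_grid(4)
  cubes <- lapply(1:6, function(i)
    random_cube(3, 3, g, lo = i, hi = i + 0.1, role = "white_reference",
                seed = i))
  lib <- cluster_library(cubes, K = 3, seed = 2)
  expect_length(generate_led_set(lib, 0, seed = 1), 0)

  out <- generate_led_set(lib, 12, seed = 4)
  parents <- attr(out, "parents")
  for (k in seq_along(out)) {
    # distinct parent clusters
    expect_true(lib$labels[parents$i[k]] != lib$labels[parents$j[k]])
    # spatial mean lies in the convex hull of the parents' spatial means
    mi <- spatial_mean_spectrum(lib$white_refs[[parents$i[k]]])
    mj <- spatial_mean_spectrum(lib$white_refs[[parents$j[k]]])
    mo <- spatial_mean_spectrum(out[[k]])
    expect_true(all(mo >= pmin(mi, mj) - 1e-12 & mo <= pmax(mi, mj) + 1e-12))
  }
  out2 <- generate_led_set(lib, 12, seed = 4)
  expect_identical(lapply(out, `[[`, "values"), lapply(out2, `[[`, "values"))

  one_cluster <- new_lib <- lib
  one_cluster$labels <- rep(1L, length(lib$labels))
  expect_error(generate_led_set(one_cluster, 2), "single cluster")
})

test_that("generate_halogen_set composes fit, sampling and spatialization", {
  g <- default_grid()
  cubes <- make_illumination_cubes(8, g, 8, 8, seed = 21)
  lib <- cluster_library(cubes, K = 4, seed = 1)

  # point intervals: the simulated mean spectrum equals the parametric
  # spectrum at the library-mean parameters
  hs0 <- generate_halogen_set(lib, n_sigma = 0, count_sim = 1,
                              count_interp = 0, seed = 2)
  mu <- attr(hs0, "fit_stats")$mu
  f_mu <- parametric_spectrum(spectrum_params(mu[1], mu[2], mu[3], mu[4]), g)
  expect_equal(spatial_mean_spectrum(hs0[[1]]), f_mu, tolerance = 1e-9)

  hs <- generate_halogen_set(lib, n_sigma = 0.25, count_sim = 6,
                             count_interp = 4, seed = 3)
  expect_length(hs, 10)
  expect_identical(attr(hs, "provenance"),
                   c(rep("simulated", 6), rep("interpolated", 4)))
  for (w in hs) {
    expect_true(all(is.finite(w$values)) && all(w$values > 0))
    expect_identical(w$role, "white_reference")
  }
  hs2 <- generate_halogen_set(lib, n_sigma = 0.25, count_sim = 6,
                              count_interp = 4, seed = 3)
  expect_identical(lapply(hs, `[[`, "values"), lapply(hs2, `[[`, "values"))
})
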