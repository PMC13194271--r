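test_that("spectral cosine similarity has its metric properties", {
  g <- short_grid(2)
  a <- pixel_cube(c(1, 0), g)
  b <- pixel_cube(c(0, 1), g)
  expect_equal(as.numeric(spectral_cosine_similarity(a, b)), 0)

  r <- random_cube(5, 5, g, seed = 1)
  r3 <- hypercube(3 * r$values, g)
  expect_equal(as.numeric(spectral_cosine_similarity(r, r3)), 1,
               tolerance = 1e-12)

  # two-pixel hand computation: cos = 1 and 1/sqrt(2), mean ~ 0.8536
  p1 <- c(1, 0); p2 <- c(1, 0)
  q1 <- c(1, 0); q2 <- c(1, 1)
  ca <- hypercube(array(c(p1[1], q1[1], p1[2], q1[2]), c(2, 1, 2)), g)
  cb <- hypercube(array(c(p2[1], q2[1], p2[2], q2[2]), c(2, 1, 2)), g)
  expect_equal(as.numeric(spectral_cosine_similarity(ca, cb)),
               (1 + 1 / sqrt(2)) / 2, tolerance = 1e-12)

  # zero-spectrum pixels are excluded and counted
  cz <- hypercube(array(c(1, 0, 1, 0), c(2, 1, 2)), g)
  sim <- spectral_cosine_similarity(cz, cz)
  expect_equal(as.numeric(sim), 1)
  expect_identical(attr(sim, "n_excluded"), 1L)
  zeros <- hypercube(array(0, c(1, 1, 2)), g)
  expect_error(spectral_cosine_similarity(zeros, zeros), "all pixel spectra")
})

test_that("spatial_std is the channel-averaged population deviation", {
  g <- short_grid(2)
  expect_equal(spatial_std(hypercube(array(2, c(3, 3, 2)), g)), 0)
  # 2 x 1 pixels with values (1, 3): population sd = 1
  one_channel <- hypercube(array(c(1, 3, 1, 3), c(2, 1, 2)), g)
  expect_equal(spatial_std(one_channel), 1)
  # invariant under adding a per-channel constant
  r <- random_cube(4, 4, g, seed = 2)
  shifted <- hypercube(sweep(r$values, 3, c(5, 9), `+`), g)
  expect_equal(spatial_std(shifted), spatial_std(r), tolerance = 1e-12)
})

test_that("gray world recovers a uniform illuminant on an achromatic scene", {
  g <- short_grid(8)
  L <- seq(2, 0.5, length.out = 8)
  gray <- hypercube(array(0.5, c(10, 10, 8)), g, role = "calibrated")
  scene <- relight(gray, constant_cube(L, 10, 10, g))
  est <- gray_world_illuminant(scene)
  cosv <- sum(est * L) / sqrt(sum(est^2) * sum(L^2))
  expect_gte(cosv, 0.999)

  s <- c(1, 2, 4, 2, 1, 1, 2, 3)
  const <- constant_cube(s, 3, 3, g, role = "raw")
  expect_equal(gray_world_illuminant(const), s / mean(s))
  expect_equal(gray_world_illuminant(hypercube(7 * const$values, g)),
               gray_world_illuminant(const))
})

test_that("max-channel recovers the illuminant from a perfect reflector", {
  g <- short_grid(5)
  L <- c(1, 2, 3, 2, 1)
  set.seed(3)
  refl <- array(runif(6 * 6 * 5, 0.1, 0.8), c(6, 6, 5))
  refl[3, 4, ] <- 1   # perfect reflector pixel
  scene <- relight(hypercube(refl, g, role = "calibrated"),
                   constant_cube(L, 6, 6, g))
  est <- max_channel_illuminant(scene)
  expect_equal(est, L / mean(L), tolerance = 1e-12)

  # brightening a single pixel never decreases any channel estimate
  brighter <- scene$values
  brighter[1, 1, ] <- brighter[1, 1, ] * 3
  est2 <- max_channel_illuminant(hypercube(brighter, g))
  d <- dim(scene$values)
  raw_max1 <- apply(matrix(scene$values, d[1] * d[2], d[3]), 2, max)
  raw_max2 <- apply(matrix(brighter, d[1] * d[2], d[3]), 2, max)
  expect_true(all(raw_max2 >= raw_max1))
})

test_that("gray edge concentrates on edges and flags degenerate scenes", {
  g <- short_grid(4)
  # constant cube: flagged uniform estimate instead of division by zero
  const <- constant_cube(c(1, 2, 3, 4), 8, 8, g, role = "raw")
  est <- gray_edge_illuminant(const)
  expect_true(isTRUE(attr(est, "degenerate")))
  expect_equal(as.numeric(est), rep(1, 4))

  # single vertical step edge with per-channel heights h_c (p = 1, no
  # smoothing): estimate proportional to h_c
  h <- c(0.2, 0.5, 1, 2)
  vals <- array(0.5, c(10, 10, 4))
  for (c in 1:4) vals[, 6:10, c] <- 0.5 + h[c]
  step <- hypercube(vals, g)
  est2 <- gray_edge_illuminant(step, minkowski_p = 1, smoothing_sigma = 0)
  expect_equal(as.numeric(est2), h / mean(h), tolerance = 1e-12)

  expect_equal(as.numeric(gray_edge_illuminant(hypercube(5 * vals, g),
                                               minkowski_p = 1,
                                               smoothing_sigma = 0)),
               as.numeric(est2), tolerance = 1e-12)
  expect_error(gray_edge_illuminant(step, minkowski_p = 0.5), "minkowski_p")
})

test_that("calibrate_uniform divides by one spectrum everywhere", {
  g <- short_grid(3)
  r <- random_cube(4, 4, g, seed = 4)
  expect_equal(calibrate_uniform(r, c(1, 1, 1))$values, r$values)
  L <- c(2, 1, 0.5)
  scene <- relight(hypercube(r$values, g, role = "calibrated"),
                   constant_cube(L, 4, 4, g))
  back <- calibrate_uniform(scene, L, floor = 1e-9)
  expect_equal(back$values, r$values, tolerance = 1e-9)
  expect_error(calibrate_uniform(r, c(1, 1)), "does not match")
})

test_that("the uniformity study reproduces the non-uniformity trend", {
  g <- default_grid()
  suite <- make_scenario_suite(g, 16, 16, seed = 1)
  samples <- lapply(1:4, function(i) make_tissue_cube(16, 16, g, seed = i)$cube)
  rep <- uniformity_study(samples, suite, seed = 2, n_boot = 200)
  df <- as.data.frame(rep)

  none <- df[df$scenario == "none", ]
  expect_true(all(abs(none$mean_cosine - 1) < 1e-9))

  res <- df[df$method == "resolved", ]
  expect_true(all(res$mean_cosine >= 0.9999))

  uni <- df[df$method == "uniform" & df$scenario != "none", ]
  uni <- uni[order(uni$scenario_spatial_std), ]
  expect_identical(
    stats::cor(uni$scenario_spatial_std, uni$mean_cosine,
               method = "spearman"), -1)
  # resolved >= uniform per scenario
  for (sc in unique(df$scenario)) {
    expect_gte(df$mean_cosine[df$scenario == sc & df$method == "resolved"],
               df$mean_cosine[df$scenario == sc & df$method == "uniform"])
  }
})

test_that("latent PCA density separates groups and flags degeneracy", {
  same <- matrix(1, 6, 8)
  out <- latent_pca_density(same, rep(c("a", "b"), 3))
  expect_true(out$degenerate)

  set.seed(5)
  g1 <- matrix(rnorm(40, mean = 0, sd = 0.1), 20, 2)
  g2 <- matrix(rnorm(40, mean = 8, sd = 0.1), 20, 2)
  res <- latent_pca_density(rbind(g1, g2), rep(c("a", "b"), each = 20))
  expect_false(res$degenerate)
  # centering: the overall score mean projects to the origin
  expect_equal(colMeans(res$scores), c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  cen_a <- colMeans(res$scores[res$groups == "a", ])
  cen_b <- colMeans(res$scores[res$groups == "b", ])
  spread <- max(apply(res$scores[res$groups == "a", ], 2, stats::sd),
                apply(res$scores[res$groups == "b", ], 2, stats::sd))
  expect_gt(sqrt(sum((cen_a - cen_b)^2)), 5 * spread)
  expect_false(is.null(res$densities$a))
  expect_error(latent_pca_density(matrix(1, 2, 3), c("a", "b")), "at least 3")
})

test_that("benchmarks rank the resolved oracle first and reproduce exactly", {
  g <- default_grid()
  suite <- make_scenario_suite(g, 12, 12, seed = 3)
  samples <- lapply(1:3, function(i) make_tissue_cube(12, 12, g, seed = i)$cube)
  methods <- c("none", "gray_world", "max_channel", "gray_edge",
               "uniform_oracle", "resolved_oracle")
  rep1 <- benchmark_methods(methods, samples, suite, seed = 4, n_boot = 200)
  df <- as.data.frame(rep1)
  for (sc in unique(df$scenario)) {
    sub <- df[df$scenario == sc, ]
    oracle <- sub$mean_cosine[sub$method == "resolved_oracle"]
    expect_true(all(oracle >= sub$mean_cosine - 1e-12))
  }
  # oracle dominance chain: resolved >= uniform oracle >= best baseline
  for (sc in unique(df$scenario)) {
    sub <- df[df$scenario == sc, ]
    expect_gte(sub$mean_cosine[sub$method == "resolved_oracle"] + 1e-12,
               sub$mean_cosine[sub$method == "uniform_oracle"])
    best_baseline <- max(sub$mean_cosine[sub$method %in%
                           c("gray_world", "max_channel", "gray_edge")])
    expect_gte(sub$mean_cosine[sub$method == "uniform_oracle"] + 1e-9,
               best_baseline)
  }
  rep2 <- benchmark_methods(methods, samples, suite, seed = 4, n_boot = 200)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
  expect_error(benchmark_methods("nonsense", samples, suite), "unknown method")
})

test_that("no recalibration scores perfectly only without stray light", {
  g <- short_grid(6)
  # unit camera spectrum, no stray light: raw == sample, so method "none"
  # (divide by ones) is exact
  ones_white <- constant_cube(rep(1, 6), 8, 8, g)
  suite <- list(none = list(spec = scenario_spec("none", "none", 0),
                            white = ones_white))
  samples <- lapply(1:2, function(i)
    make_tissue_cube(8, 8, g, n_classes = 2, seed = i)$cube)
  rep <- benchmark_methods("none", samples, suite, seed = 1, n_boot = 100)
  expect_equal(rep$mean_cosine, 1, tolerance = 1e-12)
})
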