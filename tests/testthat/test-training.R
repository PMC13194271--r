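tiny_train_setup <- function(n_samples = 4, n_illums = 3, H = 10, W = 10,
                             C = 12) {
  g <- short_grid(C)
  list(grid = g,
       samples = lapply(seq_len(n_samples), function(i)
         make_tissue_cube(H, W, g, n_classes = 2, seed = i)$cube),
       illums = make_illumination_cubes(n_illums, g, H, W, seed = 50))
}

test_that("training pairs are relit samples with the white as target", {
  g <- short_grid(4)
  ones <- hypercube(array(1, c(2, 2, 4)), g, role = "calibrated")
  w <- random_cube(2, 2, g, lo = 0.5, hi = 2, role = "white_reference",
                   seed = 1)
  pair <- make_training_pair(ones, w)
  expect_equal(pair$input$values, w$values)

  s <- pixel_cube(c(0.5, 2, 1, 1), g, role = "calibrated")
  w2 <- pixel_cube(c(2, 2, 1, 1), g, role = "white_reference")
  pair2 <- make_training_pair(s, w2)
  expect_equal(as.vector(pair2$input$values)[1:2], c(1, 4))
  # round trip: calibrating the input by the target recovers the sample
  back <- calibrate(pair2$input, pair2$target, floor = 1e-9)
  expect_equal(back$values, s$values, tolerance = 1e-12)
  expect_error(make_training_pair(ones, w2), "shape mismatch")
})

test_that("white-reference MSE matches its closed forms", {
  g <- short_grid(2)
  a <- pixel_cube(c(1, 2), g)
  b <- pixel_cube(c(3, 2), g)
  expect_equal(loss_white_mse(a, a), 0)
  expect_equal(loss_white_mse(a, b), 2)      # ((1-3)^2 + 0) / 2
  r <- random_cube(4, 4, g, seed = 2)
  shifted <- hypercube(r$values + 0.3, g)
  expect_equal(loss_white_mse(r, shifted), 0.09, tolerance = 1e-12)
  expect_error(loss_white_mse(a, random_cube(2, 2, g)), "shape mismatch")
})

test_that("train_config validates and the lr schedule is exponential", {
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(decay_factor = 0), "decay_factor")
  expect_error(train_config(batch_size = 0), "batch_size")

  setup <- tiny_train_setup()
  model <- build_model(tiny_config(), seed = 1)
  fit <- train_whiteref(setup$samples, setup$illums, model = model,
                        config = train_config(epochs = 3, steps_per_epoch = 2,
                                              batch_size = 1, seed = 2,
                                              decay_factor = 0.9,
                                              n_val_pairs = 2))
  h <- fit$history
  expect_equal(h$lr[-1], 1e-3 * 0.9^(0:2))
  expect_true(all(is.finite(h$train_loss[-1])))

  # decay_factor = 1: constant learning rate
  fit2 <- train_whiteref(setup$samples, setup$illums,
                         model = build_model(tiny_config(), seed = 1),
                         config = train_config(epochs = 3, steps_per_epoch = 2,
                                               batch_size = 1, seed = 2,
                                               decay_factor = 1,
                                               n_val_pairs = 2))
  expect_equal(unique(fit2$history$lr[-1]), 1e-3)
})

test_that("training is seeded-deterministic and does not mutate inputs", {
  setup <- tiny_train_setup()
  before <- lapply(setup$samples, `[[`, "values")
  cfg <- train_config(epochs = 2, steps_per_epoch = 3, batch_size = 1,
                      seed = 7, n_val_pairs = 2)
  f1 <- train_whiteref(setup$samples, setup$illums,
                       model = build_model(tiny_config(), seed = 4),
                       config = cfg)
  f2 <- train_whiteref(setup$samples, setup$illums,
                       model = build_model(tiny_config(), seed = 4),
                       config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
  expect_identical(lapply(setup$samples, `[[`, "values"), before)
  expect_true(f1$trained)
  expect_identical(f1$grid, setup$grid)

  expect_error(train_whiteref(list(), setup$illums), "non-empty")
  expect_error(train_whiteref(setup$samples, list()), "non-empty")
})

test_that("the pairing schedule covers the sample x illumination product", {
  setup <- tiny_train_setup(n_samples = 3, n_illums = 2, H = 6, W = 6, C = 8)
  fit <- train_whiteref(setup$samples, setup$illums,
                        model = build_model(tiny_config(), seed = 1),
                        config = train_config(epochs = 10, steps_per_epoch = 8,
                                              batch_size = 1, seed = 3,
                                              val_fraction = 0,
                                              n_val_pairs = 0))
  # at small scale every (sample, illumination) pair gets drawn
  expect_true(all(fit$pair_counts > 0))
})

test_that("validation scoring behaves as an oracle-bounded metric", {
  setup <- tiny_train_setup(n_samples = 3, n_illums = 2, H = 8, W = 8, C = 10)
  v_oracle <- validate_model("resolved_oracle", setup$samples, setup$illums,
                             n_pairs = 6, seed = 1, n_boot = 200)
  expect_equal(v_oracle$mean, 1, tolerance = 1e-9)
  v_ones <- validate_model("none", setup$samples, setup$illums,
                           n_pairs = 6, seed = 1, n_boot = 200)
  expect_lte(v_ones$mean, v_oracle$mean)
  # bootstrap interval contains the point estimate
  expect_gte(v_ones$mean, v_ones$ci[1])
  expect_lte(v_ones$mean, v_ones$ci[2])
  # a function can serve as the predictor
  v_fun <- validate_model(function(raw) {
    d <- dim(raw$values)
    hypercube(array(1, d), raw$wavelengths, role = "white_reference")
  }, setup$samples, setup$illums, n_pairs = 6, seed = 1, n_boot = 200)
  expect_equal(v_fun$mean, v_ones$mean)
})

test_that("model S3 methods print, plot and expose coefficients", {
  setup <- tiny_train_setup()
  fit <- train_whiteref(setup$samples, setup$illums,
                        model = build_model(tiny_config(), seed = 4),
                        config = train_config(epochs = 1, steps_per_epoch = 2,
                                              batch_size = 1, seed = 7,
                                              n_val_pairs = 2))
  expect_output(print(fit), "whiteref_model")
  expect_output(summary(fit), "val MSE")
  expect_identical(length(coef(fit)), count_parameters(fit))
  pw <- predict(fit, setup$samples[[1]])
  expect_identical(pw$role, "white_reference")
  pc <- predict(fit, setup$samples[[1]], type = "calibrated")
  expect_identical(pc$role, "calibrated")
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  expect_silent(plot(fit))
  grDevices::dev.off()
  unlink(f)
})
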