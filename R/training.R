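# Two-dataset relighting-augmentation training: every step pairs a
# randomly drawn calibrated sample cube with a randomly drawn illumination
# cube, multiplies them into a synthetic raw input, and optimizes the
# mean-squared error between the predicted and the true white reference
# (never the calibrated sample), so the model learns illumination rather
# than tissue geometry. Optimization is Adam with an exponentially
# decaying learning rate (lr_e = lr0 * decay^e).

#' Training configuration
#'
#' @param learning_rate Initial Adam learning rate.
#' @param decay_factor Per-epoch exponential decay of the learning rate,
#'   in `(0, 1]`.
#' @param batch_size Pairs per optimization step.
#' @param epochs Number of epochs.
#' @param steps_per_epoch Steps per epoch; defaults to the number of
#'   training samples.
#' @param max_steps Optional hard cap on total optimization steps.
#' @param val_fraction Fraction of sample cubes held out (split by sample;
#'   illuminations are shared across splits).
#' @param n_val_pairs Fixed validation pairings evaluated each epoch.
#' @param seed RNG seed governing pairing, splits and shuffling.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param clip_norm Global gradient-norm clip applied before each Adam
#'   step; `Inf` disables clipping.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, decay_factor = 0.97,
                         batch_size = 4L, epochs = 10L,
                         steps_per_epoch = NULL, max_steps = NULL,
                         val_fraction = 0.25, n_val_pairs = 8L, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         clip_norm = 1) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (decay_factor <= 0 || decay_factor > 1)
    stop("decay_factor must be in (0, 1]")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (val_fraction < 0 || val_fraction >= 1)
    stop("val_fraction must be in [0, 1)")
  structure(list(learning_rate = learning_rate, decay_factor = decay_factor,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 steps_per_epoch = steps_per_epoch, max_steps = max_steps,
                 val_fraction = val_fraction,
                 n_val_pairs = as.integer(n_val_pairs),
                 seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, clip_norm = clip_norm),
            class = "train_config")
}

#' Build one training pair by relighting
#'
#' @param sample Calibrated [hypercube].
#' @param white White-reference [hypercube] of matching geometry.
#' @return Object of class `training_pair` with fields `input`
#'   (= `relight(sample, white)`), `target` (= `white`) and provenance ids.
#' @export
make_training_pair <- function(sample, white) {
  input <- relight(sample, white)
  structure(list(input = input, target = white,
                 sample_id = sample$metadata$id,
                 illumination_id = white$metadata$id),
            class = "training_pair")
}

#' Mean-squared error between two cubes
#'
#' Mean over all `H*W*C` elements of the squared difference; the training
#' loss, computed on the predicted white reference.
#'
#' @param predicted,target [hypercube]s (or numeric arrays) of equal shape.
#' @return Nonnegative scalar, zero iff the cubes are equal.
#' @export
loss_white_mse <- function(predicted, target) {
  a <- if (is_hypercube(predicted)) predicted$values else predicted
  b <- if (is_hypercube(target)) target$values else target
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch between predicted and target")
  mean((a - b)^2)
}

# -- parameter tree <-> flat vector -----------------------------------------

conv_paths <- function(layers) {
  paths <- list(list("input"))
  for (i in seq_along(layers$enc)) {
    paths <- c(paths, list(list("enc", i, "conv1"), list("enc", i, "conv2")))
    if (!is.null(layers$enc[[i]]$proj))
      paths <- c(paths, list(list("enc", i, "proj")))
  }
  for (j in seq_along(layers$dec)) {
    paths <- c(paths, list(list("dec", j, "conv1"), list("dec", j, "conv2")))
    if (!is.null(layers$dec[[j]]$proj))
      paths <- c(paths, list(list("dec", j, "proj")))
  }
  c(paths, list(list("out")))
}

pluck <- function(tree, path) {
  for (p in path) tree <- tree[[p]]
  tree
}

poke <- function(tree, path, value) {
  if (length(path) == 1L) {
    tree[[path[[1]]]] <- value
    return(tree)
  }
  tree[[path[[1]]]] <- poke(tree[[path[[1]]]], path[-1], value)
  tree
}

flatten_wb <- function(tree, paths) {
  unlist(lapply(paths, function(p) {
    node <- pluck(tree, p)
    c(as.vector(node$W), node$b)
  }), use.names = FALSE)
}

unflatten_wb <- function(layers, paths, flat) {
  pos <- 0L
  for (p in paths) {
    node <- pluck(layers, p)
    nw <- length(node$W); nb <- length(node$b)
    node$W <- matrix(flat[pos + seq_len(nw)], nrow(node$W), ncol(node$W))
    node$b <- flat[pos + nw + seq_len(nb)]
    layers <- poke(layers, p, node)
    pos <- pos + nw + nb
  }
  layers
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Loss and gradient for one (sample, white) pairing.
pair_loss_grad <- function(model, sample, white, grad = TRUE) {
  input <- sample$values * white$values
  m <- if (model$config$normalize) mean(input) else 1
  if (m <= 0) m <- 1
  vol <- cube_to_volume(input / m)
  target <- if (model$config$mode == "uniform") {
    matrix(spatial_mean_spectrum(white) / m, ncol = 1L)
  } else {
    cube_to_volume(white$values / m)$x
  }
  fw <- forward_model(model, vol, train = grad)
  pred <- softplus(fw$z)
  diff <- pred - target
  loss <- mean(diff^2)
  if (!grad) return(list(loss = loss))
  dZ <- (2 / length(diff)) * diff * sigmoid(fw$z)
  list(loss = loss, grads = backward_model(model, fw$caches, dZ))
}

#' Fit the white-reference predictor
#'
#' Trains a [build_model()] network on calibrated sample cubes and
#' illumination (white-reference) cubes using the relighting augmentation:
#' every optimization step draws fresh random (sample, illumination)
#' pairings, so the augmentation space is the full product set. The
#' validation split is by sample id; illuminations are shared. In
#' `"uniform"` mode the target is the spatially averaged white spectrum.
#'
#' @param samples Non-empty list of calibrated [hypercube]s on one grid.
#' @param illuminations Non-empty list of white-reference [hypercube]s on
#'   the same grid.
#' @param model A `whiteref_model` from [build_model()]; defaults to a
#'   smoke-scale resolved model.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return The trained `whiteref_model`; `model$history` is a data frame
#'   (epoch, lr, train_loss, val_loss) with epoch 0 recording the
#'   pre-training validation loss.
#' @export
train_whiteref <- function(samples, illuminations,
                           model = build_model(
                             model_config(channels = smoke_channels())),
                           config = train_config(), verbose = FALSE) {
  if (!is.list(samples) || !length(samples)) stop("samples must be non-empty")
  if (!is.list(illuminations) || !length(illuminations))
    stop("illuminations must be non-empty")
  lapply(samples, stop_if_not_cube, arg = "samples element")
  lapply(illuminations, stop_if_not_cube, arg = "illuminations element")
  for (s in samples) check_same_geometry(samples[[1]], s)
  for (w in illuminations) check_same_geometry(samples[[1]], w)
  if (!inherits(config, "train_config")) stop("config must be a train_config")

  with_seed(config$seed, {
    n <- length(samples)
    n_val <- if (config$val_fraction > 0 && n > 1L)
      max(1L, round(config$val_fraction * n)) else 0L
    val_ids <- if (n_val > 0L) sort(sample.int(n, n_val)) else integer(0)
    train_ids <- setdiff(seq_len(n), val_ids)
    if (!length(train_ids)) stop("no training samples left after split")

    # fixed seeded validation pairings, re-evaluated every epoch
    val_pairs <- if (n_val > 0L) {
      k <- config$n_val_pairs
      data.frame(s = val_ids[((seq_len(k) - 1L) %% n_val) + 1L],
                 w = sample.int(length(illuminations), k, replace = TRUE))
    } else NULL

    val_loss <- function() {
      if (is.null(val_pairs)) return(NA_real_)
      mean(vapply(seq_len(nrow(val_pairs)), function(r)
        pair_loss_grad(model, samples[[val_pairs$s[r]]],
                       illuminations[[val_pairs$w[r]]], grad = FALSE)$loss,
        numeric(1)))
    }

    paths <- conv_paths(model$layers)
    theta <- flatten_wb(model$layers, paths)
    m1 <- numeric(length(theta)); m2 <- numeric(length(theta))
    t_step <- 0L
    steps_per_epoch <- if (is.null(config$steps_per_epoch))
      length(train_ids) else as.integer(config$steps_per_epoch)

    pair_counts <- matrix(0L, n, length(illuminations))
    history <- data.frame(epoch = 0L, lr = NA_real_, train_loss = NA_real_,
                          val_loss = val_loss())
    if (verbose)
      cat(sprintf("epoch 0: val_loss %.5f\n", history$val_loss[1]))

    done <- FALSE
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate * config$decay_factor^(epoch - 1L)
      epoch_losses <- numeric(0)
      for (step in seq_len(steps_per_epoch)) {
        gsum <- NULL; lsum <- 0
        for (b in seq_len(config$batch_size)) {
          si <- train_ids[sample.int(length(train_ids), 1L)]
          wi <- sample.int(length(illuminations), 1L)
          pair_counts[si, wi] <- pair_counts[si, wi] + 1L
          lg <- pair_loss_grad(model, samples[[si]], illuminations[[wi]])
          if (!is.finite(lg$loss))
            stop(sprintf("non-finite training loss at epoch %d step %d (sample %d, illumination %d)",
                         epoch, step, si, wi))
          g <- flatten_wb(lg$grads, paths)
          gsum <- if (is.null(gsum)) g else gsum + g
          lsum <- lsum + lg$loss
        }
        g <- gsum / config$batch_size
        gn <- sqrt(sum(g^2))
        if (is.finite(config$clip_norm) && gn > config$clip_norm)
          g <- g * (config$clip_norm / gn)
        epoch_losses <- c(epoch_losses, lsum / config$batch_size)
        t_step <- t_step + 1L
        m1 <- config$beta1 * m1 + (1 - config$beta1) * g
        m2 <- config$beta2 * m2 + (1 - config$beta2) * g^2
        mhat <- m1 / (1 - config$beta1^t_step)
        vhat <- m2 / (1 - config$beta2^t_step)
        theta <- theta - lr * mhat / (sqrt(vhat) + config$adam_eps)
        model$layers <- unflatten_wb(model$layers, paths, theta)
        if (!is.null(config$max_steps) && t_step >= config$max_steps) {
          done <- TRUE
          break
        }
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, lr = lr,
                                  train_loss = mean(epoch_losses),
                                  val_loss = val_loss()))
      if (verbose)
        cat(sprintf("epoch %d: lr %.2e train %.5f val %.5f\n", epoch, lr,
                    mean(epoch_losses), history$val_loss[nrow(history)]))
      if (done) break
    }

    model$trained <- TRUE
    model$grid <- samples[[1]]$wavelengths
    model$history <- history
    model$val_ids <- val_ids
    model$pair_counts <- pair_counts
    model
  })
}

#' Validate a calibration method on sample x illumination pairings
#'
#' For a seeded subset of (sample, illumination) pairings: relight the
#' sample, predict a white reference with the supplied method, recalibrate,
#' and score against the original sample with spectral cosine similarity.
#'
#' @param method A trained `whiteref_model`, a function `raw -> white`
#'   [hypercube], or one of the method tags accepted by
#'   [benchmark_methods()] (`"resolved_oracle"`, `"uniform_oracle"`,
#'   `"none"`, `"gray_world"`, `"max_channel"`, `"gray_edge"`).
#' @param samples List of calibrated [hypercube]s.
#' @param illuminations List of white-reference [hypercube]s.
#' @param n_pairs Number of pairings scored (default: up to 32).
#' @param floor Division floor for [calibrate()].
#' @param seed RNG seed (pair subset and bootstrap).
#' @param n_boot Bootstrap resamples for the 95% percentile interval.
#' @return List with `mean`, `ci` (length-2), `scores`, `n`.
#' @export
validate_model <- function(method, samples, illuminations, n_pairs = 32L,
                           floor = NULL, seed = 1L, n_boot = 1000L) {
  if (!length(samples) || !length(illuminations))
    stop("samples and illuminations must be non-empty")
  with_seed(seed, {
    combos <- expand.grid(s = seq_along(samples),
                          w = seq_along(illuminations))
    if (nrow(combos) > n_pairs)
      combos <- combos[sample.int(nrow(combos), n_pairs), ]
    scores <- vapply(seq_len(nrow(combos)), function(r) {
      sample_cube <- samples[[combos$s[r]]]
      white <- illuminations[[combos$w[r]]]
      input <- relight(sample_cube, white)
      what <- predict_white_for(method, input, white)
      recal <- calibrate(input, what, floor = floor)
      spectral_cosine_similarity(recal, sample_cube)
    }, numeric(1))
    ci <- bootstrap_ci(scores, n_boot)
    list(mean = mean(scores), ci = ci, scores = scores, n = length(scores))
  })
}

bootstrap_ci <- function(x, n_boot = 1000L, level = 0.95) {
  if (length(x) == 1L) return(c(x, x))
  means <- vapply(seq_len(n_boot), function(i)
    mean(x[sample.int(length(x), replace = TRUE)]), numeric(1))
  alpha <- (1 - level) / 2
  unname(stats::quantile(means, c(alpha, 1 - alpha)))
}

# -- S3 methods for the fitted model ----------------------------------------

#' @export
print.whiteref_model <- function(x, ...) {
  cat(sprintf("<whiteref_model> %s mode, %s parameters, %s\n",
              x$config$mode,
              format(count_parameters(x), big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  print(x$config)
  invisible(x)
}

#' @export
summary.whiteref_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("training: %d epochs, final train MSE %.5g, final val MSE %.5g\n",
                max(h$epoch), h$train_loss[nrow(h)], h$val_loss[nrow(h)]))
    cat(sprintf("initial val MSE %.5g\n", h$val_loss[1]))
  }
  invisible(object)
}

#' Predict method for white-reference models
#'
#' @param object A `whiteref_model`.
#' @param newdata A raw [hypercube].
#' @param type `"white"` for the predicted white-reference cube,
#'   `"calibrated"` for the recalibrated input.
#' @param floor Division floor for `type = "calibrated"`.
#' @param ... Unused.
#' @export
predict.whiteref_model <- function(object, newdata,
                                   type = c("white", "calibrated"),
                                   floor = NULL, ...) {
  type <- match.arg(type)
  if (type == "white") predict_white_reference(object, newdata)
  else recalibrate(object, newdata, floor = floor)
}

#' @export
coef.whiteref_model <- function(object, ...) {
  paths <- conv_paths(object$layers)
  flatten_wb(object$layers, paths)
}

#' @export
plot.whiteref_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::plot(h$epoch, h$val_loss, type = "b", col = "firebrick",
                 xlab = "epoch", ylab = "MSE",
                 ylim = range(c(h$val_loss, h$train_loss), na.rm = TRUE),
                 main = "white-reference MSE", ...)
  graphics::lines(h$epoch[-1], h$train_loss[-1], type = "b",
                  col = "steelblue")
  graphics::legend("topright", legend = c("validation", "train"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}
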