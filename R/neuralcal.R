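# The white-reference predictor: a 3D convolutional encoder-decoder
# without skip connections. The cube is treated as a one-feature volume
# with axes (spectral, row, column); feature maps are (n_voxels x
# n_features) matrices with the spectral axis fastest. The encoder grows
# the feature dimension from 32 to a 256-dimensional latent space across
# nine pre-activation ResNet blocks, down-sampling by strided convolution
# (stride 2, all three axes) at every third block. The decoder mirrors the
# encoder, restoring resolution by trilinear interpolation to the recorded
# encoder extents; U-Net-style encoder-decoder skip connections are
# deliberately omitted so all information flows through the bottleneck and
# geometric sample detail cannot leak into the predicted illumination.
# A softplus output enforces positivity.

#' Reference and smoke-scale channel progressions
#'
#' `reference_channels()` is the documented nine-block encoder progression
#' (32-32-32 / 64-64-64 / 128-256-256) whose mirrored decoder yields
#' 13.68 million trainable parameters. `smoke_channels()` is a scaled-down
#' progression (about 0.52 million parameters) used for CPU-scale training
#' runs.
#'
#' @return Integer vector of nine per-block output feature counts.
#' @export
reference_channels <- function() c(32L, 32L, 32L, 64L, 64L, 64L, 128L, 256L, 256L)

#' @rdname reference_channels
#' @export
smoke_channels <- function() c(8L, 8L, 8L, 16L, 16L, 16L, 32L, 32L, 64L)

#' Model architecture configuration
#'
#' @param mode `"resolved"` predicts a spatially resolved white-reference
#'   cube; `"uniform"` is the ablation variant that pools the latent space
#'   over the spatial axes and decodes with 1D convolutional blocks along
#'   the spectral axis, producing a spatially constant prediction.
#' @param channels Encoder per-block output feature counts (length >=
#'   `downsample_every`, non-decreasing). The decoder mirrors them.
#' @param input_kernel Kernel of the input layer as (spectral, row,
#'   column); the default widens the spectral receptive field at entry.
#' @param kernel Odd kernel extent of all other convolutions (realized as
#'   `kernel^3` volumetric kernels).
#' @param downsample_every Strided down-sampling at every this-many-th
#'   encoder block.
#' @param normalize Divide each input cube by its global mean before the
#'   network and scale the prediction back, applied identically at
#'   training and inference.
#' @return Object of class `model_config`.
#' @export
model_config <- function(mode = c("resolved", "uniform"),
                         channels = reference_channels(),
                         input_kernel = c(7L, 3L, 3L), kernel = 3L,
                         downsample_every = 3L, normalize = TRUE) {
  mode <- match.arg(mode)
  channels <- as.integer(channels)
  if (length(channels) < downsample_every)
    stop("need at least downsample_every encoder blocks")
  if (any(diff(channels) < 0))
    stop("channel progression must be non-decreasing")
  if (any(c(input_kernel, kernel) %% 2L == 0L))
    stop("kernel extents must be odd")
  structure(list(mode = mode, channels = channels,
                 latent_features = channels[length(channels)],
                 input_kernel = as.integer(input_kernel),
                 kernel = as.integer(kernel),
                 downsample_every = as.integer(downsample_every),
                 upsample = "trilinear", normalize = isTRUE(normalize)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> mode: %s, %d encoder blocks (%s), latent %d\n",
              x$mode, length(x$channels),
              paste(x$channels, collapse = "-"), x$latent_features))
  invisible(x)
}

new_conv <- function(cin, cout, kernel, stride = 1L, init_scale = 1) {
  fan_in <- cin * prod(kernel)
  list(W = matrix(stats::rnorm(fan_in * cout,
                               sd = init_scale * sqrt(2 / fan_in)),
                  fan_in, cout),
       b = numeric(cout),
       kernel = as.integer(kernel), stride = as.integer(stride),
       pad = as.integer((kernel - 1L) / 2L), cin = cin, cout = cout)
}

# Pre-activation residual block. The second convolution is initialized at a
# reduced scale so each block starts close to the identity; without this,
# activation variance compounds across the 18 residual blocks and the
# untrained network saturates its output activation.
new_block <- function(cin, cout, kernel3, stride, n_blocks_total = 18L) {
  proj <- if (cin != cout || stride != 1L)
    new_conv(cin, cout, c(1L, 1L, 1L), stride) else NULL
  list(conv1 = new_conv(cin, cout, kernel3, stride),
       conv2 = new_conv(cout, cout, kernel3, 1L,
                        init_scale = 1 / sqrt(2 * n_blocks_total)),
       proj = proj, stride = as.integer(stride))
}

#' Build a white-reference predictor
#'
#' Instantiates the 3D convolutional encoder-decoder with seeded (He
#' normal) initialization. The resolved architecture has no encoder-to-
#' decoder skip paths: the decoder sees only the latent bottleneck.
#'
#' @param config A [model_config()].
#' @param seed RNG seed for the initialization.
#' @return An object of class `whiteref_model` (untrained).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  if (!inherits(config, "model_config")) stop("config must be a model_config")
  nb <- length(config$channels)
  k3 <- rep(config$kernel, 3L)
  with_seed(seed, {
    prev <- c(config$channels[1], config$channels[-nb])
    enc <- vector("list", nb)
    for (i in seq_len(nb)) {
      stride <- if (i %% config$downsample_every == 0L) 2L else 1L
      enc[[i]] <- new_block(prev[i], config$channels[i], k3, stride)
    }
    dec_channels <- rev(prev)
    dk <- if (config$mode == "uniform") c(config$kernel, 1L, 1L) else k3
    prev_dec <- c(config$latent_features, dec_channels[-nb])
    dec <- vector("list", nb)
    for (j in seq_len(nb))
      dec[[j]] <- new_block(prev_dec[j], dec_channels[j], dk, 1L)
    # output layer: small weights and a bias at softplus^{-1}(1), so the
    # untrained prediction is ~1 (the scale of a normalized white) and the
    # softplus stays in its responsive range
    out_conv <- new_conv(dec_channels[nb], 1L, dk, 1L, init_scale = 0.05)
    out_conv$b[] <- log(exp(1) - 1)
    layers <- list(
      input = new_conv(1L, config$channels[1], config$input_kernel, 1L),
      enc = enc, dec = dec,
      out = out_conv)
    structure(list(config = config, layers = layers,
                   dec_channels = dec_channels,
                   up_before = which((seq_len(nb) - 1L) %% config$downsample_every == 0L),
                   trained = FALSE, grid = NULL, history = NULL,
                   input_scale = 1),
              class = "whiteref_model")
  })
}

#' Count trainable parameters
#'
#' Exact count of independently optimizable scalars (convolution weights
#' and biases) of a built model.
#'
#' @param model A `whiteref_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  if (!inherits(model, "whiteref_model")) stop("model must be a whiteref_model")
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$W)) n <<- n + length(x$W) + length(x$b)
      for (el in x[setdiff(names(x), c("W", "b"))])
        if (is.list(el)) walk(el)
      if (is.null(names(x))) for (el in x) walk(el)
    }
  }
  walk(model$layers)
  n
}

relu <- function(x) pmax(x, 0)
softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

conv_fwd <- function(conv, x, dims) {
  y <- cpp_conv3d_fwd(x, dims, conv$W, conv$b, conv$kernel, conv$stride,
                      conv$pad)
  list(x = y, dims = attr(y, "out_dims"))
}

conv_bwd <- function(conv, x_in, dims_in, dY, want_dx = TRUE) {
  cpp_conv3d_bwd(x_in, dims_in, dY, conv$W, conv$kernel, conv$stride,
                 conv$pad, want_dx)
}

block_fwd <- function(block, x, dims, keep_cache = FALSE) {
  a1 <- relu(x)
  c1 <- conv_fwd(block$conv1, a1, dims)
  a2 <- relu(c1$x)
  c2 <- conv_fwd(block$conv2, a2, c1$dims)
  if (!is.null(block$proj)) {
    s <- conv_fwd(block$proj, x, dims)$x
  } else {
    s <- x
  }
  out <- s + c2$x
  cache <- if (keep_cache)
    list(x = x, dims = dims, y1 = c1$x, dims1 = c1$dims) else NULL
  list(x = out, dims = c2$dims, cache = cache)
}

block_bwd <- function(block, cache, dOut) {
  a2 <- relu(cache$y1)
  b2 <- conv_bwd(block$conv2, a2, cache$dims1, dOut)
  dY1 <- b2$dX * (cache$y1 > 0)
  a1 <- relu(cache$x)
  b1 <- conv_bwd(block$conv1, a1, cache$dims, dY1)
  dX <- b1$dX * (cache$x > 0)
  grads <- list(conv1 = list(W = b1$dW, b = b1$db),
                conv2 = list(W = b2$dW, b = b2$db))
  if (!is.null(block$proj)) {
    bp <- conv_bwd(block$proj, cache$x, cache$dims, dOut)
    dX <- dX + bp$dX
    grads$proj <- list(W = bp$dW, b = bp$db)
  } else {
    dX <- dX + dOut
  }
  list(dX = dX, grads = grads)
}

# cube (H, W, C) array -> volume matrix (C*H*W x 1) with spectral fastest
cube_to_volume <- function(values) {
  d <- dim(values)
  list(x = matrix(aperm(values, c(3, 1, 2)), ncol = 1L),
       dims = c(d[3], d[1], d[2]))
}

volume_to_cube <- function(x, dims) {
  aperm(array(x, dims), c(2, 3, 1))
}

# Full forward pass. Returns the pre-activation output z (same voxel count
# as the input), the latent feature map, and caches when train = TRUE.
forward_model <- function(model, vol, train = FALSE, zero_latent = FALSE) {
  cfg <- model$config
  caches <- if (train) list(blocks_enc = list(), blocks_dec = list()) else NULL
  cin <- conv_fwd(model$layers$input, vol$x, vol$dims)
  if (train) caches$input <- list(x = vol$x, dims = vol$dims)
  x <- cin$x; dims <- cin$dims
  sizes <- list()   # extents entering each down-sampling stage
  for (i in seq_along(model$layers$enc)) {
    if (i %% cfg$downsample_every == 0L) sizes <- c(sizes, list(dims))
    bf <- block_fwd(model$layers$enc[[i]], x, dims, keep_cache = train)
    if (train) caches$blocks_enc[[i]] <- bf$cache
    x <- bf$x; dims <- bf$dims
  }
  # decoder up-sampling targets are the pre-stride extents in reverse order
  up_targets <- rev(sizes)
  latent <- list(x = x, dims = dims)
  if (zero_latent) x <- x * 0
  if (cfg$mode == "uniform") {
    n_sp <- dims[2] * dims[3]
    if (train) caches$pool <- list(dims = dims)
    xm <- matrix(0, dims[1], ncol(x))
    for (j in seq_len(n_sp))
      xm <- xm + x[seq_len(dims[1]) + (j - 1L) * dims[1], , drop = FALSE]
    x <- xm / n_sp
    dims <- c(dims[1], 1L, 1L)
    up_targets <- lapply(up_targets, function(d) c(d[1], 1L, 1L))
  }
  ui <- 0L
  for (j in seq_along(model$layers$dec)) {
    if (j %in% model$up_before) {
      ui <- ui + 1L
      target <- up_targets[[ui]]
      if (train)
        caches$ups[[ui]] <- list(from = dims, to = target, at = j)
      x <- cpp_upsample3d(x, dims, target)
      dims <- target
    }
    bf <- block_fwd(model$layers$dec[[j]], x, dims, keep_cache = train)
    if (train) caches$blocks_dec[[j]] <- bf$cache
    x <- bf$x; dims <- bf$dims
  }
  cout <- conv_fwd(model$layers$out, x, dims)
  if (train) caches$out <- list(x = x, dims = dims)
  list(z = cout$x, dims = cout$dims, latent = latent, caches = caches)
}

# Backward pass from dZ (gradient at the pre-softplus output). Returns the
# gradient tree matching model$layers.
backward_model <- function(model, caches, dZ) {
  cfg <- model$config
  grads <- list(enc = vector("list", length(model$layers$enc)),
                dec = vector("list", length(model$layers$dec)))
  bo <- conv_bwd(model$layers$out, caches$out$x, caches$out$dims, dZ)
  grads$out <- list(W = bo$dW, b = bo$db)
  d <- bo$dX
  ups <- caches$ups
  ui <- length(ups)
  for (j in rev(seq_along(model$layers$dec))) {
    bb <- block_bwd(model$layers$dec[[j]], caches$blocks_dec[[j]], d)
    grads$dec[[j]] <- bb$grads
    d <- bb$dX
    if (!is.null(ups) && ui >= 1L && ups[[ui]]$at == j) {
      d <- cpp_upsample3d_bwd(d, ups[[ui]]$from, ups[[ui]]$to)
      ui <- ui - 1L
    }
  }
  if (cfg$mode == "uniform") {
    pd <- caches$pool$dims
    n_sp <- pd[2] * pd[3]
    d <- matrix(d[rep(seq_len(pd[1]), n_sp), , drop = FALSE] / n_sp,
                pd[1] * n_sp, ncol(d))
  }
  for (i in rev(seq_along(model$layers$enc))) {
    bb <- block_bwd(model$layers$enc[[i]], caches$blocks_enc[[i]], d)
    grads$enc[[i]] <- bb$grads
    d <- bb$dX
  }
  bi <- conv_bwd(model$layers$input, caches$input$x, caches$input$dims, d,
                 want_dx = FALSE)
  grads$input <- list(W = bi$dW, b = bi$db)
  grads
}

#' Predict the white-reference cube for a raw input
#'
#' Runs the forward pass on an uncalibrated cube and returns the predicted
#' white-reference cube of identical shape and grid. The softplus output
#' is strictly positive; in `"uniform"` mode the prediction is spatially
#' constant. When the model was built with input normalization, the input
#' is divided by its global mean and the prediction scaled back.
#'
#' @param model A `whiteref_model`.
#' @param raw Raw [hypercube] with the channel count the model was trained
#'   on (any channel count is accepted by an untrained model).
#' @return A white-reference [hypercube].
#' @export
predict_white_reference <- function(model, raw) {
  if (!inherits(model, "whiteref_model")) stop("model must be a whiteref_model")
  stop_if_not_cube(raw, "raw")
  d <- dim(raw$values)
  if (!is.null(model$grid) && length(model$grid) != d[3])
    stop(sprintf("channel count mismatch: model trained on %d channels, input has %d",
                 length(model$grid), d[3]))
  m <- if (model$config$normalize) mean(raw$values) else 1
  if (m <= 0) m <- 1
  vol <- cube_to_volume(raw$values / m)
  fw <- forward_model(model, vol)
  # softplus is strictly positive in exact arithmetic; the floor guards the
  # rare underflow of exp() for extremely negative pre-activations
  w <- pmax(softplus(fw$z), 1e-30) * m
  if (model$config$mode == "uniform") {
    spec <- as.vector(w)   # one value per spectral channel
    return(constant_cube(spec, d[1], d[2], raw$wavelengths))
  }
  hypercube(volume_to_cube(w, fw$dims), raw$wavelengths,
            role = "white_reference")
}

#' Pooled latent encoding of a cube
#'
#' Runs the encoder and averages the latent feature map over all spatial
#' and spectral positions, yielding one fixed-length feature vector per
#' cube (length = latent feature count). Used for the latent PCA density
#' diagnostics.
#'
#' @param model A `whiteref_model`.
#' @param cube A [hypercube].
#' @return Numeric vector of length `model$config$latent_features`.
#' @export
encode_pooled <- function(model, cube) {
  if (!inherits(model, "whiteref_model")) stop("model must be a whiteref_model")
  stop_if_not_cube(cube)
  m <- if (model$config$normalize) mean(cube$values) else 1
  if (m <= 0) m <- 1
  vol <- cube_to_volume(cube$values / m)
  fw <- forward_model(model, vol)
  colMeans(fw$latent$x)
}

#' Recalibrate a raw cube with the model-predicted white reference
#'
#' Composition of [predict_white_reference()] and [calibrate()]: the
#' model's white-tile prediction replaces the physical white-tile
#' measurement.
#'
#' @param model A `whiteref_model`.
#' @param raw Raw [hypercube].
#' @param floor Division floor passed to [calibrate()].
#' @return Calibrated [hypercube].
#' @export
recalibrate <- function(model, raw, floor = NULL) {
  calibrate(raw, predict_white_reference(model, raw), floor = floor)
}
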