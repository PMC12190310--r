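# Per-modality 3D convolutional encoder: a stack of valid 3x3x3
# convolutions (stride 1, no padding), each followed by batch
# normalisation and leaky ReLU, with stride-2 max pooling after selected
# layers. The full-size configuration uses nine layers with channel
# counts 8, 8, 16, 16, 32, 32, 64, 64, 128 and pooling after layers
# 2, 4, 6 and 8, which maps a 113 x 137 x 113 volume to a
# 128-channel 1 x 2 x 1 feature map.

#' Encoder configuration
#'
#' Describes a per-modality 3D CNN encoder branch. The default is the
#' full-size nine-layer network; tests and desk-scale experiments pass a
#' smaller `channels` / `pool_after` schedule.
#'
#' @param channels Integer vector of output channels per convolutional
#'   layer, in order.
#' @param pool_after Integer indices (1-based layer numbers) after which a
#'   kernel-2 stride-2 max pooling is applied.
#' @param kernel Convolution kernel size (cubic); fixed stride 1, no
#'   padding.
#' @param leaky_slope Negative slope of the leaky ReLU activations.
#' @return An object of class `mmdda_encoder_config`.
#' @export
#' @examples
#' cfg <- encoder_config(channels = c(4, 8), pool_after = 2)
#' shape_trace(cfg, c(8, 8, 8))
encoder_config <- function(channels = c(8, 8, 16, 16, 32, 32, 64, 64, 128),
                           pool_after = c(2, 4, 6, 8),
                           kernel = 3, leaky_slope = 0.01) {
  channels <- as.integer(channels)
  pool_after <- as.integer(pool_after)
  if (length(channels) < 1 || any(channels < 1))
    stop_mmdda("'channels' must be a non-empty vector of positive counts",
               "mmdda_config_error")
  if (length(pool_after) && (any(pool_after < 1) ||
                             any(pool_after > length(channels))))
    stop_mmdda("'pool_after' indices must name existing layers",
               "mmdda_config_error")
  check_scalar(kernel, "kernel", 1)
  structure(list(channels = channels, pool_after = sort(unique(pool_after)),
                 kernel = as.integer(kernel), leaky_slope = leaky_slope),
            class = "mmdda_encoder_config")
}

#' Analytic per-layer spatial shape trace
#'
#' Pure integer arithmetic: each valid k^3 convolution maps spatial size
#' `s` to `s - k + 1`; each pooling halves it with floor. Errors, naming
#' the offending layer, if any dimension would collapse below 1.
#'
#' @param config An [encoder_config()].
#' @param input_shape Integer vector of 3 positive voxel counts.
#' @return Integer matrix with one row per stage (input, each conv, each
#'   pool) and columns `d`, `h`, `w`; attribute `out_channels` gives the
#'   channel count of the final feature map.
#' @export
shape_trace <- function(config, input_shape) {
  stopifnot(inherits(config, "mmdda_encoder_config"))
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3 || any(input_shape < 1))
    stop_mmdda("'input_shape' must be 3 positive integers",
               "mmdda_config_error")
  s <- input_shape
  rows <- list(input = s)
  for (l in seq_along(config$channels)) {
    s <- s - config$kernel + 1L
    if (any(s < 1))
      stop_mmdda(sprintf(
        "input too small: conv layer %d would produce non-positive dims (%s)",
        l, paste(s, collapse = "x")), "mmdda_shape_error")
    rows[[paste0("conv", l)]] <- s
    if (l %in% config$pool_after) {
      s <- s %/% 2L
      if (any(s < 1))
        stop_mmdda(sprintf(
          "input too small: pooling after layer %d would produce non-positive dims (%s)",
          l, paste(s, collapse = "x")), "mmdda_shape_error")
      rows[[paste0("pool", l)]] <- s
    }
  }
  out <- do.call(rbind, rows)
  colnames(out) <- c("d", "h", "w")
  attr(out, "out_channels") <- config$channels[length(config$channels)]
  out
}

#' Initialise an encoder branch
#'
#' Seeded Kaiming fan-in initialisation of all convolution weights; batch
#' norm scales start at 1, shifts and running means at 0, running
#' variances at 1.
#'
#' @param config An [encoder_config()].
#' @param in_channels Number of input channels (1 for a raw volume).
#' @param seed Optional integer; when given, initialisation is drawn under
#'   this seed without disturbing the caller's RNG stream.
#' @return An object of class `mmdda_encoder` holding parameters and
#'   batch-norm running statistics.
#' @export
encoder_init <- function(config, in_channels = 1L, seed = NULL) {
  stopifnot(inherits(config, "mmdda_encoder_config"))
  k <- config$kernel
  with_seed_opt(seed, {
    layers <- vector("list", length(config$channels))
    cin <- as.integer(in_channels)
    for (l in seq_along(config$channels)) {
      cout <- config$channels[l]
      layers[[l]] <- list(
        w = kaiming_init(c(k, k, k, cin, cout), fan_in = k^3 * cin,
                         slope = config$leaky_slope),
        b = numeric(cout),
        gamma = rep(1, cout), beta = numeric(cout),
        run_mean = numeric(cout), run_var = rep(1, cout))
      cin <- cout
    }
    structure(list(config = config, in_channels = as.integer(in_channels),
                   layers = layers),
              class = "mmdda_encoder")
  })
}

# single-volume forward; x is (D, H, W) or (D, H, W, Cin).
# Returns the (D', H', W', C) feature array, a cache for the backward
# pass, and the encoder with updated running statistics (training mode).
encoder_fwd <- function(enc, x, training = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[4] != enc$in_channels)
    stop_mmdda("input channel count does not match encoder", "mmdda_shape_error")
  shape_trace(enc$config, dim(x)[1:3])  # validates before allocating
  slope <- enc$config$leaky_slope
  caches <- vector("list", length(enc$layers))
  for (l in seq_along(enc$layers)) {
    p <- enc$layers[[l]]
    xin <- x
    z <- conv3d_fwd(xin, p$w, p$b)
    bn <- bn_fwd(z, p$gamma, p$beta, p$run_mean, p$run_var, training)
    enc$layers[[l]]$run_mean <- bn$run_mean
    enc$layers[[l]]$run_var <- bn$run_var
    act <- leaky_relu_fwd(bn$y, slope)
    x <- act$y
    pool <- NULL
    if (l %in% enc$config$pool_after) {
      pool <- maxpool3d_fwd(x)
      caches[[l]] <- list(xin = xin, bn = bn$cache, neg = act$neg,
                          prepool_dim = dim(x), argmax = pool$argmax)
      x <- pool$y
    } else {
      caches[[l]] <- list(xin = xin, bn = bn$cache, neg = act$neg)
    }
  }
  list(out = x, cache = caches, enc = enc)
}

# backward through encoder_fwd; returns per-layer parameter gradients
# (w, b, gamma, beta), matching the layout of enc_params()
encoder_bwd <- function(enc, cache, gy) {
  slope <- enc$config$leaky_slope
  grads <- vector("list", length(enc$layers))
  names(grads) <- paste0("L", seq_along(enc$layers))
  for (l in rev(seq_along(enc$layers))) {
    cc <- cache[[l]]
    p <- enc$layers[[l]]
    if (!is.null(cc$argmax))
      gy <- maxpool3d_bwd(gy, cc$argmax, cc$prepool_dim)
    gy <- leaky_relu_bwd(gy, cc$neg, slope)
    bb <- bn_bwd(gy, cc$bn, p$gamma)
    cb <- conv3d_bwd(cc$xin, p$w, bb$gx)
    grads[[l]] <- list(w = cb$gw, b = cb$gb,
                       gamma = bb$ggamma, beta = bb$gbeta)
    gy <- cb$gx
  }
  grads
}

# optimisable parameters of an encoder as a tree (running stats excluded)
enc_params <- function(enc) {
  ps <- lapply(enc$layers, function(p) p[c("w", "b", "gamma", "beta")])
  names(ps) <- paste0("L", seq_along(ps))
  ps
}

enc_set_params <- function(enc, ps) {
  for (l in seq_along(enc$layers))
    enc$layers[[l]][c("w", "b", "gamma", "beta")] <- ps[[l]]
  enc
}

#' Encode a batch of volumes
#'
#' Runs one encoder branch over a batch and returns the feature maps as a
#' 5-axis array `(batch, channels, depth, height, width)`. Inference uses
#' the stored batch-norm running statistics (eval mode), so outputs for a
#' sample do not depend on its batch companions.
#'
#' @param volumes A single 3-axis array or a list of 3-axis arrays of
#'   identical shape.
#' @param encoder An [encoder_init()] object.
#' @return A 5-axis feature array of class `mmdda_feature_map`.
#' @export
encode <- function(volumes, encoder) {
  if (!is.list(volumes)) volumes <- list(volumes)
  outs <- lapply(volumes, function(v) encoder_fwd(encoder, v, training = FALSE)$out)
  d <- dim(outs[[1]])                      # (D, H, W, C)
  B <- length(outs)
  fmap <- array(0, dim = c(B, d[4], d[1], d[2], d[3]))
  for (b in seq_len(B))
    fmap[b, , , , ] <- aperm(outs[[b]], c(4, 1, 2, 3))
  class(fmap) <- c("mmdda_feature_map", class(fmap))
  fmap
}

#' Flatten feature maps to per-sample vectors
#'
#' Deterministic flattening of the non-batch axes of a
#' `(B, C, D, H, W)` feature array; each row has length `C*D*H*W` and
#' `array(row, dim = dim(fmap)[-1])` restores the sample's map.
#'
#' @param fmap A 5-axis feature array as returned by [encode()].
#' @return A numeric matrix with one row per sample.
#' @export
flatten_features <- function(fmap) {
  d <- dim(fmap)
  stopifnot(length(d) == 5)
  out <- matrix(0, nrow = d[1], ncol = prod(d[-1]))
  for (b in seq_len(d[1])) out[b, ] <- as.vector(fmap[b, , , , ])
  out
}
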