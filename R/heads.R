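# Category classifier, domain discriminator, and the gradient-reversal
# layer. Both heads are three fully connected layers (default units
# 128, 64, 2) with leaky-ReLU activations and dropout after the first
# two layers; outputs are softmax probabilities.

#' Head configuration
#'
#' @param units Integer vector of fully connected layer widths; the last
#'   entry must be 2 (binary output). Default `c(128, 64, 2)`.
#' @param dropout Dropout rate applied after the first and second layers
#'   during training; default 0.5.
#' @param grl_weight Gradient-reversal coefficient `lambda`; the backward
#'   pass multiplies the feature-side gradient of the domain loss by
#'   `-lambda`. Default 0.1.
#' @return An object of class `mmdda_head_config`.
#' @export
head_config <- function(units = c(128, 64, 2), dropout = 0.5,
                        grl_weight = 0.1) {
  units <- as.integer(units)
  if (length(units) < 1 || units[length(units)] != 2L)
    stop_mmdda("'units' must end in 2 output units", "mmdda_config_error")
  if (dropout < 0 || dropout >= 1)
    stop_mmdda("'dropout' must lie in [0, 1)", "mmdda_config_error")
  structure(list(units = units, dropout = dropout, grl_weight = grl_weight),
            class = "mmdda_head_config")
}

#' Initialise a fully connected head
#'
#' @param input_dim Length of the fused feature vector fed to the head.
#' @param config A [head_config()].
#' @param seed Optional integer seed for the weight draw.
#' @return An object of class `mmdda_head`.
#' @export
head_init <- function(input_dim, config = head_config(), seed = NULL) {
  with_seed_opt(seed, {
    dims <- c(as.integer(input_dim), config$units)
    layers <- lapply(seq_along(config$units), function(l)
      linear_init(dims[l], dims[l + 1]))
    names(layers) <- paste0("fc", seq_along(layers))
    structure(list(config = config, layers = layers, input_dim = input_dim),
              class = "mmdda_head")
  })
}

# forward returning logits and a cache; x: vector or N x input_dim matrix
head_fwd <- function(head, x, training = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  nl <- length(head$layers)
  cache <- vector("list", nl)
  for (l in seq_len(nl)) {
    xin <- x
    z <- linear_fwd(x, head$layers[[l]])
    if (l < nl) {
      act <- leaky_relu_fwd(z)
      dr <- dropout_fwd(act$y, head$config$dropout, training)
      x <- dr$y
      cache[[l]] <- list(xin = xin, neg = act$neg, mask = dr$mask)
    } else {
      x <- z
      cache[[l]] <- list(xin = xin)
    }
  }
  list(logits = x, cache = cache)
}

head_bwd <- function(head, cache, glogits) {
  nl <- length(head$layers)
  grads <- vector("list", nl)
  names(grads) <- names(head$layers)
  g <- glogits
  for (l in rev(seq_len(nl))) {
    if (l < nl) {
      g <- dropout_bwd(g, cache[[l]]$mask)
      g <- leaky_relu_bwd(g, cache[[l]]$neg)
    }
    lb <- linear_bwd(g, cache[[l]]$xin, head$layers[[l]])
    grads[[l]] <- list(W = lb$gW, b = lb$gb)
    g <- lb$gx
  }
  list(grads = grads, gx = g)
}

head_params <- function(head) lapply(head$layers, function(p) p[c("W", "b")])

head_set_params <- function(head, ps) {
  for (l in seq_along(head$layers)) head$layers[[l]][c("W", "b")] <- ps[[l]]
  head
}

#' Classify fused feature vectors
#'
#' Softmax class probabilities from the category classifier. In eval mode
#' (the default) dropout is disabled and repeated calls are identical.
#'
#' @param features A fused feature vector or an `N x d` matrix of them.
#' @param head A [head_init()] object.
#' @param training Logical; enables dropout.
#' @return `N x 2` matrix of probabilities; rows sum to 1. Column 2 is
#'   `P(class 1)`.
#' @export
classify <- function(features, head, training = FALSE) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != head$input_dim)
    stop_mmdda("feature dimension does not match head input", "mmdda_shape_error")
  softmax_rows(head_fwd(head, features, training)$logits)
}

#' Gradient-reversal layer (forward)
#'
#' Identity in the forward pass; during backpropagation the gradient
#' flowing from the domain discriminator back into the feature path is
#' multiplied by `-lambda` (see [grl_backward()]), so that discriminator
#' training pushes the encoders toward domain-indistinguishable features.
#'
#' @param x Features (any numeric array).
#' @param lambda Reversal coefficient; default 0.1.
#' @return `x` unchanged, with the coefficient attached as attribute
#'   `grl_lambda`.
#' @export
gradient_reverse <- function(x, lambda = 0.1) {
  attr(x, "grl_lambda") <- lambda
  x
}

#' Gradient-reversal layer (backward)
#'
#' @param g Gradient arriving from the discriminator side.
#' @param lambda Reversal coefficient used in the forward pass.
#' @return `-lambda * g`.
#' @export
grl_backward <- function(g, lambda = 0.1) -lambda * g

#' Discriminate source from target features
#'
#' Concatenates the source and target fused feature batches in order and
#' returns, per sample, the softmax probability row of domain membership
#' (column 2 = probability of coming from the source domain).
#'
#' @param f_source,f_target Matrices of fused vectors (rows = samples);
#'   either may be `NULL` outside the adversarial phase.
#' @param head The discriminator [head_init()] object.
#' @param training Logical; enables dropout.
#' @return `(N_S + N_T) x 2` probability matrix in concatenation order.
#' @export
discriminate <- function(f_source, f_target, head, training = FALSE) {
  feats <- rbind(f_source, f_target)
  if (is.null(feats) || nrow(feats) == 0)
    stop_mmdda("discriminate: no features supplied", "mmdda_config_error")
  classify(feats, head, training)
}
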