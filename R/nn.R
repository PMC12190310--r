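# Neural-network primitives with explicit forward caches and hand-derived
# backward passes. All optimisation-facing state lives in plain R lists so
# the Adam updater can walk parameter trees generically.

kaiming_init <- function(dims, fan_in, slope = 0.01) {
  gain <- sqrt(2 / (1 + slope^2))
  array(rnorm(prod(dims), sd = gain / sqrt(fan_in)), dim = dims)
}

leaky_relu_fwd <- function(x, slope = 0.01) {
  neg <- x < 0
  y <- x
  y[neg] <- slope * x[neg]
  list(y = y, neg = neg)
}

leaky_relu_bwd <- function(gy, neg, slope = 0.01) {
  gx <- gy
  gx[neg] <- slope * gy[neg]
  gx
}

# Batch normalisation over all non-channel axes of a (D, H, W, C) array.
# With the protocol's batch size of 1 the normalisation statistics are
# the per-channel spatial moments. Running statistics use unbiased variance;
# normalisation uses the biased estimate, matching common DL frameworks.
bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[4]
  m <- prod(d[1:3])
  xm <- matrix(x, nrow = m, ncol = C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    va <- pmax(va, 0)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var +
      momentum * (if (m > 1) va * m / (m - 1) else va)
  } else {
    mu <- run_mean
    va <- run_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, dims = d,
                           training = training),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(gy, cache, gamma) {
  d <- cache$dims
  C <- d[4]
  m <- prod(d[1:3])
  gym <- matrix(gy, nrow = m, ncol = C)
  xhat <- cache$xhat
  ggamma <- colSums(gym * xhat)
  gbeta <- colSums(gym)
  if (cache$training) {
    # full backward through the batch statistics
    t1 <- sweep(gym, 2, gbeta / m, "-")
    t2 <- sweep(xhat, 2, ggamma / m, "*")
    gx <- sweep(t1 - t2, 2, gamma * cache$invstd, "*")
  } else {
    gx <- sweep(gym, 2, gamma * cache$invstd, "*")
  }
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

linear_init <- function(in_dim, out_dim, slope = 0.01) {
  list(W = kaiming_init(c(out_dim, in_dim), fan_in = in_dim, slope = slope),
       b = numeric(out_dim))
}

# x: in_dim vector or N x in_dim matrix; returns N x out_dim matrix
linear_fwd <- function(x, p) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  y <- x %*% t(p$W)
  sweep(y, 2, p$b, "+")
}

linear_bwd <- function(gy, x, p) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  list(gx = gy %*% p$W, gW = t(gy) %*% x, gb = colSums(gy))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(gy, mask) {
  if (is.null(mask)) gy else gy * mask
}

# Adam optimiser over a parameter tree
adam_init <- function(params) {
  list(m = tree_map(params, function(x) x * 0),
       v = tree_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v,
                   function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- tree_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}
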