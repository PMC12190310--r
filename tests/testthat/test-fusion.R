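test_that("concat_reshape stitches channels and linearises space", {
  f1 <- array(rnorm(1 * 128 * 2), c(1, 128, 1, 2, 1))
  f2 <- array(rnorm(1 * 128 * 2), c(1, 128, 1, 2, 1))
  sq <- concat_reshape(f1, f2)
  expect_equal(dim(sq), c(1, 2, 256))

  g1 <- array(rnorm(3 * 4 * 8), c(3, 4, 2, 2, 2))
  g2 <- array(rnorm(3 * 4 * 8), c(3, 4, 2, 2, 2))
  sq2 <- concat_reshape(g1, g2)
  expect_equal(dim(sq2), c(3, 8, 8))
  # element traceability: (b, l, e) indexes a unique source voxel/channel
  expect_equal(sq2[2, 1, 3], g1[2, 3, 1, 1, 1])
  expect_equal(sq2[2, 1, 4 + 2], g2[2, 2, 1, 1, 1])

  g3 <- array(rnorm(3 * 4 * 27), c(3, 4, 3, 3, 3))
  expect_error(concat_reshape(g1, g3), class = "mmdda_shape_error")
})

test_that("uniform attention averages the value rows", {
  # W_Q = W_K = 0 makes every score zero, so softmax is uniform over L
  E <- 4; L <- 2
  X <- matrix(c(1, 3, 2, 4, 0, 2, 5, 7), L, E)
  params <- list(Wq = matrix(0, E, E), Wk = matrix(0, E, E),
                 Wv = diag(E), Wo = diag(E))
  out <- multi_head_attention(X, fusion_config(heads = 1), params)
  expect_equal(out[1, ], colMeans(X))
  expect_equal(out[2, ], colMeans(X))
  # same property head-wise
  out2 <- multi_head_attention(X, fusion_config(heads = 2), params)
  expect_equal(out2[1, ], colMeans(X))
})

test_that("a length-one sequence gets attention weight exactly one", {
  E <- 4
  X <- matrix(rnorm(E), 1, E)
  params <- fusion_init(E, seed = 2)
  out <- multi_head_attention(X, fusion_config(heads = 2), params)
  expect_equal(out, X %*% params$Wv %*% params$Wo)
})

test_that("attention weights are a distribution over the sequence", {
  set.seed(11)
  X <- matrix(rnorm(6 * 8), 6, 8)
  params <- fusion_init(8, seed = 3)
  fw <- mmdda:::mha_fwd_one(X, params, heads = 4)
  for (A in fw$cache$A) {
    expect_true(all(A >= 0))
    expect_equal(rowSums(A), rep(1, 6))
  }
  expect_error(mmdda:::mha_fwd_one(X, params, heads = 3),
               class = "mmdda_config_error")
})

test_that("multi-head with h = 1 equals a directly coded single-head oracle", {
  set.seed(21)
  for (rep in 1:5) {
    L <- sample(2:6, 1); E <- sample(c(4, 6, 8), 1)
    X <- matrix(rnorm(L * E), L, E)
    params <- fusion_init(E, seed = rep)
    got <- multi_head_attention(X, fusion_config(heads = 1), params)
    # oracle: plain scaled dot-product attention written out longhand
    Q <- X %*% params$Wq; K <- X %*% params$Wk; V <- X %*% params$Wv
    S <- Q %*% t(K) / sqrt(E)
    A <- exp(S - apply(S, 1, max))
    A <- A / rowSums(A)
    expect_equal(got, (A %*% V) %*% params$Wo, tolerance = 1e-12)
  }
})

test_that("flatten_fused reduces the sequence axis by mean", {
  x <- array(0, c(1, 2, 4))
  x[1, 1, ] <- 0; x[1, 2, ] <- 2
  expect_equal(flatten_fused(x)[1, ], rep(1, 4))
  one <- array(rnorm(8), c(1, 1, 8))
  expect_equal(flatten_fused(one)[1, ], as.vector(one[1, 1, ]))
  big <- array(rnorm(2 * 256), c(1, 2, 256))
  expect_equal(ncol(flatten_fused(big)), 256)
  expect_equal(ncol(flatten_fused(big, reduce = "flatten")), 512)
})

test_that("batch order permutes fused vectors consistently", {
  f1 <- array(rnorm(3 * 4 * 8), c(3, 4, 2, 2, 2))
  f2 <- array(rnorm(3 * 4 * 8), c(3, 4, 2, 2, 2))
  params <- fusion_init(8, seed = 5)
  cfg <- fusion_config(heads = 2)
  fused <- flatten_fused(multi_head_attention(concat_reshape(f1, f2), cfg, params))
  perm <- c(3, 1, 2)
  fused_p <- flatten_fused(multi_head_attention(
    concat_reshape(f1[perm, , , , , drop = FALSE],
                   f2[perm, , , , , drop = FALSE]), cfg, params))
  expect_equal(fused_p, fused[perm, ])
})
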