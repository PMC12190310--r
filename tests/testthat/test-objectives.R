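test_that("gaussian kernel closed forms", {
  x <- rnorm(5)
  expect_equal(gaussian_kernel(x, x), 1.0)
  expect_equal(gaussian_kernel(c(1, 0), c(0, 0)), exp(-0.5))
  y <- rnorm(5)
  expect_equal(gaussian_kernel(x, y), gaussian_kernel(y, x))
  # width rescales the squared distance
  expect_equal(gaussian_kernel(c(2, 0), c(0, 0), kernel_config(sigma = 2)),
               exp(-0.5))
  expect_error(gaussian_kernel(1:3, 1:4), class = "mmdda_shape_error")
})

test_that("correlation loss closed forms for single pairs", {
  v <- rnorm(4)
  eps <- 1e-6
  expect_equal(correlation_loss(v, v), -log(1 + eps), tolerance = 1e-12)
  # K = exp(-1/2) from unit distance
  k <- exp(-0.5)
  expect_equal(correlation_loss(c(1, 0), c(0, 0)), -k * log(k + eps),
               tolerance = 1e-12)
  expect_error(correlation_loss(matrix(0, 0, 2), matrix(0, 0, 2)),
               class = "mmdda_config_error")
})

test_that("correlation loss equals the brute-force double sum", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(2:5, 1); p <- sample(2:6, 1)
    A <- matrix(rnorm(n * p), n, p)
    B <- matrix(rnorm(n * p), n, p)
    brute <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      k <- exp(-sum((A[i, ] - B[j, ])^2) / 2)
      brute <- brute - k * log(k + 1e-6)
    }
    expect_equal(correlation_loss(A, B), brute, tolerance = 1e-10)
  }
})

test_that("single-pair correlation loss peaks near K = 1/e", {
  # as a function of the kernel value the loss is -K log(K + eps):
  # non-negative on (0, 1) up to the O(eps) dip at K = 1, maximal near 1/e
  kgrid <- seq(0.01, 1, by = 0.005)
  loss <- vapply(kgrid, function(k) {
    d <- sqrt(-2 * log(k))       # distance giving kernel value k
    correlation_loss(c(d, 0), c(0, 0))
  }, 0)
  expect_equal(loss, -kgrid * log(kgrid + 1e-6), tolerance = 1e-8)
  expect_true(all(loss[kgrid < 1] > -1e-6))
  expect_equal(kgrid[which.max(loss)], 1 / exp(1), tolerance = 0.01)
})

test_that("correlation loss gradients agree with central differences", {
  set.seed(32)
  A <- matrix(rnorm(6, sd = 0.5), 2, 3)
  B <- matrix(rnorm(6, sd = 0.5), 2, 3)
  g <- mmdda:::correlation_loss_grad(A, B)
  ng_a <- num_grad(function(v) {
    A2 <- A; A2[] <- v; correlation_loss(A2, B)
  }, as.vector(A))
  ng_b <- num_grad(function(v) {
    B2 <- B; B2[] <- v; correlation_loss(A, B2)
  }, as.vector(B))
  expect_equal(as.vector(g$g_mri), ng_a, tolerance = 1e-6)
  expect_equal(as.vector(g$g_pet), ng_b, tolerance = 1e-6)
})

test_that("consistency loss is the mean squared difference", {
  v <- rnorm(6)
  expect_equal(consistency_loss(v, v), 0)
  expect_equal(consistency_loss(c(2, 0), c(0, 0)), 2)
  a <- rnorm(4); b <- rnorm(4)
  expect_equal(consistency_loss(a, b), consistency_loss(b, a))
  expect_error(consistency_loss(1:3, 1:4), class = "mmdda_shape_error")
})

test_that("classification and domain cross-entropies", {
  expect_equal(classification_loss(matrix(c(0.5, 0.5), 1), 1), log(2))
  expect_equal(classification_loss(matrix(c(0, 1), 1), 1), 0)
  expect_equal(classification_loss(matrix(c(0.2, 0.8), 1), 1), -log(0.8))
  expect_equal(domain_loss(matrix(c(0.5, 0.5), 1), 0), log(2))
  expect_equal(domain_loss(matrix(c(0.8, 0.2), 1), 0), -log(0.8))
  # mean over samples
  p <- rbind(c(0.2, 0.8), c(0.6, 0.4))
  expect_equal(classification_loss(p, c(1, 0)), -(log(0.8) + log(0.6)) / 2)
  expect_error(classification_loss(matrix(c(0.7, 0.7), 1), 1),
               class = "mmdda_config_error")
  expect_error(domain_loss(matrix(c(0.5, 0.5), 1), 2),
               class = "mmdda_config_error")
})

test_that("the total objective is the plain sum of its components", {
  b <- total_loss(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(b$total, 1.5)
  # phase-1 composition: only L_cor^S and L_cls present
  b1 <- total_loss(cor_s = 0.25, cls = 0.5)
  expect_equal(b1$total, 0.75)
  expect_error(total_loss(cor_s = NaN, cls = 1), "cor_s")
  expect_error(total_loss(dom = Inf), "dom")
  # ablation hook: weights rescale components
  bw <- total_loss(1, 1, 1, 1, 1, weights = list(cor = 0))
  expect_equal(bw$total, 3)
})
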