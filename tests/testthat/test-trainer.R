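test_that("fused dimension arithmetic across variants", {
  cfg <- tiny_config()
  dims <- lapply(c("SDA", "MSDA", "M3HF", "MMDDA"), function(v) {
    cfg$variant <- v
    build_model(cfg)$dims$d_fused
  })
  names(dims) <- c("SDA", "MSDA", "M3HF", "MMDDA")
  # flattened map is 4 channels x 2^3 voxels = 32
  expect_equal(dims$SDA, 32)
  expect_equal(dims$MSDA, 2 * dims$SDA)
  expect_equal(dims$MMDDA, 8)       # E = 2C under mean reduction
  expect_equal(dims$M3HF, dims$MMDDA)
  expect_error(run_variant("XXX", list(), cfg), "should be one of")
})

test_that("phase 1 smoke run records finite losses and is seed-deterministic", {
  data <- tiny_dataset(seed = 6)
  cfg <- tiny_config(seed = 6)
  m1 <- build_model(cfg)
  m1 <- train_phase1(m1, data$source, cfg, seed = 10)
  expect_true(m1$phase1_done)
  h <- m1$history
  expect_equal(nrow(h), cfg$epochs_phase1)
  expect_true(all(is.finite(h$total)))
  expect_true(all(h$mse == 0) && all(h$dom == 0))   # phase-1 composition

  m2 <- train_phase1(build_model(cfg), data$source, cfg, seed = 10)
  expect_identical(mmdda:::collect_params(m1, 1), mmdda:::collect_params(m2, 1))
})

test_that("weight sharing copies source branches without aliasing", {
  cfg <- tiny_config(seed = 7)
  model <- build_model(cfg)
  vol <- array(rnorm(14^3), c(14, 14, 14))
  before <- mmdda:::encoder_fwd(model$enc$mri_t, vol)$out
  model <- share_weights(model)
  s_out <- mmdda:::encoder_fwd(model$enc$mri_s, vol)$out
  t_out <- mmdda:::encoder_fwd(model$enc$mri_t, vol)$out
  expect_identical(s_out, t_out)
  expect_false(identical(before, t_out))
  # modifying the target copy leaves the source untouched
  model$enc$mri_t$layers[[1]]$w[1] <- 99
  expect_identical(mmdda:::encoder_fwd(model$enc$mri_s, vol)$out, s_out)
})

test_that("phase 2 logs all five loss components and requires sharing", {
  data <- tiny_dataset(seed = 8)
  cfg <- tiny_config(seed = 8)
  model <- build_model(cfg)
  expect_error(train_phase2(model, data$source, data$target, cfg, seed = 1),
               class = "mmdda_training_error")
  model <- share_weights(train_phase1(model, data$source, cfg, seed = 2))
  model <- train_phase2(model, data$source, data$target, cfg, seed = 3)
  h2 <- model$history[model$history$phase == 2, ]
  expect_equal(nrow(h2), cfg$epochs_phase2)
  expect_true(all(is.finite(unlist(h2[, c("cor_s", "cor_t", "mse",
                                          "cls", "dom", "total")]))))
  expect_gt(tail(h2$mse, 1), 0)
})

test_that("target labels are never read during phase 2", {
  data <- tiny_dataset(seed = 9)
  cfg <- tiny_config(seed = 9)
  run_with_target <- function(target) {
    model <- share_weights(train_phase1(build_model(cfg), data$source,
                                        cfg, seed = 5))
    train_phase2(model, data$source, target, cfg, seed = 6)
  }
  garbage <- lapply(data$target, function(s) {
    s$label <- sample(0:1, 1)
    s
  })
  m_a <- run_with_target(data$target)
  m_b <- run_with_target(garbage)
  expect_identical(mmdda:::collect_params(m_a, 2),
                   mmdda:::collect_params(m_b, 2))
  expect_identical(m_a$history, m_b$history)
})

test_that("dropping the correlation loss reduces MMDDA to M3HF", {
  data <- tiny_dataset(seed = 12)
  cfg_a <- tiny_config(seed = 12, variant = "M3HF")
  cfg_b <- tiny_config(seed = 12, variant = "MMDDA",
                       loss_weights = list(cor = 0))
  m_a <- fit_mmdda(data, cfg_a)
  m_b <- fit_mmdda(data, cfg_b)
  expect_identical(mmdda:::collect_params(m_a, 2),
                   mmdda:::collect_params(m_b, 2))
})

test_that("source training reaches high accuracy on separable data", {
  data <- tiny_dataset(seed = 13, n = 4, shape = c(16, 16, 16),
                       class_effect = 1.5)
  cfg <- tiny_config(seed = 13, input_shape = c(16, 16, 16),
                     epochs_phase1 = 30, epochs_phase2 = 0)
  model <- fit_mmdda(data, cfg)
  rep <- evaluate_model(model, data$source, "source")
  expect_gt(rep$acc, 0.9)
})

test_that("every variant smoke-trains and reports target metrics", {
  data <- tiny_dataset(seed = 14)
  cfg <- tiny_config(seed = 14)
  for (v in c("SDA", "MSDA", "M3HF", "MMDDA")) {
    rep <- run_variant(v, data, cfg)
    expect_s3_class(rep, "mmdda_metric_report")
    expect_true(is.finite(rep$acc))
    expect_equal(rep$n, length(data$target))
  }
})

test_that("gradients reaching the encoders match finite differences", {
  # end-to-end check through fusion, heads, correlation, consistency and
  # classification losses (dropout off). The domain loss is excluded:
  # its encoder-side gradient is reversed by design and is checked
  # against its own contract elsewhere.
  data <- tiny_dataset(seed = 15, shape = c(10, 10, 10))
  cfg <- tiny_config(seed = 15, input_shape = c(10, 10, 10),
                     head = head_config(units = c(6, 4, 2), dropout = 0),
                     loss_weights = list(dom = 0))
  model <- share_weights(build_model(cfg))
  s <- data$source[[1]]; t <- data$target[[1]]
  st <- mmdda:::step_phase2(model, s, t, cfg)
  loss_at <- function(m) mmdda:::step_phase2(m, s, t, cfg)$bundle$total
  for (probe in list(c("mri_s", 1L), c("pet_t", 2L))) {
    enc_nm <- probe[1]; layer <- as.integer(probe[2])
    w <- model$enc[[enc_nm]]$layers[[layer]]$w
    ii <- sample(length(w), 3)
    ng <- vapply(ii, function(i) {
      eps <- 1e-4
      mp <- model; mp$enc[[enc_nm]]$layers[[layer]]$w[i] <- w[i] + eps
      mm <- model; mm$enc[[enc_nm]]$layers[[layer]]$w[i] <- w[i] - eps
      (loss_at(mp) - loss_at(mm)) / (2 * eps)
    }, 0)
    ag <- as.vector(st$grads[[paste0("enc_", enc_nm)]][[layer]]$w)[ii]
    expect_equal(ag, ng, tolerance = 1e-3)
  }
})
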