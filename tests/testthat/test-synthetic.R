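test_that("generated datasets have the configured composition", {
  ds <- generate_dataset(synthetic_config(volume_shape = c(12, 12, 12),
                                          n_per_class_source = 8,
                                          n_per_class_target = 5, seed = 3))
  dom <- vapply(ds, `[[`, "", "domain")
  lab <- vapply(ds, `[[`, 0L, "label")
  expect_equal(sum(dom == "source"), 16)
  expect_equal(sum(dom == "target"), 10)
  expect_equal(sum(lab[dom == "source"] == 1), 8)
  expect_equal(sum(lab[dom == "source"] == 0), 8)
  expect_true(all(vapply(ds, function(s)
    identical(dim(s$mri), dim(s$pet)), TRUE)))
  expect_true(all(vapply(ds[dom == "target"], `[[`, TRUE, "label_held_out")))

  tab <- describe_dataset(ds)
  expect_equal(sum(tab$n), 26)
})

test_that("a fixed seed reproduces the dataset byte for byte", {
  cfg <- synthetic_config(volume_shape = c(12, 12, 12),
                          n_per_class_source = 2, n_per_class_target = 2,
                          seed = 99)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(volume_shape = c(4, 4, 4)), "at least 8")
  expect_error(synthetic_config(n_per_class_source = 0), "at least")
  expect_error(synthetic_config(modality_correlation = 1.5), "\\[0, 1\\]")
  expect_error(describe_dataset(list()), "empty")
})

test_that("zero shift leaves source and target distributions identical", {
  # per-voxel means agree within Monte-Carlo error when the target
  # transform is the identity
  diffs <- vapply(1:20, function(seed) {
    ds <- generate_dataset(synthetic_config(
      volume_shape = c(10, 10, 10), n_per_class_source = 2,
      n_per_class_target = 2, shift_gain = 1, shift_smooth = 0,
      bias_field = FALSE, seed = seed))
    dom <- vapply(ds, `[[`, "", "domain")
    ms <- rowMeans(vapply(ds[dom == "source"], function(s) as.vector(s$mri),
                          numeric(1000)))
    mt <- rowMeans(vapply(ds[dom == "target"], function(s) as.vector(s$mri),
                          numeric(1000)))
    mean(ms - mt)
  }, 0)
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("intensity gain scales the target signal component", {
  ds <- generate_dataset(synthetic_config(
    volume_shape = c(12, 12, 12), n_per_class_source = 10,
    n_per_class_target = 10, shift_gain = 2, shift_smooth = 0,
    bias_field = FALSE, noise_sd = 0.01, seed = 5))
  tab <- describe_dataset(ds)
  m_s <- sum(tab$mean_mri[tab$domain == "source"] * tab$n[tab$domain == "source"]) /
    sum(tab$n[tab$domain == "source"])
  m_t <- sum(tab$mean_mri[tab$domain == "target"] * tab$n[tab$domain == "target"]) /
    sum(tab$n[tab$domain == "target"])
  expect_equal(m_t / m_s, 2, tolerance = 0.05)
})

test_that("class_effect = 0 yields label-uninformative volumes", {
  aucs <- vapply(1:10, function(seed) {
    ds <- generate_dataset(synthetic_config(
      volume_shape = c(12, 12, 12), n_per_class_source = 10,
      n_per_class_target = 1, class_effect = 0, seed = seed))
    dom <- vapply(ds, `[[`, "", "domain")
    linear_probe_auc(ds[dom == "source"])
  }, 0)
  expect_lte(abs(mean(aucs) - 0.5), 0.1)
})

test_that("linear-probe AUC is non-decreasing in the class effect", {
  mean_auc <- vapply(c(0, 0.75, 1.5), function(eff) {
    mean(vapply(1:5, function(seed) {
      ds <- generate_dataset(synthetic_config(
        volume_shape = c(12, 12, 12), n_per_class_source = 10,
        n_per_class_target = 1, class_effect = eff, seed = seed))
      dom <- vapply(ds, `[[`, "", "domain")
      linear_probe_auc(ds[dom == "source"])
    }, 0))
  }, 0)
  expect_true(all(diff(mean_auc) >= -1e-8))
})

test_that("the domain gap is trivially detectable from mean intensity", {
  ds <- generate_dataset(synthetic_config(volume_shape = c(12, 12, 12),
                                          n_per_class_source = 10,
                                          n_per_class_target = 10, seed = 7))
  dom <- vapply(ds, `[[`, "", "domain")
  mi <- vapply(ds, function(s) mean(s$mri), 0)
  thr <- mean(c(mean(mi[dom == "source"]), mean(mi[dom == "target"])))
  acc <- mean((mi > thr) == (dom == "target"))
  expect_gt(acc, 0.9)
})
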