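# shared fixtures: all data is generated in code at test time

# tiny paired-volume task: 14^3 volumes, 2 subjects per class and domain
tiny_dataset <- function(seed = 1, n = 2, shape = c(14, 14, 14), ...) {
  ds <- generate_dataset(synthetic_config(
    volume_shape = shape, n_per_class_source = n, n_per_class_target = n,
    seed = seed, ...))
  dom <- vapply(ds, `[[`, "", "domain")
  list(source = ds[dom == "source"], target = ds[dom == "target"])
}

# matching training config: encoder channels (3, 4), pooling after both
# layers -> 2^3 final grid, E = 8, heads 2; two short phases
tiny_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    input_shape = c(14, 14, 14),
    encoder = encoder_config(channels = c(3, 4), pool_after = c(1, 2)),
    heads = 2L, epochs_phase1 = 2L, epochs_phase2 = 1L,
    lr = 1e-3, lr_phase2 = 1e-4, seed = seed)
  defaults[names(args)] <- args
  do.call(train_config, defaults)
}

# central-difference gradient of a scalar function over a vector
num_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 0)
}

# simple logistic-regression probe on per-blob mean intensities; returns
# AUC on held-out source subjects (odd/even split)
linear_probe_auc <- function(samples) {
  feats <- t(vapply(samples, function(s) {
    c(blob_region_means(s$mri), blob_region_means(s$pet))
  }, numeric(8)))
  lab <- vapply(samples, function(s) as.integer(s$label), 1L)
  # classes are interleaved in generation order, so a half split keeps
  # both classes on both sides
  idx <- seq_along(lab)
  train <- idx <= length(idx) / 2
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, feats[train, ]), lab[train],
                   family = stats::binomial()))
  scores <- as.vector(cbind(1, feats[!train, ]) %*% fit$coefficients)
  rank_auc(lab[!train], scores)
}

# mean intensity in a small box around each canonical blob centre
blob_region_means <- function(vol) {
  centres <- mmdda:::BLOB_CENTRES
  shape <- dim(vol)
  vapply(seq_len(nrow(centres)), function(k) {
    ctr <- round(centres[k, ] * (shape - 1) + 1)
    lo <- pmax(ctr - 1, 1)
    hi <- pmin(ctr + 1, shape)
    mean(vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
  }, 0)
}
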