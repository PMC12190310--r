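# One serialisable run configuration covering every module, read from
# YAML with defaults filled in recursively; the CLI and the checkpoint
# format are built on it so a saved run re-executes identically.

#' Default run configuration
#'
#' Nested desk-scale defaults for every configurable key: synthetic data,
#' encoder, fusion, losses, heads, and the training schedule. The
#' full-size settings are obtained by overriding `encoder`, `train` and
#' `fusion` (see [train_config()] defaults).
#'
#' @return A nested list of class `mmdda_run_config`.
#' @export
run_config_default <- function() {
  structure(list(
    seed = 1L,
    out_dir = "runs/latest",
    synthetic = list(volume_shape = c(32, 32, 32), n_per_class_source = 8,
                     n_per_class_target = 8, class_effect = 1,
                     modality_correlation = 0.7, shift_gain = 1.5,
                     shift_smooth = 1, noise_sd = 0.1, bias_field = TRUE),
    encoder = list(channels = c(4, 8, 8), pool_after = c(1, 2, 3)),
    fusion = list(heads = 4, reduce = "mean"),
    loss = list(sigma = 1, epsilon = 1e-6,
                weights = list(cor = 1, mse = 1, cls = 1, dom = 1)),
    heads = list(units = c(128, 64, 2), dropout = 0.5, grl_weight = 0.1),
    train = list(input_shape = c(32, 32, 32), epochs_phase1 = 40,
                 epochs_phase2 = 5, lr = 1e-3, lr_phase2 = 1e-4,
                 beta1 = 0.9, beta2 = 0.999,
                 variant = "MMDDA", shuffle = TRUE)),
    class = "mmdda_run_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a run configuration from YAML
#'
#' Keys absent from the file keep their [run_config_default()] values.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Optional nested list applied on top of the file.
#' @return An `mmdda_run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  rc <- run_config_default()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_mmdda(sprintf("config file not found: %s", path), "mmdda_io_error")
    rc <- merge_config(rc, yaml::read_yaml(path))
  }
  rc <- merge_config(rc, overrides)
  class(rc) <- "mmdda_run_config"
  rc
}

#' Convert a run configuration to module configs
#'
#' @param rc An `mmdda_run_config`.
#' @return An [mmdda_train_config][train_config()].
#' @export
as_train_config <- function(rc) {
  train_config(
    input_shape = rc$train$input_shape,
    encoder = encoder_config(channels = rc$encoder$channels,
                             pool_after = rc$encoder$pool_after),
    heads = rc$fusion$heads,
    reduce = rc$fusion$reduce,
    head = head_config(units = rc$heads$units, dropout = rc$heads$dropout,
                       grl_weight = rc$heads$grl_weight),
    kernel = kernel_config(sigma = rc$loss$sigma, epsilon = rc$loss$epsilon),
    loss_weights = rc$loss$weights,
    epochs_phase1 = rc$train$epochs_phase1,
    epochs_phase2 = rc$train$epochs_phase2,
    lr = rc$train$lr, lr_phase2 = rc$train$lr_phase2,
    beta1 = rc$train$beta1, beta2 = rc$train$beta2,
    seed = rc$seed, variant = rc$train$variant, shuffle = rc$train$shuffle)
}

#' Synthetic config from a run configuration
#'
#' @param rc An `mmdda_run_config`.
#' @return An [synthetic_config()].
#' @export
as_synthetic_config <- function(rc) {
  s <- rc$synthetic
  synthetic_config(volume_shape = s$volume_shape,
                   n_per_class_source = s$n_per_class_source,
                   n_per_class_target = s$n_per_class_target,
                   class_effect = s$class_effect,
                   modality_correlation = s$modality_correlation,
                   shift_gain = s$shift_gain, shift_smooth = s$shift_smooth,
                   noise_sd = s$noise_sd, bias_field = s$bias_field,
                   seed = rc$seed)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds all parameters, running statistics, training
#' history, and the full configuration (including the seed), so a run
#' directory is self-describing and re-executable.
#'
#' @param model A trained `mmdda_model`.
#' @param path Destination file (`.rds`).
#' @return `save_checkpoint` returns the path invisibly;
#'   `load_checkpoint` the model.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    stop_mmdda(sprintf("checkpoint not found: %s", path), "mmdda_io_error")
  model <- readRDS(path)
  if (!inherits(model, "mmdda_model"))
    stop_mmdda("file is not an mmdda checkpoint", "mmdda_io_error")
  model
}
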