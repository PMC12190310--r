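# Seeded generator of paired (MRI, PET) volumes with a controllable
# class effect and source-to-target domain shift. Subjects are smooth
# ellipsoidal "brains" carrying K Gaussian blobs at fixed canonical
# positions; the blob amplitudes differ between classes (an
# atrophy/hypometabolism analogue) and are partially shared between the
# two modalities, which gives the cross-modal correlation loss real
# structure to align. Target-domain volumes are additionally blurred,
# intensity-scaled and modulated by a low-order polynomial bias field.

# canonical blob centres (relative coordinates) and class sign pattern
BLOB_CENTRES <- matrix(c(0.30, 0.30, 0.30,
                         0.70, 0.70, 0.40,
                         0.40, 0.65, 0.70,
                         0.65, 0.35, 0.65), ncol = 3, byrow = TRUE)
BLOB_SIGNS <- c(1, -1, 1, -1)

#' Synthetic dataset configuration
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' test-suite: 32^3 volumes, 8 subjects per class and domain, a class
#' effect of 1 intensity unit on the blob amplitudes, modality coupling
#' 0.7, and a target shift of gain 1.5 with 1-voxel smoothing and a
#' polynomial bias field.
#'
#' @param volume_shape Three positive voxel counts.
#' @param n_per_class_source,n_per_class_target Subjects per class in
#'   each domain.
#' @param class_effect Non-negative difference in mean blob amplitude
#'   between the two classes (intensity units). 0 makes volumes
#'   label-uninformative.
#' @param modality_correlation In `[0, 1]`: weight of the shared latent
#'   amplitude fluctuation relative to modality-private fluctuation.
#' @param shift_gain Target-domain intensity multiplier (1 = none).
#' @param shift_smooth Target-domain Gaussian blur width in voxels
#'   (0 = none).
#' @param noise_sd Voxel-wise additive noise standard deviation.
#' @param bias_field Logical; apply a seeded degree-2 polynomial bias
#'   field to target volumes.
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @return An object of class `mmdda_synthetic_config`.
#' @export
synthetic_config <- function(volume_shape = c(32, 32, 32),
                             n_per_class_source = 8,
                             n_per_class_target = 8,
                             class_effect = 1,
                             modality_correlation = 0.7,
                             shift_gain = 1.5,
                             shift_smooth = 1,
                             noise_sd = 0.1,
                             bias_field = TRUE,
                             seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape < 8))
    stop_mmdda("'volume_shape' must be 3 integers, each at least 8 voxels (blob placement)",
               "mmdda_config_error")
  check_scalar(n_per_class_source, "n_per_class_source", 1)
  check_scalar(n_per_class_target, "n_per_class_target", 1)
  check_scalar(class_effect, "class_effect", 0)
  check_scalar(modality_correlation, "modality_correlation", 0)
  if (modality_correlation > 1)
    stop_mmdda("'modality_correlation' must lie in [0, 1]", "mmdda_config_error")
  check_scalar(shift_gain, "shift_gain", 0, strict = TRUE)
  check_scalar(shift_smooth, "shift_smooth", 0)
  check_scalar(noise_sd, "noise_sd", 0, strict = TRUE)
  structure(list(volume_shape = volume_shape,
                 n_per_class_source = as.integer(n_per_class_source),
                 n_per_class_target = as.integer(n_per_class_target),
                 class_effect = class_effect,
                 modality_correlation = modality_correlation,
                 shift_gain = shift_gain, shift_smooth = shift_smooth,
                 noise_sd = noise_sd, bias_field = isTRUE(bias_field),
                 seed = as.integer(seed)),
            class = "mmdda_synthetic_config")
}

# smooth ellipsoidal background mask (1 inside, tapering at the rim)
brain_background <- function(shape) {
  u <- lapply(shape, function(n) (seq_len(n) - (n + 1) / 2) / (0.45 * n))
  r2 <- outer(outer(u[[1]]^2, u[[2]]^2, "+"), u[[3]]^2, "+")
  1 / (1 + exp((r2 - 1) * 10))
}

# unit-amplitude Gaussian blob around a relative centre
gaussian_blob <- function(shape, centre_rel, width) {
  ctr <- centre_rel * (shape - 1) + 1
  ax <- lapply(1:3, function(a) (seq_len(shape[a]) - ctr[a])^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  exp(-r2 / (2 * width^2))
}

# separable Gaussian blur along each axis via banded smoothing matrices
gaussian_smooth3d <- function(vol, sd_vox) {
  if (sd_vox <= 0) return(vol)
  d <- dim(vol)
  smat <- function(n) {
    w <- outer(seq_len(n), seq_len(n), function(i, j)
      exp(-(i - j)^2 / (2 * sd_vox^2)))
    w / rowSums(w)
  }
  # axis 1
  x <- smat(d[1]) %*% matrix(vol, d[1])
  dim(x) <- d
  # axis 2
  x <- aperm(x, c(2, 1, 3))
  x <- smat(d[2]) %*% matrix(x, d[2])
  dim(x) <- d[c(2, 1, 3)]
  x <- aperm(x, c(2, 1, 3))
  # axis 3
  x <- aperm(x, c(3, 1, 2))
  x <- smat(d[3]) %*% matrix(x, d[3])
  dim(x) <- d[c(3, 1, 2)]
  aperm(x, c(2, 3, 1))
}

# degree-2 polynomial bias field with the given monomial coefficients
polynomial_bias <- function(shape, coefs) {
  u <- lapply(shape, function(n) seq(-1, 1, length.out = n))
  ones <- lapply(shape, function(n) rep(1, n))
  mono <- list(
    list(u[[1]], ones[[2]], ones[[3]]), list(ones[[1]], u[[2]], ones[[3]]),
    list(ones[[1]], ones[[2]], u[[3]]), list(u[[1]]^2, ones[[2]], ones[[3]]),
    list(ones[[1]], u[[2]]^2, ones[[3]]), list(ones[[1]], ones[[2]], u[[3]]^2),
    list(u[[1]], u[[2]], ones[[3]]), list(u[[1]], ones[[2]], u[[3]]),
    list(ones[[1]], u[[2]], u[[3]]))
  out <- array(0, dim = shape)
  for (m in seq_along(mono))
    out <- out + coefs[m] *
      outer(outer(mono[[m]][[1]], mono[[m]][[2]]), mono[[m]][[3]])
  out
}

#' Generate a synthetic two-domain paired-volume dataset
#'
#' Produces `2 * n_per_class_source` labelled source subjects and
#' `2 * n_per_class_target` target subjects (balanced classes). Target
#' labels are retained on the sample objects but flagged held-out: the
#' trainer never reads them; they exist for evaluation only. Per subject,
#' each blob amplitude is the class mean plus a fluctuation split into a
#' component shared between MRI and PET (weight `modality_correlation`)
#' and modality-private components; target volumes are then blurred,
#' scaled by `shift_gain` and modulated by a bias field before voxel
#' noise is added.
#'
#' @param config A [synthetic_config()].
#' @return A list of subject samples (class `mmdda_dataset`); each sample
#'   is a list with `subject_id`, `mri`, `pet`, `label`, `domain` and
#'   `label_held_out`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "mmdda_synthetic_config"))
  shape <- config$volume_shape
  bg <- brain_background(shape)
  width <- 0.10 * min(shape)
  blobs <- lapply(seq_len(nrow(BLOB_CENTRES)), function(k)
    gaussian_blob(shape, BLOB_CENTRES[k, ], width))
  K <- length(blobs)
  rho <- config$modality_correlation
  amp_sd <- 0.25   # subject-to-subject amplitude fluctuation, intensity units
  base_amp <- 1

  make_subject <- function(id, label, domain) {
    ysign <- 2 * label - 1
    cls_mean <- base_amp + 0.5 * config$class_effect * ysign * BLOB_SIGNS
    shared <- rnorm(K, sd = amp_sd)
    priv_m <- rnorm(K, sd = amp_sd)
    priv_p <- rnorm(K, sd = amp_sd)
    amp_m <- cls_mean + rho * shared + sqrt(1 - rho^2) * priv_m
    amp_p <- cls_mean + rho * shared + sqrt(1 - rho^2) * priv_p
    mri <- bg
    pet <- bg
    for (k in seq_len(K)) {
      mri <- mri + amp_m[k] * blobs[[k]]
      pet <- pet + amp_p[k] * blobs[[k]]
    }
    if (domain == "target") {
      tf <- function(v) {
        v <- gaussian_smooth3d(v, config$shift_smooth)
        v <- config$shift_gain * v
        if (config$bias_field)
          v <- v + polynomial_bias(shape, rnorm(9, sd = 0.05))
        v
      }
      mri <- tf(mri)
      pet <- tf(pet)
    }
    mri <- mri + array(rnorm(prod(shape), sd = config$noise_sd), shape)
    pet <- pet + array(rnorm(prod(shape), sd = config$noise_sd), shape)
    list(subject_id = id, mri = mri, pet = pet, label = label,
         domain = domain, label_held_out = (domain == "target"))
  }

  withr::with_seed(config$seed, {
    samples <- list()
    i <- 0L
    for (dom in c("source", "target")) {
      n_pc <- if (dom == "source") config$n_per_class_source else config$n_per_class_target
      # interleave classes so truncated subsets stay balanced
      for (s in seq_len(n_pc)) for (label in c(0L, 1L)) {
        i <- i + 1L
        id <- sprintf("%s_%03d", substr(dom, 1, 3), i)
        samples[[i]] <- make_subject(id, label, dom)
      }
    }
    structure(samples, class = "mmdda_dataset", config = config)
  })
}

#' Summarise a dataset
#'
#' Counts and mean intensities per domain and class.
#'
#' @param samples A list of subject samples (e.g. from
#'   [generate_dataset()]).
#' @return A data frame with columns `domain`, `label`, `n`, `mean_mri`,
#'   `mean_pet`.
#' @export
describe_dataset <- function(samples) {
  if (length(samples) == 0)
    stop_mmdda("describe_dataset: empty sample collection", "mmdda_config_error")
  dom <- vapply(samples, `[[`, "", "domain")
  lab <- vapply(samples, function(s) {
    if (is.null(s$label) || is.na(s$label)) NA_integer_ else as.integer(s$label)
  }, 1L)
  mm <- vapply(samples, function(s) mean(s$mri), 0)
  mp <- vapply(samples, function(s) mean(s$pet), 0)
  key <- paste(dom, lab, sep = "|")
  rows <- lapply(unique(key), function(k) {
    idx <- key == k
    data.frame(domain = dom[idx][1], label = lab[idx][1], n = sum(idx),
               mean_mri = mean(mm[idx]), mean_pet = mean(mp[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$domain, out$label), , drop = FALSE]
}
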