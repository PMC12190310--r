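# Loss functions: Gaussian-kernel cross-modal correlation loss,
# feature-consistency MSE, classification and domain cross-entropies, and
# the unweighted total objective. Gradient variants used by the trainer
# live alongside the user-facing scalar versions.

#' Kernel configuration for the correlation loss
#'
#' @param sigma Standard deviation of the Gaussian kernel (width);
#'   default 1.
#' @param epsilon Small constant added inside the logarithm for numerical
#'   stability; default 1e-6.
#' @return An object of class `mmdda_kernel_config`.
#' @export
kernel_config <- function(sigma = 1, epsilon = 1e-6) {
  check_scalar(sigma, "sigma", 0, strict = TRUE)
  check_scalar(epsilon, "epsilon", 0, strict = TRUE)
  structure(list(sigma = sigma, epsilon = epsilon),
            class = "mmdda_kernel_config")
}

#' Gaussian kernel between two feature vectors
#'
#' `K(x, y) = exp(-||x - y||^2 / (2 sigma^2))`: 1 at zero distance,
#' decaying with squared Euclidean distance, symmetric in its arguments.
#'
#' @param x,y Numeric vectors of equal length.
#' @param config A [kernel_config()].
#' @return A scalar in `(0, 1]`.
#' @export
#' @examples
#' gaussian_kernel(c(1, 0), c(0, 0))  # exp(-0.5)
gaussian_kernel <- function(x, y, config = kernel_config()) {
  if (length(x) != length(y))
    stop_mmdda("gaussian_kernel: vectors differ in length", "mmdda_shape_error")
  exp(-sum((x - y)^2) / (2 * config$sigma^2))
}

#' Cross-modal correlation loss
#'
#' Entropy-style coupling of the two modality representations within a
#' batch: with `K_ij` the Gaussian kernel between the i-th MRI feature
#' vector and the j-th PET feature vector,
#' `L_cor = -sum_ij K_ij * log(K_ij + epsilon)`.
#' The sum runs over the full cross-modal Gram matrix. For a single pair
#' the map `K -> -K log(K + eps)` vanishes at both `K -> 0` and `K -> 1`
#' (up to `O(eps)`) and peaks near `K = 1/e`; the loss therefore rewards
#' either tight agreement or strong separation of the modality features,
#' a property documented rather than altered here.
#'
#' @param mri_feats,pet_feats Matrices with one flattened feature vector
#'   per row (vectors are treated as one row); equal row and column
#'   counts.
#' @param config A [kernel_config()].
#' @return A finite scalar.
#' @export
correlation_loss <- function(mri_feats, pet_feats, config = kernel_config()) {
  correlation_loss_grad(mri_feats, pet_feats, config, want_grad = FALSE)$loss
}

# loss plus gradients with respect to both feature matrices
correlation_loss_grad <- function(mri_feats, pet_feats,
                                  config = kernel_config(), want_grad = TRUE) {
  if (is.null(dim(mri_feats))) mri_feats <- matrix(mri_feats, nrow = 1)
  if (is.null(dim(pet_feats))) pet_feats <- matrix(pet_feats, nrow = 1)
  if (nrow(mri_feats) == 0 || nrow(pet_feats) == 0)
    stop_mmdda("correlation_loss: empty feature batch", "mmdda_config_error")
  if (ncol(mri_feats) != ncol(pet_feats))
    stop_mmdda("correlation_loss: feature dimensions differ", "mmdda_shape_error")
  s2 <- config$sigma^2
  # squared cross distances via the Gram expansion
  d2 <- outer(rowSums(mri_feats^2), rowSums(pet_feats^2), "+") -
    2 * mri_feats %*% t(pet_feats)
  d2 <- pmax(d2, 0)
  K <- exp(-d2 / (2 * s2))
  loss <- -sum(K * log(K + config$epsilon))
  if (!want_grad) return(list(loss = loss))
  # dL/dK = -(log(K+eps) + K/(K+eps)); dK/dx_i = -K (x_i - y_j)/sigma^2
  dLdK <- -(log(K + config$epsilon) + K / (K + config$epsilon))
  Wg <- dLdK * K / s2                      # N x M weights
  g_mri <- Wg %*% pet_feats - rowSums(Wg) * mri_feats
  g_pet <- t(Wg) %*% mri_feats - colSums(Wg) * pet_feats
  list(loss = loss, g_mri = g_mri, g_pet = g_pet)
}

#' Feature-consistency loss
#'
#' Mean squared difference between the source and target fused feature
#' vectors: `(1/d) * sum_i (FS_i - FT_i)^2`.
#'
#' @param f_s,f_t Numeric vectors of equal length `d`.
#' @return A non-negative scalar, zero iff the vectors are equal.
#' @export
consistency_loss <- function(f_s, f_t) {
  if (length(f_s) != length(f_t))
    stop_mmdda("consistency_loss: vectors differ in length", "mmdda_shape_error")
  mean((f_s - f_t)^2)
}

check_prob_rows <- function(probabilities, what) {
  if (is.null(dim(probabilities)))
    probabilities <- matrix(probabilities, nrow = 1)
  if (ncol(probabilities) != 2 ||
      any(probabilities < -1e-8) || any(probabilities > 1 + 1e-8) ||
      any(abs(rowSums(probabilities) - 1) > 1e-6))
    stop_mmdda(sprintf("%s: rows must be binary probability vectors summing to 1",
                       what), "mmdda_config_error")
  probabilities
}

#' Classification cross-entropy
#'
#' Mean negative log-probability assigned to the true class. Column 1
#' holds `P(class 0)`, column 2 `P(class 1)`; natural logarithm.
#'
#' @param probabilities `N x 2` matrix of predicted class probabilities.
#' @param labels Integer vector in `{0, 1}` of length N.
#' @return A non-negative scalar.
#' @export
classification_loss <- function(probabilities, labels) {
  probabilities <- check_prob_rows(probabilities, "classification_loss")
  if (nrow(probabilities) != length(labels) || !all(labels %in% c(0, 1)))
    stop_mmdda("classification_loss: labels must be 0/1, one per row",
               "mmdda_config_error")
  p_true <- probabilities[cbind(seq_along(labels), labels + 1L)]
  -mean(log(p_true))
}

#' Domain-discrimination cross-entropy
#'
#' Identical in form to [classification_loss()], applied to domain
#' indicators: 1 marks a source-domain sample, 0 a target-domain sample;
#' the mean runs over all `N_{S+T}` samples presented.
#'
#' @param probabilities `N x 2` matrix; column 2 is the predicted
#'   probability of source membership.
#' @param domain_labels Integer vector in `{0, 1}` (1 = source).
#' @return A non-negative scalar.
#' @export
domain_loss <- function(probabilities, domain_labels) {
  probabilities <- check_prob_rows(probabilities, "domain_loss")
  if (nrow(probabilities) != length(domain_labels) ||
      !all(domain_labels %in% c(0, 1)))
    stop_mmdda("domain_loss: domain labels must be 0/1, one per row",
               "mmdda_config_error")
  p_true <- probabilities[cbind(seq_along(domain_labels), domain_labels + 1L)]
  -mean(log(p_true))
}

#' Assemble the total training objective
#'
#' The total loss is the unweighted sum of the five components
#' (`L_cor^S + L_cor^T + L_mse + L_cls + L_dom`); components absent from
#' the current training phase enter as 0. Per-component weight hooks
#' default to 1 and exist for ablations (e.g. dropping the correlation
#' loss recovers the attention-only variant).
#'
#' @param cor_s,cor_t,mse,cls,dom Scalar loss components.
#' @param weights Named list of multipliers (`cor`, `mse`, `cls`, `dom`),
#'   each defaulting to 1.
#' @return An object of class `mmdda_loss_bundle`: the five components
#'   and `total`.
#' @export
total_loss <- function(cor_s = 0, cor_t = 0, mse = 0, cls = 0, dom = 0,
                       weights = list()) {
  w <- list(cor = 1, mse = 1, cls = 1, dom = 1)
  w[names(weights)] <- weights
  comps <- c(cor_s = cor_s, cor_t = cor_t, mse = mse, cls = cls, dom = dom)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad))
    stop_mmdda(paste0("non-finite loss component(s): ",
                      paste(bad, collapse = ", ")), "mmdda_training_error")
  total <- w$cor * (cor_s + cor_t) + w$mse * mse + w$cls * cls + w$dom * dom
  structure(list(cor_s = cor_s, cor_t = cor_t, mse = mse, cls = cls,
                 dom = dom, total = total, weights = w),
            class = "mmdda_loss_bundle")
}
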