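# Multi-head attention fusion of the two modality feature maps.
# The MRI and PET maps are concatenated along channels, reshaped to a
# (B, L, E) sequence with L = D*H*W and E = 2C, passed through one
# multi-head attention application, and reduced over the sequence axis to
# a per-subject fused vector of dimension d = E (256 in the full-size
# configuration).

#' Fusion configuration
#'
#' @param heads Number of attention heads `h`; must divide the sequence
#'   feature dimension `E = 2C`. Task defaults in the full-size model are
#'   4 (AD vs CN), 4 (MCI vs CN), 8 (AD vs MCI) and 16 (pMCI vs sMCI).
#' @param reduce How the attended `(L, E)` sequence becomes the fused
#'   vector: `"mean"` (default) averages over the sequence axis so the
#'   fused dimension is `E`; `"flatten"` concatenates the rows (dimension
#'   `L*E`), provided for sensitivity checks.
#' @return An object of class `mmdda_fusion_config`.
#' @export
fusion_config <- function(heads = 4L, reduce = c("mean", "flatten")) {
  heads <- as.integer(heads)
  check_scalar(heads, "heads", 1)
  structure(list(heads = heads, reduce = match.arg(reduce)),
            class = "mmdda_fusion_config")
}

#' Concatenate two modality feature maps into an attention sequence
#'
#' Stacks the MRI and PET maps along channels and reshapes to
#' `(B, L, E)` with `L = D*H*W` and `E = C_mri + C_pet`. Row `l` of the
#' sequence is the spatial position with (depth, height, width) indices
#' in column-major order; columns `1..C_mri` come from MRI, the rest
#' from PET.
#'
#' @param f_mri,f_pet 5-axis feature arrays `(B, C, D, H, W)` with equal
#'   batch and spatial axes.
#' @return A 3-axis array `(B, L, E)` of class `mmdda_sequence`.
#' @export
concat_reshape <- function(f_mri, f_pet) {
  dm <- dim(f_mri); dp <- dim(f_pet)
  stopifnot(length(dm) == 5, length(dp) == 5)
  if (!all(dm[c(1, 3, 4, 5)] == dp[c(1, 3, 4, 5)]))
    stop_mmdda("MRI and PET feature maps disagree in batch or spatial dims",
               "mmdda_shape_error")
  B <- dm[1]; L <- prod(dm[3:5]); E <- dm[2] + dp[2]
  out <- array(0, dim = c(B, L, E))
  for (b in seq_len(B)) {
    am <- aperm(array(f_mri[b, , , , ], dm[-1]), c(2, 3, 4, 1))  # (D,H,W,C)
    ap <- aperm(array(f_pet[b, , , , ], dp[-1]), c(2, 3, 4, 1))
    out[b, , ] <- cbind(matrix(am, nrow = L), matrix(ap, nrow = L))
  }
  class(out) <- c("mmdda_sequence", class(out))
  out
}

# inverse of the per-sample reshape inside concat_reshape: gradient on
# the (L, E) sequence mapped back to two (D, H, W, C) arrays
split_sequence_grad <- function(gseq, spatial, c_mri, c_pet) {
  gm <- array(gseq[, seq_len(c_mri)], dim = c(spatial, c_mri))
  gp <- array(gseq[, c_mri + seq_len(c_pet)], dim = c(spatial, c_pet))
  list(g_mri = gm, g_pet = gp)
}

#' Initialise attention parameters
#'
#' Square `E x E` projection matrices for query, key, value and the
#' output mix, without biases, seeded normal init scaled by `1/sqrt(E)`.
#'
#' @param E Sequence feature dimension (`2C`).
#' @param seed Optional integer seed.
#' @return A list with entries `Wq`, `Wk`, `Wv`, `Wo`.
#' @export
fusion_init <- function(E, seed = NULL) {
  with_seed_opt(seed, {
    mk <- function() matrix(rnorm(E * E, sd = 1 / sqrt(E)), E, E)
    list(Wq = mk(), Wk = mk(), Wv = mk(), Wo = mk())
  })
}

# single-sample attention forward on an (L, E) matrix
mha_fwd_one <- function(X, params, heads) {
  E <- ncol(X)
  if (E %% heads != 0)
    stop_mmdda(sprintf("feature dimension E = %d not divisible by heads = %d",
                       E, heads), "mmdda_config_error")
  dk <- E %/% heads
  Q <- X %*% params$Wq
  K <- X %*% params$Wk
  V <- X %*% params$Wv
  Hcat <- matrix(0, nrow(X), E)
  A_list <- vector("list", heads)
  for (i in seq_len(heads)) {
    cols <- ((i - 1) * dk + 1):(i * dk)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dk)
    A <- softmax_rows(S)
    A_list[[i]] <- A
    Hcat[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  out <- Hcat %*% params$Wo
  list(out = out,
       cache = list(X = X, Q = Q, K = K, V = V, Hcat = Hcat,
                    A = A_list, dk = dk, heads = heads))
}

mha_bwd_one <- function(gout, cache, params) {
  X <- cache$X; dk <- cache$dk; heads <- cache$heads
  gWo <- t(cache$Hcat) %*% gout
  gH <- gout %*% t(params$Wo)
  gQ <- gK <- gV <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(heads)) {
    cols <- ((i - 1) * dk + 1):(i * dk)
    A <- cache$A[[i]]
    gHi <- gH[, cols, drop = FALSE]
    Vi <- cache$V[, cols, drop = FALSE]
    gA <- gHi %*% t(Vi)
    gV[, cols] <- t(A) %*% gHi
    gS <- A * (gA - rowSums(gA * A))       # softmax backward, row-wise
    gS <- gS / sqrt(dk)
    gQ[, cols] <- gS %*% cache$K[, cols, drop = FALSE]
    gK[, cols] <- t(gS) %*% cache$Q[, cols, drop = FALSE]
  }
  gX <- gQ %*% t(params$Wq) + gK %*% t(params$Wk) + gV %*% t(params$Wv)
  list(gX = gX,
       grads = list(Wq = t(X) %*% gQ, Wk = t(X) %*% gK,
                    Wv = t(X) %*% gV, Wo = gWo))
}

#' Multi-head attention over a feature sequence
#'
#' One application of multi-head scaled dot-product attention: queries,
#' keys and values are linear projections of the input; per head the
#' scores `Q K' / sqrt(d_k)` are row-softmaxed into attention weights
#' (non-negative, summing to 1 per query position); head outputs are
#' concatenated and linearly mixed by `Wo`. Output shape equals input
#' shape.
#'
#' @param seq A `(B, L, E)` array from [concat_reshape()], or a single
#'   `(L, E)` matrix.
#' @param config A [fusion_config()].
#' @param params Parameters from [fusion_init()].
#' @return Array of the same shape as `seq`.
#' @export
multi_head_attention <- function(seq, config, params) {
  stopifnot(inherits(config, "mmdda_fusion_config"))
  if (is.matrix(seq))
    return(mha_fwd_one(seq, params, config$heads)$out)
  d <- dim(seq)
  stopifnot(length(d) == 3)
  out <- array(0, dim = d)
  for (b in seq_len(d[1]))
    out[b, , ] <- mha_fwd_one(matrix(seq[b, , ], d[2], d[3]),
                              params, config$heads)$out
  class(out) <- c("mmdda_sequence", class(out))
  out
}

#' Reduce an attended sequence to the fused feature vector
#'
#' With `reduce = "mean"` (the default) the sequence axis is averaged,
#' giving a fused vector of length `E` — 256 in the full-size
#' configuration. `"flatten"` concatenates the rows instead.
#'
#' @param attn_out `(B, L, E)` array or `(L, E)` matrix.
#' @param reduce `"mean"` or `"flatten"`.
#' @return Numeric matrix, one fused vector per row.
#' @export
flatten_fused <- function(attn_out, reduce = c("mean", "flatten")) {
  reduce <- match.arg(reduce)
  if (is.matrix(attn_out)) attn_out <- array(attn_out, c(1L, dim(attn_out)))
  d <- dim(attn_out)
  stopifnot(length(d) == 3)
  if (reduce == "mean") {
    out <- matrix(0, d[1], d[3])
    for (b in seq_len(d[1]))
      out[b, ] <- colMeans(matrix(attn_out[b, , ], d[2], d[3]))
  } else {
    out <- matrix(0, d[1], d[2] * d[3])
    for (b in seq_len(d[1]))
      out[b, ] <- as.vector(matrix(attn_out[b, , ], d[2], d[3]))
  }
  out
}
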