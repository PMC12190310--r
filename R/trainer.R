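# Two-phase adversarial training. Phase 1 trains the source branch
# (encoders + fusion + classifier) on labelled source subjects with
# L_cor^S + L_cls. The source weights are then shared with the target
# branch, and phase 2 trains both branches jointly on the full objective
# L_cor^S + L_cor^T + L_mse + L_cls + L_dom, with the domain loss
# reaching the encoders through the gradient-reversal layer. Batch size
# is 1; in phase 2 each step pairs one source subject with one cycling
# target subject. Target labels are never read during training.

VARIANTS <- c("SDA", "MSDA", "M3HF", "MMDDA")

#' Training configuration
#'
#' Defaults are the full-size settings: the nine-layer encoder on
#' 113 x 137 x 113 volumes, 150 + 50 epochs, Adam with learning rate
#' 9e-7 and moment decays 0.9 / 0.999, batch size 1. Desk-scale work
#' passes a reduced encoder and epoch budget (see [desk_config()]).
#'
#' @param input_shape Voxel dimensions of the input volumes.
#' @param encoder An [encoder_config()].
#' @param heads Attention head count (must divide `E = 2C`).
#' @param reduce Sequence reduction rule, `"mean"` or `"flatten"`.
#' @param head A [head_config()] used for both classifier and
#'   discriminator.
#' @param kernel A [kernel_config()] for the correlation loss.
#' @param loss_weights Named multipliers (`cor`, `mse`, `cls`, `dom`),
#'   default 1 each.
#' @param epochs_phase1,epochs_phase2 Epoch budget of the two phases.
#' @param lr Adam learning rate.
#' @param lr_phase2 Learning rate for the joint adversarial phase;
#'   `NULL` (default) reuses `lr`. At desk scale a smaller phase-2 rate
#'   preserves the full-size regime, where the tiny shared rate makes
#'   phase 2 a gentle alignment of an already-trained source model
#'   rather than a re-training.
#' @param beta1,beta2 Adam moment decay rates.
#' @param seed Integer seed governing initialisation, shuffling and
#'   dropout.
#' @param variant One of `"SDA"` (MRI only, no fusion), `"MSDA"` (plain
#'   concatenation fusion), `"M3HF"` (attention fusion, no correlation
#'   loss), `"MMDDA"` (full model).
#' @param shuffle Logical; reshuffle sample order each epoch.
#' @return An object of class `mmdda_train_config`.
#' @export
train_config <- function(input_shape = c(113, 137, 113),
                         encoder = encoder_config(),
                         heads = 4L,
                         reduce = c("mean", "flatten"),
                         head = head_config(),
                         kernel = kernel_config(),
                         loss_weights = list(),
                         epochs_phase1 = 150L, epochs_phase2 = 50L,
                         lr = 9e-7, lr_phase2 = NULL, beta1 = 0.9, beta2 = 0.999,
                         seed = 1L, variant = "MMDDA", shuffle = TRUE) {
  variant <- match.arg(variant, VARIANTS)
  w <- list(cor = 1, mse = 1, cls = 1, dom = 1)
  w[names(loss_weights)] <- loss_weights
  structure(list(input_shape = as.integer(input_shape), encoder = encoder,
                 heads = as.integer(heads), reduce = match.arg(reduce),
                 head = head, kernel = kernel, loss_weights = w,
                 epochs_phase1 = as.integer(epochs_phase1),
                 epochs_phase2 = as.integer(epochs_phase2),
                 lr = lr, lr_phase2 = lr_phase2 %||% lr,
                 beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed), variant = variant,
                 shuffle = isTRUE(shuffle)),
            class = "mmdda_train_config")
}

#' Desk-scale training preset
#'
#' A reduced configuration sized for laptop-scale experiments and the
#' test-suite: 32^3 volumes and a three-layer encoder (channels 4, 8, 8,
#' pooling after every layer) that reproduces the full-size geometry of a
#' final feature grid a few voxels across (here 2^3, so L = 8 and
#' E = 16). Phase 1 runs 40 epochs at 1e-3, a conventional Adam rate for
#' a network this size; phase 2 runs 5 epochs at 1e-4 — the joint
#' losses plateau within about five desk-scale epochs, and running far
#' past that plateau lets the unpaired feature-consistency term erode
#' class structure (see the methods vignette).
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [train_config()].
#' @return An `mmdda_train_config`.
#' @export
desk_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(input_shape = c(32, 32, 32),
                   encoder = encoder_config(channels = c(4, 8, 8),
                                            pool_after = c(1, 2, 3)),
                   heads = 4L,
                   epochs_phase1 = 40L, epochs_phase2 = 5L,
                   lr = 1e-3, lr_phase2 = 1e-4, seed = seed)
  defaults[names(args)] <- args
  do.call(train_config, defaults)
}

#' Build an untrained model
#'
#' Instantiates the four encoder branches (MRI/PET x source/target),
#' the per-domain fusion parameters, the category classifier and the
#' domain discriminator, with a seeded initialisation. Validates the
#' shape trace for the configured input size.
#'
#' @param config An [mmdda_train_config][train_config()].
#' @return An object of class `mmdda_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "mmdda_train_config"))
  tr <- shape_trace(config$encoder, config$input_shape)
  fdim <- tr[nrow(tr), ]
  C <- attr(tr, "out_channels")
  L <- prod(fdim)
  flat_dim <- C * L
  E <- 2L * C
  d_fused <- switch(config$variant,
                    SDA = flat_dim,
                    MSDA = 2L * flat_dim,
                    if (config$reduce == "mean") E else L * E)
  if (config$variant %in% c("M3HF", "MMDDA") && E %% config$heads != 0)
    stop_mmdda(sprintf("heads = %d does not divide E = %d",
                       config$heads, E), "mmdda_config_error")
  withr::with_seed(config$seed, {
    multimodal <- config$variant != "SDA"
    attention <- config$variant %in% c("M3HF", "MMDDA")
    enc <- list(mri_s = encoder_init(config$encoder),
                pet_s = if (multimodal) encoder_init(config$encoder),
                mri_t = encoder_init(config$encoder),
                pet_t = if (multimodal) encoder_init(config$encoder))
    fus <- if (attention) list(s = fusion_init(E), t = fusion_init(E))
    clf <- head_init(d_fused, config$head)
    dis <- head_init(d_fused, config$head)
    structure(list(config = config, enc = enc, fus = fus, clf = clf,
                   dis = dis,
                   dims = list(fmap = unname(fdim), C = C, L = L,
                               flat_dim = flat_dim, E = E, d_fused = d_fused),
                   phase1_done = FALSE, shared = FALSE, phase2_done = FALSE),
              class = "mmdda_model")
  })
}

# ---- forward / backward through one domain branch -------------------------

branch_fwd <- function(model, mri, pet, domain, training) {
  v <- model$config$variant
  em <- encoder_fwd(model$enc[[paste0("mri_", domain)]], mri, training)
  model$enc[[paste0("mri_", domain)]] <- em$enc
  flat_m <- as.vector(em$out)
  res <- list(flat_m = flat_m, flat_p = NULL, cache_m = em$cache,
              cache_p = NULL, mha = NULL)
  if (v == "SDA") {
    res$F <- flat_m
  } else {
    ep <- encoder_fwd(model$enc[[paste0("pet_", domain)]], pet, training)
    model$enc[[paste0("pet_", domain)]] <- ep$enc
    res$flat_p <- as.vector(ep$out)
    res$cache_p <- ep$cache
    if (v == "MSDA") {
      res$F <- c(flat_m, res$flat_p)
    } else {
      C <- model$dims$C; L <- model$dims$L
      X <- cbind(matrix(em$out, L, C), matrix(ep$out, L, C))
      at <- mha_fwd_one(X, model$fus[[domain]], model$config$heads)
      res$mha <- at$cache
      res$F <- if (model$config$reduce == "mean") colMeans(at$out)
               else as.vector(at$out)
    }
  }
  res$model <- model
  res
}

# gF: gradient on the fused vector; g_flat_m / g_flat_p: extra gradients
# on the flattened encoder outputs (correlation loss); returns a grads
# tree matching branch_params()
branch_bwd <- function(model, fw, gF, g_flat_m = NULL, g_flat_p = NULL,
                       domain = "s") {
  v <- model$config$variant
  dims <- model$dims
  sp <- dims$fmap
  grads <- list()
  add_flat <- function(g, extra) if (is.null(extra)) g else g + extra
  if (v == "SDA") {
    gm <- add_flat(gF, g_flat_m)
    grads[[paste0("enc_mri_", domain)]] <-
      encoder_bwd(model$enc[[paste0("mri_", domain)]],
                  fw$cache_m, array(gm, c(sp, dims$C)))
    return(grads)
  }
  if (v == "MSDA") {
    gm <- add_flat(gF[seq_len(dims$flat_dim)], g_flat_m)
    gp <- add_flat(gF[dims$flat_dim + seq_len(dims$flat_dim)], g_flat_p)
  } else {
    # back through the sequence reduction and attention
    L <- dims$L; E <- dims$E; C <- dims$C
    gattn <- if (model$config$reduce == "mean")
      matrix(gF, L, E, byrow = TRUE) / L
    else matrix(gF, L, E)
    mb <- mha_bwd_one(gattn, fw$mha, model$fus[[domain]])
    grads[[paste0("fus_", domain)]] <- mb$grads
    gm <- add_flat(as.vector(mb$gX[, seq_len(C)]), g_flat_m)
    gp <- add_flat(as.vector(mb$gX[, C + seq_len(C)]), g_flat_p)
  }
  grads[[paste0("enc_mri_", domain)]] <-
    encoder_bwd(model$enc[[paste0("mri_", domain)]],
                fw$cache_m, array(gm, c(sp, dims$C)))
  grads[[paste0("enc_pet_", domain)]] <-
    encoder_bwd(model$enc[[paste0("pet_", domain)]],
                fw$cache_p, array(gp, c(sp, dims$C)))
  grads
}

# ---- parameter plumbing ---------------------------------------------------

branch_param_names <- function(model, domain) {
  v <- model$config$variant
  nm <- paste0("enc_mri_", domain)
  if (v != "SDA") nm <- c(nm, paste0("enc_pet_", domain))
  if (v %in% c("M3HF", "MMDDA")) nm <- c(nm, paste0("fus_", domain))
  nm
}

collect_params <- function(model, phase) {
  p <- list()
  grab <- function(nm) {
    if (startsWith(nm, "enc_")) enc_params(model$enc[[sub("enc_", "", nm)]])
    else model$fus[[sub("fus_", "", nm)]]
  }
  for (nm in branch_param_names(model, "s")) p[[nm]] <- grab(nm)
  p$clf <- head_params(model$clf)
  if (phase == 2) {
    for (nm in branch_param_names(model, "t")) p[[nm]] <- grab(nm)
    p$dis <- head_params(model$dis)
  }
  p
}

assign_params <- function(model, p) {
  for (nm in names(p)) {
    if (startsWith(nm, "enc_")) {
      key <- sub("enc_", "", nm)
      model$enc[[key]] <- enc_set_params(model$enc[[key]], p[[nm]])
    } else if (startsWith(nm, "fus_")) {
      model$fus[[sub("fus_", "", nm)]] <- p[[nm]]
    } else if (nm == "clf") {
      model$clf <- head_set_params(model$clf, p[[nm]])
    } else if (nm == "dis") {
      model$dis <- head_set_params(model$dis, p[[nm]])
    }
  }
  model
}

zero_like_params <- function(params) tree_map(params, function(x) x * 0)

add_grads <- function(acc, g) {
  for (nm in names(g)) acc[[nm]] <- tree_map2(acc[[nm]], g[[nm]], `+`)
  acc
}

# ---- single training steps ------------------------------------------------

use_cor <- function(config) config$variant == "MMDDA" &&
  config$loss_weights$cor != 0

step_phase1 <- function(model, sample, config) {
  w <- config$loss_weights
  fw <- branch_fwd(model, sample$mri, sample$pet, "s", training = TRUE)
  model <- fw$model

  cor_s <- 0
  g_flat_m <- g_flat_p <- NULL
  if (use_cor(config)) {
    cg <- correlation_loss_grad(fw$flat_m, fw$flat_p, config$kernel)
    cor_s <- cg$loss
    g_flat_m <- w$cor * as.vector(cg$g_mri)
    g_flat_p <- w$cor * as.vector(cg$g_pet)
  }

  hf <- head_fwd(model$clf, fw$F, training = TRUE)
  p <- softmax_rows(hf$logits)
  y <- as.integer(sample$label)
  cls <- -log(p[1, y + 1L])
  onehot <- matrix(c(1 - y, y), 1, 2)
  hb <- head_bwd(model$clf, hf$cache, w$cls * (p - onehot))

  bundle <- total_loss(cor_s = cor_s, cls = cls, weights = w)
  grads <- branch_bwd(model, fw, as.vector(hb$gx), g_flat_m, g_flat_p, "s")
  grads$clf <- hb$grads
  list(model = model, grads = grads, bundle = bundle)
}

step_phase2 <- function(model, s_sample, t_sample, config) {
  w <- config$loss_weights
  lambda <- config$head$grl_weight
  fs <- branch_fwd(model, s_sample$mri, s_sample$pet, "s", training = TRUE)
  model <- fs$model
  ft <- branch_fwd(model, t_sample$mri, t_sample$pet, "t", training = TRUE)
  model <- ft$model

  cor_s <- cor_t <- 0
  gs_m <- gs_p <- gt_m <- gt_p <- NULL
  if (use_cor(config)) {
    cg_s <- correlation_loss_grad(fs$flat_m, fs$flat_p, config$kernel)
    cg_t <- correlation_loss_grad(ft$flat_m, ft$flat_p, config$kernel)
    cor_s <- cg_s$loss; cor_t <- cg_t$loss
    gs_m <- w$cor * as.vector(cg_s$g_mri); gs_p <- w$cor * as.vector(cg_s$g_pet)
    gt_m <- w$cor * as.vector(cg_t$g_mri); gt_p <- w$cor * as.vector(cg_t$g_pet)
  }

  d <- model$dims$d_fused
  diff <- fs$F - ft$F
  mse <- mean(diff^2)
  gF_s <- w$mse * 2 * diff / d
  gF_t <- -gF_s

  hf <- head_fwd(model$clf, fs$F, training = TRUE)
  p <- softmax_rows(hf$logits)
  y <- as.integer(s_sample$label)
  cls <- -log(p[1, y + 1L])
  hb <- head_bwd(model$clf, hf$cache, w$cls * (p - matrix(c(1 - y, y), 1, 2)))
  gF_s <- gF_s + as.vector(hb$gx)

  # domain discriminator on [F_S; F_T] with labels (source = 1, target = 0);
  # feature-side gradient passes the gradient-reversal layer
  feats <- rbind(gradient_reverse(fs$F, lambda), ft$F)
  df <- head_fwd(model$dis, feats, training = TRUE)
  dp <- softmax_rows(df$logits)
  dom <- -(log(dp[1, 2]) + log(dp[2, 1])) / 2
  donehot <- rbind(c(0, 1), c(1, 0))
  db <- head_bwd(model$dis, df$cache, w$dom * (dp - donehot) / 2)
  gF_s <- gF_s + grl_backward(db$gx[1, ], lambda)
  gF_t <- gF_t + grl_backward(db$gx[2, ], lambda)

  bundle <- total_loss(cor_s = cor_s, cor_t = cor_t, mse = mse,
                       cls = cls, dom = dom, weights = w)
  grads <- branch_bwd(model, fs, gF_s, gs_m, gs_p, "s")
  grads <- c(grads, branch_bwd(model, ft, gF_t, gt_m, gt_p, "t"))
  grads$clf <- hb$grads
  grads$dis <- db$grads
  list(model = model, grads = grads, bundle = bundle)
}

# ---- phases ---------------------------------------------------------------

history_row <- function(phase, epoch, bundles) {
  avg <- function(f) mean(vapply(bundles, `[[`, 0, f))
  data.frame(phase = phase, epoch = epoch,
             cor_s = avg("cor_s"), cor_t = avg("cor_t"), mse = avg("mse"),
             cls = avg("cls"), dom = avg("dom"), total = avg("total"))
}

check_finite_epoch <- function(h) {
  if (!all(is.finite(unlist(h[, -1]))))
    stop_mmdda(sprintf("non-finite loss in phase %d, epoch %d",
                       h$phase, h$epoch), "mmdda_training_error")
}

#' Phase 1: supervised source training
#'
#' One pass per epoch over the labelled source subjects (seeded shuffled
#' order), minimising `L_cor^S + L_cls` on the source branch and
#' classifier; target branches are untouched.
#'
#' @param model An [build_model()] object.
#' @param source List of labelled source samples.
#' @param config The training configuration.
#' @param seed Optional seed scoping this call; by default the current
#'   RNG stream is used (as inside [fit_mmdda()]).
#' @return The model with attached `history` (per-epoch loss components).
#' @export
train_phase1 <- function(model, source, config = model$config, seed = NULL) {
  if (!length(source))
    stop_mmdda("train_phase1: no source samples", "mmdda_config_error")
  with_seed_opt(seed, {
    params <- collect_params(model, 1)
    opt <- adam_init(params)
    hist <- list()
    for (ep in seq_len2(config$epochs_phase1)) {
      ord <- if (config$shuffle) sample.int(length(source)) else seq_along(source)
      bundles <- list()
      for (i in ord) {
        st <- step_phase1(model, source[[i]], config)
        model <- st$model
        bundles[[length(bundles) + 1L]] <- st$bundle
        upd <- adam_step(params, st$grads, opt, config$lr,
                         config$beta1, config$beta2)
        params <- upd$params
        opt <- upd$state
        model <- assign_params(model, params)
      }
      h <- history_row(1, ep, bundles)
      check_finite_epoch(h)
      hist[[ep]] <- h
    }
    model$history <- rbind(model$history, do.call(rbind, hist))
    model$phase1_done <- TRUE
    model
  })
}

#' Share source-branch weights with the target branch
#'
#' Copies the source encoder (and fusion) parameters and batch-norm
#' running statistics into the target branch. R's copy semantics
#' guarantee no aliasing: later target updates leave the source branch
#' unchanged. Calling before phase 1 is permitted (it copies the random
#' initialisation).
#'
#' @param model An `mmdda_model`.
#' @return The model with synchronised branches.
#' @export
share_weights <- function(model) {
  model$enc$mri_t <- model$enc$mri_s
  if (!is.null(model$enc$pet_s)) model$enc$pet_t <- model$enc$pet_s
  if (!is.null(model$fus)) model$fus$t <- model$fus$s
  model$shared <- TRUE
  model
}

#' Phase 2: joint adversarial training
#'
#' Each epoch pairs every source subject (seeded shuffled order) with a
#' cycling target subject and minimises the full objective; the domain
#' loss reaches the encoders through the gradient-reversal layer. Target
#' labels are never read.
#'
#' @param model A model after [share_weights()].
#' @param source,target Sample lists; target samples need no labels.
#' @inheritParams train_phase1
#' @return The model with extended `history`.
#' @export
train_phase2 <- function(model, source, target, config = model$config,
                         seed = NULL) {
  if (!length(source) || !length(target))
    stop_mmdda("train_phase2: both domains must be non-empty", "mmdda_config_error")
  if (!model$shared)
    stop_mmdda("train_phase2: call share_weights() first", "mmdda_training_error")
  with_seed_opt(seed, {
    params <- collect_params(model, 2)
    opt <- adam_init(params)
    hist <- list()
    n_steps <- max(length(source), length(target))
    for (ep in seq_len2(config$epochs_phase2)) {
      ord_s <- if (config$shuffle) sample.int(length(source)) else seq_along(source)
      ord_t <- if (config$shuffle) sample.int(length(target)) else seq_along(target)
      bundles <- list()
      for (k in seq_len(n_steps)) {
        i <- ord_s[(k - 1) %% length(source) + 1]
        j <- ord_t[(k - 1) %% length(target) + 1]
        st <- step_phase2(model, source[[i]], target[[j]], config)
        model <- st$model
        bundles[[length(bundles) + 1L]] <- st$bundle
        upd <- adam_step(params, st$grads, opt, config$lr_phase2 %||% config$lr,
                         config$beta1, config$beta2)
        params <- upd$params
        opt <- upd$state
        model <- assign_params(model, params)
      }
      h <- history_row(2, ep, bundles)
      check_finite_epoch(h)
      hist[[ep]] <- h
    }
    model$history <- rbind(model$history, do.call(rbind, hist))
    model$phase2_done <- TRUE
    model
  })
}

#' Fit the full two-phase model
#'
#' Builds the model, runs phase 1 on the source domain, shares the
#' weights, and runs phase 2 on both domains, all under `config$seed`.
#'
#' @param data List with `source` (labelled) and `target` sample lists.
#' @param config An [mmdda_train_config][train_config()].
#' @return A trained `mmdda_model`.
#' @export
fit_mmdda <- function(data, config = train_config()) {
  model <- build_model(config)
  withr::with_seed(config$seed + 1L, {
    model <- train_phase1(model, data$source, config)
    model <- share_weights(model)
    if (config$epochs_phase2 > 0)
      model <- train_phase2(model, data$source, data$target, config)
    model
  })
}

#' Predict class probabilities for samples
#'
#' Eval-mode forward pass (batch-norm running statistics, no dropout)
#' through the requested branch and the classifier.
#'
#' @param model A trained `mmdda_model`.
#' @param samples List of subject samples.
#' @param domain `"target"` (default) or `"source"` branch.
#' @return Matrix `N x 2` of class probabilities.
#' @export
predict_proba <- function(model, samples, domain = c("target", "source")) {
  domain <- substr(match.arg(domain), 1, 1)
  feats <- t(vapply(samples, function(s)
    branch_fwd(model, s$mri, s$pet, domain, training = FALSE)$F,
    numeric(model$dims$d_fused)))
  classify(feats, model$clf)
}

#' Evaluate a model on labelled samples
#'
#' @param model A trained `mmdda_model`.
#' @param samples Samples carrying labels (held-out target labels are
#'   read here, and only here).
#' @param domain Branch to evaluate through.
#' @return An [metric_report()] object.
#' @export
evaluate_model <- function(model, samples, domain = c("target", "source")) {
  domain <- match.arg(domain)
  labels <- vapply(samples, function(s) as.integer(s$label), 1L)
  if (anyNA(labels))
    stop_mmdda("evaluate_model: all samples must carry labels", "mmdda_config_error")
  proba <- predict_proba(model, samples, domain)
  metric_report(labels, proba[, 2])
}

#' Train one ablation variant and evaluate on the target domain
#'
#' `SDA` uses MRI only with no fusion; `MSDA` concatenates the two
#' modality feature maps without attention; `M3HF` uses attention fusion
#' but drops the correlation loss; `MMDDA` is the full model. All share
#' the two-phase adversarial pipeline.
#'
#' @param variant One of `"SDA"`, `"MSDA"`, `"M3HF"`, `"MMDDA"`.
#' @param data List with `source` and `target` sample lists.
#' @param config Training configuration (its `variant` is overridden).
#' @return A [metric_report()] on the target samples, with the fitted
#'   model attached as attribute `model`.
#' @export
run_variant <- function(variant, data, config = train_config()) {
  config$variant <- match.arg(variant, VARIANTS)
  model <- fit_mmdda(data, config)
  rep <- evaluate_model(model, data$target, "target")
  attr(rep, "model") <- model
  rep
}
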