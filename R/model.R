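# The full deep phase attention (DPA) model.
#
# Image pathway: three residual branches (NC, ART, PV) -> intra-phase
# attention per branch -> inter-phase attention fusing the three attended
# maps into one -> global average pooling -> FC down to a 30-dim feature.
# Clinical pathway: FC lifting the 9-element binary vector to 30.
# Fusion head: concatenation -> FC with 2 neurons -> softmax.
# Loss: two-class cross-entropy on the fused probabilities; in joint mode
# auxiliary softmax heads on both pathways contribute
# total = 1/4 L_image + 1/4 L_clinical + 1/2 L_combine.

#' Construct a DPA model
#'
#' @param depth Backbone depth (`"small"`, `"18"`, `"50"`); see
#'   [branch_config()].
#' @param input_size Image input size (H, W); defaults per depth.
#' @param clinical_dim Length of the binary clinical vector (default 9).
#' @param feature_dim Width of the per-pathway feature FC layers (default 30).
#' @param r Attention reduction ratio (default 16).
#' @param loss_mode `"joint"` (auxiliary pathway heads, weighted loss) or
#'   `"combined"` (fused cross-entropy only; no auxiliary heads).
#' @param use_image,use_clinical Enable the pathways; disabling one yields
#'   the image-only / clinical-only ablation variants.
#' @param seed Integer seed for deterministic initialization.
#' @param conv5_width Passed to [branch_config()] for depth 18.
#' @return A `dpa_model` object.
#' @export
dpa_model <- function(depth = "small", input_size = NULL, clinical_dim = 9L,
                      feature_dim = 30L, r = 16L,
                      loss_mode = c("joint", "combined"),
                      use_image = TRUE, use_clinical = TRUE, seed = 1L,
                      conv5_width = 256L) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(use_image || use_clinical)
  bcfg <- branch_config(depth, input_size, conv5_width = conv5_width)
  cfg <- list(depth = depth, input_size = bcfg$input_size,
              clinical_dim = as.integer(clinical_dim),
              feature_dim = as.integer(feature_dim), r = as.integer(r),
              loss_mode = loss_mode, use_image = use_image,
              use_clinical = use_clinical, seed = as.integer(seed),
              conv5_width = as.integer(conv5_width))
  m <- list(config = cfg)
  C <- branch_out_channels(bcfg)
  if (use_image) {
    m$branches <- lapply(1:3, function(i) build_branch(bcfg, seed = seed + i))
    m$intra <- lapply(1:3, function(i) attention_params(C, r, seed = seed + 10L + i))
    m$inter <- lapply(1:3, function(i) attention_params(C, r, seed = seed + 20L + i))
    m$image_fc <- with_seed(seed + 30L, init_fc(C, feature_dim))
    if (loss_mode == "joint") {
      m$image_head <- with_seed(seed + 31L, init_head(feature_dim, 2L))
    }
  }
  if (use_clinical) {
    m$clin_fc <- with_seed(seed + 40L, init_fc(clinical_dim, feature_dim))
    if (loss_mode == "joint") {
      m$clin_head <- with_seed(seed + 41L, init_head(feature_dim, 2L))
    }
  }
  fin <- feature_dim * (use_image + use_clinical)
  # Classifier heads start near zero so early logits are uninformative
  # (probabilities ~0.5) and the learned signal is not buried under
  # initialization noise during short fine-tuning schedules.
  m$fusion_fc <- with_seed(seed + 50L, init_head(fin, 2L))
  structure(m, class = "dpa_model")
}

#' @export
print.dpa_model <- function(x, ...) {
  cfg <- x$config
  cat("DPA model: depth ", cfg$depth, ", pathways [",
      if (cfg$use_image) "image " else "", if (cfg$use_clinical) "clinical" else "",
      "], loss mode ", cfg$loss_mode, "\n", sep = "")
  invisible(x)
}

# Full forward pass; phases is a list of three (H, W, N) image batches,
# clin an (N, 9) binary matrix (may be NULL for image-only models).
dpa_fwd <- function(model, phases, clin, training = FALSE) {
  cfg <- model$config
  out <- list()
  n <- NULL
  if (cfg$use_image) {
    if (length(phases) != 3L) stop("exactly three phase image batches required")
    bfs <- lapply(1:3, function(i) branch_fwd(phases[[i]], model$branches[[i]], training))
    ias <- lapply(1:3, function(i) intra_fwd(bfs[[i]]$out, model$intra[[i]]))
    itf <- inter_fwd(lapply(ias, `[[`, "out"), model$inter)
    gp <- gap_fwd(itf$out)
    f1 <- fc_fwd(gp$out, model$image_fc)
    r1 <- relu_fwd(f1$out)
    out$image_feature <- r1$out
    n <- nrow(r1$out)
    if (!is.null(model$image_head)) {
      h <- fc_fwd(r1$out, model$image_head)
      out$image_probs <- softmax2(h$out)
      out$image_head_cache <- h
    }
    out$image_cache <- list(bfs = bfs, ias = ias, itf = itf, gp = gp,
                            f1 = f1, r1 = r1)
  }
  if (cfg$use_clinical) {
    clin <- matrix(as.numeric(clin), ncol = cfg$clinical_dim)
    c1 <- fc_fwd(clin, model$clin_fc)
    cr <- relu_fwd(c1$out)
    out$clinical_feature <- cr$out
    if (!is.null(n) && nrow(cr$out) != n) stop("image and clinical batch sizes differ")
    if (!is.null(model$clin_head)) {
      h <- fc_fwd(cr$out, model$clin_head)
      out$clinical_probs <- softmax2(h$out)
      out$clin_head_cache <- h
    }
    out$clin_cache <- list(c1 = c1, cr = cr)
  }
  feat <- cbind(out$image_feature, out$clinical_feature)
  fz <- fc_fwd(feat, model$fusion_fc)
  out$combined_logits <- fz$out
  out$combined_probs <- softmax2(fz$out)
  out$fusion_cache <- fz
  out
}

# Backward pass for the weighted joint objective; returns a gradient tree
# mirroring the model's parameter layout.
dpa_bwd <- function(model, fw, labels, weights) {
  cfg <- model$config
  g <- list()
  gz <- ce_softmax_grad(fw$combined_probs, labels) * weights[["combine"]]
  fz <- fc_bwd(gz, model$fusion_fc, fw$fusion_cache$cache)
  g$fusion_fc <- fz$gp
  fd <- cfg$feature_dim
  col <- 0L
  if (cfg$use_image) {
    gS <- fz$gx[, col + seq_len(fd), drop = FALSE]
    col <- col + fd
    if (!is.null(model$image_head) && weights[["image"]] > 0) {
      gh <- ce_softmax_grad(fw$image_probs, labels) * weights[["image"]]
      hb <- fc_bwd(gh, model$image_head, fw$image_head_cache$cache)
      g$image_head <- hb$gp
      gS <- gS + hb$gx
    }
    ic <- fw$image_cache
    gr <- relu_bwd(gS, ic$r1$cache)
    f1 <- fc_bwd(gr, model$image_fc, ic$f1$cache)
    g$image_fc <- f1$gp
    gfused <- gap_bwd(f1$gx, ic$gp$cache)
    ib <- inter_bwd(gfused, model$inter, ic$itf$cache)
    g$inter <- ib$gps
    g$intra <- vector("list", 3L)
    g$branches <- vector("list", 3L)
    for (i in 1:3) {
      ia <- intra_bwd(ib$gxs[[i]], model$intra[[i]], ic$ias[[i]]$cache)
      g$intra[[i]] <- ia$gp
      bb <- branch_bwd(ia$gx, model$branches[[i]], ic$bfs[[i]]$cache)
      g$branches[[i]] <- bb$gp
    }
  }
  if (cfg$use_clinical) {
    gT <- fz$gx[, col + seq_len(fd), drop = FALSE]
    if (!is.null(model$clin_head) && weights[["clinical"]] > 0) {
      gh <- ce_softmax_grad(fw$clinical_probs, labels) * weights[["clinical"]]
      hb <- fc_bwd(gh, model$clin_head, fw$clin_head_cache$cache)
      g$clin_head <- hb$gp
      gT <- gT + hb$gx
    }
    cc <- fw$clin_cache
    cr <- relu_bwd(gT, cc$cr$cache)
    c1 <- fc_bwd(cr, model$clin_fc, cc$c1$cache)
    g$clin_fc <- c1$gp
  }
  g
}

# Extract / reinstall the trainable parameter tree. Branch configs and
# attention metadata stay on the model; batch-norm stats environments ride
# along inside the parameter tree but carry no gradient.
model_params <- function(model) {
  p <- list(fusion_fc = model$fusion_fc)
  if (model$config$use_image) {
    p$branches <- lapply(model$branches, `[[`, "params")
    p$intra <- lapply(model$intra, function(a) a[c("fc1", "fc2", "conv")])
    p$inter <- lapply(model$inter, function(a) a[c("fc1", "fc2", "conv")])
    p$image_fc <- model$image_fc
    p$image_head <- model$image_head
  }
  if (model$config$use_clinical) {
    p$clin_fc <- model$clin_fc
    p$clin_head <- model$clin_head
  }
  p
}

set_model_params <- function(model, p) {
  model$fusion_fc <- p$fusion_fc
  if (model$config$use_image) {
    for (i in 1:3) {
      model$branches[[i]]$params <- p$branches[[i]]
      model$intra[[i]][c("fc1", "fc2", "conv")] <- p$intra[[i]]
      model$inter[[i]][c("fc1", "fc2", "conv")] <- p$inter[[i]]
    }
    model$image_fc <- p$image_fc
    if (!is.null(p$image_head)) model$image_head <- p$image_head
  }
  if (model$config$use_clinical) {
    model$clin_fc <- p$clin_fc
    if (!is.null(p$clin_head)) model$clin_head <- p$clin_head
  }
  model
}

#' Image pathway forward pass
#'
#' Branches, intra-phase attention, inter-phase attention, global average
#' pooling and the 30-dim FC, in evaluation mode.
#'
#' @param model A `dpa_model` with the image pathway enabled.
#' @param phases List of three (H, W, N) phase image batches (NC, ART, PV).
#' @return List with `feature` (N x 30 matrix) and, for joint-loss models,
#'   `probs` (N x 2 auxiliary class probabilities).
#' @export
image_pathway_forward <- function(model, phases) {
  stopifnot(inherits(model, "dpa_model"), model$config$use_image)
  fw <- dpa_fwd(model, phases, clin = matrix(0, dim4n(phases[[1]]), model$config$clinical_dim),
                training = FALSE)
  list(feature = fw$image_feature, probs = fw$image_probs)
}

dim4n <- function(x) if (length(dim(x)) >= 3) dim(x)[3] else 1L

#' Clinical pathway forward pass
#'
#' One FC layer lifting the 9-element binary vector to the 30-dim feature,
#' with a rectifier.
#'
#' @param model A `dpa_model` with the clinical pathway enabled.
#' @param clinical Binary matrix (N, 9) or a single length-9 vector.
#' @return List with `feature` (N x 30) and, for joint-loss models, `probs`.
#' @export
clinical_pathway_forward <- function(model, clinical) {
  stopifnot(inherits(model, "dpa_model"), model$config$use_clinical)
  if (is.null(dim(clinical))) clinical <- matrix(clinical, nrow = 1)
  if (ncol(clinical) != model$config$clinical_dim) {
    stop("clinical vector must have length ", model$config$clinical_dim)
  }
  c1 <- fc_fwd(matrix(as.numeric(clinical), ncol = ncol(clinical)), model$clin_fc)
  cr <- relu_fwd(c1$out)
  out <- list(feature = cr$out)
  if (!is.null(model$clin_head)) {
    out$probs <- softmax2(fc_fwd(cr$out, model$clin_head)$out)
  }
  out
}

#' Fusion head forward pass
#'
#' Concatenates the pathway features and applies the final two-neuron FC
#' layer with softmax.
#'
#' @param model A `dpa_model`.
#' @param image_feature Matrix (N, 30) or NULL for clinical-only models.
#' @param clinical_feature Matrix (N, 30) or NULL for image-only models.
#' @return Matrix (N, 2) of class probabilities (ER, NER); rows sum to 1.
#' @export
fusion_forward <- function(model, image_feature = NULL, clinical_feature = NULL) {
  feat <- cbind(image_feature, clinical_feature)
  stopifnot(ncol(feat) == nrow(model$fusion_fc$w))
  softmax2(fc_fwd(feat, model$fusion_fc)$out)
}

#' Weighted joint loss
#'
#' Component cross-entropies of the two auxiliary pathway heads and the
#' fused head, combined as
#' `total = 1/4 L_image + 1/4 L_clinical + 1/2 L_combine`.
#'
#' @param image_probs,clinical_probs,combined_probs (N, 2) probability
#'   matrices from the three heads.
#' @param labels 0/1 outcome labels (1 = ER).
#' @return List with `L_image`, `L_clinical`, `L_combine`, `total`.
#' @export
joint_loss <- function(image_probs, clinical_probs, combined_probs, labels) {
  li <- cross_entropy(image_probs, labels)
  lc <- cross_entropy(clinical_probs, labels)
  lm <- cross_entropy(combined_probs, labels)
  list(L_image = li, L_clinical = lc, L_combine = lm,
       total = li / 4 + lc / 4 + lm / 2)
}

#' Training configuration
#'
#' @param batch_size Minibatch size (default 8).
#' @param epochs Number of passes over the training set (default 50).
#' @param lr Learning rate for the adaptive-moment optimizer (default 1e-4).
#' @param seed Seed for shuffling (and augmentation, if enabled).
#' @param loss_mode `NULL` (use the model's mode), `"joint"` or `"combined"`.
#' @param augment Apply random flips / 90-degree rotations / intensity
#'   jitter to the training images (default FALSE).
#' @param verbose Print per-epoch losses.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 8L, epochs = 50L, lr = 1e-4, seed = 1L,
                         loss_mode = NULL, augment = FALSE, verbose = FALSE) {
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lr = lr, seed = as.integer(seed), loss_mode = loss_mode,
                 augment = augment, verbose = verbose),
            class = "train_config")
}

slice_batch <- function(dataset, idx) {
  list(phases = lapply(dataset$phases, function(a) a[, , idx, drop = FALSE]),
       clinical = if (!is.null(dataset$clinical)) dataset$clinical[idx, , drop = FALSE],
       labels = dataset$labels[idx])
}

augment_batch <- function(phases) {
  # Same geometric transform for all three phases of a sample (they are
  # co-registered); independent mild intensity jitter per phase.
  n <- dim(phases[[1]])[3]
  fliph <- stats::runif(n) < 0.5
  flipv <- stats::runif(n) < 0.5
  for (p in seq_along(phases)) {
    a <- phases[[p]]
    for (s in which(fliph)) a[, , s] <- a[dim(a)[1]:1, , s]
    for (s in which(flipv)) a[, , s] <- a[, dim(a)[2]:1, s]
    a <- a + stats::rnorm(1, sd = 0.02)
    phases[[p]] <- a
  }
  phases
}

#' Train a DPA model
#'
#' Minibatch adaptive-moment (Adam) optimization of the selected loss with
#' seeded shuffling. The per-epoch history records the total loss and, in
#' joint mode, all three component losses; the weighted decomposition
#' `total = 1/4 L_image + 1/4 L_clinical + 1/2 L_combine` holds exactly in
#' every logged row.
#'
#' @param model A `dpa_model`.
#' @param dataset List with `phases` (list of three (H, W, S) arrays; NULL
#'   for clinical-only models), `clinical` (S x 9 matrix; NULL for
#'   image-only), and `labels` (length-S 0/1 vector).
#' @param config A [train_config()].
#' @return List with the trained `model` and `history` data frame.
#' @export
train_dpa <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "dpa_model"), inherits(config, "train_config"))
  n <- length(dataset$labels)
  if (n == 0) stop("empty training dataset")
  loss_mode <- config$loss_mode %||% model$config$loss_mode
  if (loss_mode == "joint" && model$config$loss_mode != "joint") {
    stop("joint loss requested but the model was built without auxiliary heads")
  }
  joint <- loss_mode == "joint" &&
    model$config$use_image && model$config$use_clinical
  weights <- if (joint) c(image = 0.25, clinical = 0.25, combine = 0.5)
             else c(image = 0, clinical = 0, combine = 1)
  params <- model_params(model)
  state <- adam_init()
  hist <- vector("list", config$epochs)
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- li <- lc <- lm <- 0
    acc <- 0
    nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      b <- slice_batch(dataset, idx)
      if (isTRUE(config$augment) && !is.null(b$phases)) {
        b$phases <- augment_batch(b$phases)
      }
      model <- set_model_params(model, params)
      fw <- dpa_fwd(model, b$phases, b$clinical, training = TRUE)
      lcomb <- cross_entropy(fw$combined_probs, b$labels)
      if (joint) {
        jl <- joint_loss(fw$image_probs, fw$clinical_probs, fw$combined_probs,
                         b$labels)
        step_loss <- jl$total
        li <- li + jl$L_image; lc <- lc + jl$L_clinical; lm <- lm + jl$L_combine
      } else {
        step_loss <- lcomb
        lm <- lm + lcomb
      }
      if (!is.finite(step_loss)) {
        stop("non-finite loss at epoch ", ep, ", batch ", nb + 1L,
             " (combined CE = ", lcomb, "); check inputs and learning rate")
      }
      tot <- tot + step_loss
      acc <- acc + mean((fw$combined_probs[, 1] >= 0.5) == (b$labels == 1))
      g <- dpa_bwd(model, fw, b$labels, weights)
      upd <- adam_step(params, g, state, lr = config$lr)
      params <- upd$params
      state <- upd$state
      nb <- nb + 1L
    }
    hist[[ep]] <- data.frame(
      epoch = ep, total = tot / nb,
      L_image = if (joint) li / nb else NA_real_,
      L_clinical = if (joint) lc / nb else NA_real_,
      L_combine = lm / nb, accuracy = acc / nb)
    if (isTRUE(config$verbose)) {
      message(sprintf("epoch %d: loss %.4f acc %.3f", ep, tot / nb, acc / nb))
    }
  }
  model <- set_model_params(model, params)
  list(model = model, history = do.call(rbind, hist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict ER probabilities
#'
#' @param model A trained `dpa_model`.
#' @param phases List of three (H, W, N) phase arrays (NULL for
#'   clinical-only models).
#' @param clinical (N, 9) binary matrix (NULL for image-only models).
#' @return Numeric vector of per-sample ER probabilities.
#' @export
predict_dpa <- function(model, phases = NULL, clinical = NULL) {
  fw <- dpa_fwd(model, phases, clinical, training = FALSE)
  as.numeric(fw$combined_probs[, 1])
}

# ---- checkpointing ------------------------------------------------------

freeze_stats <- function(p) {
  if (is.environment(p)) return(list(.bn_stats = TRUE, rm = p$rm, rv = p$rv))
  if (is.list(p)) return(lapply(p, freeze_stats))
  p
}

thaw_stats <- function(p) {
  if (is.list(p) && isTRUE(p$.bn_stats)) {
    e <- new.env(parent = emptyenv()); e$rm <- p$rm; e$rv <- p$rv
    return(e)
  }
  if (is.list(p)) {
    out <- lapply(p, thaw_stats)
    attributes(out) <- attributes(p)
    return(out)
  }
  p
}

#' Save / load a DPA model checkpoint
#'
#' The checkpoint is a single RDS container holding the config, all
#' parameters (batch-norm running statistics included), the build seed and
#' an optional training history. Loading validates the config against the
#' current package's expectations.
#'
#' @param model A `dpa_model`.
#' @param path File path.
#' @param history Optional training history to embed.
#' @return `save_dpa_model` returns `path` invisibly; `load_dpa_model`
#'   returns a list with `model` and `history`.
#' @export
save_dpa_model <- function(model, path, history = NULL) {
  obj <- list(format = "dpanet-checkpoint-1", config = model$config,
              payload = freeze_stats(unclass(model)), history = history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_dpa_model
#' @export
load_dpa_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "dpanet-checkpoint-1")) {
    stop("not a dpanet checkpoint: ", path)
  }
  model <- thaw_stats(obj$payload)
  class(model) <- "dpa_model"
  if (!identical(model$config, obj$config)) stop("checkpoint config mismatch")
  list(model = model, history = obj$history)
}
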