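#' Training configuration
#'
#' Defaults reproduce the training recipe: Adam with exponential-decay
#' rates 0.9/0.99, weight decay 0.5 (decoupled by default; unusually large
#' and worth revisiting if coupled L2 decay is selected instead), batch of
#' 16 specimens (96 images with six views), 300 epochs, a linear warmup of
#' 60 epochs followed by a poly decay of power 1.5, and label-smoothed
#' cross-entropy with smoothing 0.1. The base learning rate is a package
#' default (1e-4, common for attention models at this batch size) and is
#' NOT part of the published recipe — tune it for your data.
#'
#' @param batch_specimens Specimens per optimization step.
#' @param epochs,warmup_epochs Total and warmup epochs
#'   (`warmup_epochs < epochs`).
#' @param poly_power Exponent of the post-warmup poly decay.
#' @param base_lr Peak learning rate reached at the end of warmup.
#' @param weight_decay Decay factor applied to weight matrices only (never
#'   biases or normalization parameters).
#' @param adam_betas Length-2 vector of Adam's exponential-decay rates.
#' @param label_smoothing Smoothing mass `epsilon` in `[0, 1)`, spread
#'   uniformly over all classes including the true one.
#' @param decoupled_decay Apply weight decay decoupled from the gradient
#'   (default) rather than as L2-in-gradient.
#' @param freeze_encoder_epochs Keep the view encoder frozen (at its
#'   random initialization or loaded weights) for the first epochs while
#'   only the fusion and head train, then fine-tune jointly. Random
#'   convolutional features preserve all image statistics, so this
#'   linear-probe-style warm start lets the attention module learn
#'   cross-view relationships before the encoder starts reshaping (and
#'   potentially shrinking) its output distribution; useful on small
#'   datasets whose classes hinge on view combinations. Default 0.
#' @param seed Seed governing shuffling and augmentation draws.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_specimens = 16L, epochs = 300L,
                         warmup_epochs = 60L, poly_power = 1.5,
                         base_lr = 1e-4, weight_decay = 0.5,
                         adam_betas = c(0.9, 0.99), label_smoothing = 0.1,
                         decoupled_decay = TRUE,
                         freeze_encoder_epochs = 0L, seed = 0L) {
  if (warmup_epochs >= epochs) stop("warmup_epochs must be < epochs")
  if (label_smoothing < 0 || label_smoothing >= 1) {
    stop("label_smoothing must lie in [0, 1)")
  }
  structure(
    list(
      batch_specimens = as.integer(batch_specimens),
      epochs = as.integer(epochs),
      warmup_epochs = as.integer(warmup_epochs),
      poly_power = poly_power, base_lr = base_lr,
      weight_decay = weight_decay, adam_betas = adam_betas,
      label_smoothing = label_smoothing,
      decoupled_decay = isTRUE(decoupled_decay),
      freeze_encoder_epochs = as.integer(freeze_encoder_epochs),
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Learning rate at a given step
#'
#' Linear warmup from 0 to `base_lr` over the warmup steps, then
#' `base_lr * (1 - (t - w) / (T - w))^poly_power` down to exactly 0 at the
#' final step.
#'
#' @param step Step index `t` in `[0, total_steps]`.
#' @param config A [train_config()].
#' @param steps_per_epoch Optimization steps per epoch (default 1 treats
#'   `step` as an epoch index).
#' @return Learning rate (non-negative scalar).
#' @export
lr_at <- function(step, config, steps_per_epoch = 1L) {
  total <- config$epochs * steps_per_epoch
  w <- config$warmup_epochs * steps_per_epoch
  if (any(step > total)) stop("step exceeds total steps (", total, ")")
  if (any(step < 0)) stop("step must be >= 0")
  ifelse(
    step < w,
    config$base_lr * step / max(w, 1),
    config$base_lr * (1 - (step - w) / (total - w))^config$poly_power
  )
}

#' Label-smoothed cross-entropy
#'
#' Cross-entropy of the softmax of `logits` against the smoothed target
#' `(1 - eps) * onehot + eps / C`, averaged over rows.
#'
#' @param logits Numeric matrix (rows = samples, cols = classes) or a
#'   single logit vector.
#' @param true_class Integer class indices (1-based), one per row.
#' @param epsilon Smoothing mass in `[0, 1)`.
#' @return Mean loss (non-negative scalar).
#' @export
smoothed_cross_entropy <- function(logits, true_class, epsilon = 0.1) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  if (any(!is.finite(logits))) stop("non-finite logits")
  n <- nrow(logits)
  c_n <- ncol(logits)
  stopifnot(length(true_class) == n, epsilon >= 0, epsilon < 1)
  target <- matrix(epsilon / c_n, n, c_n)
  target[cbind(seq_len(n), true_class)] <-
    target[cbind(seq_len(n), true_class)] + (1 - epsilon)
  logp <- logits - apply(logits, 1, max)
  logp <- logp - log(rowSums(exp(logp)))
  -mean(rowSums(target * logp))
}

smoothed_target <- function(true_class, n_classes, epsilon) {
  n <- length(true_class)
  target <- matrix(epsilon / n_classes, n, n_classes)
  target[cbind(seq_len(n), true_class)] <-
    target[cbind(seq_len(n), true_class)] + (1 - epsilon)
  target
}

#' Which parameters receive weight decay
#'
#' Weight decay is restricted to multiplicative weight matrices; biases,
#' layer-norm scales/offsets and the learned token/view embeddings are
#' exempt. Exposed so the grouping can be inspected.
#'
#' @param params A model parameter tree.
#' @return A tree of the same shape with logical leaves.
#' @export
weight_decay_mask <- function(params) {
  tree_map(params, function(leaf, path) {
    nm <- path[length(path)]
    startsWith(nm, "W")
  })
}

# One Adam step over the parameter tree. Returns updated params and state.
adam_step <- function(params, grads, m, v, lr, cfg, t) {
  b1 <- cfg$adam_betas[1]
  b2 <- cfg$adam_betas[2]
  eps <- 1e-8
  wd <- cfg$weight_decay
  rec <- function(p, g, mm, vv, path) {
    if (is.list(p)) {
      out <- list(p = p, m = mm, v = vv)
      for (i in seq_along(p)) {
        nm <- names(p)[i]
        gi <- if (!is.null(nm) && nzchar(nm)) g[[nm]] else g[[i]]
        if (is.null(nm) || !nzchar(nm)) nm <- as.character(i)
        r <- rec(p[[i]], gi, mm[[i]], vv[[i]], c(path, nm))
        out$p[[i]] <- r$p
        out$m[[i]] <- r$m
        out$v[[i]] <- r$v
      }
      out
    } else {
      is_w <- startsWith(path[length(path)], "W")
      if (!cfg$decoupled_decay && is_w && wd > 0) g <- g + wd * p
      mm <- b1 * mm + (1 - b1) * g
      vv <- b2 * vv + (1 - b2) * g^2
      mhat <- mm / (1 - b1^t)
      vhat <- vv / (1 - b2^t)
      p <- p - lr * mhat / (sqrt(vhat) + eps)
      if (cfg$decoupled_decay && is_w && wd > 0) p <- p - lr * wd * p
      list(p = p, m = mm, v = vv)
    }
  }
  rec(params, grads, m, v, character())
}

zeros_like <- function(params) tree_map(params, function(leaf, path) leaf * 0)

#' Train the set classifier
#'
#' Minimizes label-smoothed cross-entropy with Adam under the warmup +
#' poly learning-rate schedule. Deterministic given the config seed. The
#' checkpoint retained is the one with the best validation top-1 (the
#' final epoch's parameters if no validation records are given).
#' Evaluation passes never apply augmentation.
#'
#' @param model An initialized `set_classifier`.
#' @param train_records,val_records Lists of multi-view records (see
#'   [load_manifest()]) with `label` fields.
#' @param config A [train_config()].
#' @param policy An [augmentation_policy()] applied per image at train
#'   time; `NULL` or [no_augmentation()] disables augmentation.
#' @param verbose Print one line per epoch.
#' @return List: `model` (best checkpoint), `log` (per-epoch data.frame of
#'   `epoch`, `loss`, `lr`, `val_top1`), `lr_steps` (per-step learning
#'   rates), `best_val_top1`.
#' @export
train_set_classifier <- function(model, train_records, val_records = NULL,
                                 config = train_config(),
                                 policy = augmentation_policy(),
                                 verbose = FALSE) {
  stopifnot(inherits(model, "set_classifier"))
  if (length(train_records) == 0) stop("empty training manifest")
  classes <- model$classes
  labels <- vapply(train_records, function(r) r$label, character(1))
  bad <- setdiff(unique(labels), classes)
  if (length(bad) > 0) {
    stop("label(s) outside the model's classes: ", paste(bad, collapse = ", "))
  }
  missing_cls <- setdiff(classes, unique(labels))
  if (length(missing_cls) > 0) {
    warning(
      "class(es) with no training examples: ",
      paste(missing_cls, collapse = ", ")
    )
  }
  y <- match(labels, classes)
  train_records <- precache_records(train_records, model$config)
  if (!is.null(val_records)) {
    val_records <- precache_records(val_records, model$config)
    y_val <- match(
      vapply(val_records, function(r) r$label, character(1)),
      classes
    )
  }
  use_aug <- !is.null(policy) &&
    any(unlist(policy[c(
      "p_rotation", "p_dropout",
      "p_perspective", "p_affine"
    )]) > 0)
  if (isTRUE(model$config$feature_norm) &&
    !isTRUE(model$feat_norm$calibrated)) {
    model <- calibrate_feature_norm(model, train_records)
  }
  n <- length(train_records)
  bs <- min(config$batch_specimens, n)
  steps_per_epoch <- ceiling(n / bs)
  m_state <- zeros_like(model$params)
  v_state <- zeros_like(model$params)
  step <- 0L
  log_rows <- vector("list", config$epochs)
  lr_steps <- numeric(0)
  best <- list(val = -Inf, params = model$params)
  fusion_parts <- intersect(
    c("blocks", "head", "cls_token", "view_emb"),
    names(model$params)
  )
  v_tags <- length(model$config$views)
  frozen_feats <- NULL
  for (epoch in seq_len(config$epochs)) {
    frozen <- epoch <= config$freeze_encoder_epochs
    if (frozen && !use_aug && is.null(frozen_feats)) {
      # encoder fixed and inputs deterministic: view features are
      # reusable across the whole frozen phase
      frozen_feats <- encode_records(model, train_records)
    }
    ord <- withr::with_seed(
      derive_seed(config$seed, 11L, epoch),
      sample.int(n)
    )
    epoch_loss <- 0
    for (bi in seq_len(steps_per_epoch)) {
      idx <- ord[((bi - 1L) * bs + 1L):min(bi * bs, n)]
      target <- smoothed_target(
        y[idx], model$config$num_classes,
        config$label_smoothing
      )
      if (frozen) {
        if (!is.null(frozen_feats)) {
          rows <- as.vector(t(outer(
            (idx - 1L) * v_tags,
            seq_len(v_tags), "+"
          )))
          feats <- frozen_feats[rows, , drop = FALSE]
        } else {
          x <- assemble_batch(
            train_records[idx], model$config,
            policy = policy,
            seed = derive_seed(config$seed, 13L, epoch, bi)
          )
          feats <- encoder_forward(model$params, model$config, x)$features
        }
        fw <- fusion_forward(
          model$params, model$config, feats, length(idx),
          keep_cache = TRUE, feat_norm = model$feat_norm
        )
        dlogits <- (fw$probs - target) / length(idx)
        grads <- fusion_backward(
          model$params, model$config, fw$cache, dlogits
        )[fusion_parts]
      } else {
        x <- assemble_batch(
          train_records[idx], model$config,
          policy = if (use_aug) policy,
          seed = derive_seed(config$seed, 13L, epoch, bi)
        )
        fw <- model_forward(model, x, length(idx), keep_cache = TRUE)
        dlogits <- (fw$probs - target) / length(idx)
        grads <- model_backward(model, fw$cache, dlogits)
      }
      logp <- fw$logits - apply(fw$logits, 1, max)
      logp <- logp - log(rowSums(exp(logp)))
      loss <- -mean(rowSums(target * logp))
      step <- step + 1L
      lr <- lr_at(step, config, steps_per_epoch)
      lr_steps[step] <- lr
      if (frozen) {
        upd <- adam_step(
          model$params[fusion_parts], grads,
          m_state[fusion_parts], v_state[fusion_parts], lr, config, step
        )
        model$params[fusion_parts] <- upd$p
        m_state[fusion_parts] <- upd$m
        v_state[fusion_parts] <- upd$v
      } else {
        upd <- adam_step(
          model$params, grads, m_state, v_state, lr, config, step
        )
        model$params <- upd$p
        m_state <- upd$m
        v_state <- upd$v
      }
      epoch_loss <- epoch_loss + loss
    }
    val_top1 <- NA_real_
    if (!is.null(val_records)) {
      probs <- predict_proba(model, val_records, bs)
      pred_idx <- max.col(probs, ties.method = "first")
      # labels absent from the training classes count as misses
      val_top1 <- mean(!is.na(y_val) & pred_idx == y_val)
      if (val_top1 >= best$val) {
        best$val <- val_top1
        best$params <- model$params
      }
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, loss = epoch_loss / steps_per_epoch, lr = lr,
      val_top1 = val_top1
    )
    if (verbose) {
      message(sprintf(
        "epoch %3d  loss %.4f  lr %.2e  val_top1 %s",
        epoch, epoch_loss / steps_per_epoch, lr,
        ifelse(is.na(val_top1), "-", sprintf("%.3f", val_top1))
      ))
    }
  }
  if (!is.null(val_records) && is.finite(best$val)) {
    model$params <- best$params
  }
  list(
    model = model, log = do.call(rbind, log_rows), lr_steps = lr_steps,
    best_val_top1 = if (!is.null(val_records)) best$val else NA_real_
  )
}

# Per-view encoder features for a record list, in manifest order:
# rows are (record 1 view 1..V, record 2 view 1..V, ...).
encode_records <- function(model, records, batch_specimens = 32L) {
  v <- length(model$config$views)
  n <- length(records)
  out <- matrix(0, n * v, model$config$embedding_dim)
  starts <- seq(1L, n, by = batch_specimens)
  for (s in starts) {
    idx <- s:min(s + batch_specimens - 1L, n)
    x <- assemble_batch(records[idx], model$config)
    enc <- encoder_forward(model$params, model$config, x)
    out[((idx[1] - 1L) * v + 1L):(idx[length(idx)] * v), ] <- enc$features
  }
  out
}

# Replace path-valued views with letterboxed arrays so epochs reuse them.
precache_records <- function(records, cfg) {
  lapply(records, function(rec) {
    rec$views <- stats::setNames(
      lapply(cfg$views, function(tag) {
        resize_pad(record_view_image(rec, tag), cfg$side)
      }),
      cfg$views
    )
    rec
  })
}
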