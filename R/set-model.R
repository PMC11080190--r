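#' Configuration of the image-set classifier
#'
#' The classifier is a shared-weight convolutional encoder applied to each
#' of the six views, followed by a transformer-style attention encoder
#' that fuses the per-view feature tokens, and a softmax head over the
#' classes. The `tiny` encoder (four stride-2 convolution stages, global
#' average pooling, projection to `embedding_dim`) is the CPU-friendly
#' default; `convnext_s_like` is the same machinery at the stage widths of
#' a ConvNeXt-S-scale backbone (96/192/384/768 channels, 512-d embedding)
#' for users with the compute to train it.
#'
#' @param encoder `"tiny"` or `"convnext_s_like"`.
#' @param side Model input side length in pixels (images are letterboxed
#'   to `side x side`).
#' @param embedding_dim Dimension `d` of the per-view and set embeddings
#'   (default 512). Must be divisible by `fusion_heads`.
#' @param encoder_channels Integer vector of channels per conv stage; the
#'   default depends on `encoder`.
#' @param fusion_layers Number of transformer encoder blocks (default 2).
#' @param fusion_heads Attention heads (default 8).
#' @param ffn_mult Feed-forward width as a multiple of `d` (default 4).
#' @param pooling `"learned_token"` (a learned aggregation token prepended
#'   to the view tokens) or `"mean"` (average of the view tokens; makes
#'   the fusion permutation-invariant when view embeddings are off).
#' @param view_embedding Add a learned per-view-tag embedding to each view
#'   token (default `TRUE`; the six views are semantically distinct).
#' @param feature_norm Standardize each encoder feature dimension (mean 0,
#'   sd 1) before fusion, using statistics calibrated once on the training
#'   set ([calibrate_feature_norm()]; done automatically by
#'   [train_set_classifier()]). Keeps the fusion input well-conditioned
#'   regardless of the encoder's output scale. Default `TRUE`.
#' @param num_classes Number of output classes `C` (default 16).
#' @param views Character vector of view tags a specimen must provide.
#' @param seed Seed for parameter initialization.
#' @return A `set_classifier_config` list.
#' @export
set_classifier_config <- function(encoder = c("tiny", "convnext_s_like"),
                                  side = 224L, embedding_dim = 512L,
                                  encoder_channels = NULL,
                                  fusion_layers = 2L, fusion_heads = 8L,
                                  ffn_mult = 4L,
                                  pooling = c("learned_token", "mean"),
                                  view_embedding = TRUE,
                                  feature_norm = TRUE,
                                  num_classes = 16L,
                                  views = view_tags(), seed = 0L) {
  encoder <- match.arg(encoder)
  pooling <- match.arg(pooling)
  if (is.null(encoder_channels)) {
    encoder_channels <- if (encoder == "convnext_s_like") {
      c(96L, 192L, 384L, 768L)
    } else {
      c(16L, 32L, 64L, 128L)
    }
  }
  if (embedding_dim %% fusion_heads != 0) {
    stop("embedding_dim must be divisible by fusion_heads")
  }
  if (num_classes < 2) stop("num_classes must be >= 2")
  if (side %/% 2^length(encoder_channels) < 1) {
    stop("side too small for ", length(encoder_channels), " conv stages")
  }
  structure(
    list(
      encoder = encoder, side = as.integer(side),
      embedding_dim = as.integer(embedding_dim),
      encoder_channels = as.integer(encoder_channels),
      fusion_layers = as.integer(fusion_layers),
      fusion_heads = as.integer(fusion_heads),
      ffn_mult = as.integer(ffn_mult),
      pooling = pooling, view_embedding = isTRUE(view_embedding),
      feature_norm = isTRUE(feature_norm),
      num_classes = as.integer(num_classes),
      views = views, seed = as.integer(seed)
    ),
    class = "set_classifier_config"
  )
}

#' Initialize a set classifier
#'
#' @param config A [set_classifier_config()].
#' @param classes Character vector of class codes, length
#'   `config$num_classes`; defaults to the tooth taxonomy's fine classes.
#' @param taxonomy Optional `label_taxonomy` for coarse-granularity
#'   evaluation; stored (with its hash) in checkpoints.
#' @return A `set_classifier` (list of `config`, `params`, `classes`,
#'   `taxonomy`).
#' @export
init_set_classifier <- function(config, classes = NULL, taxonomy = NULL) {
  if (is.null(classes)) {
    classes <- if (!is.null(taxonomy)) {
      taxonomy$fine_classes
    } else if (config$num_classes == 16) {
      tooth_taxonomy()$fine_classes
    } else {
      paste0("C", seq_len(config$num_classes))
    }
  }
  if (length(classes) != config$num_classes) {
    stop("classes length must equal config$num_classes")
  }
  params <- withr::with_seed(config$seed, init_params(config))
  structure(
    list(
      config = config, params = params, classes = classes,
      taxonomy = taxonomy,
      feat_norm = list(
        mu = numeric(config$embedding_dim),
        sd = rep(1, config$embedding_dim), calibrated = FALSE
      )
    ),
    class = "set_classifier"
  )
}

#' Calibrate the fusion-input feature standardization
#'
#' Runs the (current) encoder over the given records and stores per-
#' dimension mean and standard deviation as non-trainable buffers; the
#' fusion then consumes standardized view features. Dimensions with
#' near-zero spread are left unscaled.
#'
#' @param model A `set_classifier` with `feature_norm = TRUE`.
#' @param records Training records.
#' @return The model with calibrated buffers.
#' @export
calibrate_feature_norm <- function(model, records) {
  feats <- encode_records(model, records)
  mu <- colMeans(feats)
  sd <- apply(feats, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  model$feat_norm <- list(mu = mu, sd = sd, calibrated = TRUE)
  model
}

#' @export
print.set_classifier <- function(x, ...) {
  cat("<set_classifier> ", x$config$encoder, " encoder, d=",
    x$config$embedding_dim, ", ", x$config$fusion_layers,
    " fusion layer(s), ", x$config$num_classes, " classes, ",
    format(n_parameters(x$params), big.mark = ","), " parameters\n",
    sep = ""
  )
  invisible(x)
}

init_params <- function(cfg) {
  d <- cfg$embedding_dim
  chans <- cfg$encoder_channels
  k <- 3L
  conv <- list()
  c_in <- 3L
  for (i in seq_along(chans)) {
    fan_in <- k * k * c_in
    conv[[i]] <- list(
      W = matrix(
        stats::rnorm(fan_in * chans[i], 0, sqrt(2 / fan_in)),
        fan_in, chans[i]
      ),
      b = numeric(chans[i])
    )
    c_in <- chans[i]
  }
  dense_init <- function(n_in, n_out, scale = 1) {
    list(
      W = matrix(
        stats::rnorm(n_in * n_out, 0, scale * sqrt(2 / (n_in + n_out))),
        n_in, n_out
      ),
      b = numeric(n_out)
    )
  }
  blocks <- lapply(seq_len(cfg$fusion_layers), function(i) {
    att <- c(
      stats::setNames(dense_init(d, d), c("Wq", "bq")),
      stats::setNames(dense_init(d, d), c("Wk", "bk")),
      stats::setNames(dense_init(d, d), c("Wv", "bv")),
      stats::setNames(dense_init(d, d), c("Wo", "bo"))
    )
    ffn <- c(
      stats::setNames(dense_init(d, d * cfg$ffn_mult), c("W1", "b1")),
      stats::setNames(dense_init(d * cfg$ffn_mult, d), c("W2", "b2"))
    )
    list(
      attn = att,
      ln1 = list(gamma = rep(1, d), beta = numeric(d)),
      ffn = ffn,
      ln2 = list(gamma = rep(1, d), beta = numeric(d))
    )
  })
  params <- list(
    conv = conv,
    proj = dense_init(chans[length(chans)], d),
    blocks = blocks,
    head = dense_init(d, cfg$num_classes)
  )
  if (cfg$pooling == "learned_token") {
    params$cls_token <- matrix(stats::rnorm(d, 0, 0.02), 1, d)
  }
  if (cfg$view_embedding) {
    params$view_emb <- matrix(
      stats::rnorm(length(cfg$views) * d, 0, 0.02),
      length(cfg$views), d
    )
  }
  params
}

# ---- encoder --------------------------------------------------------------

# x: (S, S, 3, B). Returns per-image features (B x d); with cache for
# backprop, and the final feature map for spatial visualization.
encoder_forward <- function(params, cfg, x, keep_cache = FALSE) {
  caches <- list()
  h <- x
  for (i in seq_along(params$conv)) {
    cv <- conv_forward(h, params$conv[[i]]$W, params$conv[[i]]$b)
    rl <- relu_forward(cv$out)
    h <- rl$out
    if (keep_cache) caches[[i]] <- list(conv = cv$cache, relu = rl$cache)
  }
  fmap <- h
  gp <- gap_forward(h)
  pj <- dense_forward(gp$out, params$proj$W, params$proj$b)
  list(
    features = pj$out, fmap = fmap,
    cache = if (keep_cache) {
      list(stages = caches, gap = gp$cache, proj = pj$cache)
    }
  )
}

encoder_backward <- function(params, cfg, cache, dfeat) {
  pj <- dense_backward(cache$proj, dfeat)
  grads <- list(proj = list(W = pj$dW, b = pj$db))
  dh <- gap_backward(cache$gap, pj$dx)
  conv_grads <- vector("list", length(params$conv))
  for (i in rev(seq_along(params$conv))) {
    dh <- relu_backward(cache$stages[[i]]$relu, dh)
    cv <- conv_backward(cache$stages[[i]]$conv, dh)
    conv_grads[[i]] <- list(W = cv$dW, b = cv$db)
    dh <- cv$dx
  }
  grads$conv <- conv_grads
  grads
}

# ---- fusion ---------------------------------------------------------------

# feats: (B*V x d) per-view features grouped by specimen. Returns set
# embeddings (B x d), logits, probs; cache optional.
fusion_forward <- function(params, cfg, feats, n_spec, keep_cache = FALSE,
                           feat_norm = NULL) {
  d <- cfg$embedding_dim
  v <- length(cfg$views)
  has_cls <- cfg$pooling == "learned_token"
  t_tok <- v + as.integer(has_cls)
  feat_sd <- NULL
  if (isTRUE(cfg$feature_norm) && !is.null(feat_norm)) {
    feats <- sweep(sweep(feats, 2, feat_norm$mu), 2, feat_norm$sd, "/")
    feat_sd <- feat_norm$sd
  }
  tokens <- feats
  if (cfg$view_embedding) {
    tokens <- tokens + params$view_emb[rep(seq_len(v), n_spec), , drop = FALSE]
  }
  m <- matrix(0, n_spec * t_tok, d)
  for (b in seq_len(n_spec)) {
    rows <- (b - 1L) * t_tok + seq_len(t_tok)
    vi <- (b - 1L) * v + seq_len(v)
    if (has_cls) {
      m[rows[1], ] <- params$cls_token
      m[rows[-1], ] <- tokens[vi, , drop = FALSE]
    } else {
      m[rows, ] <- tokens[vi, , drop = FALSE]
    }
  }
  layer_caches <- vector("list", cfg$fusion_layers)
  for (li in seq_len(cfg$fusion_layers)) {
    p <- params$blocks[[li]]
    attn_out <- matrix(0, nrow(m), d)
    attn_caches <- vector("list", n_spec)
    for (b in seq_len(n_spec)) {
      rows <- (b - 1L) * t_tok + seq_len(t_tok)
      r <- mha_forward(m[rows, , drop = FALSE], p$attn, cfg$fusion_heads)
      attn_out[rows, ] <- r$out
      attn_caches[[b]] <- r$cache
    }
    res1 <- m + attn_out
    ln1 <- layernorm_forward(res1, p$ln1$gamma, p$ln1$beta)
    f1 <- dense_forward(ln1$out, p$ffn$W1, p$ffn$b1)
    r1 <- relu_forward(f1$out)
    f2 <- dense_forward(r1$out, p$ffn$W2, p$ffn$b2)
    res2 <- ln1$out + f2$out
    ln2 <- layernorm_forward(res2, p$ln2$gamma, p$ln2$beta)
    if (keep_cache) {
      layer_caches[[li]] <- list(
        attn = attn_caches, ln1 = ln1$cache, f1 = f1$cache,
        r1 = r1$cache, f2 = f2$cache, ln2 = ln2$cache
      )
    }
    m <- ln2$out
  }
  if (has_cls) {
    emb <- m[(seq_len(n_spec) - 1L) * t_tok + 1L, , drop = FALSE]
  } else {
    emb <- matrix(0, n_spec, d)
    for (b in seq_len(n_spec)) {
      rows <- (b - 1L) * t_tok + seq_len(t_tok)
      emb[b, ] <- colMeans(m[rows, , drop = FALSE])
    }
  }
  hd <- dense_forward(emb, params$head$W, params$head$b)
  probs <- softmax_rows(hd$out)
  list(
    emb = emb, logits = hd$out, probs = probs,
    cache = if (keep_cache) {
      list(
        layers = layer_caches, head = hd$cache, t_tok = t_tok,
        n_spec = n_spec, has_cls = has_cls, feat_sd = feat_sd
      )
    }
  )
}

fusion_backward <- function(params, cfg, cache, dlogits, demb_extra = NULL) {
  d <- cfg$embedding_dim
  v <- length(cfg$views)
  t_tok <- cache$t_tok
  n_spec <- cache$n_spec
  hd <- dense_backward(cache$head, dlogits)
  grads <- list(head = list(W = hd$dW, b = hd$db))
  demb <- hd$dx
  if (!is.null(demb_extra)) demb <- demb + demb_extra
  dm <- matrix(0, n_spec * t_tok, d)
  if (cache$has_cls) {
    dm[(seq_len(n_spec) - 1L) * t_tok + 1L, ] <- demb
  } else {
    for (b in seq_len(n_spec)) {
      rows <- (b - 1L) * t_tok + seq_len(t_tok)
      dm[rows, ] <- matrix(demb[b, ] / t_tok, t_tok, d, byrow = TRUE)
    }
  }
  block_grads <- vector("list", cfg$fusion_layers)
  for (li in rev(seq_len(cfg$fusion_layers))) {
    p <- params$blocks[[li]]
    lc <- cache$layers[[li]]
    ln2 <- layernorm_backward(lc$ln2, dm)
    dres2 <- ln2$dx
    f2 <- dense_backward(lc$f2, dres2)
    dr1 <- relu_backward(lc$r1, f2$dx)
    f1 <- dense_backward(lc$f1, dr1)
    dln1_out <- dres2 + f1$dx
    ln1 <- layernorm_backward(lc$ln1, dln1_out)
    dres1 <- ln1$dx
    dattn_in <- matrix(0, nrow(dm), d)
    ag <- NULL
    for (b in seq_len(n_spec)) {
      rows <- (b - 1L) * t_tok + seq_len(t_tok)
      r <- mha_backward(lc$attn[[b]], dres1[rows, , drop = FALSE])
      dattn_in[rows, ] <- r$dx
      g <- r[setdiff(names(r), "dx")]
      ag <- if (is.null(ag)) g else tree_map2(ag, g, `+`)
    }
    dm <- dres1 + dattn_in
    block_grads[[li]] <- list(
      attn = list(
        Wq = ag$dWq, bq = ag$dbq, Wk = ag$dWk, bk = ag$dbk,
        Wv = ag$dWv, bv = ag$dbv, Wo = ag$dWo, bo = ag$dbo
      ),
      ln1 = list(gamma = ln1$dgamma, beta = ln1$dbeta),
      ffn = list(W1 = f1$dW, b1 = f1$db, W2 = f2$dW, b2 = f2$db),
      ln2 = list(gamma = ln2$dgamma, beta = ln2$dbeta)
    )
  }
  grads$blocks <- block_grads
  # peel tokens back to per-view feature gradients
  dtokens <- matrix(0, n_spec * v, d)
  if (cache$has_cls) {
    dcls <- matrix(0, 1, d)
    for (b in seq_len(n_spec)) {
      rows <- (b - 1L) * t_tok + seq_len(t_tok)
      dcls <- dcls + dm[rows[1], , drop = FALSE]
      dtokens[(b - 1L) * v + seq_len(v), ] <- dm[rows[-1], , drop = FALSE]
    }
    grads$cls_token <- dcls
  } else {
    dtokens <- dm
  }
  if (cfg$view_embedding) {
    dve <- matrix(0, v, d)
    for (vi in seq_len(v)) {
      idx <- (seq_len(n_spec) - 1L) * v + vi
      dve[vi, ] <- colSums(dtokens[idx, , drop = FALSE])
    }
    grads$view_emb <- dve
  }
  if (!is.null(cache$feat_sd)) {
    dtokens <- sweep(dtokens, 2, cache$feat_sd, "/")
  }
  grads$dfeats <- dtokens
  grads
}

# ---- full model -----------------------------------------------------------

# x: (S, S, 3, B*V). Full differentiable pass.
model_forward <- function(model, x, n_spec, keep_cache = FALSE) {
  cfg <- model$config
  enc <- encoder_forward(model$params, cfg, x, keep_cache = keep_cache)
  fus <- fusion_forward(model$params, cfg, enc$features, n_spec,
    keep_cache = keep_cache, feat_norm = model$feat_norm
  )
  list(
    probs = fus$probs, logits = fus$logits, emb = fus$emb,
    cache = if (keep_cache) list(enc = enc$cache, fus = fus$cache)
  )
}

model_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  fg <- fusion_backward(model$params, cfg, cache$fus, dlogits)
  eg <- encoder_backward(model$params, cfg, cache$enc, fg$dfeats)
  grads <- fg[setdiff(names(fg), "dfeats")]
  grads$conv <- eg$conv
  grads$proj <- eg$proj
  grads
}

# ---- public per-record API ------------------------------------------------

#' Encode one model-ready view image into a feature vector
#'
#' All six views of a specimen pass through this same set of encoder
#' weights (weight sharing).
#'
#' @param img A `side x side x 3` model-ready image (see [resize_pad()]).
#' @param model A `set_classifier`.
#' @return Numeric vector of length `embedding_dim`.
#' @export
encode_view <- function(img, model) {
  cfg <- model$config
  d <- dim(img)
  if (length(d) != 3 || d[1] != cfg$side || d[2] != cfg$side) {
    stop(
      "expected a ", cfg$side, "x", cfg$side,
      " model-ready image, got ", paste(d, collapse = "x")
    )
  }
  x <- array(img, dim = c(d, 1))
  enc <- encoder_forward(model$params, cfg, x)
  as.numeric(enc$features[1, ])
}

#' Fuse per-view features and classify the set
#'
#' @param view_features Matrix with one row per view (in `config$views`
#'   order) and `embedding_dim` columns.
#' @param model A `set_classifier`.
#' @return List with `probabilities` (named, sums to 1) and `embedding`
#'   (the set-level representation before the output layer).
#' @export
fuse_and_classify <- function(view_features, model) {
  cfg <- model$config
  v <- length(cfg$views)
  if (!is.matrix(view_features) || nrow(view_features) != v ||
    ncol(view_features) != cfg$embedding_dim) {
    stop(
      "expected ", v, " feature vectors of length ", cfg$embedding_dim
    )
  }
  fus <- fusion_forward(model$params, cfg, view_features, 1L,
    feat_norm = model$feat_norm
  )
  probs <- as.numeric(fus$probs[1, ])
  names(probs) <- model$classes
  list(probabilities = probs, embedding = as.numeric(fus$emb[1, ]))
}

#' Forward pass over one multi-view record
#'
#' Composes [resize_pad()], [encode_view()] (shared weights across views)
#' and [fuse_and_classify()].
#'
#' @param record A multi-view record: list with `specimen_id` and `views`,
#'   a named list/vector mapping view tag to an image path or array.
#' @param model A `set_classifier`.
#' @return Named probability vector over the model's classes.
#' @export
forward_set <- function(record, model) {
  x <- assemble_batch(list(record), model$config)
  out <- model_forward(model, x, 1L)
  probs <- as.numeric(out$probs[1, ])
  names(probs) <- model$classes
  probs
}

# Load, letterbox and stack records into an (S, S, 3, B*V) array; optional
# per-image augmentation (train path only).
assemble_batch <- function(records, cfg, policy = NULL, seed = 0L) {
  v <- length(cfg$views)
  b <- length(records)
  x <- array(0, dim = c(cfg$side, cfg$side, 3, b * v))
  for (bi in seq_len(b)) {
    rec <- records[[bi]]
    for (vi in seq_len(v)) {
      tag <- cfg$views[vi]
      img <- record_view_image(rec, tag)
      img <- resize_pad(img, cfg$side)
      if (!is.null(policy)) {
        img <- augment(img, policy, seed = derive_seed(seed, bi, vi))
      }
      x[, , , (bi - 1L) * v + vi] <- img
    }
  }
  x
}

record_view_image <- function(rec, tag) {
  src <- rec$views[[tag]]
  if (is.null(src)) {
    stop(
      "specimen ", rec$specimen_id %||% "?", " is missing view '",
      tag, "'"
    )
  }
  if (is.character(src)) read_image(src) else src
}

#' Predict class probabilities for a manifest of specimens
#'
#' @param model A `set_classifier`.
#' @param records List of multi-view records (see [load_manifest()]) or a
#'   manifest data.frame.
#' @param batch_specimens Specimens per forward pass (default 16, i.e. 96
#'   images with six views).
#' @return A row-stochastic probability matrix, rows named by specimen id,
#'   columns by class code.
#' @export
predict_proba <- function(model, records, batch_specimens = 16L) {
  if (is.data.frame(records)) records <- manifest_records(records)
  n <- length(records)
  out <- matrix(0, n, model$config$num_classes,
    dimnames = list(
      vapply(records, function(r) r$specimen_id, character(1)),
      model$classes
    )
  )
  starts <- seq(1L, n, by = batch_specimens)
  for (s in starts) {
    idx <- s:min(s + batch_specimens - 1L, n)
    x <- assemble_batch(records[idx], model$config)
    fw <- model_forward(model, x, length(idx))
    out[idx, ] <- fw$probs
  }
  out
}

#' Export set-level embeddings for a manifest
#'
#' One row per specimen: the pooled representation immediately before the
#' output layer (the `d`-dimensional embedding), plus the predicted class.
#' Suitable input for a 2-D neighbor-embedding projection.
#'
#' @inheritParams predict_proba
#' @return data.frame with `specimen_id`, `predicted`, and `e1..ed`
#'   embedding columns.
#' @export
export_embeddings <- function(model, records, batch_specimens = 16L) {
  if (is.data.frame(records)) records <- manifest_records(records)
  n <- length(records)
  d <- model$config$embedding_dim
  emb <- matrix(0, n, d)
  pred <- character(n)
  starts <- seq(1L, n, by = batch_specimens)
  for (s in starts) {
    idx <- s:min(s + batch_specimens - 1L, n)
    x <- assemble_batch(records[idx], model$config)
    fw <- model_forward(model, x, length(idx))
    emb[idx, ] <- fw$emb
    pred[idx] <- model$classes[max.col(fw$probs, ties.method = "first")]
  }
  out <- data.frame(
    specimen_id = vapply(records, function(r) r$specimen_id, character(1)),
    predicted = pred, stringsAsFactors = FALSE
  )
  emb_df <- as.data.frame(emb)
  names(emb_df) <- paste0("e", seq_len(d))
  cbind(out, emb_df)
}

# ---- checkpoints ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint carries the parameters, the full resolved configuration,
#' the class codes and the taxonomy (with its hash) for provenance.
#'
#' @param model A `set_classifier`.
#' @param path Checkpoint file path (RDS).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the restored `set_classifier`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(
    params = model$params, config = model$config, classes = model$classes,
    taxonomy = model$taxonomy, feat_norm = model$feat_norm,
    taxonomy_hash = if (!is.null(model$taxonomy)) {
      taxonomy_hash(model$taxonomy)
    }
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!is.null(obj$taxonomy) &&
    !identical(taxonomy_hash(obj$taxonomy), obj$taxonomy_hash)) {
    stop("checkpoint taxonomy hash mismatch")
  }
  structure(
    list(
      config = obj$config, params = obj$params, classes = obj$classes,
      taxonomy = obj$taxonomy,
      feat_norm = obj$feat_norm %||% list(
        mu = numeric(obj$config$embedding_dim),
        sd = rep(1, obj$config$embedding_dim), calibrated = FALSE
      )
    ),
    class = "set_classifier"
  )
}
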