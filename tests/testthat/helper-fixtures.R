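# Shared fixtures: tiny model configurations, small rendered records, and
# independent metric oracles used to cross-check the implementation.

tiny_config <- function(num_classes = 3L, side = 16L, pooling = "learned_token",
                        view_embedding = TRUE, feature_norm = TRUE,
                        views = view_tags(), seed = 3L) {
  set_classifier_config(
    encoder = "tiny", side = side, embedding_dim = 8L,
    encoder_channels = c(4L, 6L), fusion_layers = 1L, fusion_heads = 2L,
    ffn_mult = 2L, pooling = pooling, view_embedding = view_embedding,
    feature_norm = feature_norm, num_classes = num_classes,
    views = views, seed = seed
  )
}

tiny_model <- function(...) {
  cfg <- tiny_config(...)
  init_set_classifier(cfg, classes = paste0("c", seq_len(cfg$num_classes)))
}

# One in-memory multi-view record rendered from a class spec.
tiny_record <- function(spec = tooth_class_specs()[["U3"]], seed = 1L,
                        id = "S0001", height = 48L, width = 64L) {
  realized <- realize_specimen(spec, seed)
  views <- stats::setNames(lapply(seq_along(view_tags()), function(vi) {
    render_view(realized, view_tags()[vi],
      jitter_seed = derive_seed(seed, vi),
      height = height, width = width
    )
  }), view_tags())
  list(specimen_id = id, label = spec$code, views = views)
}

# A list of records covering n specimens over the given specs (in-memory).
tiny_records <- function(n, specs = tooth_class_specs()[c("U1", "L5")],
                         seed = 1L, height = 48L, width = 64L) {
  lapply(seq_len(n), function(i) {
    spec <- specs[[(i - 1L) %% length(specs) + 1L]]
    tiny_record(spec,
      seed = derive_seed(seed, i), id = sprintf("S%04d", i),
      height = height, width = width
    )
  })
}

# Random row-stochastic probability matrix with class names.
random_probs <- function(n, classes, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(stats::rexp(n * length(classes)), n, length(classes))
    m <- m / rowSums(m)
    colnames(m) <- classes
    m
  })
}

# Oracle: top-k accuracy by explicit rank enumeration per row.
oracle_topk <- function(probs, labels, k) {
  hits <- vapply(seq_len(nrow(probs)), function(i) {
    p <- probs[i, ]
    rank_true <- sum(p > p[labels[i]]) + 1L
    rank_true <= k
  }, logical(1))
  mean(hits)
}

# Oracle: AUC by concordant-pair counting over all (positive, negative)
# pairs; ties count one half.
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (length(pos) == 0 || length(neg) == 0) {
    return(NA_real_)
  }
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}
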