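test_that("view encoding is deterministic, weight-shared and d-dimensional", {
  model <- tiny_model()
  img <- withr::with_seed(1, array(stats::runif(16 * 16 * 3), c(16, 16, 3)))
  f1 <- encode_view(img, model)
  f2 <- encode_view(img, model)
  expect_identical(f1, f2)
  expect_length(f1, model$config$embedding_dim)
  expect_true(all(is.finite(f1)))
  expect_error(
    encode_view(array(0, c(20, 16, 3)), model),
    "model-ready"
  )
  # weight sharing: the encoder parameter count does not depend on the
  # number of views a specimen carries
  m6 <- init_set_classifier(tiny_config(view_embedding = FALSE))
  m1 <- init_set_classifier(
    tiny_config(view_embedding = FALSE, views = "occlusal")
  )
  expect_equal(n_parameters(m6$params), n_parameters(m1$params))
  # d = 512 is the full-scale default
  expect_equal(set_classifier_config()$embedding_dim, 512L)
})

test_that("fusion outputs a distribution and validates token counts", {
  model <- tiny_model()
  feats <- withr::with_seed(2, matrix(stats::rnorm(6 * 8), 6, 8))
  out <- fuse_and_classify(feats, model)
  expect_equal(sum(out$probabilities), 1, tolerance = 1e-9)
  expect_true(all(out$probabilities >= 0))
  expect_length(out$embedding, 8)
  expect_error(fuse_and_classify(feats[1:5, ], model), "6 feature vectors")
})

test_that("symmetric pooling without view identity is permutation invariant", {
  model <- tiny_model(pooling = "mean", view_embedding = FALSE)
  feats <- withr::with_seed(3, matrix(stats::rnorm(6 * 8), 6, 8))
  base <- fuse_and_classify(feats, model)
  withr::with_seed(4, {
    for (i in 1:8) {
      perm <- sample(6)
      out <- fuse_and_classify(feats[perm, ], model)
      expect_lt(max(abs(out$probabilities - base$probabilities)), 1e-5)
      expect_lt(max(abs(out$embedding - base$embedding)), 1e-5)
    }
  })
})

test_that("view embeddings make fusion equivariant, not invariant", {
  model <- tiny_model(pooling = "mean", view_embedding = TRUE)
  feats <- withr::with_seed(5, matrix(stats::rnorm(6 * 8), 6, 8))
  base <- fuse_and_classify(feats, model)
  perm <- c(3, 1, 2, 6, 5, 4)
  # permuting features alone changes the output...
  moved <- fuse_and_classify(feats[perm, ], model)
  expect_gt(max(abs(moved$probabilities - base$probabilities)), 1e-8)
  # ...but permuting the view-identity embeddings identically restores it
  model_p <- model
  model_p$params$view_emb <- model$params$view_emb[perm, , drop = FALSE]
  restored <- fuse_and_classify(feats[perm, ], model_p)
  expect_lt(max(abs(restored$probabilities - base$probabilities)), 1e-10)
})

test_that("forward_set composes the pipeline over a six-view record", {
  model <- tiny_model()
  rec <- tiny_record()
  probs <- forward_set(rec, model)
  expect_length(probs, model$config$num_classes)
  expect_named(probs, model$classes)
  expect_equal(sum(probs), 1, tolerance = 1e-9)
  rec_bad <- rec
  rec_bad$views$mesial <- NULL
  expect_error(forward_set(rec_bad, model), "mesial")
})

test_that("batches stack 6 images per specimen and duplicate rows agree", {
  model <- tiny_model()
  recs <- tiny_records(16)
  x <- toothset:::assemble_batch(recs, model$config)
  expect_equal(dim(x), c(16, 16, 3, 96))
  dup <- predict_proba(model, c(recs[1], recs[1], recs[2]))
  expect_equal(dup[1, ], dup[2, ], tolerance = 1e-12)
})

test_that("backpropagation matches numeric gradients", {
  model <- tiny_model()
  b <- 2L
  v <- 6L
  x <- withr::with_seed(6, array(stats::runif(16 * 16 * 3 * b * v),
    c(16, 16, 3, b * v)))
  y <- c(1L, 3L)
  loss_fn <- function(params) {
    m <- model
    m$params <- params
    fw <- toothset:::model_forward(m, x, b)
    smoothed_cross_entropy(fw$logits, y, 0.1)
  }
  fw <- toothset:::model_forward(model, x, b, keep_cache = TRUE)
  target <- toothset:::smoothed_target(y, model$config$num_classes, 0.1)
  grads <- toothset:::model_backward(model, fw$cache, (fw$probs - target) / b)
  paths <- list(
    list("conv", 1L, "W"), list("proj", "W"),
    list("blocks", 1L, "attn", "Wv"), list("blocks", 1L, "ln1", "gamma"),
    list("blocks", 1L, "ffn", "W1"), list("head", "W"),
    list("cls_token"), list("view_emb")
  )
  get_leaf <- function(tree, path) {
    for (k in path) tree <- tree[[k]]
    tree
  }
  set_leaf <- function(tree, path, i, val) {
    if (length(path) == 0) {
      tree[i] <- val
      return(tree)
    }
    tree[[path[[1]]]] <- set_leaf(tree[[path[[1]]]], path[-1], i, val)
    tree
  }
  withr::with_seed(7, {
    for (path in paths) {
      leaf <- get_leaf(model$params, path)
      g <- get_leaf(grads, path)
      for (i in sample(length(leaf), 2)) {
        eps <- 1e-5
        up <- loss_fn(set_leaf(model$params, path, i, leaf[i] + eps))
        dn <- loss_fn(set_leaf(model$params, path, i, leaf[i] - eps))
        num <- (up - dn) / (2 * eps)
        denom <- max(1e-6, abs(num) + abs(g[i]))
        expect_lt(abs(num - g[i]) / denom, 1e-4)
      }
    }
  })
})

test_that("gradients reach both the encoder and the fusion module", {
  model <- tiny_model()
  recs <- tiny_records(2)
  x <- toothset:::assemble_batch(recs, model$config)
  fw <- toothset:::model_forward(model, x, 2L, keep_cache = TRUE)
  target <- toothset:::smoothed_target(c(1L, 2L), 3L, 0.1)
  grads <- toothset:::model_backward(model, fw$cache, (fw$probs - target) / 2)
  expect_gt(max(abs(grads$conv[[1]]$W)), 0)
  expect_gt(max(abs(grads$blocks[[1]]$attn$Wq)), 0)
  expect_gt(max(abs(grads$head$W)), 0)
})

test_that("checkpoints round-trip parameters, config and taxonomy", {
  model <- init_set_classifier(tiny_config(num_classes = 16),
    taxonomy = tooth_taxonomy()
  )
  rec <- tiny_record()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(forward_set(rec, back), forward_set(rec, model))
  expect_identical(back$classes, model$classes)
  # tampered taxonomy is rejected
  obj <- readRDS(path)
  obj$taxonomy$levels[["3-type"]][1] <- "M"
  saveRDS(obj, path)
  expect_error(load_checkpoint(path), "hash mismatch")
})
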