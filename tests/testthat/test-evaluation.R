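test_that("top-k accuracy follows the rank definition", {
  probs <- matrix(
    c(0.5, 0.3, 0.2, 0.2, 0.5, 0.3, 0.1, 0.2, 0.7),
    3, 3,
    byrow = TRUE, dimnames = list(NULL, c("c1", "c2", "c3"))
  )
  labels <- c("c1", "c3", "c3")
  expect_equal(topk_accuracy(probs, labels, 1), 2 / 3)
  expect_equal(topk_accuracy(probs, labels, 2), 1)
  expect_equal(topk_accuracy(probs, labels, 3), 1) # k = C is always 1
  perfect <- diag(3)
  colnames(perfect) <- c("c1", "c2", "c3")
  expect_equal(topk_accuracy(perfect, c("c1", "c2", "c3"), 1), 1)
  expect_error(topk_accuracy(probs, c("c1", "c9", "c3"), 1), "c9")
  expect_error(topk_accuracy(probs, labels, 4), "\\[1, C\\]")
  # ties resolve in favor of the true class
  tied <- matrix(c(0.5, 0.5, 0), 1, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(rank_of_true(tied, "b"), 1L)
})

test_that("top-k agrees with brute-force rank enumeration", {
  classes <- tooth_taxonomy()$fine_classes
  for (seed in 1:5) {
    probs <- random_probs(40, classes, seed)
    labels <- withr::with_seed(seed + 100, sample(classes, 40, TRUE))
    for (k in c(1, 3, 7, 16)) {
      expect_equal(
        topk_accuracy(probs, labels, k),
        oracle_topk(probs, labels, k)
      )
    }
  }
})

test_that("probability merging conserves mass and follows the taxonomy", {
  classes <- tooth_taxonomy()$fine_classes
  probs <- random_probs(10, classes, 1)
  expect_identical(regroup_probabilities(probs, "16-type"), probs)
  merged <- regroup_probabilities(probs, "3-type")
  expect_equal(unname(rowSums(merged)), rep(1, 10), tolerance = 1e-12)
  unif <- matrix(1 / 16, 1, 16, dimnames = list(NULL, classes))
  expect_equal(
    regroup_probabilities(unif, "3-type")[1, ],
    c(A = 6 / 16, P = 4 / 16, M = 6 / 16)
  )
})

test_that("confusion matrices tally reference rows against predictions", {
  classes <- c("a", "b", "c")
  labels <- c("a", "a", "b", "b", "c", "c")
  expect_equal(
    diag(confusion_matrix(labels, labels, classes)),
    c(a = 2, b = 2, c = 2)
  )
  one_col <- confusion_matrix(labels, rep("b", 6), classes)
  expect_true(all(one_col[, c("a", "c")] == 0))
  expect_equal(sum(one_col[, "b"]), 6)
  # manual tally on a hand-built example
  pred <- c("a", "b", "b", "b", "c", "a")
  cm <- confusion_matrix(labels, pred, classes)
  expect_equal(
    cm,
    matrix(c(1, 1, 0, 0, 2, 0, 1, 0, 1), 3,
      byrow = TRUE,
      dimnames = list(classes, classes)
    )
  )
  expect_equal(sum(diag(cm)) / 6, mean(labels == pred))
  expect_error(confusion_matrix(labels, pred[-1], classes), "length")
})

test_that("sensitivity and specificity follow the one-vs-rest counts", {
  cm2 <- matrix(c(8, 2, 4, 6), 2, byrow = TRUE,
    dimnames = list(c("x", "y"), c("x", "y")))
  ss <- sensitivity_specificity(cm2)
  expect_equal(unname(ss$sensitivity), c(0.8, 0.6))
  expect_equal(unname(ss$specificity), c(0.6, 0.8))
  expect_equal(ss$macro_sensitivity, 0.7)
  # TP + FN equals the row sum; TN + FP equals N minus the row sum
  n <- sum(cm2)
  for (i in 1:2) {
    tp <- cm2[i, i]
    fn <- sum(cm2[i, ]) - tp
    fp <- sum(cm2[, i]) - tp
    tn <- n - tp - fn - fp
    expect_equal(tp + fn, sum(cm2[i, ]))
    expect_equal(tn + fp, n - sum(cm2[i, ]))
  }
  perfect <- diag(c(3, 4, 5))
  dimnames(perfect) <- list(c("a", "b", "c"), c("a", "b", "c"))
  ssp <- sensitivity_specificity(perfect)
  expect_true(all(ssp$sensitivity == 1))
  expect_true(all(ssp$specificity == 1))
  # zero-support class excluded from the macro with a warning
  cm0 <- matrix(c(5, 0, 0, 0, 0, 0, 0, 0, 4), 3, byrow = TRUE,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_warning(ss0 <- sensitivity_specificity(cm0), "zero support")
  expect_true(is.na(ss0$sensitivity["b"]))
  expect_equal(ss0$macro_sensitivity, 1)
})

test_that("threshold-sweep AUC equals concordant-pair counting", {
  # worked 4-specimen example
  probs <- matrix(c(0.9, 0.8, 0.4, 0.3), 4, 1,
    dimnames = list(NULL, "pos"))
  labels <- c("pos", "neg", "pos", "neg")
  expect_equal(roc_auc(cbind(probs, neg = 1 - probs[, 1]), labels)$auc[["pos"]],
    0.75)
  # perfect separation
  sep <- cbind(pos = c(0.9, 0.8, 0.2, 0.1), neg = c(0.1, 0.2, 0.8, 0.9))
  expect_equal(roc_auc(sep, c("pos", "pos", "neg", "neg"))$auc[["pos"]], 1)
  # random instances up to N = 50: sweep equals exhaustive pair counting
  for (seed in 1:10) {
    n <- withr::with_seed(seed, sample(5:50, 1))
    probs <- random_probs(n, c("a", "b", "c"), seed)
    labels <- withr::with_seed(seed + 50, sample(c("a", "b", "c"), n, TRUE))
    res <- roc_auc(probs, labels)
    for (cl in c("a", "b", "c")) {
      pos <- labels == cl
      if (all(pos) || !any(pos)) {
        expect_true(is.na(res$auc[[cl]]))
      } else {
        expect_equal(res$auc[[cl]], oracle_auc(probs[, cl], pos),
          tolerance = 1e-12)
      }
    }
  }
})

test_that("label-independent scores give chance-level AUC", {
  withr::with_seed(11, {
    scores <- stats::runif(4000)
    labels <- sample(c("pos", "neg"), 4000, TRUE)
    res <- roc_auc(cbind(pos = scores, neg = 1 - scores), labels)
    expect_lt(abs(res$auc[["pos"]] - 0.5), 0.03)
  })
})

test_that("sweep AUC matches an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(12, {
    scores <- stats::runif(200)
    labels <- ifelse(stats::runif(200) < scores, "pos", "neg")
    ours <- roc_auc(cbind(pos = scores, neg = 1 - scores), labels)$auc[["pos"]]
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores,
      levels = c("neg", "pos"), direction = "<", quiet = TRUE
    )))
    expect_equal(ours, ref, tolerance = 1e-10)
  })
})

test_that("hierarchical reports are internally consistent", {
  classes <- tooth_taxonomy()$fine_classes
  labels <- withr::with_seed(21, sample(classes, 60, TRUE))
  # a near-perfect model: high mass on the true class
  probs <- matrix(0.2 / 15, 60, 16, dimnames = list(NULL, classes))
  probs[cbind(1:60, match(labels, classes))] <- 0.8
  rep1 <- eval_probabilities(probs, labels)
  for (g in names(rep1$granularities)) {
    r <- rep1$granularities[[g]]
    expect_equal(unname(r$topk["top1"]), 1)
    expect_equal(sum(diag(r$confusion)) / sum(r$confusion),
      unname(r$topk["top1"]))
    expect_equal(r$cohen_kappa$kappa, 1)
  }
  # noisy model: merged argmax labels can only improve top-1
  noisy <- random_probs(200, classes, 22)
  labs <- withr::with_seed(23, sample(classes, 200, TRUE))
  rep2 <- eval_probabilities(noisy, labs)
  am <- vapply(rep2$granularities, `[[`, numeric(1), "top1_argmax_merge")
  expect_gte(am[["6-type"]], am[["16-type"]])
  expect_gte(am[["3-type"]], am[["6-type"]])
  for (g in names(rep2$granularities)) {
    r <- rep2$granularities[[g]]
    expect_equal(sum(r$confusion), 200)
    expect_equal(sum(diag(r$confusion)) / 200, unname(r$topk["top1"]))
    expect_true(all(diff(r$topk) >= 0)) # top-k non-decreasing in k
  }
})

test_that("embeddings export one row per specimen at dimension d", {
  model <- tiny_model()
  recs <- tiny_records(3)
  emb <- export_embeddings(model, c(recs, recs[1]))
  expect_equal(nrow(emb), 4)
  expect_equal(sum(startsWith(names(emb), "e")), model$config$embedding_dim)
  # duplicated specimen gets an identical embedding
  expect_equal(
    as.numeric(emb[1, -(1:2)]),
    as.numeric(emb[4, -(1:2)]),
    tolerance = 1e-12
  )
})

test_that("feature heatmaps overlay the encoder's final channels", {
  model <- tiny_model()
  rec <- tiny_record()
  maps <- feature_heatmaps(model, rec, n_channels = 3)
  expect_length(maps, 3)
  for (m in maps) {
    expect_equal(dim(m), c(16, 16, 3))
    expect_true(all(m >= 0 & m <= 1 + 1e-9))
  }
  expect_error(feature_heatmaps(model, rec, n_channels = 99), "exceeds")
})
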