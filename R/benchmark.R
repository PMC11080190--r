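#' Small-scale learning benchmark on the separable synthetic preset
#'
#' The package's standard capability check: renders the four-class
#' separable preset (70 specimens per class, 200 train / 80 test), trains
#' the tiny set classifier for ten epochs, and reports test accuracy —
#' overall and on the view-complementary pair `P1`/`P2`, optionally
#' against a single-view (occlusal-only) baseline trained with the same
#' recipe. The pair can only be solved by combining top-down and side
#' views, so the margin over the baseline isolates the value of set
#' fusion.
#'
#' The fixed small-scale recipe: input side 64 px, embedding 32, two
#' fusion layers of four heads, batch of 8 specimens, base learning rate
#' 3e-3 (poly 0.9, one warmup epoch), weight decay 0.05, label smoothing
#' 0.1, encoder frozen for the first five epochs (linear-probe warm
#' start), no augmentation.
#'
#' @param seed Root seed for data generation and training.
#' @param dir Directory for the rendered dataset (a temporary directory
#'   by default).
#' @param n_per_class Specimens per class (default 70).
#' @param with_baseline Also train the occlusal-only baseline.
#' @param verbose Print epoch logs.
#' @return List: `top1` (overall test accuracy), `pair_top1`, and with
#'   the baseline `baseline_top1`, `baseline_pair_top1`; plus `fit` (the
#'   set-model training result) and `test_records`.
#' @export
run_separable_benchmark <- function(seed = 1L, dir = tempfile("sep4_"),
                                    n_per_class = 70L,
                                    with_baseline = FALSE,
                                    verbose = FALSE) {
  specs <- separable_class_specs()
  ds <- generate_dataset(specs, n_per_class,
    dir = dir,
    train_fraction = 200 / 280, seed = seed
  )
  train_recs <- manifest_records(ds$train, taxonomy = NULL)
  test_recs <- manifest_records(ds$test, taxonomy = NULL)
  test_lab <- vapply(test_recs, function(r) r$label, character(1))
  pair_idx <- test_lab %in% c("P1", "P2")
  train_one <- function(views) {
    cfg <- set_classifier_config(
      encoder = "tiny", side = 64, embedding_dim = 32,
      encoder_channels = c(8, 16, 32, 32), fusion_layers = 2,
      fusion_heads = 4, pooling = "learned_token", view_embedding = TRUE,
      num_classes = 4, views = views, seed = seed
    )
    model <- init_set_classifier(cfg, classes = sort(names(specs)))
    tc <- train_config(
      batch_specimens = 8, epochs = 10, warmup_epochs = 1,
      base_lr = 3e-3, poly_power = 0.9, weight_decay = 0.05,
      label_smoothing = 0.1, freeze_encoder_epochs = 5, seed = seed
    )
    train_set_classifier(model, train_recs, test_recs,
      config = tc,
      policy = no_augmentation(), verbose = verbose
    )
  }
  fit <- train_one(view_tags())
  probs <- predict_proba(fit$model, test_recs)
  pred <- colnames(probs)[max.col(probs, ties.method = "first")]
  out <- list(
    top1 = mean(pred == test_lab),
    pair_top1 = mean(pred[pair_idx] == test_lab[pair_idx]),
    fit = fit, test_records = test_recs
  )
  if (with_baseline) {
    bfit <- train_one("occlusal")
    bprobs <- predict_proba(bfit$model, test_recs)
    bpred <- colnames(bprobs)[max.col(bprobs, ties.method = "first")]
    out$baseline_top1 <- mean(bpred == test_lab)
    out$baseline_pair_top1 <- mean(bpred[pair_idx] == test_lab[pair_idx])
  }
  out
}
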