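test_that("manifests load from CSV and JSON with validation", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(tooth_class_specs()[c("U2", "L6")], 2, dir,
    train_fraction = 0.5, seed = 3, height = 24, width = 32
  )
  recs <- load_manifest(file.path(dir, "manifest.csv"))
  expect_length(recs, 4)
  expect_named(recs[[1]], c("specimen_id", "label", "views"))
  expect_setequal(names(recs[[1]]$views), view_tags())
  recs_json <- load_manifest(file.path(dir, "manifest.json"))
  expect_equal(
    vapply(recs_json, function(r) r$label, character(1)),
    vapply(recs, function(r) r$label, character(1))
  )
  # empty manifest is valid
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("specimen_id,label,view,path", empty)
  expect_length(load_manifest(empty), 0)
  # a specimen missing one view is rejected, naming the absent tag
  df <- ds$manifest[-3, ] # drop one buccal row
  bad <- withr::local_tempfile(fileext = ".csv")
  write_manifest(df, bad)
  expect_error(load_manifest(bad), "buccal")
  # unknown view tags are rejected
  df2 <- ds$manifest
  df2$view[1] <- "frontal"
  expect_error(manifest_records(df2), "frontal")
  # FDI labels normalize on load
  df3 <- ds$manifest
  df3$label <- ifelse(df3$label == "U2", "12", "36")
  recs3 <- manifest_records(df3)
  expect_setequal(
    unique(vapply(recs3, function(r) r$label, character(1))),
    c("U2", "L6")
  )
})

test_that("evaluation reports round-trip through JSON without NaN", {
  classes <- tooth_taxonomy()$fine_classes
  probs <- random_probs(40, classes, 31)
  labels <- withr::with_seed(32, sample(classes[1:10], 40, TRUE))
  rep1 <- suppressWarnings(eval_probabilities(probs, labels))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, path, extra = list(config_hash = "abc123"))
  txt <- paste(readLines(path), collapse = "")
  expect_false(grepl("NaN", txt))
  expect_true(grepl("null", txt)) # degenerate AUCs serialized as null
  expect_true(grepl("abc123", txt))
  rep2 <- read_report(path)
  expect_equal(rep2$n, rep1$n)
  for (g in names(rep1$granularities)) {
    r1 <- rep1$granularities[[g]]
    r2 <- rep2$granularities[[g]]
    expect_equal(r2$confusion, r1$confusion)
    expect_equal(unname(r2$topk), unname(r1$topk), tolerance = 1e-12)
    expect_equal(unname(r2$auc), unname(r1$auc), tolerance = 1e-12)
    expect_equal(r2$cohen_kappa$kappa, r1$cohen_kappa$kappa,
      tolerance = 1e-12)
    expect_equal(r2$macro_sensitivity, r1$macro_sensitivity,
      tolerance = 1e-12)
  }
})

test_that("run configurations merge defaults and reject unknown keys", {
  cfg <- load_run_config(NULL)
  expect_equal(cfg$train$epochs, 300L)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 5, train = list(epochs = 2)), path)
  cfg2 <- load_run_config(path)
  expect_equal(cfg2$seed, 5)
  expect_equal(cfg2$train$epochs, 2)
  expect_equal(cfg2$train$warmup_epochs, 60L) # untouched default
  yaml::write_yaml(list(trian = list(epochs = 2)), path)
  expect_error(load_run_config(path), "unknown configuration key")
  yaml::write_yaml(list(train = list(epoch = 2)), path)
  expect_error(load_run_config(path), "config\\$train")
  expect_match(config_hash(cfg), "^[0-9a-f]{16}$")
  expect_false(config_hash(cfg) == config_hash(cfg2))
})

test_that("the CLI drives the full pipeline end to end", {
  base <- withr::local_tempdir()
  data_dir <- file.path(base, "data")
  cfg_path <- file.path(base, "run.yaml")
  yaml::write_yaml(list(
    seed = 11,
    data = list(n_per_class = 1, height = 64, width = 96),
    model = list(
      side = 32, embedding_dim = 16, fusion_layers = 1,
      fusion_heads = 2
    ),
    train = list(batch_specimens = 4, epochs = 1, warmup_epochs = 0)
  ), cfg_path)

  gen <- toothset_cli(c(
    "generate", "--config", cfg_path, "--out", data_dir
  ))
  expect_equal(length(unique(gen$manifest$specimen_id)), 16)
  expect_equal(nrow(gen$manifest), 96)

  # simulated annotations for the raw test split
  test_recs <- load_manifest(file.path(data_dir, "test.csv"))
  truth <- stats::setNames(
    vapply(test_recs, function(r) r$label, character(1)),
    vapply(test_recs, function(r) r$specimen_id, character(1))
  )
  ann <- simulate_annotators(truth, default_rater_models(), seed = 12)
  ann_path <- file.path(base, "annotations.csv")
  write_annotations(ann, ann_path)

  ref_dir <- file.path(base, "refined")
  ref <- toothset_cli(c(
    "refine-labels", "--config", cfg_path,
    "--annotations", ann_path, "--out", ref_dir
  ))
  expect_equal(ref$kept + ref$removed, length(test_recs))
  expect_true(file.exists(file.path(ref_dir, "pgt_labels.csv")))
  expect_true(file.exists(file.path(ref_dir, "refinement_report.json")))

  run_dir <- file.path(base, "run")
  fit <- suppressWarnings(suppressMessages(toothset_cli(c(
    "train", "--config", cfg_path,
    "--train", file.path(data_dir, "train.csv"),
    "--val", file.path(data_dir, "test.csv"),
    "--out", run_dir
  ))))
  expect_true(file.exists(file.path(run_dir, "checkpoint.rds")))
  expect_true(file.exists(file.path(run_dir, "metrics.csv")))
  expect_true(file.exists(file.path(run_dir, "resolved_config.yaml")))

  pred_path <- file.path(base, "probs.csv")
  probs <- suppressMessages(toothset_cli(c(
    "predict", "--checkpoint", file.path(run_dir, "checkpoint.rds"),
    "--manifest", file.path(data_dir, "test.csv"),
    "--out", pred_path
  )))
  expect_true(file.exists(pred_path))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)),
    tolerance = 1e-9)

  eval_dir <- file.path(base, "eval")
  rep <- suppressWarnings(suppressMessages(toothset_cli(c(
    "evaluate", "--checkpoint", file.path(run_dir, "checkpoint.rds"),
    "--manifest", file.path(data_dir, "test.csv"),
    "--pgt", file.path(ref_dir, "pgt_labels.csv"),
    "--out", eval_dir
  ))))
  expect_true(file.exists(file.path(eval_dir, "eval_report.json")))
  expect_s3_class(rep, "eval_report")

  agr_path <- file.path(base, "agreement.csv")
  agr <- suppressMessages(toothset_cli(c(
    "agreement", "--config", cfg_path,
    "--annotations", ann_path, "--out", agr_path
  )))
  expect_equal(nrow(agr), 3)
  expect_true(file.exists(agr_path))
})

test_that("identical seed and config reproduce refinement and reports", {
  truth <- withr::with_seed(41, {
    sample(tooth_taxonomy()$fine_classes, 30, TRUE)
  })
  a1 <- simulate_annotators(truth, default_rater_models(), seed = 42)
  a2 <- simulate_annotators(truth, default_rater_models(), seed = 42)
  expect_identical(a1, a2)
  r1 <- refine(a1)
  r2 <- refine(a2)
  expect_identical(r1$outcomes, r2$outcomes)
})
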