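test_that("rendering is deterministic and view evidence is partitioned", {
  spec <- class_spec("X", cusp_count = 3, root_count = 1,
    jitter = list(size = 0, pos = 0, noise = 0.02))
  a <- render_view(spec, "occlusal", 7L, height = 48, width = 64)
  b <- render_view(spec, "occlusal", 7L, height = 48, width = 64)
  expect_identical(a, b)

  zero_jit <- list(size = 0, pos = 0, noise = 0)
  s3 <- class_spec("X", 3, 1, jitter = zero_jit)
  s4 <- class_spec("X", 4, 1, jitter = zero_jit)
  # cusp evidence present in the occlusal view
  expect_false(identical(
    render_view(s3, "occlusal", 1L, 48, 64),
    render_view(s4, "occlusal", 1L, 48, 64)
  ))
  # root count must not leak into top-down views
  r1 <- class_spec("X", 3, 1, jitter = zero_jit)
  r2 <- class_spec("X", 3, 2, jitter = zero_jit)
  expect_identical(
    render_view(r1, "occlusal", 1L, 48, 64),
    render_view(r2, "occlusal", 1L, 48, 64)
  )
  # cusp count must not leak into side views
  expect_identical(
    render_view(s3, "buccal", 1L, 48, 64),
    render_view(s4, "buccal", 1L, 48, 64)
  )
  # but root count is visible there
  expect_false(identical(
    render_view(r1, "buccal", 1L, 48, 64),
    render_view(r2, "buccal", 1L, 48, 64)
  ))
  expect_error(render_view(s3, "sagittal", 1L), "unknown view tag")
  expect_error(render_view(s3, "occlusal", 1L, height = 2, width = 64),
    "at least")
})

test_that("generated datasets are balanced, complete and reproducible", {
  specs <- tooth_class_specs()[c("U1", "U5", "L7")]
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  ds1 <- generate_dataset(specs, 4, dir1,
    train_fraction = 0.75, seed = 5,
    height = 24, width = 32
  )
  ds2 <- generate_dataset(specs, 4, dir2,
    train_fraction = 0.75, seed = 5,
    height = 24, width = 32
  )
  expect_equal(nrow(ds1$manifest), 3 * 4 * 6)
  counts <- table(ds1$manifest$label) / 6
  expect_true(all(counts == 4)) # exact class balance
  per_spec <- table(ds1$manifest$specimen_id)
  expect_true(all(per_spec == 6))
  # reproducibility: identical manifests and identical pixels
  expect_identical(
    ds1$manifest[c("specimen_id", "label", "view")],
    ds2$manifest[c("specimen_id", "label", "view")]
  )
  expect_identical(
    read_image(ds1$manifest$path[1]),
    read_image(ds2$manifest$path[1])
  )
  # split sizes follow the fraction and are disjoint
  n_train <- length(unique(ds1$train$specimen_id))
  expect_equal(n_train, round(0.75 * 12))
  expect_length(
    intersect(ds1$train$specimen_id, ds1$test$specimen_id), 0
  )
  expect_error(
    generate_dataset(c(specs, specs[1]), 1, withr::local_tempdir()),
    "duplicate"
  )
})

test_that("the separable preset is Bayes-solvable only from the full set", {
  specs <- separable_class_specs()
  # attribute table: every (class, variant) with its per-view evidence
  variants <- function(s) {
    if (is.null(s$variants)) list(c(s$cusp_count, s$root_count)) else s$variants
  }
  tab <- do.call(rbind, lapply(names(specs), function(nm) {
    do.call(rbind, lapply(variants(specs[[nm]]), function(v) {
      data.frame(class = nm, cusp = v[1], root = v[2])
    }))
  }))
  # full set: the (cusp, root) pair identifies the class uniquely
  joint <- paste(tab$cusp, tab$root)
  expect_equal(anyDuplicated(joint), 0)
  # single top-down view (cusp only): P1 and P2 share {3, 4}
  expect_setequal(tab$cusp[tab$class == "P1"], tab$cusp[tab$class == "P2"])
  # single side view (root only): P1 and P2 share {1, 2}
  expect_setequal(tab$root[tab$class == "P1"], tab$root[tab$class == "P2"])
})

test_that("simulated annotators follow their confusion rows", {
  tax <- tooth_taxonomy()
  ident <- diag(16)
  dimnames(ident) <- list(tax$fine_classes, tax$fine_classes)
  perfect <- rater_model("R1", ident)
  truth <- rep(tax$fine_classes, 3)
  ann <- simulate_annotators(truth, list(perfect), seed = 1)
  expect_identical(ann$label[order(ann$specimen_id)],
    truth[order(sprintf("S%04d", seq_along(truth)))])

  noisy <- rater_model("R2", adjacent_confusion(0.8))
  truth_big <- withr::with_seed(2, sample(tax$fine_classes, 10000, TRUE))
  ann2 <- simulate_annotators(truth_big, list(noisy), seed = 3)
  agree <- mean(ann2$label == truth_big[match(
    ann2$specimen_id, sprintf("S%04d", seq_along(truth_big))
  )])
  expect_lt(abs(agree - 0.8), 0.01)

  # two independent identical raters: expected pairwise agreement is
  # sum_c p(c) * (row_c . row_c)
  cm <- adjacent_confusion(0.7)
  two <- list(rater_model("A", cm), rater_model("B", cm))
  ann3 <- simulate_annotators(truth_big, two, seed = 4)
  wide <- matrix(ann3$label[order(ann3$specimen_id, ann3$rater_id)],
    ncol = 2, byrow = TRUE
  )
  p_class <- table(factor(truth_big, tax$fine_classes)) / length(truth_big)
  expected <- sum(as.numeric(p_class) * rowSums(cm^2))
  expect_lt(abs(mean(wide[, 1] == wide[, 2]) - expected), 0.015)

  bad <- cm
  bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(rater_model("x", bad), "sum to 1")
  expect_error(
    simulate_annotators(c("Z9"), list(noisy), seed = 1),
    "absent"
  )
})

test_that("confusion presets are row-stochastic with dominant diagonals", {
  for (p in c(0.7, 0.85)) {
    cm <- adjacent_confusion(p)
    expect_equal(unname(rowSums(cm)), rep(1, 16), tolerance = 1e-12)
    expect_true(all(diag(cm) == p))
    expect_true(all(diag(cm) > apply(cm - diag(diag(cm)), 1, max)))
  }
  raters <- default_rater_models()
  expect_named(raters, c("A0", "A1", "A2", "A3"))
})
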