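#' Rank of the true class within a prediction vector
#'
#' The rank counts classes with strictly greater probability than the true
#' class, plus one — ties resolve in favor of the true class, which is
#' deterministic and measure-zero for real model outputs.
#'
#' @param probs Probability matrix (rows = specimens), columns named by
#'   class code.
#' @param labels Character vector of true classes, aligned with rows.
#' @return Integer vector of ranks in `[1, C]`.
#' @export
rank_of_true <- function(probs, labels) {
  classes <- colnames(probs)
  if (is.null(classes)) stop("probability matrix must have class colnames")
  bad <- setdiff(unique(labels), classes)
  if (length(bad) > 0) {
    stop("label(s) outside probability columns: ", paste(bad, collapse = ", "))
  }
  if (length(labels) != nrow(probs)) stop("labels/rows length mismatch")
  ci <- match(labels, classes)
  truep <- probs[cbind(seq_len(nrow(probs)), ci)]
  as.integer(rowSums(probs > truep) + 1L)
}

#' Top-k accuracy
#'
#' Fraction of specimens whose true class ranks within the `k` largest
#' predicted probabilities.
#'
#' @inheritParams rank_of_true
#' @param k Rank cutoff, `1 <= k <= C`.
#' @return Accuracy in `[0, 1]`.
#' @export
topk_accuracy <- function(probs, labels, k = 1L) {
  if (k < 1 || k > ncol(probs)) stop("k must lie in [1, C]")
  mean(rank_of_true(probs, labels) <= k)
}

#' Merge fine-class probabilities to a coarser granularity
#'
#' Each coarse category's probability is the sum of its member classes'
#' probabilities, so rows remain distributions. No retraining is involved:
#' one fine model is evaluated at every granularity.
#'
#' @param probs Probability matrix with fine-class colnames.
#' @param target Granularity name.
#' @param taxonomy A `label_taxonomy`.
#' @return Probability matrix over target-level categories.
#' @export
regroup_probabilities <- function(probs, target,
                                  taxonomy = tooth_taxonomy()) {
  map <- taxonomy_map(taxonomy, target)
  out_classes <- taxonomy_classes(taxonomy, target)
  if (identical(unname(map[colnames(probs)]), colnames(probs))) {
    return(probs)
  }
  out <- matrix(0, nrow(probs), length(out_classes),
    dimnames = list(rownames(probs), out_classes)
  )
  for (g in out_classes) {
    members <- names(map)[map == g]
    out[, g] <- rowSums(probs[, members, drop = FALSE])
  }
  out
}

#' Confusion matrix (rows = reference labels, columns = predictions)
#'
#' @param labels,predictions Aligned character vectors.
#' @param classes Category codes fixing row/column order.
#' @return Integer `C x C` matrix; `sum(diag(m)) / sum(m)` equals top-1
#'   accuracy.
#' @export
confusion_matrix <- function(labels, predictions, classes) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length")
  }
  m <- table(
    factor(labels, levels = classes),
    factor(predictions, levels = classes)
  )
  out <- matrix(as.integer(m), length(classes), length(classes),
    dimnames = list(classes, classes)
  )
  out
}

#' Per-class and macro sensitivity / specificity
#'
#' One-vs-rest reading of the confusion matrix:
#' `sensitivity_c = TP_c / (TP_c + FN_c)` and
#' `specificity_c = TN_c / (TN_c + FP_c)`; macro values are unweighted
#' means over classes. Classes with zero support have undefined
#' sensitivity and are excluded from the macro mean with a warning.
#'
#' @param cm Square confusion matrix (rows = reference).
#' @return List with `sensitivity`, `specificity` (named per-class
#'   vectors) and `macro_sensitivity`, `macro_specificity`.
#' @export
sensitivity_specificity <- function(cm) {
  stopifnot(nrow(cm) == ncol(cm))
  n <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  if (anyNA(sens)) {
    warning(
      "class(es) with zero support excluded from macro sensitivity: ",
      paste(rownames(cm)[is.na(sens)], collapse = ", ")
    )
  }
  list(
    sensitivity = sens, specificity = spec,
    macro_sensitivity = mean(sens, na.rm = TRUE),
    macro_specificity = mean(spec, na.rm = TRUE)
  )
}

#' One-vs-rest ROC curves and AUC per class
#'
#' For each class the ROC is swept over thresholds of that class's
#' predicted probability and the AUC computed by the trapezoid rule; the
#' macro AUC is the unweighted mean of the defined per-class AUCs.
#' Degenerate classes (all positive or all negative) get `NA`.
#'
#' @inheritParams rank_of_true
#' @return List with `auc` (named per-class), `macro_auc`, and `curves`
#'   (per-class data.frames of `fpr`, `tpr`).
#' @export
roc_auc <- function(probs, labels) {
  classes <- colnames(probs)
  auc <- stats::setNames(rep(NA_real_, length(classes)), classes)
  curves <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    pos <- labels == cl
    if (all(pos) || !any(pos)) next
    r <- roc_curve(probs[, cl], pos)
    curves[[cl]] <- r
    auc[cl] <- trapezoid_auc(r$fpr, r$tpr)
  }
  list(auc = auc, macro_auc = mean(auc, na.rm = TRUE), curves = curves)
}

roc_curve <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- positive[ord]
  # step only at distinct thresholds
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(p)[keep]
  fp <- cumsum(!p)[keep]
  data.frame(
    fpr = c(0, fp / sum(!positive)),
    tpr = c(0, tp / sum(positive))
  )
}

trapezoid_auc <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Full hierarchical evaluation of a trained model
#'
#' Predicts the test manifest, then reports at every granularity of the
#' taxonomy (fine plus each coarse level, probabilities merged by
#' category-summing): top-k accuracies, the confusion matrix, per-class
#' and macro sensitivity/specificity, one-vs-rest AUCs, and Cohen's kappa
#' between reference labels and top-1 predictions. The top-1 accuracy of
#' argmax-label merging (regrouping the fine argmax instead of the
#' probabilities) is reported alongside for comparison.
#'
#' @param model A `set_classifier` whose `taxonomy` is set (or pass
#'   `taxonomy`).
#' @param records Test records or manifest data.frame.
#' @param labels Reference (e.g. pseudo-ground-truth) labels; defaults to
#'   the records' own `label` fields.
#' @param ks Rank cutoffs for top-k accuracy.
#' @param taxonomy Overrides the model's taxonomy.
#' @return An `eval_report` list.
#' @export
evaluate_model <- function(model, records, labels = NULL, ks = 1:3,
                           taxonomy = NULL) {
  if (is.data.frame(records)) records <- manifest_records(records)
  taxonomy <- taxonomy %||% model$taxonomy
  if (is.null(taxonomy)) {
    taxonomy <- label_taxonomy(model$classes)
  }
  if (is.null(labels)) {
    labels <- vapply(records, function(r) r$label, character(1))
  }
  probs <- predict_proba(model, records)
  eval_probabilities(probs, labels, ks = ks, taxonomy = taxonomy)
}

#' @rdname evaluate_model
#' @param probs Row-stochastic probability matrix over the fine classes.
#' @export
eval_probabilities <- function(probs, labels, ks = 1:3,
                               taxonomy = tooth_taxonomy()) {
  grans <- c(taxonomy$fine_name, names(taxonomy$levels))
  fine_pred <- colnames(probs)[max.col(probs, ties.method = "first")]
  out <- list()
  for (g in grans) {
    p_g <- regroup_probabilities(probs, g, taxonomy)
    l_g <- regroup_label(labels, g, taxonomy)
    classes_g <- taxonomy_classes(taxonomy, g)
    pred_g <- classes_g[max.col(p_g, ties.method = "first")]
    pred_argmax_merge <- regroup_label(fine_pred, g, taxonomy)
    ks_g <- ks[ks <= ncol(p_g)]
    topk <- stats::setNames(
      vapply(ks_g, function(k) topk_accuracy(p_g, l_g, k), numeric(1)),
      paste0("top", ks_g)
    )
    cm <- confusion_matrix(l_g, pred_g, classes_g)
    ss <- sensitivity_specificity(cm)
    roc <- roc_auc(p_g, l_g)
    ck <- cohen_kappa(l_g, pred_g)
    out[[g]] <- list(
      n = length(l_g), topk = topk, confusion = cm,
      sensitivity = ss$sensitivity, specificity = ss$specificity,
      macro_sensitivity = ss$macro_sensitivity,
      macro_specificity = ss$macro_specificity,
      auc = roc$auc, macro_auc = roc$macro_auc,
      cohen_kappa = ck[c("kappa", "ci_lower", "ci_upper")],
      top1_argmax_merge = mean(pred_argmax_merge == l_g)
    )
  }
  structure(
    list(n = length(labels), granularities = out),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n, "\n")
  for (g in names(x$granularities)) {
    r <- x$granularities[[g]]
    cat(
      sprintf(
        "  %-8s top1 %.3f  macro_sens %.3f  macro_auc %.3f  kappa %.3f\n",
        g, r$topk[["top1"]], r$macro_sensitivity, r$macro_auc,
        r$cohen_kappa$kappa
      )
    )
  }
  invisible(x)
}

#' Spatial feature-response heatmaps for one view
#'
#' Takes the absolute value of the encoder's final feature map channels,
#' upsamples each to the model input size, rescales to `[0, 1]` and
#' alpha-blends a blue-to-red colormap over the (letterboxed) view image.
#'
#' @param model A `set_classifier`.
#' @param record A multi-view record.
#' @param n_channels Number of leading channels to export (default 15).
#' @param view View tag to visualize (default occlusal).
#' @param alpha Overlay opacity.
#' @return List of `side x side x 3` overlay images, one per channel.
#' @export
feature_heatmaps <- function(model, record, n_channels = 15L,
                             view = "occlusal", alpha = 0.45) {
  cfg <- model$config
  img <- resize_pad(record_view_image(record, view), cfg$side)
  x <- array(img, dim = c(dim(img), 1))
  enc <- encoder_forward(model$params, cfg, x)
  fmap <- enc$fmap
  if (length(dim(fmap)) < 4 || dim(fmap)[1] < 1) {
    stop("encoder produced no spatial output")
  }
  n_avail <- dim(fmap)[3]
  if (n_channels > n_avail) {
    stop("n_channels exceeds encoder channels (", n_avail, ")")
  }
  lapply(seq_len(n_channels), function(ch) {
    heat <- abs(fmap[, , ch, 1])
    hh <- nrow(heat)
    inv <- function(r, c) {
      list(
        (r - 0.5) * (hh / cfg$side) + 0.5,
        (c - 0.5) * (ncol(heat) / cfg$side) + 0.5
      )
    }
    up <- warp_image(
      array(heat, dim = c(dim(heat), 1)), inv,
      cfg$side, cfg$side
    )[, , 1]
    rng <- range(up)
    if (diff(rng) > 0) up <- (up - rng[1]) / diff(rng)
    overlay <- img
    overlay[, , 1] <- (1 - alpha) * img[, , 1] + alpha * up
    overlay[, , 2] <- (1 - alpha) * img[, , 2] + alpha * 0.2
    overlay[, , 3] <- (1 - alpha) * img[, , 3] + alpha * (1 - up)
    overlay
  })
}
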