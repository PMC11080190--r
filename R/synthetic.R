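#' Deterministic seed derivation
#'
#' Derives a child seed from a root seed and any number of integer keys
#' (class index, specimen index, view index, rater index, ...) by a
#' multiply-add hash. Generation order therefore never affects the stream
#' a particular specimen, view or rater receives.
#'
#' @param root Integer root seed.
#' @param ... Integer keys.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root, ...) {
  m <- 2147483647 # 2^31 - 1
  x <- as.numeric(root) %% m
  keys <- as.numeric(c(...))
  for (i in seq_along(keys)) {
    x <- (x * 69069 + (keys[i] + 1) * 104729 + i * 7919) %% m
  }
  as.integer(x)
}

#' Synthetic class specification
#'
#' Describes how to draw one class of synthetic specimens. The
#' class-determining attributes are deliberately split across views, like
#' real tooth anatomy: `cusp_count` is rendered only in the top-down views
#' (occlusal, apical) and `root_count` only in the four side views
#' (buccal, lingual, mesial, distal). A class may carry several
#' `(cusp, root)` `variants`, sampled uniformly per specimen; two classes
#' whose variants swap the pairing of the same attribute values are then
#' indistinguishable from any single view yet fully determined by the set.
#'
#' @param code Class code (character).
#' @param cusp_count Integer number of cusp bumps (top-down views only).
#' @param root_count Integer number of root stems (side views only).
#' @param crown_root_ratio Crown height relative to root height in side
#'   views (positive).
#' @param jaw_curvature Signed bowing of the crown's occlusal edge in side
#'   views; the subtle cue separating upper from lower jaw.
#' @param jitter Named list of non-negative jitter amplitudes:
#'   `size` (relative scale), `pos` (relative placement), `noise`
#'   (additive pixel noise sd).
#' @param variants Optional list of `c(cusp, root)` pairs overriding
#'   `cusp_count`/`root_count`; one is drawn per specimen.
#' @return A `synthetic_class_spec`.
#' @export
class_spec <- function(code, cusp_count, root_count,
                       crown_root_ratio = 1.2, jaw_curvature = 0,
                       jitter = list(size = 0.05, pos = 0.03, noise = 0.02),
                       variants = NULL) {
  stopifnot(cusp_count >= 0, root_count >= 0, crown_root_ratio > 0)
  if (any(unlist(jitter) < 0)) stop("jitter amplitudes must be non-negative")
  structure(
    list(
      code = as.character(code), cusp_count = as.integer(cusp_count),
      root_count = as.integer(root_count),
      crown_root_ratio = crown_root_ratio, jaw_curvature = jaw_curvature,
      jitter = jitter, variants = variants
    ),
    class = "synthetic_class_spec"
  )
}

#' Built-in 16-class synthetic preset
#'
#' One spec per tooth class: the position (1-8) sets cusp count, root count
#' and crown/root proportions along a gradient from incisor-like to
#' molar-like shapes; the jaw is carried only by the sign of the occlusal
#' edge curvature, visible in side views. Classifying all 16 classes thus
#' requires evidence from both top-down and side views.
#'
#' @param jitter Jitter list applied to every class (see [class_spec()]).
#' @return Named list of 16 `synthetic_class_spec`s in taxonomy order.
#' @export
tooth_class_specs <- function(jitter = list(size = 0.05, pos = 0.03,
                                            noise = 0.02)) {
  tax <- tooth_taxonomy()
  cusps <- c(1, 2, 3, 4, 5, 6, 7, 8)
  roots <- c(1, 1, 1, 1, 2, 2, 3, 3)
  ratios <- c(1.8, 1.7, 1.6, 1.2, 1.1, 0.85, 0.8, 0.75)
  specs <- lapply(tax$fine_classes, function(code) {
    pos <- as.integer(substr(code, 2, 2))
    jaw <- substr(code, 1, 1)
    class_spec(
      code,
      cusp_count = cusps[pos], root_count = roots[pos],
      crown_root_ratio = ratios[pos],
      jaw_curvature = if (jaw == "U") 0.35 else -0.35,
      jitter = jitter
    )
  })
  names(specs) <- tax$fine_classes
  specs
}

#' Separable 4-class preset with a view-complementary pair
#'
#' Four classes whose attributes make a Bayes-optimal classifier perfect
#' when it sees all six views. Classes `P1` and `P2` are the
#' view-complementary pair: both show cusp counts \{3, 4\} in top-down
#' views and root counts \{1, 2\} in side views, but `P1` pairs (3,1) with
#' (4,2) while `P2` pairs (3,2) with (4,1) — so any single view is
#' uninformative between them and only the cross-view combination decides.
#' `Q1` and `Q2` are ordinary separable classes.
#'
#' @param jitter Jitter list (zero size/pos jitter keeps the preset exactly
#'   separable).
#' @return Named list of 4 specs.
#' @export
separable_class_specs <- function(jitter = list(size = 0, pos = 0,
                                                noise = 0.02)) {
  specs <- list(
    P1 = class_spec("P1", 3, 1,
      jitter = jitter,
      variants = list(c(3, 1), c(4, 2))
    ),
    P2 = class_spec("P2", 3, 2,
      jitter = jitter,
      variants = list(c(3, 2), c(4, 1))
    ),
    Q1 = class_spec("Q1", 6, 1, crown_root_ratio = 1.6, jitter = jitter),
    Q2 = class_spec("Q2", 8, 3, crown_root_ratio = 0.8, jitter = jitter)
  )
  specs
}

#' Realize one specimen from a class spec
#'
#' Draws the specimen-level attributes (variant choice and size/position
#' jitter) that must be consistent across the six views. Rendering a view
#' afterwards only adds per-view pixel noise.
#'
#' @param spec A `synthetic_class_spec`.
#' @param seed Specimen seed.
#' @return A realized spec: same structure, concrete attributes, zero
#'   residual attribute jitter.
#' @export
realize_specimen <- function(spec, seed) {
  withr::with_seed(as.integer(seed), {
    if (!is.null(spec$variants)) {
      v <- spec$variants[[sample.int(length(spec$variants), 1)]]
      spec$cusp_count <- as.integer(v[1])
      spec$root_count <- as.integer(v[2])
      spec$variants <- NULL
    }
    js <- spec$jitter$size %||% 0
    jp <- spec$jitter$pos %||% 0
    spec$size_mul <- exp(stats::rnorm(1, 0, js))
    spec$pos_shift <- stats::rnorm(2, 0, jp)
    spec$angle_shift <- stats::runif(1, 0, 2 * pi)
    spec$jitter$size <- 0
    spec$jitter$pos <- 0
  })
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render one view of a synthetic specimen
#'
#' Procedural 2-D drawing of a tooth-like shape on a dark background:
#' top-down views show an elliptical crown with `cusp_count` bright bumps
#' on a ring (root count invisible); side views show a crown block over
#' `root_count` root stems with the occlusal edge bowed by
#' `jaw_curvature` (cusp count invisible). Bit-identical output for
#' identical `(spec, view, jitter_seed)`.
#'
#' @param spec A (possibly realized) `synthetic_class_spec`.
#' @param view One of [view_tags()].
#' @param jitter_seed Integer seed for residual jitter and pixel noise.
#' @param height,width Output dimensions in pixels (non-square default
#'   exercises the letterbox path downstream).
#' @return Image array `height x width x 3` in `[0, 1]`.
#' @export
render_view <- function(spec, view, jitter_seed = 0L,
                        height = 192L, width = 256L) {
  height <- as.integer(height)
  width <- as.integer(width)
  if (height < 8 || width < 8) stop("image dimensions must be at least 8 px")
  if (!view %in% view_tags()) {
    stop(
      "unknown view tag '", view, "'; expected one of: ",
      paste(view_tags(), collapse = ", ")
    )
  }
  if (is.null(spec$size_mul)) {
    spec <- realize_specimen(spec, derive_seed(jitter_seed, 104729L))
  }
  noise_sd <- spec$jitter$noise %||% 0
  R <- matrix(seq_len(height), height, width)
  C <- matrix(seq_len(width), height, width, byrow = TRUE)
  img <- array(0.05, dim = c(height, width, 3))
  cy <- height * (0.5 + spec$pos_shift[1])
  cx <- width * (0.5 + spec$pos_shift[2])
  withr::with_seed(as.integer(jitter_seed), {
    if (view %in% c("occlusal", "apical")) {
      img <- draw_topdown(
        img, R, C, cy, cx, spec, view,
        height, width
      )
    } else {
      img <- draw_side(img, R, C, cy, cx, spec, view, height, width)
    }
    if (noise_sd > 0) {
      img <- img + array(
        stats::rnorm(length(img), 0, noise_sd),
        dim = dim(img)
      )
    }
  })
  pmin(pmax(img, 0), 1)
}

draw_topdown <- function(img, R, C, cy, cx, spec, view, height, width) {
  shrink <- if (view == "apical") 0.72 else 1
  ry <- 0.34 * height * spec$size_mul * shrink
  rx <- 0.38 * width * spec$size_mul * shrink
  crown <- ((R - cy) / ry)^2 + ((C - cx) / rx)^2 <= 1
  base_col <- if (view == "apical") {
    c(0.38, 0.34, 0.28)
  } else {
    c(0.5, 0.46, 0.38)
  }
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[crown] <- base_col[ch]
    img[, , ch] <- plane
  }
  k <- spec$cusp_count
  if (k > 0) {
    # big, high-contrast bumps: cusp count stays legible after heavy
    # downscaling and dominates pooled image statistics
    ring_r <- 0.58
    bump_r <- 0.24 * min(ry, rx) + 0.04 * min(height, width)
    angles <- spec$angle_shift + 2 * pi * (seq_len(k) - 1) / k
    for (a in angles) {
      by <- cy + ring_r * ry * sin(a)
      bx <- cx + ring_r * rx * cos(a)
      bump <- (R - by)^2 + (C - bx)^2 <= bump_r^2
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[bump & crown] <- c(1, 0.95, 0.8)[ch]
        img[, , ch] <- plane
      }
    }
  }
  img
}

draw_side <- function(img, R, C, cy, cx, spec, view, height, width) {
  width_mul <- c(buccal = 1, lingual = 0.88, mesial = 0.68, distal = 0.76)
  half_w <- 0.32 * width * spec$size_mul * width_mul[[view]]
  total_h <- 0.8 * height * spec$size_mul
  ratio <- spec$crown_root_ratio
  crown_h <- total_h * ratio / (1 + ratio)
  root_h <- total_h - crown_h
  top <- cy - total_h / 2
  junction <- top + crown_h
  # occlusal edge bowed by jaw curvature (sign = jaw identity)
  bow <- spec$jaw_curvature * crown_h * ((C - cx) / (half_w + 1e-9))^2
  in_x <- abs(C - cx) <= half_w
  crown <- in_x & R >= top + bow & R <= junction
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[crown] <- c(0.5, 0.47, 0.4)[ch]
    img[, , ch] <- plane
  }
  k <- spec$root_count
  if (k > 0) {
    # constant stem width: total root area grows with root count, keeping
    # the count visible to area-pooling feature extractors
    stem_w <- 0.22 * half_w
    centers <- cx + (seq_len(k) - (k + 1) / 2) * (2 * half_w * 0.8 / max(k, 1))
    for (sc in centers) {
      taper <- 1 - 0.6 * (R - junction) / (root_h + 1e-9)
      stem <- R > junction & R <= junction + root_h &
        abs(C - sc) <= stem_w * pmax(taper, 0.15)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[stem] <- c(0.95, 0.82, 0.45)[ch]
        img[, , ch] <- plane
      }
    }
  }
  img
}

#' Generate a class-balanced multi-view dataset on disk
#'
#' Renders `n_per_class` specimens for every class spec, writes one PNG per
#' (specimen, view), and returns long-format manifests. The train/test
#' split is a seed-reproducible random partition of specimens.
#'
#' @param specs List of `synthetic_class_spec`s with distinct codes.
#' @param n_per_class Specimens per class (>= 1).
#' @param dir Output directory (created if needed).
#' @param train_fraction Fraction of specimens assigned to the training
#'   split, strictly between 0 and 1.
#' @param seed Root seed; all specimen, view and split randomness derives
#'   from it by counters, never from generation order.
#' @param height,width Rendered image dimensions.
#' @return List with data.frames `manifest`, `train`, `test` (columns
#'   `specimen_id`, `label`, `view`, `path`) and the `dir`. The manifests
#'   are also written as `manifest.csv`, `train.csv`, `test.csv` plus a
#'   JSON variant `manifest.json` (one object per specimen).
#' @export
generate_dataset <- function(specs, n_per_class, dir,
                             train_fraction = 0.765, seed = 1L,
                             height = 192L, width = 256L) {
  codes <- vapply(specs, function(s) s$code, character(1))
  if (anyDuplicated(codes)) stop("duplicate class codes in specs")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  views <- view_tags()
  n_total <- length(specs) * n_per_class
  rows <- vector("list", n_total)
  idx <- 0L
  for (ci in seq_along(specs)) {
    for (si in seq_len(n_per_class)) {
      idx <- idx + 1L
      id <- sprintf("S%04d", idx)
      realized <- realize_specimen(specs[[ci]], derive_seed(seed, ci, si))
      paths <- character(length(views))
      for (vi in seq_along(views)) {
        img <- render_view(
          realized, views[vi],
          jitter_seed = derive_seed(seed, ci, si, vi),
          height = height, width = width
        )
        paths[vi] <- file.path(img_dir, paste0(id, "_", views[vi], ".png"))
        write_image(img, paths[vi])
      }
      rows[[idx]] <- data.frame(
        specimen_id = id, label = unname(codes[ci]), view = unname(views),
        path = unname(paths), stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  ids <- unique(manifest$specimen_id)
  n_train <- round(train_fraction * length(ids))
  train_ids <- withr::with_seed(
    derive_seed(seed, 999983L),
    sample(ids, n_train)
  )
  train <- manifest[manifest$specimen_id %in% train_ids, ]
  test <- manifest[!manifest$specimen_id %in% train_ids, ]
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  write_manifest(train, file.path(dir, "train.csv"))
  write_manifest(test, file.path(dir, "test.csv"))
  write_manifest_json(manifest, file.path(dir, "manifest.json"))
  list(manifest = manifest, train = train, test = test, dir = dir)
}

#' Rater model: a row-stochastic confusion matrix over classes
#'
#' @param id Rater id.
#' @param confusion Square matrix with identical row/column names (the
#'   class codes); row `t` is the distribution of this rater's label given
#'   true class `t`. Rows must sum to 1 within 1e-9.
#' @return A `rater_model`.
#' @export
rater_model <- function(id, confusion) {
  if (is.null(rownames(confusion)) || is.null(colnames(confusion)) ||
    !identical(rownames(confusion), colnames(confusion))) {
    stop("confusion matrix needs identical row and column class names")
  }
  if (any(abs(rowSums(confusion) - 1) > 1e-9)) {
    stop("confusion matrix rows must each sum to 1 (tolerance 1e-9)")
  }
  if (any(confusion < 0)) stop("confusion probabilities must be >= 0")
  structure(list(id = as.character(id), confusion = confusion),
    class = "rater_model"
  )
}

#' Structured confusion matrix for a simulated tooth annotator
#'
#' Errors concentrate where real observers err: on the adjacent positions
#' in the same jaw and on the same position in the opposite jaw (the
#' "counterpart"), with a small uniform remainder over other classes.
#'
#' @param diag_p Probability of the correct label (diagonal mass).
#' @param adjacent_share,counterpart_share,uniform_share Split of the
#'   off-diagonal mass `1 - diag_p` (must sum to 1).
#' @param taxonomy The dental `label_taxonomy`.
#' @return Row-stochastic matrix over the 16 classes.
#' @export
adjacent_confusion <- function(diag_p = 0.85, adjacent_share = 0.6,
                               counterpart_share = 0.3,
                               uniform_share = 0.1,
                               taxonomy = tooth_taxonomy()) {
  stopifnot(abs(adjacent_share + counterpart_share + uniform_share - 1) < 1e-9)
  classes <- taxonomy$fine_classes
  n <- length(classes)
  pos <- as.integer(substr(classes, 2, 2))
  jaw <- substr(classes, 1, 1)
  M <- matrix(0, n, n, dimnames = list(classes, classes))
  off <- 1 - diag_p
  for (i in seq_len(n)) {
    adj <- which(jaw == jaw[i] & abs(pos - pos[i]) == 1)
    cpart <- which(jaw != jaw[i] & pos == pos[i])
    others <- setdiff(seq_len(n), c(i, adj, cpart))
    M[i, i] <- diag_p
    if (length(adj) > 0) M[i, adj] <- off * adjacent_share / length(adj)
    M[i, cpart] <- off * counterpart_share / length(cpart)
    # fold any unassignable share into the uniform remainder
    assigned <- sum(M[i, ])
    M[i, others] <- (1 - assigned) / length(others)
  }
  M
}

#' Default panel of four simulated annotators
#'
#' Mirrors the annotation design the consensus module expects: two more
#' reliable raters (`A0`, `A1`) and two noisier ones (`A2`, `A3`), all
#' with adjacency/counterpart-structured confusion.
#'
#' @param reliable_diag,noisy_diag Diagonal mass for the two groups.
#' @param taxonomy The `label_taxonomy`.
#' @return Named list of four `rater_model`s.
#' @export
default_rater_models <- function(reliable_diag = 0.85, noisy_diag = 0.7,
                                 taxonomy = tooth_taxonomy()) {
  mk <- function(id, p) {
    rater_model(id, adjacent_confusion(p, taxonomy = taxonomy))
  }
  list(
    A0 = mk("A0", reliable_diag), A1 = mk("A1", reliable_diag),
    A2 = mk("A2", noisy_diag), A3 = mk("A3", noisy_diag)
  )
}

#' Simulate multi-rater annotations of a labeled specimen list
#'
#' Each rater labels every specimen independently, drawing from their
#' confusion row for the specimen's true class.
#'
#' @param true_labels Character vector of true class codes; names (if any)
#'   are used as specimen ids, otherwise `S0001...` are assigned.
#' @param raters List of `rater_model`s.
#' @param seed Root seed; per-(rater, specimen) draws derive from it.
#' @return Long data.frame with columns `specimen_id`, `rater_id`,
#'   `label`.
#' @export
simulate_annotators <- function(true_labels, raters, seed = 1L) {
  ids <- names(true_labels)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_along(true_labels))
  out <- vector("list", length(raters))
  for (ri in seq_along(raters)) {
    rater <- raters[[ri]]
    cm <- rater$confusion
    missing <- setdiff(unique(true_labels), rownames(cm))
    if (length(missing) > 0) {
      stop(
        "label(s) absent from rater ", rater$id, "'s confusion matrix: ",
        paste(missing, collapse = ", ")
      )
    }
    labels <- withr::with_seed(derive_seed(seed, 7L, ri), {
      vapply(as.character(true_labels), function(tl) {
        sample(colnames(cm), 1, prob = cm[tl, ])
      }, character(1))
    })
    out[[ri]] <- data.frame(
      specimen_id = ids, rater_id = rater$id,
      label = unname(labels), stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res[order(res$specimen_id, res$rater_id), , drop = FALSE]
}
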