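#' Load a multi-view manifest into records
#'
#' The canonical manifest is a long CSV with columns `specimen_id`,
#' `label` (may be empty for unlabeled data), `view`, `path` — one row per
#' image. A JSON variant (array of objects with `specimen_id`, `label`
#' and a `views` object mapping tag to path) is also accepted. Every
#' specimen must carry exactly one image per required view tag.
#'
#' @param path Manifest file (`.csv` or `.json`).
#' @param taxonomy Optional `label_taxonomy` used to normalize labels
#'   (FDI two-digit codes are collapsed to jaw + position).
#' @param views Required view tags.
#' @param check_paths Verify that the image files exist at load time.
#' @return List of records: each a list with `specimen_id`, `label`
#'   (`NA` if absent) and `views` (named character vector tag -> path).
#' @export
load_manifest <- function(path, taxonomy = tooth_taxonomy(),
                          views = view_tags(), check_paths = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    df <- do.call(rbind, lapply(doc, function(o) {
      data.frame(
        specimen_id = o$specimen_id,
        label = o$label %||% NA_character_,
        view = names(o$views),
        path = unlist(o$views, use.names = FALSE),
        stringsAsFactors = FALSE
      )
    }))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (is.null(df) || nrow(df) == 0) {
    return(list())
  }
  manifest_records(df,
    taxonomy = taxonomy, views = views,
    check_paths = check_paths, base_dir = dirname(path)
  )
}

#' Group a long manifest data.frame into multi-view records
#'
#' @param df data.frame with columns `specimen_id`, `label`, `view`,
#'   `path`.
#' @param base_dir Directory against which relative image paths are
#'   resolved.
#' @inheritParams load_manifest
#' @return List of records (see [load_manifest()]).
#' @export
manifest_records <- function(df, taxonomy = tooth_taxonomy(),
                             views = view_tags(), check_paths = FALSE,
                             base_dir = NULL) {
  required <- c("specimen_id", "view", "path")
  if (!all(required %in% names(df))) {
    stop("manifest needs columns: ", paste(required, collapse = ", "))
  }
  unknown <- setdiff(unique(df$view), views)
  if (length(unknown) > 0) {
    stop("unknown view tag(s): ", paste(unknown, collapse = ", "))
  }
  has_label <- "label" %in% names(df)
  split_rows <- split(df, df$specimen_id)
  ids <- unique(as.character(df$specimen_id))
  records <- lapply(split_rows[ids], function(d) {
    missing <- setdiff(views, d$view)
    dup <- unique(d$view[duplicated(d$view)])
    if (length(missing) > 0 || length(dup) > 0) {
      stop(
        "specimen ", d$specimen_id[1], " has an invalid view set",
        if (length(missing)) {
          paste0(" (missing: ", paste(missing, collapse = ", "), ")")
        },
        if (length(dup)) {
          paste0(" (duplicated: ", paste(dup, collapse = ", "), ")")
        }
      )
    }
    paths <- as.character(d$path)
    if (!is.null(base_dir)) {
      rel <- !file.exists(paths) & !grepl("^/", paths)
      paths[rel] <- file.path(base_dir, paths[rel])
    }
    if (check_paths && !all(file.exists(paths))) {
      stop(
        "missing image file(s) for specimen ", d$specimen_id[1], ": ",
        paste(paths[!file.exists(paths)], collapse = ", ")
      )
    }
    label <- NA_character_
    if (has_label && !is.na(d$label[1]) && nzchar(d$label[1])) {
      label <- if (!is.null(taxonomy)) {
        normalize_label(d$label[1], taxonomy)
      } else {
        as.character(d$label[1])
      }
    }
    list(
      specimen_id = as.character(d$specimen_id[1]), label = label,
      views = stats::setNames(paths[match(views, d$view)], views)
    )
  })
  names(records) <- NULL
  records
}

#' Write a manifest (long CSV or per-specimen JSON)
#'
#' @param df Long manifest data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
write_manifest_json <- function(df, path) {
  recs <- lapply(split(df, df$specimen_id)[unique(df$specimen_id)], function(d) {
    list(
      specimen_id = d$specimen_id[1],
      label = if ("label" %in% names(d)) d$label[1] else NULL,
      views = as.list(stats::setNames(d$path, d$view))
    )
  })
  names(recs) <- NULL
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write a multi-rater annotation table
#'
#' CSV with columns `specimen_id`, `rater_id`, `label`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("specimen_id", "rater_id", "label")
  if (!all(required %in% names(df))) {
    stop("annotation CSV needs columns: ", paste(required, collapse = ", "))
  }
  df
}

#' @rdname read_annotations
#' @param df Annotation data.frame.
#' @export
write_annotations <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- run configuration ----------------------------------------------------

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "runs",
    data = list(
      preset = "tooth16", n_per_class = 10L, train_fraction = 0.765,
      height = 192L, width = 256L
    ),
    augment = list(
      p_rotation = 0.5, p_dropout = 0.2, p_perspective = 0.2,
      p_affine = 0.2, rotation_deg = 15, dropout_frac = 0.1,
      perspective_scale = 0.2, affine_translate = 0.1,
      affine_scale = c(0.9, 1.1)
    ),
    model = list(
      encoder = "tiny", side = 224L, embedding_dim = 512L,
      fusion_layers = 2L, fusion_heads = 8L, pooling = "learned_token",
      view_embedding = TRUE, num_classes = 16L
    ),
    train = list(
      batch_specimens = 16L, epochs = 300L, warmup_epochs = 60L,
      poly_power = 1.5, base_lr = 1e-4, weight_decay = 0.5,
      label_smoothing = 0.1
    ),
    eval = list(ks = c(1L, 2L, 3L)),
    consensus = list(
      weights = list(A0 = 2, A1 = 2, A2 = 1, A3 = 1), threshold = 4
    )
  )
}

#' Load a YAML run configuration
#'
#' Unknown keys are rejected; missing keys are filled from the defaults.
#' The fully resolved configuration should be serialized with every run
#' for provenance ([write_run_config()], [config_hash()]).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) {
    return(cfg)
  }
  user <- yaml::read_yaml(path)
  merge_config(cfg, user, "config")
}

merge_config <- function(base, user, where) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop(
      "unknown configuration key(s) under ", where, ": ",
      paste(unknown, collapse = ", ")
    )
  }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
      !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], paste0(where, "$", nm))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' @rdname load_run_config
#' @param config Resolved configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname load_run_config
#' @export
config_hash <- function(config) {
  text_digest(as.character(jsonlite::toJSON(config, auto_unbox = TRUE)))
}

# ---- evaluation report I/O ------------------------------------------------

#' Write / read an evaluation report as JSON
#'
#' Matrices are serialized with their class names; undefined metrics
#' (e.g. AUC of a degenerate class) become `null`. `read_report()`
#' restores the report so that `read_report(write_report(r)) == r` on all
#' metric fields.
#'
#' @param report An `eval_report` (see [evaluate_model()]).
#' @param path Output JSON path.
#' @param extra Named list merged into the top level (e.g. the resolved
#'   config hash).
#' @return `path` invisibly; `read_report` returns the `eval_report`.
#' @export
write_report <- function(report, path, extra = list()) {
  doc <- list(n = report$n)
  doc$granularities <- lapply(report$granularities, function(r) {
    list(
      n = r$n,
      topk = as.list(r$topk),
      classes = rownames(r$confusion),
      confusion = unname(apply(r$confusion, 1, as.integer, simplify = FALSE)),
      sensitivity = as.list(r$sensitivity),
      specificity = as.list(r$specificity),
      macro_sensitivity = r$macro_sensitivity,
      macro_specificity = r$macro_specificity,
      auc = as.list(r$auc),
      macro_auc = r$macro_auc,
      cohen_kappa = r$cohen_kappa,
      top1_argmax_merge = r$top1_argmax_merge
    )
  })
  doc <- c(doc, extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  grans <- lapply(doc$granularities, function(r) {
    classes <- unlist(r$classes)
    cm <- do.call(rbind, lapply(r$confusion, function(row) {
      as.integer(unlist(row))
    }))
    dimnames(cm) <- list(classes, classes)
    null_to_na <- function(x) {
      vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 1)
    }
    list(
      n = r$n,
      topk = null_to_na(r$topk),
      confusion = cm,
      sensitivity = null_to_na(r$sensitivity),
      specificity = null_to_na(r$specificity),
      macro_sensitivity = r$macro_sensitivity,
      macro_specificity = r$macro_specificity,
      auc = null_to_na(r$auc),
      macro_auc = r$macro_auc,
      cohen_kappa = lapply(r$cohen_kappa, function(v) {
        if (is.null(v)) NA_real_ else v
      }),
      top1_argmax_merge = r$top1_argmax_merge
    )
  })
  structure(
    list(n = doc$n, granularities = grans),
    class = "eval_report"
  )
}
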