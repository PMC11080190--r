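#' The six standardized view directions
#'
#' Every specimen is photographed from these six directions: the chewing
#' surface (occlusal), the root tip (apical), the cheek side (buccal), the
#' tongue side (lingual), and toward/away from the dental-arch midline
#' (mesial/distal).
#'
#' @return Character vector of the six view tags, in canonical order.
#' @export
view_tags <- function() {
  c("occlusal", "apical", "buccal", "lingual", "mesial", "distal")
}

#' Label taxonomy: fine classes plus nested coarse groupings
#'
#' A taxonomy is the fine label space together with one or more coarser
#' levels, each a total mapping from fine class to super-category. Levels
#' must be nested so that counts and probabilities can be merged upward
#' without loss.
#'
#' @param fine_classes Character vector of distinct fine class codes. Their
#'   order is the canonical column/row order for matrices and reports.
#' @param levels Named list of coarser levels. Each element is a character
#'   vector mapping fine class -> group code, named by fine class (or
#'   unnamed, aligned with `fine_classes`). List names are the level names.
#' @return An object of class `label_taxonomy`.
#' @seealso [tooth_taxonomy()] for the built-in dental taxonomy.
#' @export
label_taxonomy <- function(fine_classes, levels = list()) {
  fine_classes <- as.character(fine_classes)
  if (anyDuplicated(fine_classes)) {
    stop("fine classes must be distinct")
  }
  levels <- lapply(levels, function(map) {
    map <- as.character(map)
    if (length(map) != length(fine_classes)) {
      stop("each level must map all ", length(fine_classes), " fine classes")
    }
    names(map) <- fine_classes
    map
  })
  fine_name <- paste0(length(fine_classes), "-type")
  structure(
    list(fine_classes = fine_classes, fine_name = fine_name, levels = levels),
    class = "label_taxonomy"
  )
}

#' Built-in tooth taxonomy (16-type / 6-type / 3-type)
#'
#' The 16 fine classes are the FDI positions with left and right collapsed:
#' `U1`..`U8` (upper jaw) and `L1`..`L8` (lower jaw). The 6-type level keeps
#' the jaw and groups positions into anterior (1-3), premolar (4-5) and
#' molar (6-8): `UA, UP, UM, LA, LP, LM`. The 3-type level discards the jaw:
#' `A, P, M`.
#'
#' @return A `label_taxonomy` with levels `"6-type"` and `"3-type"`.
#' @export
tooth_taxonomy <- function() {
  fine <- c(paste0("U", 1:8), paste0("L", 1:8))
  pos <- as.integer(substr(fine, 2, 2))
  jaw <- substr(fine, 1, 1)
  typ <- ifelse(pos <= 3, "A", ifelse(pos <= 5, "P", "M"))
  label_taxonomy(
    fine,
    levels = list(
      "6-type" = paste0(jaw, typ),
      "3-type" = typ
    )
  )
}

#' @export
print.label_taxonomy <- function(x, ...) {
  cat("<label_taxonomy> ", length(x$fine_classes), " fine classes (",
    x$fine_name, ")\n",
    sep = ""
  )
  for (nm in names(x$levels)) {
    cat("  level ", nm, ": ",
      paste(taxonomy_classes(x, nm), collapse = " "), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Class codes at a given granularity
#'
#' @param taxonomy A `label_taxonomy`.
#' @param granularity Level name, e.g. `"16-type"`, `"6-type"`, `"3-type"`.
#'   The fine level may also be addressed as `"fine"`.
#' @return Character vector of category codes, ordered by first appearance
#'   of each group along the fine-class order (so coarse orders are stable).
#' @export
taxonomy_classes <- function(taxonomy, granularity = "fine") {
  stopifnot(inherits(taxonomy, "label_taxonomy"))
  if (granularity %in% c("fine", taxonomy$fine_name)) {
    return(taxonomy$fine_classes)
  }
  map <- taxonomy_map(taxonomy, granularity)
  unique(unname(map))
}

taxonomy_map <- function(taxonomy, granularity) {
  if (granularity %in% c("fine", taxonomy$fine_name)) {
    map <- taxonomy$fine_classes
    names(map) <- taxonomy$fine_classes
    return(map)
  }
  if (!granularity %in% names(taxonomy$levels)) {
    stop(
      "unknown granularity '", granularity, "'; available: ",
      paste(c(taxonomy$fine_name, names(taxonomy$levels)), collapse = ", ")
    )
  }
  taxonomy$levels[[granularity]]
}

#' Map labels to a coarser granularity
#'
#' Identity at the fine level; otherwise each label is replaced by its
#' super-category. Labels are validated against the taxonomy.
#'
#' @param label Character vector of fine class codes.
#' @param target Granularity name (see [taxonomy_classes()]).
#' @param taxonomy A `label_taxonomy`; defaults to [tooth_taxonomy()].
#' @return Character vector of category codes at the target level.
#' @examples
#' regroup_label("U6", "6-type") # "UM"
#' regroup_label("L4", "3-type") # "P"
#' @export
regroup_label <- function(label, target, taxonomy = tooth_taxonomy()) {
  label <- as.character(label)
  bad <- setdiff(unique(label), taxonomy$fine_classes)
  if (length(bad) > 0) {
    stop("unknown label code(s): ", paste(bad, collapse = ", "))
  }
  map <- taxonomy_map(taxonomy, target)
  unname(map[label])
}

#' Aggregate per-class counts to a coarser granularity
#'
#' Each super-category count is the sum of its members' counts; the grand
#' total is preserved exactly.
#'
#' @param counts Named numeric vector covering every fine class.
#' @param target Granularity name.
#' @param taxonomy A `label_taxonomy`.
#' @return Named numeric vector over the target-level categories.
#' @export
regroup_counts <- function(counts, target, taxonomy = tooth_taxonomy()) {
  missing <- setdiff(taxonomy$fine_classes, names(counts))
  if (length(missing) > 0) {
    stop("counts missing class(es): ", paste(missing, collapse = ", "))
  }
  counts <- counts[taxonomy$fine_classes]
  map <- taxonomy_map(taxonomy, target)
  out_classes <- taxonomy_classes(taxonomy, target)
  grp <- factor(map[names(counts)], levels = out_classes)
  out <- tapply(counts, grp, sum)
  res <- as.numeric(out)
  names(res) <- out_classes
  res
}

#' Normalize assorted tooth label spellings to taxonomy codes
#'
#' Accepts the canonical codes (`U6`, `L3`), and FDI two-digit codes
#' (`16` and `26` both become `U6`; `36` and `46` become `L6`).
#'
#' @param labels Character (or numeric FDI) vector.
#' @param taxonomy A `label_taxonomy`; normalization of FDI codes only makes
#'   sense for the dental taxonomy, other codes are validated as-is.
#' @return Character vector of canonical class codes.
#' @export
normalize_label <- function(labels, taxonomy = tooth_taxonomy()) {
  labels <- toupper(trimws(as.character(labels)))
  is_fdi <- grepl("^[1-4][1-8]$", labels)
  if (any(is_fdi)) {
    quad <- as.integer(substr(labels[is_fdi], 1, 1))
    pos <- substr(labels[is_fdi], 2, 2)
    jaw <- ifelse(quad <= 2, "U", "L")
    labels[is_fdi] <- paste0(jaw, pos)
  }
  bad <- setdiff(unique(labels), taxonomy$fine_classes)
  if (length(bad) > 0) {
    stop("unrecognized label(s): ", paste(bad, collapse = ", "))
  }
  labels
}

#' Export / import a taxonomy as JSON
#'
#' The document has two members: `fine_classes` (array) and `groups`
#' (object mapping level name -> object mapping fine class -> group code),
#' so the toolkit can be pointed at label spaces other than teeth.
#'
#' @param taxonomy A `label_taxonomy`.
#' @param path File path.
#' @return `write_taxonomy_json` returns `path` invisibly;
#'   `read_taxonomy_json` returns a `label_taxonomy`.
#' @export
write_taxonomy_json <- function(taxonomy, path) {
  doc <- list(
    fine_classes = taxonomy$fine_classes,
    groups = lapply(taxonomy$levels, as.list)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_taxonomy_json
#' @export
read_taxonomy_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  levels <- lapply(doc$groups, function(g) unlist(g)[doc$fine_classes])
  label_taxonomy(doc$fine_classes, levels = levels)
}

#' Hash of a taxonomy for checkpoint provenance
#' @param taxonomy A `label_taxonomy`.
#' @return A short hex digest string.
#' @export
taxonomy_hash <- function(taxonomy) {
  json <- jsonlite::toJSON(list(
    fine = taxonomy$fine_classes,
    levels = lapply(taxonomy$levels, unname)
  ), auto_unbox = TRUE)
  text_digest(as.character(json))
}

# FNV-1a style digest over a string; avoids an external digest dependency.
# Collision resistance is irrelevant here: the hash only flags accidental
# taxonomy/checkpoint mismatches.
text_digest <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h1 <- 2166136261
  h2 <- 16777619
  for (b in bytes) {
    h1 <- ((bitwXor(as.integer(h1 %% 2^16), b) * 31 + h1 %/% 2^16) %% 2^31)
    h2 <- ((h2 * 33 + b) %% 2^31)
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}
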