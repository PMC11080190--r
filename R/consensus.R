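#' Default rater weights and acceptance threshold
#'
#' Four annotations contribute to the consensus: the direct-observation
#' label from the collecting observers (`A0`), the expert's image-based
#' label (`A1`), and the collecting observers' later image-based re-labels
#' (`A2`, `A3`). The two more reliable observations carry weight 2, the
#' two less reliable ones weight 1; a category is accepted only when its
#' summed weight reaches 4.
#'
#' @return Named numeric vector of weights.
#' @export
default_rater_weights <- function() {
  c(A0 = 2, A1 = 2, A2 = 1, A3 = 1)
}

#' @rdname default_rater_weights
#' @export
default_vote_threshold <- function() 4

#' Weighted vote scores per category
#'
#' Each category's score is the sum of the weights of the raters that voted
#' for it. The scores over all categories therefore sum to the total weight.
#'
#' @param votes Named character vector: rater id -> voted label.
#' @param weights Named positive numeric vector: rater id -> weight. Must
#'   cover exactly the raters present in `votes`.
#' @return Named numeric vector of scores, sorted by decreasing score.
#' @examples
#' score_categories(c(A0 = "U3", A1 = "U3", A2 = "L3", A3 = "L3"))
#' @export
score_categories <- function(votes, weights = default_rater_weights()) {
  if (is.null(names(votes)) || is.null(names(weights))) {
    stop("votes and weights must be named by rater id")
  }
  only_votes <- setdiff(names(votes), names(weights))
  only_weights <- setdiff(names(weights), names(votes))
  if (length(only_votes) || length(only_weights)) {
    stop(
      "rater mismatch between votes and weights: ",
      paste(c(only_votes, only_weights), collapse = ", ")
    )
  }
  if (any(weights <= 0)) stop("rater weights must be strictly positive")
  w <- weights[names(votes)]
  scores <- tapply(w, factor(as.character(votes)), sum)
  out <- as.numeric(scores)
  names(out) <- names(scores)
  sort(out, decreasing = TRUE)
}

#' Weighted-voting refinement of a multi-rater annotation table
#'
#' Converts per-specimen rater votes into pseudo-ground-truth (P-GT) labels
#' or removes the specimen as ambiguous. A specimen is accepted when some
#' category's weighted score reaches the threshold, and the accepted label
#' is the unique highest-scoring such category; under the default weights
#' (2, 2, 1, 1) and threshold 4 no two categories can reach the threshold
#' simultaneously, so the outcome is always unambiguous. For non-default
#' configurations where two categories tie at the threshold with equal
#' maximal score, the specimen is removed (treated as ambiguous).
#'
#' @param annotations A data.frame with columns `specimen_id`, `rater_id`,
#'   `label` (long format, one row per vote), or a named list of named vote
#'   vectors.
#' @param weights Named rater weights; see [default_rater_weights()].
#' @param threshold Minimum accepted score; default 4.
#' @return A `refinement_result`: data.frame `outcomes` with columns
#'   `specimen_id`, `outcome` (`"accepted"`/`"removed"`), `label` (P-GT or
#'   `NA`), `max_score`; list `scores` of per-specimen score tables; and
#'   counts `kept`/`removed`.
#' @export
refine <- function(annotations, weights = default_rater_weights(),
                   threshold = default_vote_threshold()) {
  votes_by_specimen <- as_vote_list(annotations)
  n <- length(votes_by_specimen)
  ids <- names(votes_by_specimen)
  outcome <- character(n)
  label <- rep(NA_character_, n)
  max_score <- numeric(n)
  scores <- vector("list", n)
  names(scores) <- ids
  for (i in seq_len(n)) {
    s <- score_categories(votes_by_specimen[[i]], weights)
    scores[[i]] <- s
    max_score[i] <- s[1]
    reaching <- s[s >= threshold]
    if (length(reaching) >= 1 && sum(s == s[1]) == 1) {
      outcome[i] <- "accepted"
      label[i] <- names(s)[1]
    } else {
      outcome[i] <- "removed"
    }
  }
  outcomes <- data.frame(
    specimen_id = ids, outcome = outcome, label = label,
    max_score = max_score, stringsAsFactors = FALSE
  )
  structure(
    list(
      outcomes = outcomes, scores = scores,
      kept = sum(outcome == "accepted"), removed = sum(outcome == "removed"),
      weights = weights, threshold = threshold
    ),
    class = "refinement_result"
  )
}

#' @export
print.refinement_result <- function(x, ...) {
  cat("<refinement_result> ", nrow(x$outcomes), " specimens: ",
    x$kept, " kept, ", x$removed, " removed (threshold ",
    x$threshold, ")\n",
    sep = ""
  )
  invisible(x)
}

# Accepts long data.frame or list of named vote vectors; enforces complete,
# single votes per (specimen, rater).
as_vote_list <- function(annotations) {
  if (is.data.frame(annotations)) {
    required <- c("specimen_id", "rater_id", "label")
    if (!all(required %in% names(annotations))) {
      stop(
        "annotation table needs columns: ",
        paste(required, collapse = ", ")
      )
    }
    split_rows <- split(annotations, annotations$specimen_id)
    votes <- lapply(split_rows, function(d) {
      if (anyDuplicated(d$rater_id)) {
        stop(
          "duplicate vote(s) for specimen ", d$specimen_id[1], ": ",
          paste(d$rater_id[duplicated(d$rater_id)], collapse = ", ")
        )
      }
      v <- as.character(d$label)
      names(v) <- as.character(d$rater_id)
      v
    })
    # keep first-appearance order of specimens
    votes[unique(as.character(annotations$specimen_id))]
  } else if (is.list(annotations)) {
    if (is.null(names(annotations))) {
      names(annotations) <- as.character(seq_along(annotations))
    }
    annotations
  } else {
    stop("annotations must be a data.frame or a list of vote vectors")
  }
}

#' The two-condition acceptance rule, stated directly
#'
#' Independent restatement of the default consensus configuration: with two
#' reliable raters (weight 2) and two less reliable raters (weight 1), a
#' specimen is accepted iff (1) the two reliable raters agree, or (2) they
#' disagree but one of them agrees with both less reliable raters. Used as
#' an exhaustive cross-check of [refine()]; the accepted label is the
#' agreeing category.
#'
#' @param a0,a1,a2,a3 Single labels from the four raters (a0, a1 reliable).
#' @return List with `accepted` (logical) and `label` (or `NA`).
#' @export
two_condition_rule <- function(a0, a1, a2, a3) {
  if (a0 == a1) {
    return(list(accepted = TRUE, label = a0))
  }
  if (a0 == a2 && a0 == a3) {
    return(list(accepted = TRUE, label = a0))
  }
  if (a1 == a2 && a1 == a3) {
    return(list(accepted = TRUE, label = a1))
  }
  list(accepted = FALSE, label = NA_character_)
}
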