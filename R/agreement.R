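#' Cohen's kappa between two labelings
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` from the product of the two marginal
#' distributions, and an asymptotic 95% confidence interval from
#' `SE = sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`. If both labelings are the
#' same constant (`p_e = 1`), kappa is defined as 1 and flagged.
#'
#' @param a,b Aligned categorical vectors.
#' @return List: `kappa`, `p_o`, `p_e`, `se`, `ci_lower`, `ci_upper`, `n`,
#'   `degenerate` (TRUE when `p_e = 1`).
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("labelings differ in length")
  n <- length(a)
  cats <- sort(unique(c(as.character(a), as.character(b))))
  fa <- factor(a, levels = cats)
  fb <- factor(b, levels = cats)
  tab <- table(fa, fb) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - p_e) < 1e-12) {
    return(list(
      kappa = 1, p_o = p_o, p_e = p_e, se = 0,
      ci_lower = 1, ci_upper = 1, n = n, degenerate = TRUE
    ))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  list(
    kappa = kappa, p_o = p_o, p_e = p_e, se = se,
    ci_lower = kappa - 1.96 * se, ci_upper = kappa + 1.96 * se,
    n = n, degenerate = FALSE
  )
}

#' Fleiss' kappa among three or more raters
#'
#' Standard Fleiss formulation for `N` subjects each rated by the same
#' number `n` of raters. The 95% confidence interval is a percentile
#' bootstrap over subjects (the published tables report CIs without naming
#' a method; resampling subjects makes no distributional assumption).
#'
#' @param ratings Matrix or data.frame of labels, rows = subjects,
#'   columns = raters; or a long annotation data.frame with columns
#'   `specimen_id`, `rater_id`, `label`.
#' @param n_boot Bootstrap resamples for the CI (default 2000; 0 skips
#'   the CI).
#' @param seed Seed for the bootstrap.
#' @return List: `kappa`, `ci_lower`, `ci_upper`, `n_subjects`,
#'   `n_raters`.
#' @export
fleiss_kappa <- function(ratings, n_boot = 2000L, seed = 1L) {
  ratings <- as_rating_matrix(ratings)
  n_sub <- nrow(ratings)
  n_rat <- ncol(ratings)
  if (n_rat < 2) stop("Fleiss' kappa needs at least 2 raters")
  cats <- sort(unique(as.character(ratings)))
  counts <- count_matrix(ratings, cats)
  k <- fleiss_from_counts(counts, n_rat)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n_sub, replace = TRUE)
        fleiss_from_counts(counts[idx, , drop = FALSE], n_rat)
      }, numeric(1))
    })
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  list(
    kappa = k, ci_lower = ci[1], ci_upper = ci[2],
    n_subjects = n_sub, n_raters = n_rat
  )
}

as_rating_matrix <- function(ratings) {
  if (is.data.frame(ratings) &&
    all(c("specimen_id", "rater_id", "label") %in% names(ratings))) {
    wide <- stats::reshape(
      ratings[, c("specimen_id", "rater_id", "label")],
      idvar = "specimen_id", timevar = "rater_id", direction = "wide"
    )
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$specimen_id
    if (anyNA(m)) stop("unequal rater counts per specimen")
    return(m)
  }
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("unequal rater counts per specimen")
  m
}

count_matrix <- function(ratings, cats) {
  t(apply(ratings, 1, function(r) {
    tabulate(factor(r, levels = cats), nbins = length(cats))
  }))
}

fleiss_from_counts <- function(counts, n_rat) {
  n_sub <- nrow(counts)
  p_j <- colSums(counts) / (n_sub * n_rat)
  p_i <- (rowSums(counts^2) - n_rat) / (n_rat * (n_rat - 1))
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  if (abs(1 - p_e) < 1e-12) {
    return(1)
  }
  (p_bar - p_e) / (1 - p_e)
}

#' Agreement summary across granularities
#'
#' Computes Fleiss' kappa among the raters of an annotation table at the
#' fine level and at every coarse level of the taxonomy (labels regrouped
#' before the computation), optionally restricted to a subset of
#' specimens (e.g. the consensus-refined test set).
#'
#' @param annotations Long annotation data.frame (`specimen_id`,
#'   `rater_id`, `label`).
#' @param taxonomy A `label_taxonomy`.
#' @param specimen_ids Optional subset of specimens.
#' @param n_boot,seed Passed to [fleiss_kappa()].
#' @return data.frame with one row per granularity: `granularity`,
#'   `fleiss_kappa`, `ci_lower`, `ci_upper`, `n_subjects`.
#' @export
agreement_by_granularity <- function(annotations,
                                     taxonomy = tooth_taxonomy(),
                                     specimen_ids = NULL,
                                     n_boot = 2000L, seed = 1L) {
  if (!is.null(specimen_ids)) {
    annotations <- annotations[annotations$specimen_id %in% specimen_ids, ]
  }
  grans <- c(taxonomy$fine_name, names(taxonomy$levels))
  rows <- lapply(grans, function(g) {
    ann <- annotations
    ann$label <- regroup_label(ann$label, g, taxonomy)
    fk <- fleiss_kappa(ann, n_boot = n_boot, seed = seed)
    data.frame(
      granularity = g, fleiss_kappa = fk$kappa,
      ci_lower = fk$ci_lower, ci_upper = fk$ci_upper,
      n_subjects = fk$n_subjects, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
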