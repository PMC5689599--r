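# ROC comparison of disease rankings against a gold trait list. Gold
# membership is the positive label; the ranking score is the decision
# statistic (ascending rankings such as min adjusted p are negated so that
# larger always means "more related").

#' ROC curve and AUC of a disease ranking against a gold list
#'
#' Thresholds sweep the distinct score values; tied scores are grouped, so a
#' tied positive-negative pair contributes 0.5 to the AUC (trapezoidal area,
#' equivalent to the normalized Mann-Whitney U statistic).
#'
#' @param ranking a `disease_ranking` (from [rank_diseases()],
#'   [obsp_rank()] or [oboverlap_rank()]), or any tibble with `disease_id`
#'   and `score` plus a `direction` attribute.
#' @param gold character vector of positive trait ids.
#' @param missing how to treat gold diseases absent from the ranking:
#'   "worst" (default) scores them at the worst observed score (p = 1 for
#'   p-value rankings), "drop" ignores them.
#' @param blocklist trait ids excluded from the evaluation (e.g. the query
#'   trait itself or self-referential traits like body-mass-index measures,
#'   whose gold membership is circular).
#' @param universe optional character vector of all evaluated disease ids;
#'   when given, every universe disease absent from the ranking (not only
#'   the gold ones) is appended at the worst score, so diseases that never
#'   reached an eligible module still count as negatives or missed
#'   positives.
#' @return a `roc_curve`: tibble (threshold, tpr, fpr) with attributes
#'   `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(ranking, gold, missing = c("worst", "drop"),
                    blocklist = character(), universe = NULL) {
  missing <- match.arg(missing)
  ascending <- identical(attr(ranking, "direction"), "ascending") ||
    is.null(attr(ranking, "direction"))  # p-value-like by default
  tb <- tibble(disease_id = ranking$disease_id, score = ranking$score)
  tb <- dplyr::filter(tb, !.data$disease_id %in% blocklist)
  gold <- setdiff(unique(gold), blocklist)
  pool <- if (is.null(universe)) gold else setdiff(unique(universe), blocklist)
  absent <- setdiff(pool, tb$disease_id)
  if (length(absent) > 0 && missing == "worst") {
    worst <- if (ascending) max(c(tb$score[is.finite(tb$score)], 1)) else
      min(c(tb$score[is.finite(tb$score)], 0))
    tb <- dplyr::bind_rows(tb, tibble(disease_id = absent, score = worst))
  }
  tb$label <- tb$disease_id %in% gold
  n_pos <- sum(tb$label)
  n_neg <- sum(!tb$label)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC needs at least one gold and one non-gold ranked disease")
  }
  stat <- if (ascending) -tb$score else tb$score
  stat[stat == -Inf] <- -.Machine$double.xmax
  stat[stat == Inf] <- .Machine$double.xmax
  ord <- order(-stat)
  stat <- stat[ord]
  lab <- tb$label[ord]
  # group tied statistics into single thresholds
  grp <- cumsum(!duplicated(stat))
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  last <- which(!duplicated(grp, fromLast = TRUE))
  curve <- tibble(
    threshold = stat[last],
    tpr = tp[last] / n_pos,
    fpr = fp[last] / n_neg
  )
  fpr <- c(0, curve$fpr)
  tpr <- c(0, curve$tpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(curve, auc = auc, n_pos = n_pos, n_neg = n_neg,
            class = c("roc_curve", class(curve)))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d positives, %d negatives)\n",
              attr(x, "auc"), attr(x, "n_pos"), attr(x, "n_neg")))
  NextMethod()
}

#' @rdname roc_auc
#' @param x a `roc_curve`.
#' @param ... unused.
#' @export
glance.roc_curve <- function(x, ...) {
  tibble(auc = attr(x, "auc"), n_pos = attr(x, "n_pos"),
         n_neg = attr(x, "n_neg"))
}

#' @rdname roc_auc
#' @export
tidy.roc_curve <- function(x, ...) as_tibble(x)
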