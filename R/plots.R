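# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#' @param object a `roc_curve` from [roc_auc()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  tb <- dplyr::bind_rows(tibble(fpr = 0, tpr = 0), as_tibble(object))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot a disease ranking
#'
#' Shows the per-disease score on a -log10 scale for p-value rankings, or
#' raw scale otherwise, optionally colouring gold-list membership.
#'
#' @param object a `disease_ranking`.
#' @param gold optional character vector of gold trait ids.
#' @param top show only the top `top` diseases; default 30.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.disease_ranking <- function(object, gold = NULL, top = 30, ...) {
  tb <- head(as_tibble(object), top)
  pval_like <- identical(attr(object, "direction"), "ascending") &&
    all(tb$score >= 0 & tb$score <= 1)
  tb$value <- if (pval_like) -log10(pmax(tb$score, 1e-300)) else tb$score
  tb$disease_id <- factor(tb$disease_id, levels = rev(tb$disease_id))
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$value, y = .data$disease_id))
  if (!is.null(gold)) {
    tb$gold <- tb$disease_id %in% gold
    p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$value, y = .data$disease_id,
                                          fill = .data$gold))
  }
  p + ggplot2::geom_col() +
    ggplot2::labs(x = if (pval_like) "-log10(min adjusted p)" else
                    attr(object, "statistic") %||% "score",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname rank_diseases
#' @param x a `disease_ranking`.
#' @param ... unused.
#' @export
tidy.disease_ranking <- function(x, ...) as_tibble(x)

#' @rdname rank_diseases
#' @export
glance.disease_ranking <- function(x, ...) {
  tibble(n_diseases = nrow(x),
         statistic = attr(x, "statistic") %||% NA_character_,
         direction = attr(x, "direction") %||% NA_character_)
}
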