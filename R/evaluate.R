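#' Confusion counts of a dichotomous prediction
#'
#' Tallies true/false positives and negatives by matching predicted to true
#' labels per spot id.
#'
#' @param predicted character/factor of predicted labels (`"positive"` /
#'   `"negative"`), named by spot id (or supply `ids`).
#' @param truth true labels, named by spot id (or supply `ids`).
#' @param ids optional spot ids, used for both vectors when they are
#'   unnamed.
#' @return List of class `confusion_counts` with integer `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_counts <- function(predicted, truth, ids = NULL) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (!is.null(ids)) {
    names(predicted) <- names(truth) <- as.character(ids)
  }
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    if (!setequal(names(predicted), names(truth))) {
      stop("spot ids of predictions and truth do not match")
    }
    predicted <- predicted[names(truth)]
  } else if (length(predicted) != length(truth)) {
    stop("predictions and truth have different lengths and no ids")
  }
  ok <- c("positive", "negative")
  if (!all(predicted %in% ok) || !all(truth %in% ok)) {
    stop("labels must be 'positive' or 'negative'")
  }
  structure(list(tp = sum(predicted == "positive" & truth == "positive"),
                 fp = sum(predicted == "positive" & truth == "negative"),
                 tn = sum(predicted == "negative" & truth == "negative"),
                 fn = sum(predicted == "negative" & truth == "positive")),
            class = "confusion_counts")
}

#' Sensitivity, specificity and Youden index from confusion counts
#'
#' Sensitivity is the fraction of true positives identified,
#' `tp / (tp + fn)`; specificity the fraction of true negatives identified,
#' `tn / (tn + fp)`; and the Youden index combines both into a single
#' performance score, `J = sens + spc - 1` (1 = perfect sorting, 0 = chance,
#' negative = systematically inverted).
#'
#' @param counts a [confusion_counts()] object, or a list with fields
#'   `tp`, `fp`, `tn`, `fn`.
#' @return List of class `eval_result` with `sens`, `spc`, `J` and the
#'   counts.
#' @export
sens_spc_j <- function(counts) {
  with(counts, {
    if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
    if (tp + fn == 0) stop("no true positives in the score set: sensitivity undefined")
    if (tn + fp == 0) stop("no true negatives in the score set: specificity undefined")
    sens <- tp / (tp + fn)
    spc <- tn / (tn + fp)
    structure(list(sens = sens, spc = spc, J = sens + spc - 1,
                   counts = list(tp = tp, fp = fp, tn = tn, fn = fn)),
              class = "eval_result")
  })
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> sens %.3f, spc %.3f, J %.3f\n",
              x$sens, x$spc, x$J))
  invisible(x)
}

#' Youden index from sensitivity and specificity
#'
#' `J = sens + spc - 1`. Vectorized; used for worked examples where only the
#' two fractions are reported.
#'
#' @param sens sensitivity in \[0, 1\].
#' @param spc specificity in \[0, 1\].
#' @return Youden index in \[-1, 1\].
#' @export
youden_index <- function(sens, spc) {
  if (any(sens < 0 | sens > 1) || any(spc < 0 | spc > 1)) {
    stop("sens and spc must lie in [0, 1]")
  }
  sens + spc - 1
}

#' Collapse trial results to ROC scatter points with multiplicities
#'
#' The trials of a hyperparameter grid are dichotomous classifiers, so each
#' maps to a single (false positive rate, true positive rate) point rather
#' than a threshold-swept curve; identical outcomes are collapsed and
#' annotated with the number of trials observing them.
#'
#' @param results a `trial_grid_result` (see [run_grid()]) or any data.frame
#'   with `sens` and `spc` columns; alternatively a list of `eval_result`s.
#' @return data.frame of class `roc_scatter` with columns `fpr`, `tpr`,
#'   `multiplicity` (summing to the number of trials).
#' @export
roc_scatter <- function(results) {
  if (is.data.frame(results)) {
    sens <- results$sens; spc <- results$spc
  } else {
    sens <- vapply(results, `[[`, numeric(1), "sens")
    spc <- vapply(results, `[[`, numeric(1), "spc")
  }
  if (!length(sens)) stop("need at least one trial result")
  key <- paste(signif(1 - spc, 12), signif(sens, 12))
  tab <- table(key)
  first <- !duplicated(key)
  out <- data.frame(fpr = (1 - spc)[first], tpr = sens[first],
                    multiplicity = as.integer(tab[key[first]]))
  out <- out[order(out$fpr, out$tpr), ]
  rownames(out) <- NULL
  class(out) <- c("roc_scatter", "data.frame")
  out
}

#' Plot an ROC scatter with trial multiplicities
#'
#' @param x a [roc_scatter()] (or objects coercible by it).
#' @param col point colour.
#' @param add overlay on an existing plot.
#' @param ... further [graphics::points()] arguments.
#' @return `x`, invisibly.
#' @export
plot_roc_scatter <- function(x, col = "forestgreen", add = FALSE, ...) {
  if (!inherits(x, "roc_scatter")) x <- roc_scatter(x)
  if (!add) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "1 - specificity", ylab = "sensitivity")
    graphics::abline(0, 1, lty = 3, col = "grey60")
  }
  graphics::points(x$fpr, x$tpr, pch = 19, col = col, ...)
  graphics::text(x$fpr, x$tpr, labels = x$multiplicity, pos = 4, cex = 0.8,
                 col = col)
  invisible(x)
}

#' Compare Youden indices of two conditions
#'
#' Tests whether two sets of per-trial Youden indices (for example digested
#' versus intact acquisitions of one case) differ in mean, using Welch's
#' two-sample t-test (two-sided, unequal variances) - a conservative default
#' for small trial sets. Also reports the ratio of mean J values,
#' `mean(js_a) / mean(js_b)`. Means are computed at full precision from the
#' per-trial values, never from rounded averages. Two identical
#' zero-variance inputs are degenerate for the t statistic and return
#' `p = 1` by convention (with a message).
#'
#' @param js_a,js_b numeric vectors of per-trial J values, each length >= 2.
#' @param alpha significance level (default 0.05).
#' @param names optional length-2 labels for the two conditions.
#' @return List of class `comparison_result` with `mean_J_a`, `mean_J_b`,
#'   `ratio`, `p_value`, `significant`, `alpha`, `test` and the condition
#'   names.
#' @export
compare_conditions <- function(js_a, js_b, alpha = 0.05,
                               names = c("a", "b")) {
  if (length(js_a) < 2 || length(js_b) < 2) {
    stop("each condition needs at least 2 trial J values")
  }
  degenerate <- stats::var(js_a) == 0 && stats::var(js_b) == 0
  if (degenerate && isTRUE(all.equal(mean(js_a), mean(js_b)))) {
    message("identical zero-variance conditions: p = 1 by convention")
    p <- 1
  } else if (degenerate) {
    # constant but different: separation is exact
    p <- 0
  } else {
    p <- stats::t.test(js_a, js_b, var.equal = FALSE)$p.value
  }
  structure(list(mean_J_a = mean(js_a), mean_J_b = mean(js_b),
                 ratio = mean(js_a) / mean(js_b),
                 p_value = p, significant = p < alpha, alpha = alpha,
                 test = "Welch two-sample t-test (two-sided)",
                 conditions = names),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> mean J %s = %.3f, %s = %.3f (ratio %.2f)\n  %s: p = %.4g (%ssignificant at alpha = %g)\n",
    x$conditions[1], x$mean_J_a, x$conditions[2], x$mean_J_b, x$ratio,
    x$test, x$p_value, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}
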