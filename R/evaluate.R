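# Classification metrics and the channel-wise raw-EEG statistical screen.

#' Evaluate predictions against labels
#'
#' Builds the confusion matrix and computes accuracy plus
#' precision/recall/F1. Averaging is macro by default (robust under class
#' imbalance); micro and support-weighted averaging are available.
#'
#' @param predicted,actual Equal-length label vectors.
#' @param average `"macro"` (default), `"micro"` or `"weighted"`.
#' @return A `ctesm_eval`: list with `confusion` (actual rows x predicted
#'   columns), `accuracy`, `precision`, `recall`, `f1`, `support` and the
#'   per-class metric table.
#' @export
#' @examples
#' evaluate_predictions(c("PD", "PD", "HC"), c("PD", "HC", "HC"))
evaluate_predictions <- function(predicted, actual,
                                 average = c("macro", "micro", "weighted")) {
  average <- match.arg(average)
  if (length(predicted) != length(actual)) {
    stop_validation(sprintf(
      "length mismatch: %d predictions vs %d labels",
      length(predicted), length(actual)))
  }
  classes <- sort(unique(c(as.character(predicted), as.character(actual))))
  if (length(classes) < 2L) {
    stop_validation("need at least 2 distinct classes across labels")
  }
  pf <- factor(predicted, levels = classes)
  af <- factor(actual, levels = classes)
  cm <- table(actual = af, predicted = pf)
  acc <- sum(diag(cm)) / sum(cm)
  tp <- diag(cm)
  per_class <- data.frame(
    class = classes,
    precision = ifelse(colSums(cm) > 0, tp / colSums(cm), 0),
    recall = ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0),
    support = as.numeric(rowSums(cm)),
    row.names = NULL
  )
  per_class$f1 <- ifelse(per_class$precision + per_class$recall > 0,
                         2 * per_class$precision * per_class$recall /
                           (per_class$precision + per_class$recall), 0)
  agg <- switch(average,
    macro = c(precision = mean(per_class$precision),
              recall = mean(per_class$recall),
              f1 = mean(per_class$f1)),
    weighted = {
      w <- per_class$support / sum(per_class$support)
      c(precision = sum(w * per_class$precision),
        recall = sum(w * per_class$recall),
        f1 = sum(w * per_class$f1))
    },
    micro = c(precision = acc, recall = acc, f1 = acc)
  )
  structure(
    list(confusion = cm, accuracy = acc,
         precision = unname(agg["precision"]), recall = unname(agg["recall"]),
         f1 = unname(agg["f1"]), support = per_class$support,
         per_class = per_class, average = average),
    class = "ctesm_eval"
  )
}

#' @export
print.ctesm_eval <- function(x, ...) {
  cat(sprintf(
    "<ctesm_eval> accuracy %.4f | %s precision %.4f recall %.4f F1 %.4f\n",
    x$accuracy, x$average, x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Channel-wise statistical screen of raw EEG
#'
#' For each channel, each subject's mean signal amplitude is computed and
#' the two groups (PD vs HC) are compared by a two-sample t-test and a
#' one-way ANOVA. With two groups and equal variances assumed these are the
#' same test (t squared equals F), so the two p-value columns agree — the
#' paired presentation mirrors the conventional screening table. No
#' multiple-testing correction is applied by default; Benjamini-Hochberg
#' adjusted columns can be added.
#'
#' @param cohort A `ctesm_cohort` or list of recordings with labels.
#' @param var_equal Use the pooled-variance (Student) t-test (default TRUE,
#'   keeping the t^2 = F identity exact); FALSE gives Welch.
#' @param adjust `"none"` (default) or `"BH"` to append adjusted columns.
#' @param stat Per-subject summary statistic of each channel: `"mean"`
#'   (default, the raw-amplitude screen) or a function of a numeric vector.
#' @return Data frame with one row per channel: `channel`, `t_stat`,
#'   `t_p`, `f_stat`, `anova_p` (and `t_p_adj`/`anova_p_adj` if requested).
#' @export
channel_screen <- function(cohort, var_equal = TRUE, adjust = c("none", "BH"),
                           stat = "mean") {
  adjust <- match.arg(adjust)
  labels <- cohort_labels(cohort)
  groups <- unique(labels)
  if (length(groups) != 2L) {
    stop_validation("channel screen requires exactly 2 groups")
  }
  if (any(table(labels) < 2L)) {
    stop_validation("each group needs at least 2 subjects")
  }
  fun <- if (is.function(stat)) stat else match.fun(stat)
  summ <- t(vapply(cohort, function(r) apply(r$signal, 2, fun),
                   numeric(ncol(cohort[[1]]$signal))))
  nc <- ncol(summ)
  out <- data.frame(channel = seq_len(nc), t_stat = NA_real_, t_p = NA_real_,
                    f_stat = NA_real_, anova_p = NA_real_)
  g <- factor(labels)
  for (ch in seq_len(nc)) {
    v <- summ[, ch]
    if (stats::var(v) == 0) {          # degenerate: identical values
      out$t_stat[ch] <- 0; out$t_p[ch] <- 1
      out$f_stat[ch] <- 0; out$anova_p[ch] <- 1
      next
    }
    tt <- stats::t.test(v ~ g, var.equal = var_equal)
    av <- stats::anova(stats::aov(v ~ g))
    out$t_stat[ch] <- unname(tt$statistic)
    out$t_p[ch] <- tt$p.value
    out$f_stat[ch] <- av$`F value`[1]
    out$anova_p[ch] <- av$`Pr(>F)`[1]
  }
  if (adjust == "BH") {
    out$t_p_adj <- stats::p.adjust(out$t_p, "BH")
    out$anova_p_adj <- stats::p.adjust(out$anova_p, "BH")
  }
  out
}
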