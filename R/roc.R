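#' ROC curve for the mean alpha ratio biomarker
#'
#' Positive class = patient; classification rule: score >= threshold is
#' called a patient (a higher log ratio is more patient-like).  Ties are
#' grouped at a single threshold, which makes the trapezoidal AUC equal the
#' Mann-Whitney statistic U / (n_pos * n_neg) with ties counted half.
#' Thresholds are the sorted unique scores plus a +Inf sentinel (the
#' all-negative operating point).
#'
#' @param scores Finite per-subject numeric scores.
#' @param labels Logical/0-1 vector (TRUE/1 = patient) or character/factor
#'   equal to `positive_label` for patients; both classes must be present.
#' @param positive_label Label of the positive class for character/factor
#'   input (default `"patient"`).
#' @return A `roc_result`: list with `thresholds`, `fpr`, `tpr`, `auc`,
#'   `n_pos`, `n_neg`, `positive_label`.
#' @export
roc_curve <- function(scores, labels, positive_label = "patient") {
  if (!all(is.finite(scores))) stop("scores must be finite")
  pos <- if (is.logical(labels)) labels
         else if (is.numeric(labels)) labels != 0
         else as.character(labels) == positive_label
  if (length(pos) != length(scores))
    stop("scores and labels must have equal length")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present (got ", n_pos, " positives, ",
         n_neg, " negatives)")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg,
                 positive_label = positive_label),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d patients vs %d controls, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("Mean alpha ratio ROC (AUC = %.3f)", x$auc),
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Evaluate the mean alpha ratio as a patient/control biomarker
#'
#' Composes [global_mean_ratio()] with [roc_curve()] and attaches the
#' control-vs-patient unpaired t-test on the same subject-level means.
#'
#' @param table An [alpha_ratio_table()] with >= 2 subjects per class.
#' @param patient_groups Groups forming the positive class.
#' @param variant Unpaired t-test variant.
#' @return A `biomarker_eval`: list with `roc` (`roc_result`), `scores`,
#'   `labels`, `group_means` (named: control, patient) and `t_test`
#'   (`test_result`, patients minus controls).
#' @export
evaluate_biomarker <- function(table, patient_groups = c("left_TLE", "right_TLE"),
                               variant = "student") {
  stopifnot(inherits(table, "alpha_ratio_table"))
  gm <- global_mean_ratio(table)
  is_pat <- table$subjects$group %in% patient_groups
  if (sum(is_pat) < 2 || sum(!is_pat) < 2)
    stop("need >= 2 subjects per class (got ", sum(is_pat), " patients, ",
         sum(!is_pat), " controls)")
  roc <- roc_curve(gm, is_pat)
  tt <- unpaired_t(gm[is_pat], gm[!is_pat], variant = variant)
  tt$comparison <- "patients vs controls, global mean alpha ratio"
  structure(list(roc = roc, scores = gm, labels = is_pat,
                 group_means = c(control = mean(gm[!is_pat]),
                                 patient = mean(gm[is_pat])),
                 t_test = tt),
            class = "biomarker_eval")
}

#' @export
print.biomarker_eval <- function(x, ...) {
  cat("<biomarker_eval> subject-level mean alpha power log ratio\n")
  cat(sprintf("  group means: control %.4f, patient %.4f\n",
              x$group_means["control"], x$group_means["patient"]))
  cat(sprintf("  unpaired t = %.3f, p = %.3g;  AUC = %.4f\n",
              x$t_test$statistic, x$t_test$p_value, x$roc$auc))
  invisible(x)
}
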