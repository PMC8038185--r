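# Discrimination reporting: rank-based AUC and the age-group-specific
# AUC table comparing full, compact and index models.

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney form: the probability a random case outscores a random
#' control, with ties counted as one half. Equivalent to trapezoidal
#' integration of the empirical ROC curve.
#'
#' @param scores numeric predictions (higher = more DR-like).
#' @param labels 0/1 outcome.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when only one class
#'   is present.
#' @export
#' @examples
#' auc(c(1, 2, 3, 4), c(0, 0, 1, 1))  # 1
auc <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile bootstrap over patients. Not part of the standard reports
#' (the derivation workflow reports point AUCs only); provided as an
#' opt-in helper.
#'
#' @param scores,labels as in [auc()].
#' @param n_boot bootstrap replicates.
#' @param conf_level confidence level.
#' @param seed integer seed.
#' @return Named vector `auc`, `ci_low`, `ci_high`.
#' @export
auc_ci <- function(scores, labels, n_boot = 500L, conf_level = 0.95,
                   seed = 1L) {
  point <- auc(scores, labels)
  n <- length(scores)
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    suppressWarnings(auc(scores[i], labels[i]))
  }, numeric(1)))
  qs <- stats::quantile(reps, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                        na.rm = TRUE, names = FALSE)
  c(auc = point, ci_low = qs[1], ci_high = qs[2])
}

#' Age-group-specific AUC report
#'
#' Computes the overall AUC and the AUC within each age group. Groups
#' with fewer than two distinct labels are reported as `NA` (undefined),
#' never as zero.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 outcome.
#' @param age_groups character vector of group labels per patient.
#' @param model name recorded in the report.
#' @return Object of class `eval_report`: data.frame with columns
#'   `model`, `group` (`"overall"` first), `n`, `events`, `auc`.
#' @export
age_specific_auc <- function(scores, labels, age_groups, model = "model") {
  groups <- c("overall", .AGE_LABELS[.AGE_LABELS %in% unique(age_groups)])
  rows <- lapply(groups, function(g) {
    sel <- if (g == "overall") rep(TRUE, length(scores)) else age_groups == g
    a <- suppressWarnings(auc(scores[sel], labels[sel]))
    data.frame(model = model, group = g, n = sum(sel),
               events = sum(labels[sel] == 1L), auc = a,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat("AUC report (", x$model[1], ")\n", sep = "")
  df <- as.data.frame(x)
  df$auc <- round(df$auc, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
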