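# Bivariate screening of the 26 candidate variables: chi-squared tests
# for categorical variables, two-sample t-tests for labs, and per-level
# odds ratios with Woolf (log-scale) confidence intervals against a
# designated reference level. Variables with p < alpha survive to
# predictor selection.

# Reference levels used for the per-level odds ratios (the same levels
# the published bivariate table anchors on).
.REFERENCE_LEVELS <- c(
  age_group = ">=85", gender = "Female", race = "Black",
  duration_group = "0-1", nephropathy = "0", neuropathy = "0"
)

#' Pearson chi-squared test on a contingency table
#'
#' Thin wrapper over `stats::chisq.test` with the continuity correction
#' disabled, with explicit degenerate-margin errors.
#'
#' @param contingency matrix of counts (levels x outcome).
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi_squared_test <- function(contingency) {
  contingency <- as.matrix(contingency)
  rs <- rowSums(contingency); cs <- colSums(contingency)
  if (any(rs == 0) || any(cs == 0)) {
    bad <- c(rownames(contingency)[rs == 0], colnames(contingency)[cs == 0])
    stopf("degenerate contingency table: zero marginal for %s",
          paste(if (length(bad)) bad else "an unnamed level", collapse = ", "))
  }
  ct <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       df = unname(ct$parameter))
}

#' Two-sample t-test for a laboratory variable
#'
#' Welch's unequal-variance test by default (set `var_equal = TRUE` for
#' the pooled version).
#'
#' @param case_values,control_values numeric vectors (n >= 2 each).
#' @param var_equal pool the variances?
#' @return List with `statistic`, `p_value`, `df`.
#' @export
two_sample_t <- function(case_values, control_values, var_equal = FALSE) {
  if (length(case_values) < 2L || length(control_values) < 2L) {
    stopf("both groups need at least 2 values")
  }
  tt <- stats::t.test(case_values, control_values, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = unname(tt$p.value),
       df = unname(tt$parameter))
}

#' Odds ratio with Woolf confidence interval
#'
#' For an exposed level against a reference level, with counts given as
#' (DR cases, level total): `OR = (a*d)/(b*c)` on the implied 2x2 table
#' and `CI = exp(log(OR) +/- z*sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param exposed,reference length-2 vectors `c(dr, total)`.
#' @param conf_level confidence level (default 0.95, z = 1.96).
#' @return List with `or`, `ci_low`, `ci_high`, `p_value` (Wald, on the
#'   log OR).
#' @export
#' @examples
#' odds_ratio_ci(c(1038, 5723), c(2711, 92153))  # OR 7.31
odds_ratio_ci <- function(exposed, reference, conf_level = 0.95) {
  a <- exposed[1]; b <- exposed[2] - exposed[1]
  c_ <- reference[1]; d <- reference[2] - reference[1]
  cells <- c(a = a, b = b, c = c_, d = d)
  if (any(cells <= 0)) {
    stopf("zero cell in 2x2 table (%s); apply a continuity policy upstream",
          paste(names(cells)[cells <= 0], collapse = ", "))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(or = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       p_value = 2 * stats::pnorm(-abs(log(or) / se)))
}

#' Screen candidate variables for association with DR
#'
#' Applies the chi-squared test to categorical variables (age group,
#' gender, race, duration group, complication flags) and the two-sample
#' t-test to the laboratory means, computes per-level odds ratios for
#' the categorical variables against their reference levels, and keeps
#' variables with `p < alpha`. Constant variables are excluded with a
#' log entry rather than tested.
#'
#' @param features a complete-case feature table ([complete_case_filter()]).
#' @param alpha significance gate (default 0.05, unadjusted).
#' @param var_equal passed to [two_sample_t()].
#' @return Object of class `bivariate_screen`: list with `results` (one
#'   element per variable: `variable`, `type`, `statistic`, `p_value`,
#'   `levels` data.frame of per-level counts/OR/CI), `table` (a tidy
#'   report of the same), `kept` (variable names with p < alpha), and
#'   `dropped_constant`.
#' @export
screen_variables <- function(features, alpha = 0.05, var_equal = FALSE) {
  check_prob(alpha, "alpha")
  lab_names <- attr(features, "labs") %||% character(0)
  cat_vars <- c("age_group", "gender", "race", "duration_group",
                "nephropathy", "neuropathy")
  cat_vars <- intersect(cat_vars, names(features))
  lab_names <- intersect(lab_names, names(features))
  label <- features$label

  results <- list()
  dropped <- character(0)

  for (v in cat_vars) {
    x <- as.character(features[[v]])
    if (length(unique(x)) < 2L) {
      dropped <- c(dropped, v)
      next
    }
    ref <- .REFERENCE_LEVELS[[v]]
    lev <- unique(c(intersect(ref, x), sort(setdiff(unique(x), ref))))
    tab <- table(factor(x, levels = lev), factor(label, levels = c(0, 1)))
    ts <- chi_squared_test(tab)
    lv <- data.frame(level = lev,
                     count = as.integer(rowSums(tab)),
                     dr_count = as.integer(tab[, "1"]),
                     or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     p_value = NA_real_,
                     reference = lev == lev[1L],
                     stringsAsFactors = FALSE)
    ref_counts <- c(lv$dr_count[1L], lv$count[1L])
    for (j in seq_along(lev)[-1L]) {
      orr <- tryCatch(odds_ratio_ci(c(lv$dr_count[j], lv$count[j]), ref_counts),
                      error = function(e) NULL)
      if (!is.null(orr)) {
        lv$or[j] <- orr$or; lv$ci_low[j] <- orr$ci_low
        lv$ci_high[j] <- orr$ci_high; lv$p_value[j] <- orr$p_value
      }
    }
    lv$or[1L] <- 1
    results[[v]] <- list(variable = v, type = "chi_squared",
                         statistic = ts$statistic, p_value = ts$p_value,
                         levels = lv)
  }

  for (v in lab_names) {
    x <- features[[v]]
    if (stats::sd(x) == 0) {
      dropped <- c(dropped, v)
      next
    }
    ts <- two_sample_t(x[label == 1L], x[label == 0L], var_equal = var_equal)
    results[[v]] <- list(variable = v, type = "t_test",
                         statistic = ts$statistic, p_value = ts$p_value,
                         levels = NULL)
  }

  p <- vapply(results, `[[`, numeric(1), "p_value")
  kept <- names(results)[p < alpha]

  rows <- lapply(results, function(r) {
    base <- data.frame(variable = r$variable, test = r$type,
                       statistic = r$statistic, p_value = r$p_value,
                       significant = r$p_value < alpha,
                       stringsAsFactors = FALSE)
    if (is.null(r$levels)) {
      cbind(base, data.frame(level = NA_character_, count = NA_integer_,
                             dr_count = NA_integer_, or = NA_real_,
                             ci_low = NA_real_, ci_high = NA_real_,
                             level_p = NA_real_))
    } else {
      cbind(base[rep(1L, nrow(r$levels)), ],
            data.frame(level = r$levels$level, count = r$levels$count,
                       dr_count = r$levels$dr_count, or = r$levels$or,
                       ci_low = r$levels$ci_low, ci_high = r$levels$ci_high,
                       level_p = r$levels$p_value))
    }
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  structure(list(results = results, table = tab, kept = kept,
                 dropped_constant = dropped, alpha = alpha),
            class = "bivariate_screen")
}

#' @export
print.bivariate_screen <- function(x, ...) {
  cat(sprintf("Bivariate screen: %d variables tested, %d kept at alpha = %g\n",
              length(x$results), length(x$kept), x$alpha))
  if (length(x$dropped_constant)) {
    cat("  dropped (constant):", paste(x$dropped_constant, collapse = ", "), "\n")
  }
  cat("  kept:", paste(x$kept, collapse = ", "), "\n")
  invisible(x)
}
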