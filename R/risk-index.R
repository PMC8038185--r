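# Points-based risk index: multivariate logistic fit on the essential
# predictors, then the five-step scoring method — break predictors into
# levels with representative values M_ij, anchor each predictor at a
# reference level M_iR, express each level's distance in regression risk
# units beta_i * (M_ij - M_iR), map risk units to integer points via the
# unit B (the risk of 5 years of age per point), and sum per-patient.

#' Level scheme for a points system
#'
#' Validates and classes a level table: one row per (predictor, level)
#' with half-open numeric bounds `[lower, upper)`, the representative
#' level value `M`, and exactly one reference level per predictor. Level
#' bounds of a predictor must not overlap.
#'
#' @param levels data.frame with columns `predictor`, `level`, `lower`,
#'   `upper`, `value`, `reference`.
#' @return The validated data.frame, class `level_scheme`.
#' @seealso [published_scoring_inputs()] for the published scheme,
#'   [make_level_scheme()] to build one from data.
#' @export
level_scheme <- function(levels) {
  need <- c("predictor", "level", "lower", "upper", "value", "reference")
  if (!all(need %in% names(levels))) {
    stopf("level scheme needs columns: %s", paste(need, collapse = ", "))
  }
  for (p in unique(levels$predictor)) {
    lv <- levels[levels$predictor == p, ]
    if (sum(lv$reference) != 1L) {
      stopf("predictor `%s` must have exactly one reference level", p)
    }
    if (any(lv$lower >= lv$upper)) {
      stopf("predictor `%s` has an empty level interval", p)
    }
    lv <- lv[order(lv$lower), ]
    if (nrow(lv) > 1L && any(lv$upper[-nrow(lv)] > lv$lower[-1L])) {
      stopf("predictor `%s` has overlapping level intervals", p)
    }
  }
  structure(as.data.frame(levels), class = c("level_scheme", "data.frame"))
}

#' Build a level scheme from data
#'
#' Cuts each predictor at the supplied break points. The representative
#' value `M` of a bounded interval is its midpoint; open-ended intervals
#' use the empirical mean of the in-level observations (matching how the
#' published open-level values were evidently chosen). An empty open
#' level raises a warning and falls back to the boundary plus/minus half
#' the adjacent interval width.
#'
#' @param data feature table supplying the empirical values.
#' @param breaks named list: per predictor, the interior break points
#'   (the outer bounds are `-Inf`/`Inf`; binary predictors use
#'   `breaks = 0.5`).
#' @param reference named character: per predictor, the label of the
#'   reference level (labels are formed as `"<b1"`, `"b1-b2"`, ...,
#'   `">bk"`, or `"No"`/`"Yes"` for binary predictors); the special
#'   values `"first"` and `"last"` pick the lowest / highest level.
#' @param labels optional named list of per-predictor level labels
#'   overriding the generated ones (e.g. category names for an
#'   integer-coded nominal predictor).
#' @return A [level_scheme()].
#' @export
make_level_scheme <- function(data, breaks, reference, labels = NULL) {
  rows <- list()
  for (p in names(breaks)) {
    b <- sort(breaks[[p]])
    x <- feature_matrix(data, p)[, 1L]
    binary <- length(b) == 1L && b == 0.5
    lower <- c(-Inf, b)
    upper <- c(b, Inf)
    labs_p <- labels[[p]] %||% if (binary) c("No", "Yes") else {
      k <- length(b)
      c(paste0("<", b[1L]),
        if (k > 1L) paste0(b[-k], "-", b[-1L]),
        paste0(">", b[k]))
    }
    if (length(labs_p) != length(lower)) {
      stopf("`labels` for `%s` must have %d entries", p, length(lower))
    }
    value <- numeric(length(labs_p))
    for (j in seq_along(labs_p)) {
      bounded <- is.finite(lower[j]) && is.finite(upper[j])
      if (binary) {
        value[j] <- j - 1
      } else if (bounded) {
        value[j] <- (lower[j] + upper[j]) / 2
      } else {
        inlev <- x[x >= lower[j] & x < upper[j]]
        if (length(inlev) > 0L) {
          value[j] <- mean(inlev)
        } else {
          step <- if (length(b) > 1L) diff(b)[if (j == 1L) 1L else length(b) - 1L] else 1
          value[j] <- if (j == 1L) upper[j] - step / 2 else lower[j] + step / 2
          warning(sprintf("empty open level %s for `%s`; using interval midpoint fallback",
                          labs_p[j], p))
        }
      }
    }
    ref_p <- switch(reference[[p]],
                    first = labs_p[1L],
                    last = labs_p[length(labs_p)],
                    reference[[p]])
    if (!ref_p %in% labs_p) {
      stopf("reference level `%s` not among levels of `%s` (%s)",
            ref_p, p, paste(labs_p, collapse = ", "))
    }
    rows[[p]] <- data.frame(predictor = p, level = labs_p, lower = lower,
                            upper = upper, value = value,
                            reference = labs_p == ref_p,
                            stringsAsFactors = FALSE)
  }
  level_scheme(do.call(rbind, rows))
}

# Break points and reference levels used when deriving a new scoring
# system on the 10 essential predictors (same level structure as the
# published index; references are the clinically lowest-risk levels).
essential_breaks <- function() {
  list(
    age = c(35, 50, 65, 75, 85),
    creatinine = c(0.5, 1, 1.5, 2),
    hba1c = c(6, 8, 10, 12),
    neuropathy = 0.5,
    duration = c(1, 2, 3, 4),
    wbc = c(4, 6, 8, 12),
    nephropathy = 0.5,
    glucose = c(60, 80, 100, 200),
    hematocrit = c(30, 35, 40, 50),
    sodium = c(136, 144)
  )
}

essential_references <- function() {
  c(age = ">85", creatinine = "<0.5", hba1c = "<6", neuropathy = "No",
    duration = "<1", wbc = ">12", nephropathy = "No", glucose = "<60",
    hematocrit = ">50", sodium = "<136")
}

#' Level scheme for an arbitrary essential predictor set
#'
#' Canonical clinical breaks and reference levels for the 10 published
#' predictors; for any other selected predictor, interior breaks at the
#' empirical 20/40/60/80th percentiles (integer-coded categories at the
#' half-steps) with the reference level chosen as the lowest-risk end by
#' the sign of its logistic coefficient.
#'
#' @param features feature table supplying empirical values.
#' @param predictors model variable names the index must cover.
#' @param coefficients named coefficients (for sign-based references),
#'   or a `logistic_fit`.
#' @return A [level_scheme()].
#' @export
index_scheme <- function(features, predictors, coefficients) {
  if (inherits(coefficients, "logistic_fit")) {
    tab <- coefficients$coefficients
    coefficients <- stats::setNames(tab$beta, tab$term)
  }
  canon_b <- essential_breaks()
  canon_r <- essential_references()
  breaks <- list(); refs <- character(0); labels <- list()
  for (p in predictors) {
    if (p %in% names(canon_b)) {
      breaks[[p]] <- canon_b[[p]]
      refs[p] <- canon_r[[p]]
      next
    }
    if (p == "gender") {
      breaks[[p]] <- 0.5
      labels[[p]] <- .GENDER_LEVELS
    } else if (p == "race") {
      breaks[[p]] <- c(0.5, 1.5)
      labels[[p]] <- .RACE_LEVELS
    } else {
      x <- feature_matrix(features, p)[, 1L]
      q <- unique(signif(stats::quantile(x, c(0.2, 0.4, 0.6, 0.8),
                                         names = FALSE, type = 7), 3))
      if (length(q) < 1L) stopf("cannot derive breaks for constant predictor `%s`", p)
      breaks[[p]] <- q
    }
    beta <- coefficients[[p]] %||% 0
    refs[p] <- if (beta >= 0) "first" else "last"
  }
  make_level_scheme(features, breaks, refs, labels = labels)
}

#' Multivariate logistic regression on the essential predictors
#'
#' Maximum-likelihood fit of `label ~ predictors` with age and duration
#' of diabetes entered as continuous years, complications as 0/1 flags
#' and labs as their aggregated means. Reports per-coefficient odds
#' ratios with Wald confidence intervals.
#'
#' @param features a complete-case feature table.
#' @param predictors model variable names (see [feature_matrix()]).
#' @param conf_level confidence level for the Wald intervals.
#' @return Object of class `logistic_fit`: list with `coefficients`
#'   (data.frame `term`, `beta`, `se`, `or`, `ci_low`, `ci_high`,
#'   `p_value`; the intercept first), and the underlying `glm` object as
#'   `fit`.
#' @export
fit_logistic <- function(features, predictors, conf_level = 0.95) {
  x <- feature_matrix(features, predictors)
  y <- features$label
  if (length(unique(y)) < 2L) stopf("both classes required")
  df <- data.frame(label = y, x)
  fit <- stats::glm(label ~ ., data = df, family = stats::binomial())
  beta <- stats::coef(fit)
  if (any(abs(beta[-1L]) > 20)) {
    stopf("apparent separation: coefficient of `%s` diverged",
          names(beta)[-1L][which.max(abs(beta[-1L]))])
  }
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(
    term = c("(Intercept)", colnames(x)),
    beta = unname(beta), se = unname(se),
    or = exp(unname(beta)),
    ci_low = exp(unname(beta) - z * se),
    ci_high = exp(unname(beta) + z * se),
    p_value = 2 * stats::pnorm(-abs(unname(beta) / se)),
    stringsAsFactors = FALSE
  )
  structure(list(coefficients = tab, fit = fit), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 4, ...) {
  cat("Logistic regression (", nrow(x$fit$model), " patients)\n", sep = "")
  df <- x$coefficients
  df[, -1] <- lapply(df[, -1], signif, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Derive integer points from logistic coefficients
#'
#' The scoring step of the five-step method: each level's points are
#' `round(beta_i * (M_ij - M_iR) / B)` (half away from zero), where `B`
#' defaults to five times the magnitude of the age coefficient — one
#' point equals the regression risk of five years of age. Reference
#' levels score exactly 0.
#'
#' @param coefficients named numeric vector of per-predictor logistic
#'   coefficients (no intercept), or a `logistic_fit`.
#' @param scheme a [level_scheme()] covering every coefficient.
#' @param b the risk-units-per-point constant; overrides `b_rule`.
#' @param b_rule `"age5"` (default): `B = 5 * |beta_age|`.
#' @return Object of class `scoring_system`: `table` (the scheme plus a
#'   `points` column), `B`, `coefficients`, `score_range`.
#' @export
#' @examples
#' sys <- published_risk_index()
#' subset(sys$table, predictor == "neuropathy")
derive_points <- function(coefficients, scheme, b = NULL, b_rule = "age5") {
  if (inherits(coefficients, "logistic_fit")) {
    tab <- coefficients$coefficients
    coefficients <- stats::setNames(tab$beta, tab$term)
    coefficients <- coefficients[names(coefficients) != "(Intercept)"]
  }
  preds <- unique(scheme$predictor)
  missing_coef <- setdiff(preds, names(coefficients))
  if (length(missing_coef)) {
    stopf("no coefficient for predictor(s): %s",
          paste(missing_coef, collapse = ", "))
  }
  if (is.null(b)) {
    if (!identical(b_rule, "age5")) stopf("unknown `b_rule`: %s", b_rule)
    if (!"age" %in% names(coefficients)) {
      stopf("b_rule \"age5\" needs an `age` coefficient")
    }
    b <- 5 * abs(coefficients[["age"]])
  }
  if (b <= 0) stopf("`b` must be positive")

  tab <- as.data.frame(scheme)
  ref_value <- stats::setNames(tab$value[tab$reference], tab$predictor[tab$reference])
  beta <- coefficients[tab$predictor]
  tab$points <- round_half_away(beta * (tab$value - ref_value[tab$predictor]) / b)
  tab$points[tab$reference] <- 0L

  per_pred <- split(tab$points, tab$predictor)
  score_range <- c(min_total = sum(vapply(per_pred, min, numeric(1))),
                   max_total = sum(vapply(per_pred, max, numeric(1))))

  structure(list(table = tab, B = unname(b),
                 coefficients = coefficients[preds],
                 score_range = score_range),
            class = "scoring_system")
}

#' @export
print.scoring_system <- function(x, ...) {
  cat(sprintf("Points scoring system: %d predictors, B = %.4f, score range %d-%d\n",
              length(unique(x$table$predictor)), x$B,
              x$score_range[["min_total"]], x$score_range[["max_total"]]))
  print.data.frame(x$table, row.names = FALSE)
  invisible(x)
}

#' Score range of a scoring system
#'
#' @param system a `scoring_system`.
#' @return Named vector `min_total`, `max_total` (sums of per-predictor
#'   level minima and maxima).
#' @export
score_range <- function(system) system$score_range

#' Score patients with a points system
#'
#' Assigns each patient's predictor value to its level by the half-open
#' bounds `[lower, upper)` and sums the matched points. A value falling
#' outside every level, or a missing value, is an error naming the
#' predictor and value.
#'
#' @param system a `scoring_system` from [derive_points()].
#' @param patients feature table (needs `age_years`, `duration_years`,
#'   the complication flags and the labs the system uses), or a
#'   data.frame with one column per predictor.
#' @return Integer vector of total scores, one per row.
#' @export
#' @examples
#' sys <- published_risk_index()
#' pt <- data.frame(age = 55, creatinine = 1.2, hba1c = 9, neuropathy = 0,
#'                  duration = 2.5, wbc = 7, nephropathy = 0, glucose = 150,
#'                  hematocrit = 37, sodium = 140)
#' score_patients(sys, pt)  # 66
score_patients <- function(system, patients) {
  preds <- unique(system$table$predictor)
  get_col <- function(p) {
    if (!is.null(patients[[p]])) return(as.numeric(patients[[p]]))
    alt <- switch(p, age = "age_years", duration = "duration_years", NULL)
    if (!is.null(alt) && !is.null(patients[[alt]])) {
      return(as.numeric(patients[[alt]]))
    }
    stopf("patients table lacks predictor `%s`", p)
  }
  total <- integer(nrow(patients))
  for (p in preds) {
    lv <- system$table[system$table$predictor == p, ]
    v <- get_col(p)
    idx <- rep(NA_integer_, length(v))
    for (j in seq_len(nrow(lv))) {
      idx[v >= lv$lower[j] & v < lv$upper[j]] <- j
    }
    bad <- which(is.na(idx))
    if (length(bad)) {
      stopf("value %s of `%s` (row %d) falls outside every level",
            format(v[bad[1]]), p, bad[1])
    }
    total <- total + lv$points[idx]
  }
  as.integer(total)
}

#' Bin risk scores and tabulate observed DR rates
#'
#' Bins are `[min, c1), [c1, c2), ..., [ck, max]` over the system's
#' score range (defaults to the published cutoffs 40..100 by 10, i.e.
#' eight bins).
#'
#' @param scores integer scores.
#' @param labels 0/1 outcome.
#' @param cutoffs ordered interior cutoffs.
#' @param score_range total range the bins must cover; defaults to the
#'   observed range widened to the cutoffs.
#' @return Object of class `risk_bins`: data.frame with `bin`, `lower`,
#'   `upper`, `n`, `dr`, `rate`.
#' @export
bin_scores <- function(scores, labels,
                       cutoffs = c(40, 50, 60, 70, 80, 90, 100),
                       score_range = NULL) {
  if (length(scores) == 0L) stopf("empty cohort")
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    stopf("`cutoffs` must be strictly increasing")
  }
  lo <- min(min(scores), cutoffs[1] - 1, score_range[1] %||% Inf)
  hi <- max(max(scores), cutoffs[length(cutoffs)],
            score_range[2] %||% -Inf)
  brk <- c(lo, cutoffs, hi + 1)
  labels_bin <- c(paste0("<", cutoffs[1]),
                  paste0(cutoffs[-length(cutoffs)], "-",
                         cutoffs[-1] - 1),
                  paste0(">=", cutoffs[length(cutoffs)]))
  bin <- cut(scores, breaks = brk, labels = labels_bin, right = FALSE,
             include.lowest = TRUE)
  n <- as.integer(table(bin))
  dr <- as.integer(tapply(labels, bin, sum, default = 0L))
  out <- data.frame(bin = labels_bin,
                    lower = brk[-length(brk)],
                    upper = c(cutoffs, hi),
                    n = n, dr = dr,
                    rate = ifelse(n > 0, dr / n, NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("risk_bins", "data.frame")
  out
}

#' @export
print.risk_bins <- function(x, ...) {
  cat("Risk index bins\n")
  df <- as.data.frame(x)
  df$rate <- round(df$rate, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
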