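# Ensemble predictor selection (EPS): (i) AUC-weighted aggregation of
# gradient-boosted-tree variable importance over bootstrap resamples of
# the training split, (ii) golden-section search on the importance-sorted
# variables for the smallest top-k set whose model stays within an AUC
# tolerance of the full model.

#' EPS configuration
#'
#' @param n_bootstrap bootstrap resamples for importance ranking
#'   (default 100).
#' @param train_fraction fraction of the cohort in the training split
#'   (default 0.7; the remaining 30% is held out for reporting only).
#' @param learner_params gradient-boosted-tree settings passed to
#'   xgboost; `nrounds` is extracted, the rest go to `params`.
#' @param auc_tolerance largest allowed AUC drop of the top-k model
#'   below the full model during the search (default 0.005).
#' @param inner_eval_fraction fraction of the training split held out to
#'   evaluate `eval_auc(k)` inside the search (default 0.25), so the
#'   held-out 30% never informs selection.
#' @param importance_measure `"gain"` (default), `"cover"` or
#'   `"frequency"` — the per-tree importance attributed to a variable.
#' @param seed integer seed driving the split, the resamples and the
#'   learner.
#' @return Object of class `eps_config`.
#' @export
eps_config <- function(n_bootstrap = 100L,
                       train_fraction = 0.7,
                       learner_params = list(max_depth = 3, eta = 0.3,
                                             nrounds = 60),
                       auc_tolerance = 0.005,
                       inner_eval_fraction = 0.25,
                       importance_measure = c("gain", "cover", "frequency"),
                       seed = 1L) {
  n_bootstrap <- check_count(n_bootstrap, "n_bootstrap", min = 2L)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stopf("`train_fraction` must be in (0, 1)")
  }
  if (!is.numeric(auc_tolerance) || auc_tolerance < 0) {
    stopf("`auc_tolerance` must be >= 0")
  }
  check_prob(inner_eval_fraction, "inner_eval_fraction")
  structure(list(
    n_bootstrap = n_bootstrap, train_fraction = train_fraction,
    learner_params = learner_params, auc_tolerance = auc_tolerance,
    inner_eval_fraction = inner_eval_fraction,
    importance_measure = match.arg(importance_measure),
    seed = as.integer(seed)
  ), class = "eps_config")
}

# Map screened variable names to model variables: the grouped age and
# duration screens correspond to the continuous columns in the model.
model_variables <- function(kept) {
  v <- kept
  v[v == "age_group"] <- "age"
  v[v == "duration_group"] <- "duration"
  unique(v)
}

#' Numeric model matrix for the tree learner
#'
#' One column per variable: continuous years for `age` and `duration`,
#' integer-coded categories for `gender` and `race`, 0/1 complication
#' flags, and the aggregated lab means.
#'
#' @param features a feature table.
#' @param variables model variable names (see `select_predictors()`).
#' @return Numeric matrix with `variables` as columns.
#' @export
feature_matrix <- function(features, variables) {
  cols <- lapply(variables, function(v) {
    switch(v,
      age = features$age_years,
      duration = features$duration_years,
      gender = as.numeric(factor(features$gender, levels = .GENDER_LEVELS)) - 1,
      race = as.numeric(factor(features$race, levels = .RACE_LEVELS)) - 1,
      {
        if (is.null(features[[v]])) stopf("unknown model variable `%s`", v)
        as.numeric(features[[v]])
      })
  })
  m <- do.call(cbind, cols)
  colnames(m) <- variables
  m
}

fit_gbt <- function(x, y, learner_params) {
  lp <- learner_params
  nrounds <- lp$nrounds %||% 60
  lp$nrounds <- NULL
  params <- utils::modifyList(
    list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
         tree_method = "hist", nthread = 1),
    lp)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

predict_gbt <- function(model, x) {
  stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
}

#' Bootstrap variable-importance ranking
#'
#' For each of `n_bootstrap` resamples (with replacement, same size as
#' the input) a gradient-boosted-tree model is fitted; its per-variable
#' importance and its AUC on the out-of-bag rows are recorded. The
#' aggregated importance is the AUC-weighted mean over resamples, sorted
#' descending with ties broken by variable name.
#'
#' A resample missing one of the two classes is redrawn (up to 100
#' retries); an out-of-bag set missing a class falls back to the in-bag
#' AUC for the weight.
#'
#' @param x numeric model matrix ([feature_matrix()]).
#' @param y 0/1 outcome.
#' @param cfg an [eps_config()].
#' @return Object of class `importance_ranking`: list with `table`
#'   (variable, importance, sorted), `raw_importance`
#'   (n_bootstrap x p matrix), `weights` (per-resample AUCs).
#' @export
bootstrap_importance <- function(x, y, cfg = eps_config()) {
  if (nrow(x) == 0L || length(unique(y)) < 2L) {
    stopf("training data must be nonempty with both classes present")
  }
  p <- ncol(x)
  vars <- colnames(x)
  imp <- matrix(0, nrow = cfg$n_bootstrap, ncol = p,
                dimnames = list(NULL, vars))
  wts <- numeric(cfg$n_bootstrap)
  n <- nrow(x)
  measure <- c(gain = "Gain", cover = "Cover",
               frequency = "Frequency")[[cfg$importance_measure]]
  with_seed(derive_seed(cfg$seed, "bootstrap"), {
    for (b in seq_len(cfg$n_bootstrap)) {
      idx <- NULL
      for (try in 1:100) {
        cand <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[cand])) == 2L) { idx <- cand; break }
      }
      if (is.null(idx)) stopf("could not draw a two-class bootstrap resample")
      fit <- fit_gbt(x[idx, , drop = FALSE], y[idx], cfg$learner_params)
      it <- xgboost::xgb.importance(model = fit)
      imp[b, it$Feature] <- it[[measure]]
      oob <- setdiff(seq_len(n), unique(idx))
      w <- if (length(oob) > 1L && length(unique(y[oob])) == 2L) {
        auc(predict_gbt(fit, x[oob, , drop = FALSE]), y[oob])
      } else {
        auc(predict_gbt(fit, x[idx, , drop = FALSE]), y[idx])
      }
      wts[b] <- w
    }
  })
  agg <- colSums(imp * wts) / sum(wts)
  ord <- order(-agg, vars)
  tab <- data.frame(variable = vars[ord], importance = unname(agg[ord]),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, raw_importance = imp, weights = wts),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("AUC-weighted importance over %d bootstrap resamples\n",
              nrow(x$raw_importance)))
  print.data.frame(transform(x$table, importance = signif(importance, 4)),
                   row.names = FALSE)
  invisible(x)
}

#' Golden-section search for the minimal predictor count
#'
#' Finds the smallest `k` whose top-k model keeps
#' `eval_auc(k_max) - eval_auc(k) <= tolerance`, assuming `eval_auc` is
#' (approximately) non-decreasing in `k`. Probes follow golden-section
#' interval reduction on the integer range with rounding to the nearest
#' integer; evaluations are memoised; a final linear pass over the
#' terminal bracket confirms minimality there.
#'
#' @param eval_auc function mapping `k` (1..k_max) to an AUC.
#' @param k_max number of candidate variables; the full model defines
#'   the target AUC.
#' @param tolerance maximum allowed AUC drop below the full model.
#' @return List with `k`, `target` (the full-model AUC), `trace`
#'   (data.frame `k`, `auc` of every evaluation, in probe order) and
#'   `n_evaluations`.
#' @export
#' @examples
#' f <- function(k) min(0.6 + 0.05 * k, 0.85)
#' golden_section_min_k(f, k_max = 23, tolerance = 0.005)$k  # 5
golden_section_min_k <- function(eval_auc, k_max, tolerance) {
  k_max <- check_count(k_max, "k_max")
  memo <- new.env(parent = emptyenv())
  order_probed <- integer(0)
  f <- function(k) {
    key <- as.character(k)
    if (is.null(memo[[key]])) {
      memo[[key]] <- eval_auc(k)
      order_probed <<- c(order_probed, k)
    }
    memo[[key]]
  }
  target <- f(k_max)
  if (is.na(target)) {
    warning("full-model AUC is undefined; returning k_max")
    return(list(k = k_max, target = target,
                trace = data.frame(k = k_max, auc = target),
                n_evaluations = 1L))
  }
  # an undefined AUC cannot certify the tolerance
  ok <- function(k) isTRUE(target - f(k) <= tolerance)

  # Shrink [lo, hi] keeping the invariant: every k' >= hi satisfies the
  # tolerance, no probed k' < lo does. Golden-ratio interior probes.
  gr <- (sqrt(5) - 1) / 2  # 0.618...
  lo <- 1L; hi <- k_max
  while (hi - lo > 2L) {
    probe <- as.integer(round(hi - gr * (hi - lo)))
    probe <- min(max(probe, lo), hi - 1L)
    if (ok(probe)) hi <- probe else lo <- probe + 1L
  }
  # terminal linear verification over [lo, hi]
  k <- hi
  for (kk in seq.int(lo, hi)) {
    if (ok(kk)) { k <- kk; break }
  }
  if (!ok(k)) {
    warning("no predictor count satisfies the tolerance; returning k_max")
    k <- k_max
  }
  trace <- data.frame(k = order_probed,
                      auc = vapply(as.character(order_probed),
                                   function(key) memo[[key]], numeric(1)))
  list(k = k, target = target, trace = trace,
       n_evaluations = length(order_probed))
}

#' Ensemble predictor selection
#'
#' Runs the full EPS procedure on a screened feature table: seeded 70/30
#' train/test split, bootstrap importance ranking on the training side,
#' golden-section search for the minimal top-k predictor set (evaluated
#' on an inner split of the training data), then full- and compact-model
#' AUCs on the held-out 30%.
#'
#' @param features a complete-case feature table.
#' @param variables screened variable names (e.g. `screen_variables()$kept`);
#'   grouped age/duration names map to the continuous model columns.
#' @param cfg an [eps_config()].
#' @return Object of class `selection_result`: `essential_set` (ordered),
#'   `k`, `auc_full`, `auc_compact` (held-out), `ranking`
#'   (an `importance_ranking`), `search` (the golden-section trace),
#'   `split` (row indices of the test set).
#' @export
select_predictors <- function(features, variables, cfg = eps_config()) {
  vars <- model_variables(variables)
  x <- feature_matrix(features, vars)
  y <- features$label
  if (length(unique(y)) < 2L) stopf("both classes required")

  # stratified draws keep the rare DR class present in every split
  strat_sample <- function(y, fraction, seed) {
    with_seed(seed, {
      idx1 <- which(y == 1L); idx0 <- which(y == 0L)
      c(sample(idx1, max(1L, round(fraction * length(idx1)))),
        sample(idx0, max(1L, round(fraction * length(idx0)))))
    })
  }
  test_idx <- strat_sample(y, 1 - cfg$train_fraction,
                           derive_seed(cfg$seed, "split"))
  tr_x <- x[-test_idx, , drop = FALSE]; tr_y <- y[-test_idx]
  te_x <- x[test_idx, , drop = FALSE]; te_y <- y[test_idx]

  ranking <- bootstrap_importance(tr_x, tr_y, cfg)
  sorted_vars <- ranking$table$variable

  # inner split of the training data for the search criterion
  inner_idx <- strat_sample(tr_y, cfg$inner_eval_fraction,
                            derive_seed(cfg$seed, "inner"))
  eval_auc <- function(k) {
    v <- sorted_vars[seq_len(k)]
    fit <- fit_gbt(tr_x[-inner_idx, v, drop = FALSE], tr_y[-inner_idx],
                   cfg$learner_params)
    auc(predict_gbt(fit, tr_x[inner_idx, v, drop = FALSE]), tr_y[inner_idx])
  }
  search <- golden_section_min_k(eval_auc, k_max = length(sorted_vars),
                                 tolerance = cfg$auc_tolerance)
  essential <- sorted_vars[seq_len(search$k)]

  fit_full <- fit_gbt(tr_x, tr_y, cfg$learner_params)
  fit_compact <- fit_gbt(tr_x[, essential, drop = FALSE], tr_y,
                         cfg$learner_params)
  auc_full <- auc(predict_gbt(fit_full, te_x), te_y)
  auc_compact <- auc(predict_gbt(fit_compact, te_x[, essential, drop = FALSE]),
                     te_y)

  structure(list(
    essential_set = essential, k = search$k,
    auc_full = auc_full, auc_compact = auc_compact,
    ranking = ranking, search = search, split = sort(test_idx)
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("EPS selection: %d of %d variables\n",
              x$k, nrow(x$ranking$table)))
  cat("  essential:", paste(x$essential_set, collapse = ", "), "\n")
  cat(sprintf("  held-out AUC: full %.3f, compact %.3f\n",
              x$auc_full, x$auc_compact))
  invisible(x)
}
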