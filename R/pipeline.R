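# End-to-end orchestration: synth -> cohort -> screen -> select ->
# index -> evaluate, with a manifest recording per-stage attrition,
# seeds and output checksums.

#' Pipeline configuration
#'
#' Bundles the stage configurations; all stage seeds derive
#' deterministically from the one global seed.
#'
#' @param out_dir output directory for stage files; `NULL` keeps
#'   everything in memory.
#' @param generator a [generator_config()]; its seed is overridden by
#'   `seed`.
#' @param windows a [window_config()].
#' @param eps an [eps_config()]; its seed is overridden by `seed`.
#' @param alpha bivariate significance gate.
#' @param cutoffs risk-index bin cutoffs.
#' @param seed global integer seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir = NULL,
                       generator = generator_config(),
                       windows = window_config(),
                       eps = eps_config(),
                       alpha = 0.05,
                       cutoffs = c(40, 50, 60, 70, 80, 90, 100),
                       seed = 1L) {
  check_prob(alpha, "alpha")
  generator$seed <- derive_seed(seed, "generator")
  eps$seed <- derive_seed(seed, "eps")
  structure(list(out_dir = out_dir, generator = generator,
                 windows = windows, eps = eps, alpha = alpha,
                 cutoffs = cutoffs, seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage `%s` failed: %s", name, conditionMessage(e))
  })
}

#' Run the full derivation pipeline
#'
#' Generates (or loads) the raw EHR tables, builds and filters the
#' feature table, screens variables, runs ensemble predictor selection,
#' fits the multivariate logistic model on the essential predictors,
#' derives the points system, scores and bins the cohort, and reports
#' overall and age-specific AUCs of the compact model and the index.
#'
#' @param config a [run_config()].
#' @param ehr optional pre-built `ehr_tables`; skips the generator.
#' @return Object of class `pipeline_run`: list with `features`,
#'   `screen`, `selection`, `logistic`, `system`, `scores`, `bins`,
#'   `evaluation` (an `eval_report`), and `manifest` (stage counts,
#'   seeds, package version, file checksums when `out_dir` is set).
#' @export
run_pipeline <- function(config = run_config(), ehr = NULL) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("drindex")),
    seed = config$seed,
    stage_counts = list()
  )
  count <- function(name, value) {
    manifest$stage_counts[[name]] <<- value
  }

  truth <- NULL
  if (is.null(ehr)) {
    gen <- stage("synthesize", generate_cohort(config$generator))
    ehr <- gen$ehr
    truth <- gen$truth
  }
  count("patients_generated", nrow(ehr$patients))

  features <- stage("aggregate",
                    build_features(ehr, config$windows,
                                   seed = derive_seed(config$seed, "cohort")))
  count("patients_windowed", nrow(features))
  count("window_exclusions", nrow(attr(features, "exclusions")))

  cc <- stage("complete_case", complete_case_filter(features))
  features <- cc$kept
  count("patients_complete_case", nrow(features))
  count("complete_case_exclusions", nrow(cc$exclusions))

  screen <- stage("screen", screen_variables(features, alpha = config$alpha))
  count("variables_tested", length(screen$results))
  count("variables_kept", length(screen$kept))

  selection <- stage("select",
                     select_predictors(features, screen$kept, config$eps))
  count("essential_predictors", selection$k)

  # The unit B is defined as the regression risk of five years of age,
  # so age always enters the index model even if the search drops it.
  index_predictors <- union(selection$essential_set, "age")
  logistic <- stage("logistic",
                    fit_logistic(features, index_predictors))
  scheme <- stage("scheme",
                  index_scheme(features, index_predictors, logistic))
  system <- stage("derive_points", derive_points(logistic, scheme))

  scores <- stage("score", score_patients(system, features))
  bins <- stage("bin", bin_scores(scores, features$label, config$cutoffs,
                                  score_range = score_range(system)))

  # compact-model probabilities on the whole cohort for the report
  compact_x <- feature_matrix(features, selection$essential_set)
  compact_fit <- stage("evaluate_fit",
                       fit_gbt(compact_x[-selection$split, , drop = FALSE],
                               features$label[-selection$split],
                               config$eps$learner_params))
  test_idx <- selection$split
  evaluation <- rbind(
    age_specific_auc(predict_gbt(compact_fit,
                                 compact_x[test_idx, , drop = FALSE]),
                     features$label[test_idx],
                     features$age_group[test_idx], model = "compact"),
    age_specific_auc(scores[test_idx], features$label[test_idx],
                     features$age_group[test_idx], model = "risk_index")
  )
  class(evaluation) <- c("eval_report", "data.frame")

  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_ehr(ehr, file.path(dir, "ehr"))
    write_features(features, file.path(dir, "features.tsv"))
    utils::write.table(screen$table, file.path(dir, "bivariate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(selection$ranking$table,
                       file.path(dir, "importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(selection$search$trace,
                       file.path(dir, "search_trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_scoring_system(system, file.path(dir, "scoring_system.txt"))
    utils::write.table(data.frame(id = features$id, score = scores,
                                  label = features$label),
                       file.path(dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(bins), file.path(dir, "bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(evaluation),
                       file.path(dir, "evaluation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- list.files(dir, recursive = TRUE, full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- substring(names(manifest$checksums),
                                           nchar(dir) + 2L)
    write_manifest(manifest, file.path(dir, "manifest.txt"))
  }

  structure(list(features = features, truth = truth, screen = screen,
                 selection = selection, logistic = logistic,
                 system = system, scores = scores, bins = bins,
                 evaluation = evaluation, manifest = manifest),
            class = "pipeline_run")
}

write_manifest <- function(manifest, file) {
  lines <- c(
    paste0("package_version\t", manifest$package_version),
    paste0("seed\t", manifest$seed),
    vapply(names(manifest$stage_counts), function(nm) {
      paste0("count_", nm, "\t", manifest$stage_counts[[nm]])
    }, character(1)),
    vapply(names(manifest$checksums %||% list()), function(nm) {
      paste0("md5_", nm, "\t", manifest$checksums[[nm]])
    }, character(1))
  )
  writeLines(lines, file)
  invisible(file)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("DR risk-index pipeline run\n")
  for (nm in names(x$manifest$stage_counts)) {
    cat(sprintf("  %-26s %s\n", nm, x$manifest$stage_counts[[nm]]))
  }
  cat(sprintf("  essential set: %s\n",
              paste(x$selection$essential_set, collapse = ", ")))
  cat(sprintf("  held-out AUC: full %.3f, compact %.3f, index %.3f\n",
              x$selection$auc_full, x$selection$auc_compact,
              x$evaluation$auc[x$evaluation$model == "risk_index" &
                               x$evaluation$group == "overall"]))
  invisible(x)
}
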