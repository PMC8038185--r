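# Ensemble predictor selection: importance ranking, the integer
# golden-section search, and end-to-end selection behaviour.

test_that("golden-section search matches the worked example and edge cases", {
  f <- function(k) min(0.6 + 0.05 * k, 0.85)
  res <- golden_section_min_k(f, k_max = 23, tolerance = 0.005)
  expect_equal(res$k, 5)

  expect_equal(golden_section_min_k(function(k) 0.8, 12, 0.005)$k, 1)
  expect_equal(golden_section_min_k(function(k) 0.5 + 0.01 * k, 15, 0)$k, 15)
})

test_that("golden-section equals exhaustive search on random monotone curves", {
  for (i in 1:200) {
    curve <- withr::with_seed(2000 + i, {
      k_max <- sample(2:30, 1)
      cumsum(c(stats::runif(1, 0.5, 0.6),
               stats::runif(k_max - 1, 0, 0.02)))
    })
    k_max <- length(curve)
    tol <- 0.005
    f <- function(k) curve[k]
    exhaustive <- min(which(curve[k_max] - curve <= tol))
    expect_equal(golden_section_min_k(f, k_max, tol)$k, exhaustive,
                 info = paste("curve", i))
  }
})

test_that("search cost is logarithmic plus the terminal bracket", {
  evals <- 0L
  f <- function(k) { evals <<- evals + 1L; min(0.6 + 0.02 * k, 0.8) }
  res <- golden_section_min_k(f, k_max = 30, tolerance = 0.001)
  expect_equal(evals, res$n_evaluations)
  # golden-section probes ~log(k_max)/log(1/0.618) plus <=3 in the bracket
  expect_lte(res$n_evaluations, ceiling(log(30) / log(1 / 0.618)) + 4)
})

test_that("a single informative variable ranks first", {
  n <- 1500
  x <- withr::with_seed(31, matrix(stats::rnorm(n * 6), ncol = 6,
                                   dimnames = list(NULL, paste0("v", 1:6))))
  y <- withr::with_seed(32, stats::rbinom(n, 1, stats::plogis(2 * x[, 4])))
  rk <- bootstrap_importance(x, y, eps_config(n_bootstrap = 10, seed = 1))
  expect_equal(rk$table$variable[1], "v4")
})

test_that("equal weights reduce the aggregation to the unweighted mean", {
  imp <- matrix(c(0.5, 0.3, 0.2,
                  0.1, 0.6, 0.3), nrow = 2, byrow = TRUE,
                dimnames = list(NULL, c("a", "b", "c")))
  w_equal <- c(0.7, 0.7)
  agg <- colSums(imp * w_equal) / sum(w_equal)
  expect_equal(agg, colMeans(imp))
})

test_that("selection is deterministic under a fixed seed", {
  f <- small_features()
  sc <- screen_variables(f, alpha = 1)
  cfg <- eps_config(n_bootstrap = 4,
                    learner_params = list(max_depth = 2, eta = 0.3,
                                          nrounds = 10),
                    seed = 77)
  s1 <- select_predictors(f, sc$kept, cfg)
  s2 <- select_predictors(f, sc$kept, cfg)
  expect_identical(s1$essential_set, s2$essential_set)
  expect_identical(s1$auc_full, s2$auc_full)
  expect_identical(s1$ranking$table, s2$ranking$table)
})

test_that("a huge tolerance selects a single predictor", {
  f <- small_features()
  cfg <- eps_config(n_bootstrap = 4, auc_tolerance = 1,
                    learner_params = list(max_depth = 2, eta = 0.3,
                                          nrounds = 10),
                    seed = 5)
  s <- select_predictors(f, c("creatinine", "hba1c", "glucose", "sodium"),
                         cfg)
  expect_equal(s$k, 1)
})

test_that("informative variables are recovered ahead of pure noise", {
  gen <- generate_cohort(recovery_config(8000, seed = 21))
  f <- complete_case_filter(build_features(gen$ehr, seed = 21))$kept
  vars <- c("age_group", "race", "duration_group", "nephropathy",
            "neuropathy", attr(f, "labs"))
  vars <- setdiff(vars, c("triglycerides", "anion_gap"))  # 23 candidates
  sel <- select_predictors(f, vars,
                           eps_config(n_bootstrap = 15,
                                      learner_params = list(max_depth = 3,
                                                            eta = 0.3,
                                                            nrounds = 30),
                                      seed = 22))
  informative <- c("age", "creatinine", "hba1c", "neuropathy", "duration",
                   "wbc", "nephropathy", "glucose", "hematocrit", "sodium")
  strong <- setdiff(informative, c("wbc", "sodium"))
  # the strongly separated predictors should dominate the top of the
  # ranking ahead of the no-signal labs
  top10 <- sel$ranking$table$variable[1:10]
  expect_gte(length(intersect(top10, informative)), 7)
  expect_true(all(c("creatinine", "hba1c", "glucose", "hematocrit")
                  %in% top10))
  # removing a pure-noise variable leaves the informative members alone
  sel2 <- select_predictors(f, setdiff(vars, "mcv"),
                            eps_config(n_bootstrap = 15,
                                       learner_params = list(max_depth = 3,
                                                             eta = 0.3,
                                                             nrounds = 30),
                                       seed = 22))
  expect_setequal(intersect(sel$essential_set, strong),
                  intersect(sel2$essential_set, strong))
})
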