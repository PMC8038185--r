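# Points scoring: full regression against the published table, score
# arithmetic, level assignment, binning, logistic fitting.

test_that("the published scoring table is reproduced exactly, level by level", {
  sys <- published_risk_index()
  expected <- published_points()
  got <- merge(sys$table[, c("predictor", "level", "points")], expected,
               by = c("predictor", "level"), suffixes = c("_got", "_want"))
  expect_equal(nrow(got), nrow(expected))  # every printed level matched
  expect_identical(got$points_got, got$points_want)
})

test_that("the score range is 0 to 160", {
  rng <- score_range(published_risk_index())
  expect_equal(rng[["min_total"]], 0)
  expect_equal(rng[["max_total"]], 160)
})

test_that("reference levels score zero and B follows the age coefficient", {
  sys <- published_risk_index()
  expect_true(all(sys$table$points[sys$table$reference] == 0L))
  expect_equal(sys$B, 0.0935)
  # explicit unit overrides the rule
  sys2 <- derive_points(published_scoring_inputs()$coefficients,
                        published_scoring_inputs()$scheme, b = 0.187)
  expect_equal(max(sys2$table$points[sys2$table$predictor == "hba1c"]), 14)
  expect_error(derive_points(c(creatinine = 0.86),
                             published_scoring_inputs()$scheme),
               "no coefficient")
})

test_that("patients are scored by summing matched level points", {
  sys <- published_risk_index()
  ref_patient <- data.frame(age = 90, creatinine = 0.3, hba1c = 5,
                            neuropathy = 0, duration = 0.5, wbc = 13,
                            nephropathy = 0, glucose = 50, hematocrit = 52,
                            sodium = 130)
  expect_equal(score_patients(sys, ref_patient), 0L)

  max_patient <- data.frame(age = 25, creatinine = 3, hba1c = 14,
                            neuropathy = 1, duration = 9, wbc = 3,
                            nephropathy = 1, glucose = 300, hematocrit = 25,
                            sodium = 150)
  expect_equal(score_patients(sys, max_patient), 160L)

  worked <- data.frame(age = 55, creatinine = 1.2, hba1c = 9, neuropathy = 0,
                       duration = 2.5, wbc = 7, nephropathy = 0,
                       glucose = 150, hematocrit = 37, sodium = 140)
  expect_equal(score_patients(sys, worked), 66L)

  # feature-table column names are accepted too
  ft <- data.frame(age_years = 55, creatinine = 1.2, hba1c = 9,
                   neuropathy = 0, duration_years = 2.5, wbc = 7,
                   nephropathy = 0, glucose = 150, hematocrit = 37,
                   sodium = 140)
  expect_equal(score_patients(sys, ft), 66L)

  bad <- worked; bad$creatinine <- NA
  expect_error(score_patients(sys, bad), "creatinine")
})

test_that("scores are order-invariant and monotone in risk levels", {
  sys <- published_risk_index()
  shuffled <- sys
  perm <- withr::with_seed(9, sample(nrow(sys$table)))
  shuffled$table <- sys$table[perm, ]
  pts <- data.frame(age = c(40, 70), creatinine = c(0.8, 2.5),
                    hba1c = c(7, 11), neuropathy = c(0, 1),
                    duration = c(1.5, 6), wbc = c(5, 9),
                    nephropathy = c(0, 1), glucose = c(90, 250),
                    hematocrit = c(33, 44), sodium = c(140, 146))
  expect_equal(score_patients(sys, pts), score_patients(shuffled, pts))

  # raising a positive-coefficient predictor to a higher level never
  # lowers the total
  base <- pts[1, ]
  for (hba1c in c(5, 7, 9, 11, 14)) {
    higher <- base; higher$hba1c <- hba1c
    if (hba1c > 5) {
      lower <- base; lower$hba1c <- hba1c - 2
      expect_gte(score_patients(sys, higher), score_patients(sys, lower))
    }
  }
})

test_that("rounding is half away from zero", {
  expect_identical(round_half_away(c(0.5, 1.5, -0.5, -1.5, 0.49, -0.49)),
                   c(1L, 2L, -1L, -2L, 0L, 0L))
})

test_that("level schemes validate structure", {
  inp <- published_scoring_inputs()
  expect_s3_class(inp$scheme, "level_scheme")
  broken <- as.data.frame(inp$scheme)
  broken$reference[broken$predictor == "age"] <- FALSE
  expect_error(level_scheme(broken), "exactly one reference")
  overlap <- as.data.frame(inp$scheme)
  overlap$upper[overlap$predictor == "sodium" & overlap$level == "<136"] <- 145
  expect_error(level_scheme(overlap), "overlapping")
})

test_that("data-driven schemes use midpoints and empirical open-level means", {
  df <- data.frame(creatinine = c(0.3, 0.8, 1.2, 2.5, 3.5))
  sch <- make_level_scheme(df, list(creatinine = c(0.5, 1, 1.5, 2)),
                           c(creatinine = "<0.5"))
  lv <- sch[sch$predictor == "creatinine", ]
  expect_equal(lv$value[lv$level == "0.5-1"], 0.75)   # midpoint
  expect_equal(lv$value[lv$level == ">2"], 3)         # mean(2.5, 3.5)
  expect_equal(lv$value[lv$level == "<0.5"], 0.3)     # empirical mean
  # both empty open levels warn and fall back to midpoint-style values
  df2 <- data.frame(creatinine = c(0.8, 1.2))
  w <- capture_warnings(
    make_level_scheme(df2, list(creatinine = c(0.5, 1, 1.5, 2)),
                      c(creatinine = "<0.5")))
  expect_match(w, "empty open level", all = TRUE)
  expect_length(w, 2)
})

test_that("logistic fit recovers known coefficients and matches printed ORs", {
  # recovery within 2 SE on data simulated from a known model
  n <- 20000
  dat <- withr::with_seed(55, {
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n); x3 <- stats::rbinom(n, 1, 0.3)
    eta <- -3 + 0.8 * x1 - 0.5 * x2 + 1.1 * x3
    data.frame(hba1c = x1, sodium = x2, nephropathy = x3,
               label = stats::rbinom(n, 1, stats::plogis(eta)))
  })
  fit <- fit_logistic(dat, c("hba1c", "sodium", "nephropathy"))
  truth <- c("(Intercept)" = -3, hba1c = 0.8, sodium = -0.5,
             nephropathy = 1.1)
  for (term in names(truth)) {
    row <- fit$coefficients[fit$coefficients$term == term, ]
    expect_lt(abs(row$beta - truth[[term]]), 2 * row$se)
  }

  # printed coefficient / OR consistency
  expect_equal(round(exp(0.8601), 2), 2.36)
  expect_equal(round(exp(0.2877), 2), 1.33)

  # separation is reported, not silently fitted
  sep <- data.frame(hba1c = c(rep(0, 50), rep(1, 50)),
                    label = c(rep(0, 50), rep(1, 50)))
  expect_error(suppressWarnings(fit_logistic(sep, "hba1c")), "separation")
})

test_that("score binning respects cutoffs and boundary conventions", {
  b <- bin_scores(c(35, 45, 105), c(0, 0, 1))
  expect_equal(b$n, c(1, 1, 0, 0, 0, 0, 0, 1))
  expect_equal(sum(b$n), 3)

  b0 <- bin_scores(rep(0, 10), rep(0, 10))
  expect_equal(b0$n[1], 10)
  expect_true(all(b0$n[-1] == 0))

  # boundary values land in the right-open bins
  b2 <- bin_scores(c(39, 40, 49, 50, 100), rep(0, 5))
  expect_equal(b2$n[1:3], c(1, 2, 1))
  expect_equal(b2$n[8], 1)

  expect_error(bin_scores(integer(0), integer(0)), "empty")
  expect_error(bin_scores(1, 0, cutoffs = c(50, 40)), "increasing")
})

test_that("scoring systems survive a serialisation round trip", {
  sys <- published_risk_index()
  tmp <- tempfile(fileext = ".txt")
  write_scoring_system(sys, tmp)
  back <- read_scoring_system(tmp)
  expect_equal(back$B, sys$B, tolerance = 1e-6)
  expect_equal(back$table$points, sys$table$points)
  expect_equal(back$score_range[["max_total"]], 160)
  pts <- data.frame(age = 55, creatinine = 1.2, hba1c = 9, neuropathy = 0,
                    duration = 2.5, wbc = 7, nephropathy = 0, glucose = 150,
                    hematocrit = 37, sodium = 140)
  expect_equal(score_patients(back, pts), score_patients(sys, pts))
})
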