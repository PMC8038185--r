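# Synthetic EHR generator: determinism, configured rates, label/code
# consistency, effect directions, outlier injection.

test_that("identical configs give byte-identical tables; seeds change them", {
  g1 <- generate_cohort(generator_config(n_patients = 200, seed = 5))
  g2 <- generate_cohort(generator_config(n_patients = 200, seed = 5))
  expect_identical(g1$ehr, g2$ehr)
  expect_identical(g1$truth$labels, g2$truth$labels)
  g3 <- generate_cohort(generator_config(n_patients = 200, seed = 6))
  expect_false(identical(g1$ehr$labs, g3$ehr$labs))
})

test_that("DR prevalence is realised within binomial tolerance", {
  gen <- generate_cohort(generator_config(n_patients = 1000,
                                          dr_prevalence = 0.038, seed = 7))
  n_dr <- sum(gen$truth$labels$label)
  sd3 <- 3 * sqrt(1000 * 0.038 * 0.962)
  expect_lt(abs(n_dr - 38), sd3)

  gen0 <- generate_cohort(generator_config(n_patients = 150,
                                           dr_prevalence = 0, seed = 1))
  codes <- icd_code_lists()
  expect_false(any(matches_icd <- vapply(codes$retinopathy, function(p) {
    any(startsWith(gen0$ehr$diagnoses$icd_code, p))
  }, logical(1))))
})

test_that("ground-truth labels agree exactly with DR codes in diagnoses", {
  gen <- small_cohort()
  codes <- icd_code_lists()
  dx <- gen$ehr$diagnoses
  is_dr <- rep(FALSE, nrow(dx))
  for (p in codes$retinopathy) is_dr <- is_dr | startsWith(dx$icd_code, p)
  dr_ids <- sort(unique(dx$id[is_dr]))
  expect_identical(dr_ids,
                   gen$truth$labels$id[gen$truth$labels$label == 1L])
})

test_that("every patient has a diabetes code; DR follows diabetes onset", {
  gen <- small_cohort()
  codes <- icd_code_lists()
  dx <- gen$ehr$diagnoses
  diab <- rep(FALSE, nrow(dx)); dr <- rep(FALSE, nrow(dx))
  for (p in codes$diabetes) diab <- diab | startsWith(dx$icd_code, p)
  for (p in codes$retinopathy) dr <- dr | startsWith(dx$icd_code, p)
  expect_setequal(unique(dx$id[diab]), gen$ehr$patients$id)
  first_diab <- tapply(dx$date[diab], dx$id[diab], min)
  first_dr <- tapply(dx$date[dr], dx$id[dr], min)
  expect_true(all(first_dr >= first_diab[names(first_dr)]))
})

test_that("missingness rate is realised as absent (patient, lab) pairs", {
  gen <- generate_cohort(generator_config(n_patients = 200,
                                          missing_rate = 0.5, seed = 1))
  pairs_present <- nrow(unique(gen$ehr$labs[, c("id", "test_name")]))
  n_pairs <- 200 * nrow(lab_reference_stats())
  absent_frac <- 1 - pairs_present / n_pairs
  sd3 <- 3 * sqrt(0.5 * 0.5 / n_pairs)
  expect_lt(abs(absent_frac - 0.5), sd3)
})

test_that("case/control separation has the configured direction for powered labs", {
  gen <- generate_cohort(generator_config(n_patients = 5000, seed = 11))
  f <- build_features(gen$ehr, seed = 2)
  specs <- lab_reference_stats()
  # restrict to labs whose configured standardised difference is large
  # enough that the sign is determined at this sample size
  std_diff <- abs(specs$case_mean - specs$control_mean) /
    ((specs$case_sd + specs$control_sd) / 2)
  powered <- specs[std_diff >= 0.1, ]
  for (i in seq_len(nrow(powered))) {
    lab <- powered$lab[i]
    v <- f[[lab]]
    emp <- mean(v[f$label == 1L], na.rm = TRUE) -
      mean(v[f$label == 0L], na.rm = TRUE)
    expect_equal(sign(emp),
                 sign(powered$case_mean[i] - powered$control_mean[i]),
                 info = lab)
  }
})

test_that("outlier injection is identity at 0, saturating at 1, seed-recomputable", {
  labs <- small_cohort()$ehr$labs

  out0 <- inject_outliers(labs, rate = 0, seed = 3)
  expect_identical(out0$value, labs$value)
  expect_length(attr(out0, "injected"), 0)

  out1 <- inject_outliers(labs, rate = 1, magnitude = 10, seed = 3)
  expect_identical(attr(out1, "injected"), seq_len(nrow(labs)))
  specs <- lab_reference_stats()
  m <- match(labs$test_name, specs$lab)
  expect_equal(out1$value, specs$control_mean[m] + 10 * specs$control_sd[m])

  out <- inject_outliers(labs, rate = 0.05, seed = 3)
  # recompute the seeded selection mask independently
  mask <- withr::with_seed(3, stats::runif(nrow(labs)) < 0.05)
  expect_identical(attr(out, "injected"), which(mask))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(dr_prevalence = 1.2), "probability")
  expect_error(generator_config(n_patients = 0), "integer")
  expect_error(generator_config(lab_specs = data.frame()), "lab_specs")
  expect_error(generator_config(lab_correlation = diag(20)), "hook")
})
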