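# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small derivation-like cohort (default config) for structural tests.
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_cohort(
      generator_config(n_patients = 400, seed = 7))
  }
  .fixtures$small
}

small_features <- function() {
  if (is.null(.fixtures$small_features)) {
    f <- build_features(small_cohort()$ehr, seed = 3)
    .fixtures$small_features <- complete_case_filter(f)$kept
  }
  .fixtures$small_features
}

# Mid-size cohort for screening / power-sensitive checks.
mid_features <- function() {
  if (is.null(.fixtures$mid_features)) {
    gen <- generate_cohort(generator_config(n_patients = 6000, seed = 11))
    f <- build_features(gen$ehr, seed = 4)
    .fixtures$mid <- gen
    .fixtures$mid_features <- complete_case_filter(f)$kept
  }
  .fixtures$mid_features
}

# Published Table-3-shaped expected points, frozen from the printed
# scoring table (predictor, level, points).
published_points <- function() {
  tab <- rbind(
    c("age", "18-34", 12), c("age", "35-49", 9), c("age", "50-64", 6),
    c("age", "65-74", 4), c("age", "75-84", 2), c("age", ">=85", 0),
    c("creatinine", "<0.5", 0), c("creatinine", "0.5-1", 3),
    c("creatinine", "1-1.5", 8), c("creatinine", "1.5-2", 12),
    c("creatinine", ">2", 21),
    c("hba1c", "<6", 0), c("hba1c", "6-8", 6), c("hba1c", "8-10", 12),
    c("hba1c", "10-12", 18), c("hba1c", ">12", 28),
    c("neuropathy", "No", 0), c("neuropathy", "Yes", 10),
    c("duration", "<1", 0), c("duration", "1-2", 2), c("duration", "2-3", 3),
    c("duration", "3-4", 5), c("duration", ">4", 14),
    c("wbc", "<4", 17), c("wbc", "4-6", 15), c("wbc", "6-8", 13),
    c("wbc", "8-12", 9), c("wbc", ">12", 0),
    c("nephropathy", "No", 0), c("nephropathy", "Yes", 6),
    c("glucose", "<60", 0), c("glucose", "60-80", 1), c("glucose", "80-100", 2),
    c("glucose", "100-200", 6), c("glucose", ">200", 20),
    c("hematocrit", "<30", 19), c("hematocrit", "30-35", 15),
    c("hematocrit", "35-40", 11), c("hematocrit", "40-50", 7),
    c("hematocrit", ">50", 0),
    c("sodium", "<136", 0), c("sodium", "136-144", 7), c("sodium", ">144", 13)
  )
  data.frame(predictor = tab[, 1], level = tab[, 2],
             points = as.integer(tab[, 3]), stringsAsFactors = FALSE)
}

# Generator configuration for predictor-recovery benchmarks: exactly 10
# informative variables (the published essential set) among 23
# candidates; all other labs carry no case/control separation, race and
# gender mixes are equalised.
recovery_config <- function(n_patients, seed) {
  specs <- lab_reference_stats()
  informative_labs <- c("creatinine", "hba1c", "glucose", "wbc",
                        "hematocrit", "sodium")
  null_rows <- !(specs$lab %in% informative_labs)
  specs$case_mean[null_rows] <- specs$control_mean[null_rows]
  specs$case_sd[null_rows] <- specs$control_sd[null_rows]
  counts <- cohort_reference_counts()
  flat <- function(tab) {
    p <- tab$total / sum(tab$total)
    list(case = p, control = p)
  }
  generator_config(
    n_patients = n_patients,
    lab_specs = specs,
    race_mix = flat(counts$race),
    gender_mix = flat(counts$gender),
    seed = seed
  )
}
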