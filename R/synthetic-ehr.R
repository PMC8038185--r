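# Seeded synthetic EHR generator. Emits the four raw tables the pipeline
# consumes (patients, diagnoses, labs, encounters) with the statistical
# structure of a derivation-like diabetic cohort: ~3.8% DR prevalence,
# case/control laboratory mean shifts, complication prevalences,
# duration-of-diabetes mixture, and missingness that exercises the
# complete-case filter. Ground truth (labels, designed event dates, true
# lab means) is returned alongside for recovery tests.

#' Configuration for the synthetic EHR generator
#'
#' Defaults reproduce the derivation-like condition: DR prevalence 3.8%,
#' case/control lab means and SDs from [lab_reference_stats()], level
#' mixes of age, race, gender, duration and complications from
#' [cohort_reference_counts()].
#'
#' @param n_patients number of diabetic patients to generate.
#' @param dr_prevalence probability a patient is a DR case.
#' @param lab_specs data.frame like [lab_reference_stats()] giving per-lab
#'   case/control means and SDs; every generated lab needs a row.
#' @param complication_odds named list (`nephropathy`, `neuropathy`) of
#'   `c(case =, control =)` prevalence pairs. Defaults derived from the
#'   reference counts.
#' @param duration_mix list with `case` and `control` probability vectors
#'   over the duration groups `0-1, 1-2, 2-3, 3-4, >4` (years).
#' @param age_mix,race_mix,gender_mix like `duration_mix`, over the age
#'   groups, races and genders.
#' @param missing_rate probability that a (patient, lab) pair has no
#'   recorded value at all, so the aggregated feature is missing.
#' @param outlier_rate probability an individual lab value is replaced by
#'   an extreme value (see [inject_outliers()]); 0 disables injection.
#' @param outlier_magnitude displacement of injected outliers, in SDs.
#' @param visit_lambda Poisson rate for extra in-window lab draws; each
#'   present (patient, lab) pair gets `1 + rpois(visit_lambda)` values.
#' @param pred_window_lab_rate probability of an additional lab value
#'   falling inside the prediction window (it must never reach features).
#' @param lab_correlation reserved hook for a between-lab correlation
#'   structure; only `NULL` (independent labs) is currently implemented.
#' @param seed integer seed; identical configs give byte-identical tables.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 1000L,
                             dr_prevalence = 0.038,
                             lab_specs = lab_reference_stats(),
                             complication_odds = NULL,
                             duration_mix = NULL,
                             age_mix = NULL,
                             race_mix = NULL,
                             gender_mix = NULL,
                             missing_rate = 0.02,
                             outlier_rate = 0,
                             outlier_magnitude = 8,
                             visit_lambda = 1.5,
                             pred_window_lab_rate = 0.3,
                             lab_correlation = NULL,
                             seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients")
  check_prob(dr_prevalence, "dr_prevalence")
  check_prob(missing_rate, "missing_rate")
  check_prob(outlier_rate, "outlier_rate")
  check_prob(pred_window_lab_rate, "pred_window_lab_rate")
  if (!is.data.frame(lab_specs) || nrow(lab_specs) == 0L ||
      !all(c("lab", "case_mean", "case_sd", "control_mean", "control_sd")
           %in% names(lab_specs))) {
    stopf("`lab_specs` must be a nonempty data.frame with columns lab, case_mean, case_sd, control_mean, control_sd")
  }
  if (anyDuplicated(lab_specs$lab)) stopf("duplicate lab names in `lab_specs`")
  if (!is.null(lab_correlation)) {
    stopf("`lab_correlation` is a reserved hook; only independent labs are implemented")
  }

  counts <- cohort_reference_counts()
  mix_from <- function(tab) {
    list(case = tab$dr / sum(tab$dr),
         control = (tab$total - tab$dr) / sum(tab$total - tab$dr))
  }
  duration_mix <- duration_mix %||% mix_from(counts$duration_group)
  age_mix <- age_mix %||% mix_from(counts$age_group)
  race_mix <- race_mix %||% mix_from(counts$race)
  gender_mix <- gender_mix %||% mix_from(counts$gender)
  prev_from <- function(tab) {
    yes <- tab[tab$level == "1", ]
    c(case = yes$dr / sum(tab$dr),
      control = (yes$total - yes$dr) / sum(tab$total - tab$dr))
  }
  complication_odds <- complication_odds %||% list(
    nephropathy = prev_from(counts$nephropathy),
    neuropathy  = prev_from(counts$neuropathy)
  )
  for (nm in names(complication_odds)) {
    check_prob(complication_odds[[nm]][["case"]], paste0(nm, " case prevalence"))
    check_prob(complication_odds[[nm]][["control"]], paste0(nm, " control prevalence"))
  }
  for (nm in c("duration_mix", "age_mix", "race_mix", "gender_mix")) {
    mx <- get(nm)
    for (arm in c("case", "control")) {
      p <- mx[[arm]]
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
        stopf("`%s$%s` must be a probability vector summing to 1", nm, arm)
      }
    }
  }

  structure(list(
    n_patients = n_patients, dr_prevalence = dr_prevalence,
    lab_specs = lab_specs, complication_odds = complication_odds,
    duration_mix = duration_mix, age_mix = age_mix, race_mix = race_mix,
    gender_mix = gender_mix, missing_rate = missing_rate,
    outlier_rate = outlier_rate, outlier_magnitude = outlier_magnitude,
    visit_lambda = visit_lambda, pred_window_lab_rate = pred_window_lab_rate,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Level-group definitions shared by the generator and the windowing code.
.AGE_BREAKS <- c(18, 35, 50, 65, 75, 85, Inf)
.AGE_LABELS <- c("18-34", "35-49", "50-64", "65-74", "75-84", ">=85")
.DUR_BREAKS <- c(0, 1, 2, 3, 4, Inf)
.DUR_LABELS <- c("0-1", "1-2", "2-3", "3-4", ">4")
.RACE_LEVELS <- c("Black", "White", "Other")
.GENDER_LEVELS <- c("Female", "Male")

# Draw one category per patient from label-specific mixes.
sample_mix <- function(label, mix, levels) {
  out <- character(length(label))
  idx_case <- which(label == 1L)
  idx_ctrl <- which(label == 0L)
  if (length(idx_case)) {
    out[idx_case] <- sample(levels, length(idx_case), replace = TRUE,
                            prob = mix$case)
  }
  if (length(idx_ctrl)) {
    out[idx_ctrl] <- sample(levels, length(idx_ctrl), replace = TRUE,
                            prob = mix$control)
  }
  out
}

# Uniform duration (years) within the drawn group; the open-ended ">4"
# group is 4 + Exp(mean 5.2), giving the reference empirical mean of 9.2
# years for that level.
sample_duration_years <- function(group) {
  n <- length(group)
  lo <- c(`0-1` = 0, `1-2` = 1, `2-3` = 2, `3-4` = 3)[group]
  out <- numeric(n)
  open <- group == ">4"
  out[!open] <- stats::runif(sum(!open), lo[!open], lo[!open] + 1)
  out[open] <- 4 + stats::rexp(sum(open), rate = 1 / 5.2)
  out
}

#' Generate a synthetic diabetic cohort as raw EHR tables
#'
#' Builds, per patient: a DR label, an event-of-interest (EOI) day (first
#' DR diagnosis for cases, an encounter for controls), a first-diabetes
#' diagnosis placed so the designed duration of diabetes is realised, an
#' early registration encounter guaranteeing enough history for the
#' observation + prediction windows, complication diagnosis codes dated
#' before the prediction window, and laboratory values drawn around the
#' label-specific means inside the designed observation window (plus
#' occasional prediction-window values that the windowing stage must
#' ignore).
#'
#' @param config a [generator_config()].
#' @return List with `ehr` (class `ehr_tables`: data.frames `patients`,
#'   `diagnoses`, `labs`, `encounters`, all dates as `Date`) and `truth`
#'   (class `ground_truth`: per-patient `labels`, designed `eoi_day`,
#'   `informative_predictors`, and the `true_lab_means` matrix).
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 50, seed = 1))
#' nrow(cohort$ehr$patients)
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    stopf("`config` must be created by generator_config()")
  }
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  id <- seq_len(n)
  label <- stats::rbinom(n, 1L, cfg$dr_prevalence)

  # Anchor timeline: EOI day, then diabetes onset backwards from the
  # designed duration (duration = pred_start - onset, in years).
  eoi <- as.integer(round(stats::runif(n, 3000, 4000)))
  pred_days <- 182L
  windows_span <- 912L   # observation (730) + prediction (182)
  dur_group <- sample_mix(label, cfg$duration_mix, .DUR_LABELS)
  dur_years <- sample_duration_years(dur_group)
  pred_start <- eoi - pred_days
  onset <- pmin(as.integer(round(pred_start - dur_years * 365.25)), pred_start)

  # Registration encounter early enough that every patient has full
  # window coverage regardless of duration.
  reg_day <- pmin(onset, eoi - windows_span) -
    as.integer(round(stats::runif(n, 30, 400)))

  age_group <- sample_mix(label, cfg$age_mix, .AGE_LABELS)
  age_lo <- c(`18-34` = 18L, `35-49` = 35L, `50-64` = 50L, `65-74` = 65L,
              `75-84` = 75L, `>=85` = 85L)[age_group]
  age_hi <- c(`18-34` = 34L, `35-49` = 49L, `50-64` = 64L, `65-74` = 74L,
              `75-84` = 84L, `>=85` = 90L)[age_group]
  # Integer age at pred_start; birth year chosen so the fractional age at
  # pred_start stays inside [age, age + 1) and hence inside the group.
  age_int <- age_lo + as.integer(floor(stats::runif(n) * (age_hi - age_lo + 1L)))
  pred_year <- as.integer(format(day_to_date(pred_start), "%Y"))
  birth_year <- pred_year - age_int

  gender <- sample_mix(label, cfg$gender_mix, .GENDER_LEVELS)
  race <- sample_mix(label, cfg$race_mix, .RACE_LEVELS)

  patients <- data.frame(
    id = id, birth_year = birth_year, gender = gender, race = race,
    stringsAsFactors = FALSE
  )

  # Diagnoses: diabetes onset code for everyone; DR code at the EOI for
  # cases; complication codes dated before the prediction window.
  dx <- list(
    data.frame(id = id, day = onset,
               icd_code = sample(c("250.00", "E11.9", "E10.9"), n, TRUE,
                                 prob = c(0.5, 0.4, 0.1)),
               stringsAsFactors = FALSE)
  )
  cases <- which(label == 1L)
  if (length(cases)) {
    dx[[length(dx) + 1L]] <- data.frame(
      id = id[cases], day = eoi[cases],
      icd_code = sample(c("362.01", "E11.319", "E10.311"),
                        length(cases), TRUE, prob = c(0.5, 0.4, 0.1)),
      stringsAsFactors = FALSE
    )
  }
  comp_codes <- list(nephropathy = c("250.40", "E11.21"),
                     neuropathy  = c("250.60", "E11.40"))
  comp_flags <- list()
  for (comp in names(cfg$complication_odds)) {
    pr <- cfg$complication_odds[[comp]]
    p <- ifelse(label == 1L, pr[["case"]], pr[["control"]])
    has <- stats::rbinom(n, 1L, p)
    comp_flags[[comp]] <- has
    hit <- which(has == 1L)
    if (length(hit)) {
      # dated strictly before pred_start so the flag is 1 downstream
      day <- reg_day[hit] + as.integer(floor(stats::runif(length(hit)) *
                                             pmax(pred_start[hit] - reg_day[hit], 1L)))
      dx[[length(dx) + 1L]] <- data.frame(
        id = id[hit], day = pmin(day, pred_start[hit] - 1L),
        icd_code = sample(comp_codes[[comp]], length(hit), TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  diagnoses <- do.call(rbind, dx)

  # Encounters: registration for everyone; the control anchor at the
  # designed EOI (the only encounter that is both post-onset and has
  # >= 912 days of history, so cohort assembly recovers the designed
  # windows); ineligible decoys before onset for some patients.
  ctrl <- which(label == 0L)
  enc <- list(
    data.frame(id = id, day = reg_day, stringsAsFactors = FALSE),
    data.frame(id = id[ctrl], day = eoi[ctrl], stringsAsFactors = FALSE)
  )
  n_decoy <- stats::rpois(n, 0.7)
  has_decoy <- which(n_decoy > 0 & onset - reg_day > 2L)
  if (length(has_decoy)) {
    decoys <- rep(has_decoy, n_decoy[has_decoy])
    enc[[length(enc) + 1L]] <- data.frame(
      id = id[decoys],
      day = reg_day[decoys] + 1L +
        as.integer(floor(stats::runif(length(decoys)) *
                         (onset[decoys] - reg_day[decoys] - 1L))),
      stringsAsFactors = FALSE
    )
  }
  encounters <- do.call(rbind, enc)

  # Labs: per (patient, lab), absent entirely with prob missing_rate,
  # else 1 + Poisson(visit_lambda) values at uniform days inside the
  # designed observation window, Gaussian around the label mean; with
  # prob pred_window_lab_rate one extra value inside the prediction
  # window (must be excluded by the windowing stage).
  specs <- cfg$lab_specs
  n_lab <- nrow(specs)
  grid <- data.table::CJ(pid = id, lab_i = seq_len(n_lab), sorted = TRUE)
  present <- stats::runif(nrow(grid)) >= cfg$missing_rate
  grid <- grid[present]
  grid[, n_val := 1L + stats::rpois(.N, cfg$visit_lambda)]
  lab_rows <- grid[rep(seq_len(nrow(grid)), grid$n_val)]
  pid <- lab_rows$pid
  lab_i <- lab_rows$lab_i
  mu <- ifelse(label[pid] == 1L, specs$case_mean[lab_i], specs$control_mean[lab_i])
  sd <- ifelse(label[pid] == 1L, specs$case_sd[lab_i], specs$control_sd[lab_i])
  obs_start <- eoi - windows_span
  day <- obs_start[pid] +
    as.integer(floor(stats::runif(length(pid)) * 730L))
  labs <- data.frame(
    id = pid, day = day, test_name = specs$lab[lab_i],
    value = stats::rnorm(length(pid), mu, sd),
    stringsAsFactors = FALSE
  )
  # prediction-window extras
  extra <- grid[stats::runif(nrow(grid)) < cfg$pred_window_lab_rate]
  if (nrow(extra)) {
    pid2 <- extra$pid
    lab_i2 <- extra$lab_i
    mu2 <- ifelse(label[pid2] == 1L, specs$case_mean[lab_i2],
                  specs$control_mean[lab_i2])
    sd2 <- ifelse(label[pid2] == 1L, specs$case_sd[lab_i2],
                  specs$control_sd[lab_i2])
    labs <- rbind(labs, data.frame(
      id = pid2,
      day = pred_start[pid2] + as.integer(floor(stats::runif(length(pid2)) * 182L)),
      test_name = specs$lab[lab_i2],
      value = stats::rnorm(length(pid2), mu2, sd2),
      stringsAsFactors = FALSE
    ))
  }
  labs <- labs[order(labs$id, labs$test_name, labs$day), , drop = FALSE]
  rownames(labs) <- NULL

  if (cfg$outlier_rate > 0) {
    labs <- inject_outliers(labs, rate = cfg$outlier_rate,
                            magnitude = cfg$outlier_magnitude,
                            seed = derive_seed(cfg$seed, "outliers"),
                            lab_specs = specs)
  }

  to_date <- function(df) {
    df$date <- day_to_date(df$day)
    df$day <- NULL
    df[, c(1, ncol(df), seq_len(ncol(df))[-c(1, ncol(df))]), drop = FALSE]
  }
  diagnoses <- diagnoses[order(diagnoses$id, diagnoses$day), , drop = FALSE]
  encounters <- encounters[order(encounters$id, encounters$day), , drop = FALSE]
  rownames(diagnoses) <- rownames(encounters) <- NULL

  ehr <- structure(list(
    patients = patients,
    diagnoses = to_date(diagnoses),
    labs = to_date(labs),
    encounters = to_date(encounters)
  ), class = "ehr_tables")

  true_means <- matrix(ifelse(rep(label, n_lab) == 1L,
                              rep(specs$case_mean, each = n),
                              rep(specs$control_mean, each = n)),
                       nrow = n, dimnames = list(id, specs$lab))
  informative <- c(
    specs$lab[specs$case_mean != specs$control_mean],
    names(cfg$complication_odds)[vapply(cfg$complication_odds,
                                        function(p) p[["case"]] != p[["control"]],
                                        logical(1))],
    c("age_group", "race", "duration_group", "gender")[c(
      !identical(cfg$age_mix$case, cfg$age_mix$control),
      !identical(cfg$race_mix$case, cfg$race_mix$control),
      !identical(cfg$duration_mix$case, cfg$duration_mix$control),
      !identical(cfg$gender_mix$case, cfg$gender_mix$control))]
  )
  truth <- structure(list(
    labels = data.frame(id = id, label = label),
    eoi_day = eoi,
    duration_years = dur_years,
    complications = comp_flags,
    informative_predictors = informative,
    true_lab_means = true_means
  ), class = "ground_truth")

  list(ehr = ehr, truth = truth)
}

#' @export
print.ehr_tables <- function(x, ...) {
  cat("Synthetic EHR tables:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-10s %7d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Inject extreme laboratory values
#'
#' Replaces a seeded random subset of lab values with
#' `control_mean + magnitude * control_sd` of the corresponding test, to
#' exercise the interquartile-range outlier filter. Injection positions
#' are recorded in the `"injected"` attribute so tests can assert against
#' them.
#'
#' @param labs lab table (columns `test_name`, `value`).
#' @param rate probability each value is replaced.
#' @param magnitude displacement in control SDs.
#' @param seed integer seed for the selection mask.
#' @param lab_specs lab statistics table, defaults to
#'   [lab_reference_stats()].
#' @return The lab table with replaced values; attribute `"injected"`
#'   holds the integer row positions that were replaced.
#' @export
inject_outliers <- function(labs, rate, magnitude = 8, seed = 1L,
                            lab_specs = lab_reference_stats()) {
  check_prob(rate, "rate")
  if (rate == 0 || nrow(labs) == 0L) {
    attr(labs, "injected") <- integer(0)
    return(labs)
  }
  mask <- with_seed(seed, stats::runif(nrow(labs)) < rate)
  idx <- which(mask)
  m <- match(labs$test_name[idx], lab_specs$lab)
  if (anyNA(m)) stopf("labs contain tests absent from `lab_specs`")
  labs$value[idx] <- lab_specs$control_mean[m] + magnitude * lab_specs$control_sd[m]
  attr(labs, "injected") <- idx
  labs
}
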