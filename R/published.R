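# Published reference values from the derivation study: ICD code lists,
# derivation-cohort summary statistics, and the inputs of the published
# 10-predictor scoring table. These are data, not tuning knobs: the
# synthetic generator defaults to them and the regression tests pin the
# scoring arithmetic against them.

#' ICD-9/10-CM code lists defining the cohort
#'
#' Diagnosis-code prefixes identifying diabetes mellitus, diabetic
#' retinopathy (DR, the outcome), and the two microvascular complication
#' covariates. A code matches a concept when it starts with one of the
#' listed prefixes (so `250.40` is both a diabetes and a nephropathy
#' code, as in the ICD hierarchy).
#'
#' @return Named list of character vectors of code prefixes with elements
#'   `diabetes`, `retinopathy`, `nephropathy`, `neuropathy`.
#' @export
#' @examples
#' icd_code_lists()$retinopathy
icd_code_lists <- function() {
  list(
    diabetes    = c("250", "E10", "E11"),
    retinopathy = c("362.0",
                    paste0("E10.3", 1:5), paste0("E11.3", 1:5)),
    nephropathy = c("250.4", "E10.21", "E11.21"),
    neuropathy  = c("250.6", "E10.40", "E11.40")
  )
}

# TRUE for codes matching any prefix in `prefixes`.
matches_icd <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) {
    out <- out | startsWith(codes, p)
  }
  out
}

#' Derivation-cohort laboratory statistics
#'
#' Case (DR) and control (non-DR) means and standard deviations of the 20
#' routine blood tests in the derivation cohort. These are the default
#' generative parameters of [generator_config()].
#'
#' @return data.frame with columns `lab`, `case_mean`, `case_sd`,
#'   `control_mean`, `control_sd`.
#' @export
lab_reference_stats <- function() {
  tab <- rbind(
    c("hba1c",          8.36,  2.03,   7.14,  1.51),
    c("creatinine",     1.94,  1.81,   1.07,  0.46),
    c("glucose",      174.83, 61.95, 142.89, 46.24),
    c("hemoglobin",    12.08,  1.65,  13.03,  1.70),
    c("hematocrit",    36.24,  4.72,  38.97,  4.75),
    c("calcium",        9.12,  0.49,   9.26,  0.44),
    c("triglycerides",155.56, 89.85, 154.40, 84.71),
    c("potassium",      4.33,  0.38,   4.24,  0.35),
    c("chloride",     103.00,  3.45, 103.19,  2.85),
    c("mch",           29.57,  2.00,  29.95,  1.94),
    c("sodium",       138.49,  2.39, 138.83,  2.47),
    c("mchc",          33.32,  0.92,  33.43,  0.96),
    c("mcv",           88.74,  5.31,  89.53,  5.00),
    c("albumin",        3.64,  0.55,   3.86,  0.46),
    c("bilirubin",      0.58,  0.27,   0.61,  0.28),
    c("anion_gap",      9.55,  2.69,   9.47,  2.56),
    c("ast",           24.45,  9.79,  24.88, 10.08),
    c("alt",           25.18, 12.24,  27.86, 14.47),
    c("rbc",            4.10,  0.58,   4.37,  0.56),
    c("wbc",            7.97,  2.24,   8.13,  2.21)
  )
  out <- data.frame(
    lab          = tab[, 1],
    case_mean    = as.numeric(tab[, 2]),
    case_sd      = as.numeric(tab[, 3]),
    control_mean = as.numeric(tab[, 4]),
    control_sd   = as.numeric(tab[, 5]),
    stringsAsFactors = FALSE
  )
  out
}

#' Derivation-cohort categorical counts
#'
#' Per-level totals and DR counts for the categorical variables of the
#' derivation cohort (3749 DR / 94,127 non-DR diabetic patients). Used as
#' default level mixes by the synthetic generator and as printed inputs
#' for odds-ratio regression tests.
#'
#' @return Named list of data.frames, each with columns `level`, `total`,
#'   `dr`; names `age_group`, `gender`, `race`, `duration_group`,
#'   `nephropathy`, `neuropathy`.
#' @export
cohort_reference_counts <- function() {
  df <- function(level, total, dr) {
    data.frame(level = level, total = total, dr = dr, stringsAsFactors = FALSE)
  }
  list(
    age_group = df(c("18-34", "35-49", "50-64", "65-74", "75-84", ">=85"),
                   c(2723, 13247, 33554, 25118, 17198, 6036),
                   c(135, 620, 1585, 854, 480, 75)),
    gender = df(c("Female", "Male"),
                c(53396, 44480), c(2034, 1715)),
    race = df(c("Black", "White", "Other"),
              c(17993, 72488, 7395), c(1363, 2126, 260)),
    duration_group = df(c("0-1", "1-2", "2-3", "3-4", ">4"),
                        c(36536, 26359, 13560, 8696, 12725),
                        c(775, 843, 723, 518, 890)),
    nephropathy = df(c("0", "1"), c(92153, 5723), c(2711, 1038)),
    neuropathy  = df(c("0", "1"), c(88657, 9219), c(2507, 1242))
  )
}

#' Published scoring-table inputs
#'
#' The logistic coefficients, level definitions, level values M and
#' reference levels of the published 10-predictor DR risk index. Feeding
#' these into [derive_points()] with the published unit (B = 0.0935)
#' reproduces the published integer point values and the 0-160 score
#' range.
#'
#' Level bounds are left-closed, right-open intervals on the aggregated
#' predictor scale (years for age and duration of diabetes, 0/1 for the
#' complication flags, laboratory units otherwise).
#'
#' @return List with elements `coefficients` (named numeric, one entry
#'   per predictor, age in per-year units), `scheme` (a [level_scheme()])
#'   and `B` (the published risk-unit-per-point constant, 5 x |age
#'   coefficient|).
#' @seealso [derive_points()], [score_patients()]
#' @export
published_scoring_inputs <- function() {
  coefficients <- c(
    age         = -0.0187,
    creatinine  =  0.8601,
    hba1c       =  0.2877,
    neuropathy  =  0.9229,
    duration    =  0.1455,
    wbc         = -0.1077,
    nephropathy =  0.5598,
    glucose     =  0.0059,
    hematocrit  = -0.0609,
    sodium      =  0.0822
  )
  lv <- function(predictor, level, lower, upper, value, reference = FALSE) {
    data.frame(predictor = predictor, level = level, lower = lower,
               upper = upper, value = value, reference = reference,
               stringsAsFactors = FALSE)
  }
  scheme <- rbind(
    lv("age", "18-34", 18, 35, 26),
    lv("age", "35-49", 35, 50, 42),
    lv("age", "50-64", 50, 65, 57),
    lv("age", "65-74", 65, 75, 69.5),
    lv("age", "75-84", 75, 85, 79.5),
    lv("age", ">=85", 85, Inf, 87.5, reference = TRUE),

    lv("creatinine", "<0.5", -Inf, 0.5, 0.41, reference = TRUE),
    lv("creatinine", "0.5-1", 0.5, 1, 0.75),
    lv("creatinine", "1-1.5", 1, 1.5, 1.25),
    lv("creatinine", "1.5-2", 1.5, 2, 1.75),
    lv("creatinine", ">2", 2, Inf, 2.68),

    lv("hba1c", "<6", -Inf, 6, 5, reference = TRUE),
    lv("hba1c", "6-8", 6, 8, 7),
    lv("hba1c", "8-10", 8, 10, 9),
    lv("hba1c", "10-12", 10, 12, 11),
    lv("hba1c", ">12", 12, Inf, 14),

    lv("neuropathy", "No", 0, 0.5, 0, reference = TRUE),
    lv("neuropathy", "Yes", 0.5, Inf, 1),

    lv("duration", "<1", -Inf, 1, 0.5, reference = TRUE),
    lv("duration", "1-2", 1, 2, 1.5),
    lv("duration", "2-3", 2, 3, 2.5),
    lv("duration", "3-4", 3, 4, 3.5),
    lv("duration", ">4", 4, Inf, 9.2),

    lv("wbc", "<4", -Inf, 4, 3.5),
    lv("wbc", "4-6", 4, 6, 5),
    lv("wbc", "6-8", 6, 8, 7),
    lv("wbc", "8-12", 8, 12, 10),
    lv("wbc", ">12", 12, Inf, 18.2, reference = TRUE),

    lv("nephropathy", "No", 0, 0.5, 0, reference = TRUE),
    lv("nephropathy", "Yes", 0.5, Inf, 1),

    lv("glucose", "<60", -Inf, 60, 53, reference = TRUE),
    lv("glucose", "60-80", 60, 80, 70),
    lv("glucose", "80-100", 80, 100, 90),
    lv("glucose", "100-200", 100, 200, 150),
    lv("glucose", ">200", 200, Inf, 364),

    lv("hematocrit", "<30", -Inf, 30, 25.7),
    lv("hematocrit", "30-35", 30, 35, 32.5),
    lv("hematocrit", "35-40", 35, 40, 37.5),
    lv("hematocrit", "40-50", 40, 50, 45),
    lv("hematocrit", ">50", 50, Inf, 55, reference = TRUE),

    lv("sodium", "<136", -Inf, 136, 131.5, reference = TRUE),
    lv("sodium", "136-144", 136, 144, 140),
    lv("sodium", ">144", 144, Inf, 146.5)
  )
  list(
    coefficients = coefficients,
    scheme = level_scheme(scheme),
    B = 5 * abs(coefficients[["age"]])
  )
}

#' The published DR risk index as a ready-to-use scoring system
#'
#' Convenience wrapper: derives the published points system from
#' [published_scoring_inputs()] at call time, so the integer points are
#' always the output of the scoring arithmetic, not a stored table.
#'
#' @return A `scoring_system` object; see [derive_points()].
#' @export
#' @examples
#' sys <- published_risk_index()
#' score_range(sys)
published_risk_index <- function() {
  inp <- published_scoring_inputs()
  derive_points(inp$coefficients, inp$scheme, b = inp$B)
}
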