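# Window-based feature construction: event-of-interest selection,
# prediction/observation window arithmetic, IQR outlier removal, mean
# aggregation of labs, complication flags, duration of diabetes, and the
# complete-case filter. Produces one feature row per patient.

#' Windowing configuration
#'
#' @param prediction_days length of the prediction window, in days
#'   (default 182, i.e. six months). No data from this window feeds any
#'   feature: it is the lead time of the early warning.
#' @param observation_days length of the observation window immediately
#'   before the prediction window, over which labs are aggregated
#'   (default 730, i.e. two years).
#' @param iqr_factor multiplier of the interquartile range defining the
#'   outlier fences (default 1.5).
#' @param min_history_days minimum record history (days between a
#'   control's candidate encounter and the patient's earliest record)
#'   for the encounter to be an eligible event of interest. Defaults to
#'   `prediction_days + observation_days` so both windows are covered.
#' @param outlier_scope `"patient"` (default) computes IQR fences per
#'   patient per lab; `"cohort"` computes them per lab over all
#'   in-window values of the cohort.
#' @return An object of class `window_config`.
#' @export
window_config <- function(prediction_days = 182L,
                          observation_days = 730L,
                          iqr_factor = 1.5,
                          min_history_days = NULL,
                          outlier_scope = c("patient", "cohort")) {
  prediction_days <- check_count(prediction_days, "prediction_days")
  observation_days <- check_count(observation_days, "observation_days")
  if (!is.numeric(iqr_factor) || length(iqr_factor) != 1L || iqr_factor <= 0) {
    stopf("`iqr_factor` must be a single positive number")
  }
  min_history_days <- check_count(
    min_history_days %||% (prediction_days + observation_days),
    "min_history_days")
  outlier_scope <- match.arg(outlier_scope)
  structure(list(
    prediction_days = prediction_days,
    observation_days = observation_days,
    iqr_factor = iqr_factor,
    min_history_days = min_history_days,
    outlier_scope = outlier_scope
  ), class = "window_config")
}

#' Window bounds around an event of interest
#'
#' All intervals are half-open `[start, end)` on integer days, with the
#' EOI itself excluded: the prediction window is `[eoi - P, eoi)` and the
#' observation window `[eoi - P - O, eoi - P)`, so the two windows are
#' disjoint and adjacent (`obs_end == pred_start`).
#'
#' @param eoi event-of-interest day (integer day offset or `Date`).
#' @param cfg a [window_config()].
#' @return Named integer vector `obs_start`, `obs_end`, `pred_start`,
#'   `pred_end`.
#' @export
#' @examples
#' window_bounds(1000, window_config())
window_bounds <- function(eoi, cfg = window_config()) {
  if (inherits(eoi, "Date")) eoi <- date_to_day(eoi)
  eoi <- as.integer(eoi)
  pred_start <- eoi - cfg$prediction_days
  c(obs_start = pred_start - cfg$observation_days,
    obs_end = pred_start,
    pred_start = pred_start,
    pred_end = eoi)
}

#' Select the event of interest for one patient
#'
#' Cases anchor on their earliest DR diagnosis. Controls anchor on a
#' seeded uniform draw among eligible encounters: encounters strictly
#' after the first diabetes diagnosis with at least `min_history_days` of
#' record history behind them.
#'
#' @param dr_days integer days of DR diagnosis codes (cases).
#' @param encounter_days integer days of encounters (controls).
#' @param first_diabetes_day day of the first diabetes diagnosis.
#' @param first_record_day earliest day in the patient's record.
#' @param label 1 for a DR case, 0 for a control.
#' @param cfg a [window_config()] (for `min_history_days`).
#' @param seed integer seed for the control draw.
#' @return The EOI day, or `NA` with attribute `"reason"` when a control
#'   has no eligible encounter.
#' @export
identify_eoi <- function(dr_days, encounter_days, first_diabetes_day,
                         first_record_day, label, cfg = window_config(),
                         seed = 1L) {
  if (label == 1L) {
    if (length(dr_days) == 0L) stopf("case patient has no DR diagnosis code")
    return(as.integer(min(dr_days)))
  }
  eligible <- encounter_days[encounter_days > first_diabetes_day &
                             encounter_days - first_record_day >= cfg$min_history_days]
  if (length(eligible) == 0L) {
    return(structure(NA_integer_, reason = "no eligible encounter"))
  }
  if (length(eligible) == 1L) return(as.integer(eligible))
  with_seed(seed, as.integer(sample(eligible, 1L)))
}

#' Interquartile-range outlier filter
#'
#' Keeps values within `[Q1 - f*IQR, Q3 + f*IQR]`, with quartiles by
#' linear interpolation between order statistics (`stats::quantile`
#' type 7, the R default).
#'
#' @param values numeric vector.
#' @param factor fence multiplier `f` (default 1.5).
#' @return The retained values, in input order.
#' @export
#' @examples
#' remove_outliers_iqr(c(1, 2, 3, 4, 100))  # drops 100
remove_outliers_iqr <- function(values, factor = 1.5) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) return(numeric(0))
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values[values >= q[1] - factor * iqr & values <= q[2] + factor * iqr]
}

# Fractional age in years at `day` for a patient born on Jan 1 of
# `birth_year` (EHR sources carry birth year only).
age_at <- function(day, birth_year) {
  birth_day <- date_to_day(as.Date(paste0(birth_year, "-01-01")))
  (day - birth_day) / 365.25
}

cut_group <- function(x, breaks, labels) {
  as.character(cut(x, breaks = breaks, labels = labels, right = FALSE))
}

#' Aggregate one patient's record into a feature row
#'
#' Reference single-patient implementation of the windowing semantics:
#' lab means over post-IQR in-window values, complication flags from
#' codes dated strictly before the prediction window, duration of
#' diabetes in years from first diabetes diagnosis to the prediction
#' window start, and age at that same day. [build_features()] is the
#' vectorised cohort version; the two are cross-checked in the tests.
#'
#' @param patient one row of the patients table.
#' @param diagnoses,labs this patient's diagnosis and lab rows (with a
#'   `date` or integer `day` column).
#' @param eoi the patient's event-of-interest day.
#' @param cfg a [window_config()].
#' @param lab_names labs expected in the output (missing ones are `NA`).
#' @param label DR indicator for the row.
#' @return A one-row data.frame feature row.
#' @export
aggregate_patient <- function(patient, diagnoses, labs, eoi,
                              cfg = window_config(),
                              lab_names = lab_reference_stats()$lab,
                              label = NA_integer_) {
  days <- function(df) {
    if ("day" %in% names(df)) as.integer(df$day) else date_to_day(df$date)
  }
  wb <- window_bounds(eoi, cfg)
  dx_day <- days(diagnoses)
  codes <- icd_code_lists()

  first_diabetes <- min(dx_day[matches_icd(diagnoses$icd_code, codes$diabetes)])
  duration <- (wb[["pred_start"]] - first_diabetes) / 365.25
  age <- age_at(wb[["pred_start"]], patient$birth_year)

  flag <- function(prefixes) {
    as.integer(any(matches_icd(diagnoses$icd_code, prefixes) &
                   dx_day < wb[["pred_start"]]))
  }

  lab_day <- days(labs)
  in_obs <- lab_day >= wb[["obs_start"]] & lab_day < wb[["obs_end"]]
  lab_means <- vapply(lab_names, function(nm) {
    v <- labs$value[in_obs & labs$test_name == nm]
    v <- remove_outliers_iqr(v, cfg$iqr_factor)
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))

  row <- data.frame(
    id = patient$id,
    label = as.integer(label),
    eoi_day = wb[["pred_end"]],
    age_years = age,
    age_group = cut_group(age, .AGE_BREAKS, .AGE_LABELS),
    gender = patient$gender,
    race = patient$race,
    duration_years = duration,
    duration_group = cut_group(duration, .DUR_BREAKS, .DUR_LABELS),
    nephropathy = flag(codes$nephropathy),
    neuropathy = flag(codes$neuropathy),
    stringsAsFactors = FALSE
  )
  cbind(row, as.data.frame(as.list(lab_means)))
}

#' Build the cohort feature table from raw EHR tables
#'
#' Labels patients by presence of DR codes, selects each patient's event
#' of interest, lays out the observation and prediction windows, and
#' aggregates every variable: six age groups, gender, race, duration of
#' diabetes (years and group), nephropathy/neuropathy flags, and the
#' per-lab observation-window means after IQR outlier removal. Patients
#' younger than 18 at the prediction-window start, and controls without
#' an eligible encounter, are excluded with a logged reason. Missing lab
#' or demographic values are retained here and handled by
#' [complete_case_filter()].
#'
#' @param ehr an `ehr_tables` object (or a list of the four tables).
#' @param cfg a [window_config()].
#' @param seed seed for the control EOI draws; a stream independent of
#'   the generator's.
#' @return A `dr_features` data.frame, one row per retained patient,
#'   with attributes `exclusions` (data.frame id, reason) and `labs`
#'   (lab column names).
#' @export
build_features <- function(ehr, cfg = window_config(), seed = 1L) {
  if (inherits(ehr, "dr_features")) {
    stopf("`ehr` is already an aggregated feature table; re-aggregation is not supported")
  }
  for (nm in c("patients", "diagnoses", "labs", "encounters")) {
    if (is.null(ehr[[nm]])) stopf("`ehr` lacks the `%s` table", nm)
  }
  codes <- icd_code_lists()
  pts <- ehr$patients

  dx <- data.table::as.data.table(ehr$diagnoses)
  dx[, day := date_to_day(date)]
  enc <- data.table::as.data.table(ehr$encounters)
  enc[, day := date_to_day(date)]
  labs <- data.table::as.data.table(ehr$labs)
  labs[, day := date_to_day(date)]

  bad_id <- setdiff(unique(c(dx$id, enc$id, labs$id)), pts$id)
  if (length(bad_id)) {
    stopf("diagnosis/lab/encounter rows reference unknown patient ids: %s",
          paste(utils::head(bad_id, 5), collapse = ", "))
  }

  dx[, is_diab := matches_icd(icd_code, codes$diabetes)]
  dx[, is_dr := matches_icd(icd_code, codes$retinopathy)]
  dx[, is_neph := matches_icd(icd_code, codes$nephropathy)]
  dx[, is_neu := matches_icd(icd_code, codes$neuropathy)]

  first_diab <- dx[is_diab == TRUE, .(first_diabetes = min(day)), by = id]
  first_dr <- dx[is_dr == TRUE, .(first_dr = min(day)), by = id]
  first_rec <- data.table::rbindlist(list(
    dx[, .(id, day)], enc[, .(id, day)], labs[, .(id, day)]
  ))[, .(first_record = min(day)), by = id]

  info <- data.table::as.data.table(pts)
  info <- merge(info, first_diab, by = "id", all.x = TRUE)
  info <- merge(info, first_dr, by = "id", all.x = TRUE)
  info <- merge(info, first_rec, by = "id", all.x = TRUE)
  info[, label := as.integer(!is.na(first_dr))]

  excl <- list()
  no_diab <- info[is.na(first_diabetes)]
  if (nrow(no_diab)) {
    excl[[length(excl) + 1L]] <- data.frame(id = no_diab$id,
                                            reason = "no diabetes diagnosis")
    info <- info[!is.na(first_diabetes)]
  }

  # EOI: cases anchor on first DR; controls draw among eligible
  # encounters with a per-patient seed derived from the cohort stream.
  # Controls with a single eligible encounter need no draw; only the
  # (rare) multi-eligible controls go through the seeded selection.
  elig <- merge(enc[, .(id, day)],
                info[label == 0L, .(id, first_diabetes, first_record)],
                by = "id")
  elig <- elig[day > first_diabetes & day - first_record >= cfg$min_history_days]
  n_elig <- elig[, .N, by = id]
  single <- elig[id %in% n_elig[N == 1L, id]]
  eoi_map <- stats::setNames(single$day, single$id)
  for (pid_multi in n_elig[N > 1L, id]) {
    days_i <- elig[id == pid_multi, day]
    eoi_map[as.character(pid_multi)] <-
      with_seed(derive_seed(seed, "eoi", pid_multi),
                as.integer(sample(days_i, 1L)))
  }
  info[, eoi := data.table::fifelse(label == 1L, first_dr,
                                    eoi_map[as.character(id)])]
  no_eoi <- info[is.na(eoi)]
  if (nrow(no_eoi)) {
    excl[[length(excl) + 1L]] <- data.frame(id = no_eoi$id,
                                            reason = "no eligible encounter")
    info <- info[!is.na(eoi)]
  }

  info[, pred_start := eoi - cfg$prediction_days]
  info[, obs_start := pred_start - cfg$observation_days]
  info[, age_years := age_at(pred_start, birth_year)]
  under18 <- info[age_years < 18]
  if (nrow(under18)) {
    excl[[length(excl) + 1L]] <- data.frame(id = under18$id,
                                            reason = "younger than 18 at prediction window")
    info <- info[age_years >= 18]
  }
  if (nrow(info) == 0L) stopf("no patients remain after exclusions")

  info[, duration_years := (pred_start - first_diabetes) / 365.25]

  # Complication flags: any matching code strictly before pred_start.
  flags <- merge(dx[is_neph | is_neu, .(id, day, is_neph, is_neu)],
                 info[, .(id, pred_start)], by = "id")
  neph_ids <- unique(flags[is_neph == TRUE & day < pred_start, id])
  neu_ids <- unique(flags[is_neu == TRUE & day < pred_start, id])

  # Lab aggregation: in-window values, IQR filter (per patient or per
  # cohort), then the mean.
  lw <- merge(labs[, .(id, day, test_name, value)],
              info[, .(id, obs_start, pred_start)], by = "id")
  lw <- lw[day >= obs_start & day < pred_start]
  if (cfg$outlier_scope == "patient") {
    # Vectorised per-(patient, lab) IQR fences: quartiles by linear
    # interpolation (type 7) computed from within-group order
    # statistics. Semantics identical to remove_outliers_iqr(), which
    # the tests cross-check against this path.
    data.table::setorder(lw, id, test_name, value)
    lw[, g := .GRP, by = .(id, test_name)]
    starts <- lw[, .(start = .I[1], n = .N), by = g]
    qidx <- function(p) {
      h <- (starts$n - 1) * p
      lo <- floor(h)
      v_lo <- lw$value[starts$start + lo]
      v_hi <- lw$value[starts$start + pmin(lo + 1, starts$n - 1)]
      v_lo + (h - lo) * (v_hi - v_lo)
    }
    q1 <- qidx(0.25)[lw$g]
    q3 <- qidx(0.75)[lw$g]
    f <- cfg$iqr_factor * (q3 - q1)
    lw[, keep := value >= q1 - f & value <= q3 + f]
    agg <- lw[keep == TRUE, .(mean_value = mean(value)), by = .(id, test_name)]
  } else {
    lw[, keep := {
      q <- stats::quantile(value, c(0.25, 0.75), names = FALSE, type = 7)
      f <- cfg$iqr_factor * (q[2] - q[1])
      value >= q[1] - f & value <= q[2] + f
    }, by = test_name]
    agg <- lw[keep == TRUE, .(mean_value = mean(value)), by = .(id, test_name)]
  }
  lab_names <- sort(unique(labs$test_name))
  wide <- data.table::dcast(agg, id ~ test_name, value.var = "mean_value")
  missing_cols <- setdiff(lab_names, names(wide))
  for (mc in missing_cols) wide[, (mc) := NA_real_]

  out <- data.frame(
    id = info$id,
    label = info$label,
    eoi_day = info$eoi,
    age_years = info$age_years,
    age_group = cut_group(info$age_years, .AGE_BREAKS, .AGE_LABELS),
    gender = info$gender,
    race = info$race,
    duration_years = info$duration_years,
    duration_group = cut_group(info$duration_years, .DUR_BREAKS, .DUR_LABELS),
    nephropathy = as.integer(info$id %in% neph_ids),
    neuropathy = as.integer(info$id %in% neu_ids),
    stringsAsFactors = FALSE
  )
  m <- merge(data.table::as.data.table(out),
             wide, by = "id", all.x = TRUE, sort = FALSE)
  data.table::setcolorder(m, c(names(out), lab_names))
  out <- as.data.frame(m)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL

  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id = integer(0), reason = character(0))
  structure(out,
            exclusions = exclusions,
            labs = lab_names,
            class = c("dr_features", "data.frame"))
}

#' Complete-case filter
#'
#' Drops any row with a missing demographic or laboratory value. The
#' complication flags and duration of diabetes can never be missing by
#' construction and never cause removal.
#'
#' @param features a feature table from [build_features()].
#' @return List with `kept` (the complete rows, class preserved) and
#'   `exclusions` (data.frame `id`, `reason` naming the first missing
#'   variable per excluded patient).
#' @export
complete_case_filter <- function(features) {
  lab_names <- attr(features, "labs") %||%
    setdiff(names(features),
            c("id", "label", "eoi_day", "age_years", "age_group", "gender",
              "race", "duration_years", "duration_group",
              "nephropathy", "neuropathy"))
  checked <- c("age_years", "age_group", "gender", "race", lab_names)
  miss <- is.na(features[, checked, drop = FALSE])
  any_miss <- rowSums(miss) > 0
  reasons <- apply(miss[any_miss, , drop = FALSE], 1L, function(r) {
    paste0("missing ", checked[which(r)[1]])
  })
  kept <- features[!any_miss, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stopf("complete-case filter removed all %d rows (missing counts: %s)",
          nrow(features),
          paste(sprintf("%s=%d", checked[colSums(miss) > 0],
                        colSums(miss)[colSums(miss) > 0]), collapse = ", "))
  }
  rownames(kept) <- NULL
  attr(kept, "labs") <- lab_names
  attr(kept, "exclusions") <- data.frame(id = features$id[any_miss],
                                         reason = unname(reasons))
  list(kept = kept,
       exclusions = data.frame(id = features$id[any_miss],
                               reason = unname(reasons)))
}
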