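# Plain-text interchange: the four EHR tables and the feature table as
# tab-separated files with ISO-8601 dates, and the scoring system as a
# human-readable table usable without the software.

#' Write / read the raw EHR tables
#'
#' One tab-separated file per table (`patients.tsv`, `diagnoses.tsv`,
#' `labs.tsv`, `encounters.tsv`) with header rows and ISO-8601 dates.
#'
#' @param ehr an `ehr_tables` object.
#' @param dir output directory (created if needed).
#' @return `write_ehr` the directory invisibly; `read_ehr` an
#'   `ehr_tables` object.
#' @export
write_ehr <- function(ehr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "diagnoses", "labs", "encounters")) {
    df <- ehr[[nm]]
    if ("date" %in% names(df)) df$date <- format(df$date, "%Y-%m-%d")
    utils::write.table(df, file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_ehr
#' @export
read_ehr <- function(dir) {
  out <- lapply(c("patients", "diagnoses", "labs", "encounters"), function(nm) {
    df <- utils::read.delim(file.path(dir, paste0(nm, ".tsv")),
                            stringsAsFactors = FALSE)
    if ("date" %in% names(df)) df$date <- as.Date(df$date)
    if ("icd_code" %in% names(df)) df$icd_code <- as.character(df$icd_code)
    df
  })
  names(out) <- c("patients", "diagnoses", "labs", "encounters")
  structure(out, class = "ehr_tables")
}

#' Write / read a feature table
#'
#' Tab-separated, one row per patient; the exclusion log goes to a
#' sidecar `<file>.exclusions.tsv` when present.
#'
#' @param features a `dr_features` table.
#' @param file output path.
#' @export
write_features <- function(features, file) {
  utils::write.table(as.data.frame(features), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  excl <- attr(features, "exclusions")
  if (!is.null(excl) && nrow(excl)) {
    utils::write.table(excl, paste0(file, ".exclusions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_features
#' @export
read_features <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  lab_names <- setdiff(names(df),
                       c("id", "label", "eoi_day", "age_years", "age_group",
                         "gender", "race", "duration_years", "duration_group",
                         "nephropathy", "neuropathy"))
  structure(df, labs = lab_names, class = c("dr_features", "data.frame"))
}

#' Serialise a scoring system to a readable text file
#'
#' Key-value header (`B`, coefficients, score range) followed by the
#' level table, so the index can be applied by hand without the package.
#'
#' @param system a `scoring_system`.
#' @param file output path.
#' @export
write_scoring_system <- function(system, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# points-based DR risk index"),
    sprintf("B\t%.6f", system$B),
    sprintf("score_min\t%d", system$score_range[["min_total"]]),
    sprintf("score_max\t%d", system$score_range[["max_total"]]),
    paste0("coef_", names(system$coefficients), "\t",
           format(system$coefficients, trim = TRUE)),
    ""
  ), con)
  utils::write.table(system$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_scoring_system
#' @export
read_scoring_system <- function(file) {
  lines <- readLines(file)
  hdr_end <- which(lines == "")[1]
  hdr <- lines[seq_len(hdr_end - 1)]
  hdr <- hdr[!startsWith(hdr, "#")]
  kv <- do.call(rbind, strsplit(hdr, "\t"))
  vals <- stats::setNames(kv[, 2], kv[, 1])
  tab <- utils::read.delim(textConnection(lines[-seq_len(hdr_end)]),
                           stringsAsFactors = FALSE)
  coef_keys <- grep("^coef_", names(vals), value = TRUE)
  coefficients <- stats::setNames(as.numeric(vals[coef_keys]),
                                  sub("^coef_", "", coef_keys))
  structure(list(
    table = tab,
    B = as.numeric(vals[["B"]]),
    coefficients = coefficients,
    score_range = c(min_total = as.numeric(vals[["score_min"]]),
                    max_total = as.numeric(vals[["score_max"]]))
  ), class = "scoring_system")
}
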