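# Cohort CSV reading/writing with schema validation. Dialect: comma
# separated, period decimal point, UTF-8, "NA" for missing.

.cohort_required_cols <- c(
  "patient_id", "vap_confirmed", "temperature_c", "wbc_per_mm3",
  "band_forms_per_mm3", "pf_ratio", "ards", "secretions", "radiography",
  "microbiology", "pct_ng_ml", "lus_performed", "consolidation_type",
  "size_band", "laterality", "bronchogram")

.check_enum_col <- function(x, col, allowed, allow_na = FALSE,
                            idx = seq_along(x)) {
  bad <- which(!(x %in% allowed) & !(allow_na & is.na(x)))
  if (length(bad)) {
    stop(sprintf("row %d, column '%s': invalid value '%s' (valid: %s)",
                 idx[bad[1]], col, x[bad[1]], paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
}

.check_numeric_col <- function(x, col, min = -Inf, max = Inf, allow_na = FALSE) {
  if (!is.numeric(x))
    stop(sprintf("column '%s': non-numeric values", col), call. = FALSE)
  bad <- which((is.na(x) & !allow_na) | (!is.na(x) & (x < min | x > max)))
  if (length(bad))
    stop(sprintf("row %d, column '%s': value %s outside [%g, %g]",
                 bad[1], col, x[bad[1]], min, max), call. = FALSE)
}

#' Validate a cohort data frame against the cohort schema
#'
#' Checks required columns, enum levels, numeric domains, and the
#' structural consistency of the ultrasound columns: when
#' `lus_performed = 0` all four LUS columns must be `NA`; when an exam
#' exists but shows no consolidation, size and laterality must be
#' `"none"`. Errors name the first offending row and column.
#'
#' @param cohort data frame.
#' @return `cohort`, invisibly.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(.cohort_required_cols, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  .check_numeric_col(cohort$temperature_c, "temperature_c", 25, 45)
  .check_numeric_col(cohort$wbc_per_mm3, "wbc_per_mm3", 0)
  .check_numeric_col(cohort$band_forms_per_mm3, "band_forms_per_mm3", 0)
  .check_numeric_col(cohort$pf_ratio, "pf_ratio", 1e-9)
  .check_numeric_col(cohort$pct_ng_ml, "pct_ng_ml", 0, allow_na = TRUE)
  .check_enum_col(cohort$vap_confirmed, "vap_confirmed", c(0L, 1L))
  .check_enum_col(cohort$ards, "ards", c(0L, 1L))
  .check_enum_col(cohort$lus_performed, "lus_performed", c(0L, 1L))
  .check_enum_col(cohort$secretions, "secretions", .secretions_levels)
  .check_enum_col(cohort$radiography, "radiography", .radiography_levels,
                  allow_na = TRUE)
  .check_enum_col(cohort$microbiology, "microbiology", .microbiology_levels)
  off <- cohort$lus_performed == 0
  for (col in c("consolidation_type", "size_band", "laterality", "bronchogram")) {
    bad <- which(off & !is.na(cohort[[col]]))
    if (length(bad))
      stop(sprintf("row %d, column '%s': value present but lus_performed = 0",
                   bad[1], col), call. = FALSE)
  }
  on <- !off
  .check_enum_col(cohort$consolidation_type[on], "consolidation_type",
                  .consolidation_levels, idx = which(on))
  .check_enum_col(cohort$size_band[on], "size_band", .size_levels,
                  idx = which(on))
  .check_enum_col(cohort$laterality[on], "laterality", .laterality_levels,
                  idx = which(on))
  .check_enum_col(cohort$bronchogram[on], "bronchogram", .bronchogram_levels,
                  idx = which(on))
  nocons <- on & cohort$consolidation_type == "none"
  bad <- which(nocons & (cohort$size_band != "none" | cohort$laterality != "none"))
  if (length(bad))
    stop(sprintf("row %d: size_band/laterality without a consolidation", bad[1]),
         call. = FALSE)
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads and validates a patient-level cohort file. One row per
#' suspected-VAP episode; see the package README for the column
#' dictionary. Unknown enum values, missing required columns and
#' non-numeric measurements raise errors naming the row and column.
#'
#' @param path path to a cohort CSV (UTF-8, comma separated, `NA` for
#'   missing).
#' @return validated cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  classes <- c(patient_id = "character", vap_confirmed = "integer",
               temperature_c = "numeric", wbc_per_mm3 = "numeric",
               band_forms_per_mm3 = "numeric", pf_ratio = "numeric",
               ards = "integer", secretions = "character",
               radiography = "character", microbiology = "character",
               pct_ng_ml = "numeric", lus_performed = "integer",
               consolidation_type = "character", size_band = "character",
               laterality = "character", bronchogram = "character")
  header <- names(utils::read.csv(path, nrows = 0))
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = "NA", fileEncoding = "UTF-8",
                            colClasses = classes[intersect(header, names(classes))])
  validate_cohort(cohort)
  cohort
}

#' Write a cohort CSV
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Turn one cohort row into a patient_record
#'
#' @param row a single-row cohort data frame.
#' @return a [patient_record()].
#' @export
as_patient_record <- function(row) {
  stopifnot(is.data.frame(row), nrow(row) == 1)
  lus <- NULL
  if (row$lus_performed == 1)
    lus <- lus_exam(row$consolidation_type, row$size_band,
                    row$laterality, row$bronchogram)
  patient_record(
    patient_id = row$patient_id,
    vap_confirmed = row$vap_confirmed == 1,
    temperature = row$temperature_c, wbc = row$wbc_per_mm3,
    band_forms = row$band_forms_per_mm3, pf_ratio = row$pf_ratio,
    ards = row$ards == 1, secretions = row$secretions,
    radiography = row$radiography, microbiology = row$microbiology,
    pct = row$pct_ng_ml, lus = lus)
}
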