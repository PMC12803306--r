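#' Normalize a raw ICD code string
#'
#' Diagnosis tables and feature maps may write the same code differently
#' ("I50.9", "i50.9 ", "I509"). All comparisons in this package are done on
#' a canonical form: whitespace-trimmed, uppercased, with every `.` removed.
#' Codes are treated purely as identifiers within an ICD version; no
#' semantic ICD knowledge is applied.
#'
#' @param code character vector of raw code strings.
#' @param version ICD version(s), 9 or 10. Accepted for interface symmetry
#'   with the rest of the package; normalization itself is version-agnostic.
#' @return character vector of normalized codes. Idempotent:
#'   `normalize_icd(normalize_icd(x)) == normalize_icd(x)`.
#' @examples
#' normalize_icd("I50.9")      # "I509"
#' normalize_icd(" e11.9 ")    # "E119"
#' @export
normalize_icd <- function(code, version = NULL) {
  if (length(code) == 0L) return(character(0))
  out <- gsub(".", "", trimws(toupper(as.character(code))), fixed = TRUE)
  bad <- which(is.na(out) | out == "")
  if (length(bad) > 0L) {
    stop("empty ICD code after normalization at position(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  out
}

check_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s file '%s' is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

report_rows <- function(idx, msg) {
  stop(msg, " at data row(s): ",
       paste(utils::head(idx, 10L), collapse = ", "),
       if (length(idx) > 10L) sprintf(" (and %d more)", length(idx) - 10L) else "",
       call. = FALSE)
}

#' Read a long-format diagnosis table
#'
#' Expects a UTF-8, comma-delimited CSV with header
#' `patient_id,icd_code,icd_version,date`. Every code is normalized via
#' [normalize_icd()]; duplicate rows are legal and retained (presence of a
#' phenotype is decided downstream, so ingestion is lossless). Dates must be
#' ISO 8601 (`YYYY-MM-DD`); only the year is used downstream (age at last
#' diagnosis), but full dates are stored.
#'
#' @param path path to the CSV file.
#' @return data.frame with columns `patient_id` (character), `icd_code`
#'   (normalized character), `icd_version` (integer, 9 or 10), `event_date`
#'   (`Date`). Row count equals the number of data rows in the file.
#' @export
read_diagnoses <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  check_columns(df, c("patient_id", "icd_code", "icd_version", "date"),
                "diagnosis", path)
  n <- nrow(df)
  if (n == 0L) {
    return(data.frame(patient_id = character(0), icd_code = character(0),
                      icd_version = integer(0),
                      event_date = as.Date(character(0))))
  }
  ver_raw <- trimws(df$icd_version)
  bad_ver <- which(!ver_raw %in% c("9", "10"))
  if (length(bad_ver) > 0L) {
    report_rows(bad_ver, "icd_version must be 9 or 10")
  }
  code_raw <- trimws(df$icd_code)
  bad_code <- which(is.na(code_raw) | code_raw == "")
  if (length(bad_code) > 0L) report_rows(bad_code, "empty icd_code")
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad_date <- which(is.na(dates))
  if (length(bad_date) > 0L) {
    report_rows(bad_date, "unparseable date (expected YYYY-MM-DD)")
  }
  data.frame(
    patient_id = df$patient_id,
    icd_code = normalize_icd(df$icd_code),
    icd_version = as.integer(ver_raw),
    event_date = dates,
    stringsAsFactors = FALSE
  )
}

#' Write a diagnosis table in the dialect [read_diagnoses()] consumes
#' @param diagnoses data.frame as returned by [read_diagnoses()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_diagnoses <- function(diagnoses, path) {
  out <- data.frame(
    patient_id = diagnoses$patient_id,
    icd_code = diagnoses$icd_code,
    icd_version = diagnoses$icd_version,
    date = format(diagnoses$event_date, "%Y-%m-%d"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a demographics table
#'
#' One row per patient: `patient_id,birth_year,sex,race_ethnicity`.
#' `race_ethnicity` is kept verbatim (EHR labels such as
#' `"BLACK OR AFRICAN AMERICAN"`); stratification matches on the exact
#' string.
#'
#' @param path path to the CSV file.
#' @return data.frame with one row per patient.
#' @export
read_demographics <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  check_columns(df, c("patient_id", "birth_year", "sex", "race_ethnicity"),
                "demographics", path)
  dup <- which(duplicated(df$patient_id))
  if (length(dup) > 0L) {
    report_rows(dup, paste0("duplicate patient_id (",
                            paste(unique(df$patient_id[dup]), collapse = ", "),
                            ")"))
  }
  by_raw <- trimws(df$birth_year)
  by <- suppressWarnings(as.integer(by_raw))
  bad <- which(is.na(by) | as.character(by) != by_raw)
  if (length(bad) > 0L) report_rows(bad, "non-integer birth_year")
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  out_of_range <- which(by < 1880L | by > this_year)
  if (length(out_of_range) > 0L) {
    report_rows(out_of_range,
                sprintf("birth_year outside [1880, %d]", this_year))
  }
  data.frame(
    patient_id = df$patient_id,
    birth_year = by,
    sex = df$sex,
    race_ethnicity = df$race_ethnicity,
    stringsAsFactors = FALSE
  )
}

#' @rdname read_demographics
#' @param demographics data.frame as returned by [read_demographics()].
#' @export
write_demographics <- function(demographics, path) {
  utils::write.csv(
    demographics[, c("patient_id", "birth_year", "sex", "race_ethnicity")],
    path, row.names = FALSE)
  invisible(path)
}

GENOTYPE_STATUSES <- c("carrier", "noncarrier_confirmed", "unknown")

#' Read a genotype-status table
#'
#' One row per patient: `patient_id,status` where `status` is one of
#' `carrier` (harbors the target pathogenic variant),
#' `noncarrier_confirmed` (sequencing-confirmed absence), or `unknown`
#' (no determination; these patients form the weight-training pool, see
#' [assign_roles()]).
#'
#' @param path path to the CSV file.
#' @return data.frame with columns `patient_id`, `status`.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  check_columns(df, c("patient_id", "status"), "genotype", path)
  dup <- which(duplicated(df$patient_id))
  if (length(dup) > 0L) report_rows(dup, "duplicate patient_id")
  status <- trimws(df$status)
  bad <- which(!status %in% GENOTYPE_STATUSES)
  if (length(bad) > 0L) {
    report_rows(bad, paste0("status must be one of: ",
                            paste(GENOTYPE_STATUSES, collapse = ", ")))
  }
  data.frame(patient_id = df$patient_id, status = status,
             stringsAsFactors = FALSE)
}

#' @rdname read_genotypes
#' @param genotypes data.frame as returned by [read_genotypes()].
#' @export
write_genotypes <- function(genotypes, path) {
  utils::write.csv(genotypes[, c("patient_id", "status")], path,
                   row.names = FALSE)
  invisible(path)
}
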