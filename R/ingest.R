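#' Normalize raw ICD-10 codes to three-character categories
#'
#' The analysis groups diagnoses at the ICD-10 three-character category
#' level: the first letter plus two digits of the code (e.g. `"M81.0"` ->
#' `"M81"`). Input is handled case-insensitively and dots and whitespace
#' are stripped before truncation.
#'
#' @param raw_code Character vector of raw ICD-10 codes.
#' @return Character vector of 3-character category codes.
#' @export
#' @examples
#' normalize_icd(c("M81.0", "I10", " e11.9 "))
normalize_icd <- function(raw_code) {
  if (length(raw_code) == 0L) return(character(0))
  cleaned <- gsub("[[:space:].]", "", toupper(as.character(raw_code)))
  out <- substr(cleaned, 1L, 3L)
  bad <- is.na(raw_code) | !grepl("^[A-Z][0-9]{2}$", out)
  if (any(bad)) {
    stop("not valid ICD-10 codes (need letter + 2 digits): ",
         paste(utils::head(unique(raw_code[bad]), 5L), collapse = ", "))
  }
  out
}

#' Flag clinically significant anxiety and/or depression (CSAD)
#'
#' CSAD is defined by the screening instrument's validated cutoff: an HEI
#' total score of 11 or more. Missing scores return `NA`; records without a
#' score are excluded from CSAD analyses downstream.
#'
#' @param hei_total Integer vector of HEI total scores (>= 0 or `NA`).
#' @param cutoff Score threshold, default 11.
#' @return Logical vector.
#' @export
#' @examples
#' flag_csad(c(0, 10, 11, NA))
flag_csad <- function(hei_total, cutoff = 11L) {
  if (any(hei_total < 0, na.rm = TRUE)) stop("hei_total must be nonnegative")
  hei_total >= cutoff
}

#' Count multimorbidities
#'
#' Any diagnosed disease other than the index disease (osteoporosis) counts
#' as a multimorbidity; a patient with only index codes counts 0. Set
#' semantics: duplicates never inflate the count.
#'
#' @param codes Character vector (treated as a set) of normalized 3-character
#'   codes carried by one patient.
#' @param index_codes Index-disease category codes to exclude; the default
#'   covers osteoporosis with and without pathological fracture.
#' @return Integer count.
#' @export
#' @examples
#' count_multimorbidity(c("M81", "I10", "E11"))
count_multimorbidity <- function(codes, index_codes = c("M80", "M81")) {
  length(setdiff(unique(codes), index_codes))
}

#' Ingest patient and diagnosis tables into an analysis-ready cohort
#'
#' Normalizes diagnosis codes, de-duplicates patients and diagnoses, and
#' derives the per-patient analysis variables: multimorbidity count and
#' CSAD flag. Patients appearing on multiple rows (multiple admissions) are
#' merged: diagnosis codes are unioned across rows, demographics come from
#' the earliest row (input order), and the HEI total from the earliest row
#' carrying a score. Diagnosis rows whose code cannot be normalized are
#' dropped and reported in the `rejected` element.
#'
#' @param patients Data frame with columns `patient_id`, `age`, `sex`,
#'   `marital`, `hei_total` (NA allowed).
#' @param diagnoses Data frame with columns `patient_id`, `icd_code`.
#' @param index_codes Index-disease 3-character codes (default
#'   `c("M80", "M81")`).
#' @param hei_cutoff CSAD cutoff passed to [flag_csad()].
#' @param quiet Suppress the rejected-row message.
#' @return An object of class `emr_cohort`: list with `records` (one row
#'   per patient: patient_id, age, sex, marital, hei_total, csad,
#'   n_multimorbidity), `diagnoses` (normalized, de-duplicated long table),
#'   `index_codes`, and `rejected` (dropped diagnosis rows with reasons).
#' @export
ingest_cohort <- function(patients, diagnoses,
                          index_codes = c("M80", "M81"),
                          hei_cutoff = 11L, quiet = FALSE) {
  need_p <- c("patient_id", "age", "sex", "marital", "hei_total")
  if (!all(need_p %in% names(patients)))
    stop("patients table must have columns: ", paste(need_p, collapse = ", "))
  if (!all(c("patient_id", "icd_code") %in% names(diagnoses)))
    stop("diagnoses table must have columns: patient_id, icd_code")
  if (nrow(patients) == 0L) stop("empty cohort")

  # earliest-admission merge policy: first row per patient for demographics,
  # first non-missing HEI score
  first_idx <- !duplicated(patients$patient_id)
  recs <- patients[first_idx, need_p, drop = FALSE]
  has_hei <- !is.na(patients$hei_total)
  hei_rows <- patients[has_hei, c("patient_id", "hei_total")]
  hei_rows <- hei_rows[!duplicated(hei_rows$patient_id), , drop = FALSE]
  recs$hei_total <- hei_rows$hei_total[match(recs$patient_id, hei_rows$patient_id)]

  dx <- diagnoses[diagnoses$patient_id %in% recs$patient_id, , drop = FALSE]
  cleaned <- gsub("[[:space:].]", "", toupper(as.character(dx$icd_code)))
  norm <- substr(cleaned, 1L, 3L)
  ok <- !is.na(dx$icd_code) & grepl("^[A-Z][0-9]{2}$", norm)
  rejected <- data.frame(patient_id = dx$patient_id[!ok],
                         icd_code = dx$icd_code[!ok],
                         reason = rep("not an ICD-10 letter+2-digit category",
                                      sum(!ok)),
                         stringsAsFactors = FALSE)
  orphan <- diagnoses[!diagnoses$patient_id %in% recs$patient_id, , drop = FALSE]
  if (nrow(orphan)) {
    rejected <- rbind(rejected,
                      data.frame(patient_id = orphan$patient_id,
                                 icd_code = orphan$icd_code,
                                 reason = rep("patient_id not in patients table",
                                              nrow(orphan)),
                                 stringsAsFactors = FALSE))
  }
  if (!quiet && nrow(rejected))
    message("ingest_cohort: dropped ", nrow(rejected), " diagnosis row(s)")

  dx <- data.frame(patient_id = dx$patient_id[ok], icd_code = norm[ok],
                   stringsAsFactors = FALSE)
  dx <- unique(dx)
  dx <- dx[order(dx$patient_id, dx$icd_code), , drop = FALSE]
  rownames(dx) <- NULL

  non_index <- dx[!dx$icd_code %in% index_codes, , drop = FALSE]
  counts <- table(non_index$patient_id)
  recs$n_multimorbidity <- as.integer(counts[recs$patient_id])
  recs$n_multimorbidity[is.na(recs$n_multimorbidity)] <- 0L
  recs$csad <- flag_csad(recs$hei_total, cutoff = hei_cutoff)
  recs <- recs[, c("patient_id", "age", "sex", "marital", "hei_total",
                   "csad", "n_multimorbidity")]
  rownames(recs) <- NULL

  structure(list(records = recs, diagnoses = dx,
                 index_codes = index_codes, rejected = rejected),
            class = "emr_cohort")
}

#' Read a cohort from delimited files
#'
#' Reads the two-file interchange format written by [write_cohort()]
#' (comma-delimited, header row, UTF-8) and ingests it via
#' [ingest_cohort()]. Column names can be remapped for foreign exports.
#'
#' @param patients_path,diagnoses_path CSV paths.
#' @param col_map Optional named character vector mapping the expected
#'   column names to the names used in the files, e.g.
#'   `c(patient_id = "pid")`.
#' @param ... Passed to [ingest_cohort()].
#' @return An `emr_cohort`.
#' @export
read_cohort <- function(patients_path, diagnoses_path, col_map = NULL, ...) {
  pat <- read.csv(patients_path, stringsAsFactors = FALSE)
  dx <- read.csv(diagnoses_path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      names(pat)[names(pat) == col_map[[std]]] <- std
      names(dx)[names(dx) == col_map[[std]]] <- std
    }
  }
  ingest_cohort(pat, dx, ...)
}

#' Build the patients-by-diseases presence matrix
#'
#' Binary presence with set semantics (repeat diagnoses never inflate
#' counts), columns ordered lexicographically by code, and per-code
#' prevalence as column sum over the number of patients.
#'
#' @param cohort An `emr_cohort`, or a list with `records` and `diagnoses`
#'   in the ingest format.
#' @param drop_index Drop the index-disease columns from the matrix
#'   (default `FALSE`; the network builder applies its own exclusion).
#' @return An object of class `disease_matrix`: list with `presence`
#'   (sparse logical patients x codes matrix), `codes`, `patient_ids`,
#'   `n_patients`, and `prevalence` (named vector).
#' @export
build_matrix <- function(cohort, drop_index = FALSE) {
  records <- cohort$records
  dx <- cohort$diagnoses
  if (is.null(records) || nrow(records) == 0L) stop("empty cohort")
  if (anyDuplicated(records$patient_id))
    stop("duplicate patient_id after de-duplication")
  if (drop_index) dx <- dx[!dx$icd_code %in% cohort$index_codes, , drop = FALSE]
  codes <- sort(unique(dx$icd_code))
  ids <- records$patient_id
  presence <- Matrix::sparseMatrix(
    i = match(dx$patient_id, ids),
    j = match(dx$icd_code, codes),
    x = 1,
    dims = c(length(ids), length(codes)),
    dimnames = list(ids, codes)
  )
  presence@x[] <- 1  # set semantics: collapse any repeated entries
  prevalence <- Matrix::colSums(presence) / length(ids)
  structure(list(presence = presence, codes = codes, patient_ids = ids,
                 n_patients = length(ids), prevalence = prevalence),
            class = "disease_matrix")
}

#' @exportS3Method base::print
print.emr_cohort <- function(x, ...) {
  cat("<emr_cohort>", nrow(x$records), "patients,",
      nrow(x$diagnoses), "unique diagnoses,",
      nrow(x$rejected), "rejected rows\n")
  invisible(x)
}

#' @exportS3Method base::print
print.disease_matrix <- function(x, ...) {
  cat("<disease_matrix>", x$n_patients, "patients x",
      length(x$codes), "codes\n")
  invisible(x)
}
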