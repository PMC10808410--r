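#' Generate a synthetic EMR-style cohort
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes. Disease presence uses Gaussian-copula thresholding: a latent
#' multivariate normal vector with the config's association matrix is drawn
#' per patient, and disease j is present iff the latent value exceeds
#' `qnorm(1 - prevalence_j)` (after any probit-scale sex/age shifts). This
#' gives exact marginal control with tunable pairwise dependence. CSAD is
#' Bernoulli with logit p = intercept + b_female*female + b_age*age +
#' b_widowed*widowed + b_count*multimorbidity (+ any planted per-disease
#' terms), and the HEI total is drawn uniformly from [11, hei_max] for CSAD
#' patients and [0, 10] otherwise, so the score is always consistent with
#' the flag. Every patient additionally carries the index osteoporosis code
#' so the downstream exclusion rule is exercised.
#'
#' Identical `(config, seed)` yields an identical cohort.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `synthetic_cohort`: a list with `patients`
#'   (data frame: patient_id, age, sex, marital, hei_total), `diagnoses`
#'   (long data frame: patient_id, icd_code), `truth` (logical matrix of
#'   generated disease presence plus the csad vector, for oracles), and
#'   `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_config(n_patients = 500), seed = 42)
#' head(cohort$patients)
generate_cohort <- function(config, seed = config$seed) {
  validate_config(config)
  set.seed(as.integer(seed))
  n <- config$n_patients
  specs <- config$disease_specs
  k <- nrow(specs)

  # age: rejection sampling within the bounds, integer years
  age <- numeric(0)
  while (length(age) < n) {
    draw <- rnorm(2L * (n - length(age)) + 10L, config$age_mean, config$age_sd)
    draw <- draw[draw >= config$age_bounds[1] & draw <= config$age_bounds[2]]
    age <- c(age, draw)
  }
  age <- as.integer(round(age[seq_len(n)]))

  female <- rbinom(n, 1L, config$p_female) == 1L
  sex <- ifelse(female, "female", "male")
  marital <- sample(names(config$marital_probs), n, replace = TRUE,
                    prob = config$marital_probs)

  # latent MVN via the (pivoted, PSD-safe) Cholesky factor
  R <- config$association_matrix
  L <- tryCatch(chol(R), error = function(e) {
    ed <- eigen(R, symmetric = TRUE)
    chol_from_eigen(ed)
  })
  Z <- matrix(rnorm(n * k), n, k) %*% L
  shift <- outer(as.numeric(female), specs$probit_female) +
    outer((age - config$age_mean) / 10, specs$probit_age10)
  thresholds <- qnorm(1 - specs$prevalence)
  present <- sweep(Z + shift, 2L, thresholds, ">")
  colnames(present) <- specs$code

  n_multi <- as.integer(rowSums(present))
  eta <- config$csad_betas[["intercept"]] +
    config$csad_betas[["female"]] * as.numeric(female) +
    config$csad_betas[["age"]] * age +
    config$csad_betas[["widowed"]] * as.numeric(marital == "widowed") +
    config$csad_betas[["count"]] * n_multi
  for (code in names(config$csad_disease_betas)) {
    eta <- eta + config$csad_disease_betas[[code]] * as.numeric(present[, code])
  }
  csad <- rbinom(n, 1L, plogis(eta)) == 1L
  hei_total <- integer(n)
  hei_total[csad] <- 11L + sample.int(config$hei_max - 10L,
                                      sum(csad), replace = TRUE) - 1L
  hei_total[!csad] <- sample.int(11L, sum(!csad), replace = TRUE) - 1L

  id <- sprintf("P%06d", seq_len(n))
  patients <- data.frame(patient_id = id, age = age, sex = sex,
                         marital = marital, hei_total = hei_total,
                         stringsAsFactors = FALSE)
  per_patient <- apply(present, 1L, function(row) specs$code[row],
                       simplify = FALSE)
  counts <- lengths(per_patient)
  diagnoses <- data.frame(
    patient_id = c(rep(id, counts), id),
    icd_code = c(unlist(per_patient, use.names = FALSE),
                 rep(config$index_code, n)),
    stringsAsFactors = FALSE
  )
  diagnoses <- diagnoses[order(match(diagnoses$patient_id, id),
                               diagnoses$icd_code), , drop = FALSE]
  rownames(diagnoses) <- NULL

  structure(list(patients = patients, diagnoses = diagnoses,
                 truth = list(present = present, csad = csad, seed = seed),
                 config = config),
            class = "synthetic_cohort")
}

# Cholesky-like factor for a PSD (possibly singular) correlation matrix
chol_from_eigen <- function(ed) {
  vals <- pmax(ed$values, 0)
  t(ed$vectors %*% diag(sqrt(vals), length(vals)))
}

#' Write a synthetic cohort to delimited files
#'
#' Serializes the cohort in the pipeline's interchange format: two UTF-8,
#' comma-delimited files with header rows — `patients.csv` (patient_id,
#' age, sex, marital, hei_total) and `diagnoses.csv` (patient_id,
#' icd_code).
#'
#' @param cohort A `synthetic_cohort` (or any list with `patients` and
#'   `diagnoses` data frames).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             diagnoses = file.path(dir, "diagnoses.csv"))
  write.csv(cohort$patients, paths[["patients"]], row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8")
  write.csv(cohort$diagnoses, paths[["diagnoses"]], row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$patients), "patients,",
      nrow(x$diagnoses), "diagnosis rows\n")
  invisible(x)
}
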