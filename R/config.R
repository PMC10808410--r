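#' Reference calibration tables
#'
#' Published summary tables from a large tertiary-hospital inpatient cohort
#' of 13,359 Chinese Han patients with osteoporosis (aged 50 or older),
#' shipped as plain CSV under `extdata`. They calibrate the synthetic
#' cohort generator and serve as arithmetic fixtures: every printed
#' percentage can be recomputed from its printed numerator and the stratum
#' denominator.
#'
#' @param which One of `"demographics"` (counts and percentages by CSAD
#'   status), `"means"` (means and SDs of age and multimorbidity count),
#'   `"prevalence"` (the 16 diseases with prevalence over 10%, by sex and
#'   age group, with within-column ranks), or `"strata"` (stratum
#'   denominators).
#' @return A data frame.
#' @export
#' @examples
#' head(reference_table("prevalence"))
reference_table <- function(which = c("demographics", "means", "prevalence", "strata")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("reference_", which, ".csv"),
                      package = "comorbnet", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Cohort simulation configuration
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' defaults reproduce the reference cohort's stated world: n = 13,359
#' patients, 80.2% female, age normal(69.9, 10.2) truncated to [50, 101],
#' marital proportions married/unmarried/widowed/divorced =
#' 0.868/0.006/0.110/0.015 (renormalized; the printed proportions sum to
#' 0.999 from rounding), the 16 reference diseases at their printed overall
#' prevalences, and a latent (tetrachoric-scale) correlation of 0.4 for the
#' pairs (I10, E11) and (I10, I70) with zeros elsewhere.
#'
#' Disease presence is generated by Gaussian-copula thresholding, so
#' `association_matrix` is a latent correlation matrix: symmetric, unit
#' diagonal, positive semidefinite. CSAD status is drawn from a logistic
#' model in female sex, age (per year), widowhood and multimorbidity count;
#' `csad_betas` are free simulation parameters (the reference cohort's
#' fitted odds ratios are model outputs, not generative truth). Optional
#' `csad_disease_betas` add per-disease log-odds to the CSAD model, for
#' planting disease-distress associations.
#'
#' @param n_patients Cohort size.
#' @param age_mean,age_sd,age_bounds Age distribution (years); ages are
#'   sampled by rejection within `age_bounds` and rounded to whole years.
#'   `age_bounds[1]` must be >= 50 (cohort inclusion rule).
#' @param p_female Proportion of female patients.
#' @param marital_probs Named proportions over
#'   married/unmarried/widowed/divorced; renormalized to sum to 1.
#' @param disease_specs Data frame with columns `code` (3-character ICD-10
#'   category), `prevalence` (target marginal prevalence in (0,1)), and
#'   optionally `probit_female` and `probit_age10` (probit-scale shifts of
#'   the latent threshold for female sex and per decade of age centred at
#'   `age_mean`; defaults 0, which keeps marginals exactly at target).
#' @param association_matrix Latent correlation matrix over
#'   `disease_specs$code` (dimnames required when not the default).
#' @param csad_betas Named numeric: `intercept`, `female`, `age`, `widowed`,
#'   `count` — log-odds scale coefficients of the CSAD model.
#' @param csad_disease_betas Named numeric, extra CSAD log-odds per disease
#'   code (default none).
#' @param hei_max Maximum attainable HEI total score. The nine-item scale's
#'   item scoring is not part of this model; totals are drawn directly, and
#'   27 (nine items scored 0-3) is the documented default.
#' @param index_code Full ICD code written for the index disease in every
#'   patient's diagnosis list (default `"M81.0"`, osteoporosis without
#'   pathological fracture, exercising the truncation rule downstream).
#' @param seed Default random seed used when [generate_cohort()] is called
#'   without one.
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$disease_specs[cfg$disease_specs$code == "I10", "prevalence"]
cohort_config <- function(n_patients,
                          age_mean, age_sd, age_bounds,
                          p_female,
                          marital_probs,
                          disease_specs,
                          association_matrix = NULL,
                          csad_betas,
                          csad_disease_betas = numeric(0),
                          hei_max = 27L,
                          index_code = "M81.0",
                          seed = 1L) {
  if (is.null(disease_specs$probit_female)) disease_specs$probit_female <- 0
  if (is.null(disease_specs$probit_age10)) disease_specs$probit_age10 <- 0
  k <- nrow(disease_specs)
  if (is.null(association_matrix)) {
    association_matrix <- diag(k)
    dimnames(association_matrix) <- list(disease_specs$code, disease_specs$code)
  }
  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
    p_female = p_female,
    marital_probs = marital_probs / sum(marital_probs),
    disease_specs = disease_specs,
    association_matrix = association_matrix,
    csad_betas = csad_betas,
    csad_disease_betas = csad_disease_betas,
    hei_max = as.integer(hei_max),
    index_code = index_code,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_config(cfg)
}

#' @rdname cohort_config
#' @export
default_config <- function(n_patients = 13359L, seed = 1L) {
  prev <- reference_table("prevalence")
  specs <- data.frame(code = prev$code,
                      prevalence = prev$pct_total / 100,
                      stringsAsFactors = FALSE)
  k <- nrow(specs)
  R <- diag(k)
  dimnames(R) <- list(specs$code, specs$code)
  # planted positive associations: hypertension with diabetes and with
  # atherosclerosis; 0.4 on the latent scale reproduces the observed-scale
  # O/E ~ 1.5 implied by the reference co-occurrence counts
  for (pair in list(c("I10", "E11"), c("I10", "I70"))) {
    R[pair[1], pair[2]] <- R[pair[2], pair[1]] <- 0.4
  }
  cohort_config(
    n_patients = n_patients,
    age_mean = 69.9, age_sd = 10.2, age_bounds = c(50, 101),
    p_female = 0.802,
    marital_probs = c(married = 0.868, unmarried = 0.006,
                      widowed = 0.110, divorced = 0.015),
    disease_specs = specs,
    association_matrix = R,
    # free parameters: ~7.5% CSAD prevalence, effect directions matching
    # the reference cohort's risk-factor analysis
    csad_betas = c(intercept = -1.0, female = 0.21, age = -0.03,
                   widowed = 0.42, count = 0.058),
    seed = seed
  )
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants: marital proportions sum to 1, all
#' prevalences lie strictly in (0, 1), the association matrix is symmetric
#' positive semidefinite with unit diagonal, and the lower age bound
#' respects the cohort inclusion rule (>= 50 years).
#'
#' @param config A `cohort_config`.
#' @return The config, invisibly unchanged, or an error.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_patients < 1L) stop("n_patients must be positive")
  if (abs(sum(config$marital_probs) - 1) > 1e-9)
    stop("marital_probs must sum to 1")
  if (!all(names(config$marital_probs) %in%
           c("married", "unmarried", "widowed", "divorced")))
    stop("marital_probs must be named married/unmarried/widowed/divorced")
  p <- config$disease_specs$prevalence
  if (any(p <= 0 | p >= 1)) stop("disease prevalences must lie in (0, 1)")
  if (config$p_female <= 0 || config$p_female >= 1)
    stop("p_female must lie in (0, 1)")
  if (config$age_bounds[1] < 50)
    stop("age_bounds[1] must be >= 50: the cohort is defined as aged 50 or older")
  R <- config$association_matrix
  k <- nrow(config$disease_specs)
  if (!is.matrix(R) || nrow(R) != k || ncol(R) != k)
    stop("association_matrix must be ", k, "x", k)
  if (max(abs(R - t(R))) > 1e-10) stop("association_matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10)
    stop("association_matrix must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("association_matrix is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  off <- R[upper.tri(R)]
  if (any(off <= -1 | off >= 1))
    stop("latent correlations must lie in (-1, 1)")
  bad <- setdiff(names(config$csad_disease_betas), config$disease_specs$code)
  if (length(bad))
    stop("csad_disease_betas name unknown disease codes: ",
         paste(bad, collapse = ", "))
  needed <- c("intercept", "female", "age", "widowed", "count")
  if (!all(needed %in% names(config$csad_betas)))
    stop("csad_betas must be named: ", paste(needed, collapse = ", "))
  if (config$hei_max < 11L)
    stop("hei_max must be at least the CSAD cutoff (11)")
  invisible(config)
}

#' @exportS3Method base::print
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  n_patients:", x$n_patients, "\n")
  cat(sprintf("  age: %.1f (SD %.1f), bounds [%g, %g]\n",
              x$age_mean, x$age_sd, x$age_bounds[1], x$age_bounds[2]))
  cat(sprintf("  p_female: %.3f\n", x$p_female))
  cat("  diseases:", nrow(x$disease_specs), "| planted latent correlations:",
      sum(x$association_matrix[upper.tri(x$association_matrix)] != 0), "\n")
  invisible(x)
}
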