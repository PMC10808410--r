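# shared fixtures and independent oracles, all built in code

# brute-force pair statistics: explicit per-patient loop, independent of
# the vectorized implementation
brute_pairs <- function(X) {
  n <- nrow(X)
  codes <- colnames(X)
  rows <- list()
  for (i in seq_along(codes)) {
    for (j in seq_along(codes)) {
      if (j <= i) next
      co <- 0L
      for (p in seq_len(n)) {
        if (X[p, i] != 0 && X[p, j] != 0) co <- co + 1L
      }
      if (co == 0L) next
      pa <- sum(X[, i] != 0) / n
      pb <- sum(X[, j] != 0) / n
      rows[[length(rows) + 1L]] <- data.frame(
        code_a = codes[i], code_b = codes[j], co_count = co,
        observed = co / n, expected = pa * pb,
        rr = (co / n) / (pa * pb), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(code_a = character(0), code_b = character(0),
                      co_count = integer(0), observed = numeric(0),
                      expected = numeric(0), rr = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$code_a, res$code_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# wrap a plain binary matrix (colnames = ICD-like codes) as a disease_matrix
dm_from_matrix <- function(X) {
  ids <- sprintf("P%04d", seq_len(nrow(X)))
  rownames(X) <- NULL
  dx_idx <- which(X != 0, arr.ind = TRUE)
  diagnoses <- data.frame(patient_id = ids[dx_idx[, 1]],
                          icd_code = colnames(X)[dx_idx[, 2]],
                          stringsAsFactors = FALSE)
  records <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  build_matrix(list(records = records, diagnoses = diagnoses,
                    index_codes = character(0)))
}

# small cohort config with explicit disease set and latent correlations
small_cfg <- function(n, prevalences, corr = NULL,
                      csad_betas = c(intercept = -2.5, female = 0.2,
                                     age = -0.03, widowed = 0.4,
                                     count = 0.05),
                      csad_disease_betas = numeric(0)) {
  codes <- sprintf("A%02d", seq_along(prevalences))
  specs <- data.frame(code = codes, prevalence = prevalences,
                      stringsAsFactors = FALSE)
  R <- diag(length(codes))
  dimnames(R) <- list(codes, codes)
  if (!is.null(corr)) {
    for (entry in corr) {
      R[entry$i, entry$j] <- R[entry$j, entry$i] <- entry$rho
    }
  }
  if (length(csad_disease_betas) && is.null(names(csad_disease_betas)))
    names(csad_disease_betas) <- codes[seq_along(csad_disease_betas)]
  cohort_config(
    n_patients = n,
    age_mean = 69.9, age_sd = 10.2, age_bounds = c(50, 101),
    p_female = 0.802,
    marital_probs = c(married = 0.868, unmarried = 0.006,
                      widowed = 0.110, divorced = 0.015),
    disease_specs = specs,
    association_matrix = R,
    csad_betas = csad_betas,
    csad_disease_betas = csad_disease_betas
  )
}

# realized relative risk from the generator's truth matrix (direct 2x2 count)
realized_rr <- function(present, a, b) {
  n <- nrow(present)
  co <- sum(present[, a] & present[, b])
  (co / n) / ((sum(present[, a]) / n) * (sum(present[, b]) / n))
}

# small ingestible cohort built by hand
toy_tables <- function() {
  patients <- data.frame(
    patient_id = c("p1", "p2", "p3", "p4"),
    age = c(55L, 63L, 71L, 85L),
    sex = c("female", "female", "male", "female"),
    marital = c("married", "widowed", "married", "divorced"),
    hei_total = c(3L, 12L, NA, 11L),
    stringsAsFactors = FALSE
  )
  diagnoses <- data.frame(
    patient_id = c("p1", "p1", "p2", "p2", "p3", "p4"),
    icd_code = c("M81.0", "I10", "M81.0", "E11.9", "M81.0", "M81.0"),
    stringsAsFactors = FALSE
  )
  list(patients = patients, diagnoses = diagnoses)
}
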