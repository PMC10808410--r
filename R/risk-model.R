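#' Multivariable logistic regression with Wald odds-ratio intervals
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares
#' via the binomial GLM machinery; up to 100 iterations, convergence
#' tolerance 1e-8) with Wald 95% confidence intervals on the odds-ratio
#' scale, `exp(beta +/- 1.96 * SE)`. No regularization is applied: complete
#' or quasi-complete separation is detected (fitted probabilities pinned at
#' 0/1 or exploding coefficients) and reported through the `converged`
#' flag, not penalized away.
#'
#' @param design Data frame of covariates (numeric columns and/or factors;
#'   factors are expanded with treatment contrasts against their first
#'   level). No missing values allowed.
#' @param outcome Logical (or 0/1) vector; both classes must be present.
#' @param conf_level Confidence level for the Wald intervals.
#' @return An object of class `logit_fit`: list with `coefficients` (data
#'   frame: term, estimate, se, or_, ci_lower, ci_upper, z, p_value), `n`,
#'   `converged`, `loglik`, and the underlying `glm` object in `fit`.
#' @export
#' @examples
#' d <- data.frame(x = rep(c(1, 0), c(100, 100)))
#' y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 70, 10, 90))
#' fit_logistic(d, y)$coefficients
fit_logistic <- function(design, outcome, conf_level = 0.95) {
  outcome <- as.logical(outcome)
  if (anyNA(outcome) || anyNA(design)) stop("missing values in outcome or covariates")
  if (length(unique(outcome)) < 2L)
    stop("outcome has a single class; logistic model is not identifiable")
  if (nrow(design) != length(outcome)) stop("design/outcome length mismatch")

  dat <- cbind(.y = as.integer(outcome), design)
  warns <- character(0)
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial(),
        control = list(maxit = 100L, epsilon = 1e-8)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  separated <- any(grepl("fitted probabilities numerically 0 or 1", warns)) ||
    any(abs(coef(fit)) > 15)
  converged <- isTRUE(fit$converged) && !separated
  if (!converged)
    warning("logistic fit did not converge cleanly",
            if (separated) " (separation suspected)" else "")

  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  z <- est / se
  coefs <- data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    or_ = exp(unname(est)),
    ci_lower = exp(unname(est - zq * se)),
    ci_upper = exp(unname(est + zq * se)),
    z = unname(z),
    p_value = 2 * pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE
  )
  structure(list(coefficients = coefs, n = length(outcome),
                 converged = converged, loglik = as.numeric(stats::logLik(fit)),
                 fit = fit),
            class = "logit_fit")
}

#' @exportS3Method base::print
print.logit_fit <- function(x, digits = 3, ...) {
  cat("<logit_fit> n =", x$n,
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

csad_design <- function(rec, include_sex = TRUE) {
  d <- data.frame(
    age = as.numeric(rec$age),
    marital = factor(rec$marital,
                     levels = c("married", "unmarried", "widowed", "divorced")),
    n_multimorbidity = as.numeric(rec$n_multimorbidity)
  )
  if (include_sex)
    d <- cbind(data.frame(female = as.integer(rec$sex == "female")), d)
  d
}

#' Risk factors for emotional distress, overall and sex-stratified
#'
#' Fits the multivariable logistic model of CSAD on sex, age (per year),
#' marital status (married as the reference level) and multimorbidity count
#' (per condition) for all patients, then refits within the female and male
#' strata with sex dropped. Records without an HEI score are excluded. A
#' stratum with fewer than two CSAD events (or fewer than two non-events)
#' is flagged and not fit.
#'
#' @param cohort An `emr_cohort` with complete demographic covariates.
#' @param conf_level Confidence level for Wald intervals.
#' @return A list of class `table_three` with elements `all`, `female`,
#'   `male` (each a `logit_fit` or `NULL` if not fit), and `summary`, a
#'   combined data frame with a `stratum` column, including reference-level
#'   rows (OR fixed at 1, no interval).
#' @export
table_three <- function(cohort, conf_level = 0.95) {
  rec <- cohort$records[!is.na(cohort$records$hei_total), , drop = FALSE]
  fits <- list(all = NULL, female = NULL, male = NULL)
  strata <- list(all = rec,
                 female = rec[rec$sex == "female", , drop = FALSE],
                 male = rec[rec$sex == "male", , drop = FALSE])
  for (s in names(strata)) {
    r <- strata[[s]]
    if (sum(r$csad) < 2L || sum(!r$csad) < 2L) {
      warning("stratum '", s, "' has fewer than 2 outcome events; not fit")
      next
    }
    fits[[s]] <- fit_logistic(csad_design(r, include_sex = s == "all"),
                              r$csad, conf_level = conf_level)
  }

  ref_row <- function(stratum, term) data.frame(
    stratum = stratum, term = term, estimate = 0, se = NA_real_, or_ = 1,
    ci_lower = NA_real_, ci_upper = NA_real_, z = NA_real_,
    p_value = NA_real_, reference = TRUE, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(names(fits), function(s) {
    f <- fits[[s]]
    if (is.null(f)) return(NULL)
    co <- cbind(stratum = s, f$coefficients, reference = FALSE,
                stringsAsFactors = FALSE)
    refs <- rbind(if (s == "all") ref_row(s, "sex: male (ref)"),
                  ref_row(s, "marital: married (ref)"))
    rbind(co, refs)
  }))
  rownames(summ) <- NULL
  structure(list(all = fits$all, female = fits$female, male = fits$male,
                 summary = summ),
            class = "table_three")
}

#' @exportS3Method base::print
print.table_three <- function(x, ...) {
  cat("<table_three> CSAD risk-factor models\n")
  print(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}
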