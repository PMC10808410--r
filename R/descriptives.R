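#' Chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction by default (matching
#' the classical large-sample test; the Yates-corrected variant is behind
#' the flag). For 2x2 tables the uncorrected statistic equals the square of
#' the two-proportion z statistic.
#'
#' @param tab A contingency table (matrix of counts).
#' @param correct Apply Yates continuity correction (2x2 only).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chisq_group_test <- function(tab, correct = FALSE) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  res <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

welch_or_pooled_t <- function(x, y, pooled = FALSE) {
  res <- t.test(x, y, var.equal = pooled)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

pct1 <- function(num, den) round(100 * num / den, 1)

#' Demographic characteristics and emotional distress (table one)
#'
#' Summarizes the cohort by CSAD status: counts and row percentages for sex
#' and marital status (chi-square test across groups), mean (SD) for age
#' and multimorbidity count (t test, Welch by default). Records without an
#' HEI score are excluded, mirroring the voluntary-screening subcohort
#' design. Percentages use one decimal place; within a categorical row the
#' CSAD and non-CSAD percentages are row percentages (share of that level's
#' patients), as in the reference layout.
#'
#' @param cohort An `emr_cohort`.
#' @param correct Continuity-correct the chi-square tests (default FALSE).
#' @param pooled_t Use the pooled-variance t test instead of Welch.
#' @return A data frame of class `table_one` with one row per level (or per
#'   quantitative variable): columns variable, level, n, pct, n_no_csad,
#'   pct_no_csad, n_csad, pct_csad, mean, sd, mean_no_csad, sd_no_csad,
#'   mean_csad, sd_csad, test, statistic, p_value. Group rows with n = 0
#'   are emitted with a missing test.
#' @export
table_one <- function(cohort, correct = FALSE, pooled_t = FALSE) {
  rec <- cohort$records[!is.na(cohort$records$hei_total), , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records with an HEI score")
  csad <- rec$csad
  out <- list()

  cat_block <- function(variable, values, levels) {
    tab <- table(factor(values, levels = levels), factor(csad, c(FALSE, TRUE)))
    test <- if (all(rowSums(tab) > 0) && nrow(tab) >= 2L)
      chisq_group_test(tab[rowSums(tab) > 0, , drop = FALSE], correct = correct)
    else list(statistic = NA_real_, p_value = NA_real_)
    data.frame(
      variable = variable, level = levels,
      n = as.integer(rowSums(tab)),
      pct = pct1(rowSums(tab), nrow(rec)),
      n_no_csad = as.integer(tab[, 1]),
      pct_no_csad = pct1(tab[, 1], rowSums(tab)),
      n_csad = as.integer(tab[, 2]),
      pct_csad = pct1(tab[, 2], rowSums(tab)),
      mean = NA_real_, sd = NA_real_,
      mean_no_csad = NA_real_, sd_no_csad = NA_real_,
      mean_csad = NA_real_, sd_csad = NA_real_,
      test = "chi-square",
      statistic = c(test$statistic, rep(NA_real_, length(levels) - 1L)),
      p_value = c(test$p_value, rep(NA_real_, length(levels) - 1L)),
      stringsAsFactors = FALSE
    )
  }
  num_block <- function(variable, values) {
    grp0 <- values[!csad]; grp1 <- values[csad]
    test <- if (length(grp0) > 1L && length(grp1) > 1L) {
      if (stats::sd(grp0) == 0 && stats::sd(grp1) == 0) {
        # degenerate constant groups: t test undefined; report by comparison
        if (mean(grp0) == mean(grp1)) list(statistic = 0, p_value = 1)
        else list(statistic = Inf, p_value = 0)
      } else welch_or_pooled_t(grp0, grp1, pooled = pooled_t)
    } else list(statistic = NA_real_, p_value = NA_real_)
    data.frame(
      variable = variable, level = "mean_sd",
      n = length(values), pct = NA_real_,
      n_no_csad = length(grp0), pct_no_csad = NA_real_,
      n_csad = length(grp1), pct_csad = NA_real_,
      mean = mean(values), sd = stats::sd(values),
      mean_no_csad = mean(grp0), sd_no_csad = stats::sd(grp0),
      mean_csad = mean(grp1), sd_csad = stats::sd(grp1),
      test = if (pooled_t) "t (pooled)" else "t (Welch)",
      statistic = test$statistic, p_value = test$p_value,
      stringsAsFactors = FALSE
    )
  }

  out$sex <- cat_block("sex", rec$sex, c("female", "male"))
  out$age <- num_block("age", rec$age)
  out$marital <- cat_block("marital", rec$marital,
                           c("married", "unmarried", "widowed", "divorced"))
  out$multi <- num_block("n_multimorbidity", rec$n_multimorbidity)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("table_one", "data.frame")
  res
}

#' Age groups used throughout the analysis
#'
#' Decadal bands 50-59, 60-69, 70-79 and >= 80, matching the reference
#' cohort's stratification.
#'
#' @param age Numeric vector of ages in years (>= 50).
#' @return Factor with levels `"50-59"`, `"60-69"`, `"70-79"`, `">=80"`.
#' @export
age_group <- function(age) {
  cut(age, breaks = c(50, 60, 70, 80, Inf), right = FALSE,
      labels = c("50-59", "60-69", "70-79", ">=80"))
}

#' Prevalence of separate multimorbidities by sex and age group (table two)
#'
#' For every non-index disease whose overall prevalence meets
#' `min_prevalence`, reports the overall count and percentage, the count,
#' percentage and within-column rank for each sex and age group, and
#' chi-square p-values across sex and across age groups. Ranks are
#' descending by count within each column, with ties broken by code
#' lexicographic order.
#'
#' @param matrix_ A `disease_matrix` from [build_matrix()].
#' @param cohort The `emr_cohort` the matrix was built from (for sex, age
#'   and the index-code set).
#' @param min_prevalence Overall-prevalence filter; the reference table
#'   prints diseases over 10% (default `0.10`).
#' @param correct Continuity-correct the chi-square tests.
#' @return A data frame of class `prevalence_table`, one row per retained
#'   code, ordered by descending overall count.
#' @export
prevalence_table <- function(matrix_, cohort, min_prevalence = 0.10,
                             correct = FALSE) {
  rec <- cohort$records
  stopifnot(identical(matrix_$patient_ids, rec$patient_id))
  keep <- setdiff(matrix_$codes[matrix_$prevalence >= min_prevalence],
                  cohort$index_codes)
  n <- matrix_$n_patients
  groups <- list(
    female = rec$sex == "female",
    male = rec$sex == "male"
  )
  ag <- age_group(rec$age)
  age_keys <- c("50-59" = "age_50_59", "60-69" = "age_60_69",
                "70-79" = "age_70_79", ">=80" = "age_80plus")
  for (lev in levels(ag)) groups[[age_keys[[lev]]]] <- !is.na(ag) & ag == lev

  rows <- lapply(keep, function(code) {
    present <- as.logical(matrix_$presence[, code])
    row <- list(code = code, n_total = sum(present),
                pct_total = pct1(sum(present), n))
    for (g in names(groups)) {
      sel <- groups[[g]]
      row[[paste0("n_", g)]] <- sum(present & sel)
      row[[paste0("pct_", g)]] <- pct1(sum(present & sel), sum(sel))
    }
    sex_tab <- rbind(c(sum(present & groups$female), sum(!present & groups$female)),
                     c(sum(present & groups$male), sum(!present & groups$male)))
    row$p_sex <- chisq_group_test(sex_tab, correct = correct)$p_value
    age_tab <- t(vapply(unname(age_keys), function(key) {
      sel <- groups[[key]]
      c(sum(present & sel), sum(!present & sel))
    }, numeric(2)))
    row$p_age <- chisq_group_test(age_tab, correct = correct)$p_value
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(code = character(0))
  } else {
    # ranks: descending count within each column, ties by code
    for (g in names(groups)) {
      cnt <- res[[paste0("n_", g)]]
      ord <- order(-cnt, res$code)
      rk <- integer(length(ord)); rk[ord] <- seq_along(ord)
      res[[paste0("rank_", g)]] <- rk
    }
    res <- res[order(-res$n_total, res$code), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("prevalence_table", "data.frame")
  res
}

#' Write a descriptive table as CSV and aligned text
#'
#' @param x A data frame (e.g. from [table_one()] or [prevalence_table()]).
#' @param path Output path without extension; writes `<path>.csv` and
#'   `<path>.txt`.
#' @return Invisibly, the two paths.
#' @export
write_table <- function(x, path) {
  csv <- paste0(path, ".csv"); txt <- paste0(path, ".txt")
  write.csv(as.data.frame(x), csv, row.names = FALSE, fileEncoding = "UTF-8")
  writeLines(utils::capture.output(print(format(as.data.frame(x)),
                                         row.names = FALSE)), txt)
  invisible(c(csv = csv, txt = txt))
}
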