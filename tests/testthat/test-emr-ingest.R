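test_that("ICD-10 codes normalize to the three-character category", {
  cases <- list(
    c("M81.0", "M81"),
    c("I10", "I10"),
    c(" e11.9 ", "E11"),
    c("j44.1", "J44"),
    c("N18.5x", "N18")
  )
  for (cs in cases) expect_identical(normalize_icd(cs[1]), cs[2])
  expect_identical(normalize_icd(c("M81.0", "I10")), c("M81", "I10"))
  expect_error(normalize_icd("81M"), "81M")
  expect_error(normalize_icd(""), "valid ICD-10")
  expect_error(normalize_icd("Mxx"), "Mxx")
})

test_that("CSAD flag follows the score >= 11 cutoff", {
  expect_identical(flag_csad(c(0L, 10L, 11L, 27L, NA)),
                   c(FALSE, FALSE, TRUE, TRUE, NA))
  expect_error(flag_csad(-1L), "nonnegative")
})

test_that("multimorbidity counting excludes the index codes with set semantics", {
  expect_equal(count_multimorbidity("M81"), 0L)
  expect_equal(count_multimorbidity(c("M81", "I10", "E11")), 2L)
  expect_equal(count_multimorbidity(c("M81", "M80", "I10")), 1L)
  expect_equal(count_multimorbidity(c("I10", "I10", "E11")), 2L)
  expect_equal(count_multimorbidity(character(0)), 0L)
  expect_equal(count_multimorbidity(c("M81", "I10"), index_codes = "M81"), 1L)
})

test_that("ingest derives per-patient analysis variables", {
  tt <- toy_tables()
  ic <- ingest_cohort(tt$patients, tt$diagnoses)
  rec <- ic$records
  expect_equal(nrow(rec), 4L)
  expect_equal(rec$n_multimorbidity, c(1L, 1L, 0L, 0L))
  expect_identical(rec$csad, c(FALSE, TRUE, NA, TRUE))
  # codes were truncated
  expect_true(all(nchar(ic$diagnoses$icd_code) == 3L))
})

test_that("invalid diagnosis rows are rejected with the offending value", {
  tt <- toy_tables()
  tt$diagnoses <- rbind(tt$diagnoses,
                        data.frame(patient_id = c("p1", "p9"),
                                   icd_code = c("bogus", "I10"),
                                   stringsAsFactors = FALSE))
  expect_message(ic <- ingest_cohort(tt$patients, tt$diagnoses),
                 "dropped 2")
  expect_equal(nrow(ic$rejected), 2L)
  expect_true("bogus" %in% ic$rejected$icd_code)
  expect_true("p9" %in% ic$rejected$patient_id)
})

test_that("multiple admissions merge by the earliest-record policy", {
  patients <- data.frame(
    patient_id = c("p1", "p1", "p1"),
    age = c(60L, 61L, 62L),
    sex = "female", marital = c("married", "widowed", "widowed"),
    hei_total = c(NA, 14L, 2L),
    stringsAsFactors = FALSE
  )
  diagnoses <- data.frame(patient_id = "p1",
                          icd_code = c("M81.0", "I10", "I10.1", "E11"),
                          stringsAsFactors = FALSE)
  ic <- ingest_cohort(patients, diagnoses)
  expect_equal(nrow(ic$records), 1L)
  expect_equal(ic$records$age, 60L)                 # earliest demographics
  expect_equal(ic$records$marital, "married")
  expect_equal(ic$records$hei_total, 14L)           # earliest row WITH a score
  expect_true(ic$records$csad)
  expect_equal(ic$records$n_multimorbidity, 2L)     # I10 union-deduplicated
})

test_that("disease matrix counts presence with deterministic ordering", {
  pats <- data.frame(patient_id = paste0("p", 1:4), age = 60L,
                     sex = "female", marital = "married", hei_total = 0L,
                     stringsAsFactors = FALSE)
  dx <- data.frame(
    patient_id = c("p1", "p2", "p2", "p3"),
    icd_code = c("I10", "I10", "E11", "E11"),
    stringsAsFactors = FALSE)
  dm <- build_matrix(ingest_cohort(pats, dx))
  expect_equal(dm$codes, c("E11", "I10"))  # lexicographic
  expect_equal(unname(dm$prevalence["I10"]), 0.5)
  expect_equal(unname(dm$prevalence["E11"]), 0.5)
  expect_equal(as.integer(sum(dm$presence[, "I10"] * dm$presence[, "E11"])), 1L)
})

test_that("degenerate matrices are rejected", {
  expect_error(build_matrix(list(records = data.frame(patient_id = character(0)),
                                 diagnoses = data.frame())),
               "empty cohort")
  recs <- data.frame(patient_id = c("p1", "p1"))
  dx <- data.frame(patient_id = "p1", icd_code = "I10",
                   stringsAsFactors = FALSE)
  expect_error(build_matrix(list(records = recs, diagnoses = dx)),
               "duplicate patient_id")
})

test_that("ingest is idempotent and order-independent, and counts are conserved", {
  cfg <- default_config(n_patients = 300)
  co <- generate_cohort(cfg, seed = 4)
  ic1 <- ingest_cohort(co$patients, co$diagnoses)

  # idempotence: re-ingesting the normalized tables changes nothing
  renorm <- ic1$diagnoses
  pats2 <- ic1$records[, c("patient_id", "age", "sex", "marital", "hei_total")]
  ic2 <- ingest_cohort(pats2, renorm)
  expect_identical(ic1$records, ic2$records)
  expect_identical(ic1$diagnoses, ic2$diagnoses)

  # order independence: shuffled input rows give the same matrix
  set.seed(1)
  shuf_p <- co$patients[sample(nrow(co$patients)), ]
  shuf_d <- co$diagnoses[sample(nrow(co$diagnoses)), ]
  ic3 <- ingest_cohort(shuf_p, shuf_d)
  dm1 <- build_matrix(ic1)
  ord <- match(dm1$patient_ids, build_matrix(ic3)$patient_ids)
  dm3 <- build_matrix(ic3)
  expect_identical(as.matrix(dm1$presence),
                   as.matrix(dm3$presence[ord, dm1$codes]))
  expect_equal(dm1$prevalence, dm3$prevalence[dm1$codes])

  # conservation: sum of multimorbidity counts = presence minus index presence
  dm_all <- build_matrix(ic1)
  total_presence <- sum(dm_all$presence)
  index_presence <- sum(dm_all$presence[, intersect(dm_all$codes,
                                                    ic1$index_codes)])
  expect_equal(sum(ic1$records$n_multimorbidity),
               total_presence - index_presence)
})
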