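test_that("pair statistics follow the O/E formulas on a worked example", {
  # 100 patients: A in 50, B in 40, both in 30
  X <- matrix(0L, 100, 2, dimnames = list(NULL, c("A01", "B01")))
  X[1:50, "A01"] <- 1L
  X[21:60, "B01"] <- 1L   # overlap 21..50 = 30
  dm <- dm_from_matrix(X)
  ps <- pair_stats(dm, "A01", "B01")
  expect_equal(ps$co_count, 30L)
  expect_equal(ps$observed, 0.30)
  expect_equal(ps$expected, 0.20)
  expect_equal(ps$rr, 1.5)
  # symmetry
  expect_identical(ps, pair_stats(dm, "B01", "A01"))
})

test_that("reference-scale arithmetic: hypertension-diabetes pair exceeds the edge criterion", {
  # printed prevalences 43.9% and 20.1%, 1,835 co-occurrences among 13,359
  O <- 1835 / 13359
  E <- 0.439 * 0.201
  expect_equal(round(O, 4), 0.1374)
  expect_equal(E, 0.0883, tolerance = 1e-3)
  expect_gt(O / E, 1.0)
  expect_equal(O / E, 1.56, tolerance = 0.01)
})

test_that("count form and prevalence form of RR agree to machine precision", {
  set.seed(7)
  X <- matrix(rbinom(600 * 10, 1, 0.3), 600, 10,
              dimnames = list(NULL, sprintf("A%02d", 1:10)))
  dm <- dm_from_matrix(X)
  ap <- all_pairs(dm)
  counts <- Matrix::colSums(dm$presence)
  rr_count_form <- (dm$n_patients * ap$co_count) /
    (counts[ap$code_a] * counts[ap$code_b])
  expect_equal(ap$rr, unname(rr_count_form), tolerance = 1e-12)
  expect_equal(ap$rr, ap$observed / ap$expected)
  # O <= min(prev_a, prev_b)
  expect_true(all(ap$observed <= pmin(dm$prevalence[ap$code_a],
                                      dm$prevalence[ap$code_b]) + 1e-15))
})

test_that("patient order never changes pair statistics", {
  set.seed(11)
  X <- matrix(rbinom(200 * 6, 1, 0.25), 200, 6,
              dimnames = list(NULL, sprintf("A%02d", 1:6)))
  ap1 <- all_pairs(dm_from_matrix(X))
  ap2 <- all_pairs(dm_from_matrix(X[sample(nrow(X)), , drop = FALSE]))
  expect_identical(ap1, ap2)
})

test_that("all-pairs matches the brute-force per-patient oracle exhaustively at small size", {
  # every binary matrix up to 4 patients x 3 diseases
  for (n in 1:4) {
    for (k in 2:3) {
      cells <- n * k
      for (bits in 0:(2^cells - 1)) {
        X <- matrix(as.integer(intToBits(bits))[seq_len(cells)], n, k)
        colnames(X) <- sprintf("A%02d", seq_len(k))
        if (all(colSums(X) == 0)) next
        dm <- dm_from_matrix(X)
        got <- all_pairs(dm)
        want <- brute_pairs(X[, colSums(X) > 0, drop = FALSE])
        expect_equal(got, want)
      }
    }
  }
})

test_that("all-pairs matches the oracle on random matrices, including 8x4 and 500x20", {
  set.seed(23)
  for (rep in 1:500) {
    X <- matrix(rbinom(32, 1, runif(1, 0.2, 0.8)), 8, 4,
                dimnames = list(NULL, sprintf("A%02d", 1:4)))
    if (all(colSums(X) == 0)) next
    expect_equal(all_pairs(dm_from_matrix(X)),
                 brute_pairs(X[, colSums(X) > 0, drop = FALSE]))
  }
  for (rep in 1:3) {
    X <- matrix(rbinom(500 * 20, 1, 0.15), 500, 20,
                dimnames = list(NULL, sprintf("A%02d", 1:20)))
    expect_equal(all_pairs(dm_from_matrix(X)), brute_pairs(X))
  }
})

test_that("codes never diagnosed appear in no pair; K diseases yield at most choose(K,2) pairs", {
  X <- cbind(A01 = c(1, 1, 0, 0), A02 = c(0, 1, 1, 0), A03 = c(0, 0, 0, 0),
             A04 = c(1, 0, 1, 0))
  dm <- dm_from_matrix(X)
  ap <- all_pairs(dm)
  expect_false("A03" %in% c(ap$code_a, ap$code_b))
  expect_lte(nrow(ap), choose(4, 2))
  expect_error(pair_stats(dm, "A01", "A01"), "distinct")
})

test_that("network construction applies prevalence and RR filters with degree after filtering", {
  pairs <- data.frame(
    code_a = c("A01", "A01", "A02", "B01"),
    code_b = c("A02", "A03", "A03", "B02"),
    co_count = c(50L, 40L, 30L, 20L),
    observed = c(0.05, 0.04, 0.03, 0.02),
    expected = c(0.02, 0.05, 0.04, 0.019),
    stringsAsFactors = FALSE)
  pairs$rr <- pairs$observed / pairs$expected
  prev <- c(A01 = 0.2, A02 = 0.15, A03 = 0.12, B01 = 0.005, B02 = 0.3)

  net <- build_network(pairs, prev)
  # rr > 1: rows 1 and 4; row 4 dropped because B01 fails the 1% node filter
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$code_a, "A01")
  expect_setequal(net$nodes$code, c("A01", "A02"))
  expect_equal(net$nodes$degree, c(1L, 1L))

  # raising the RR threshold never adds edges
  n_prev <- Inf
  for (thr in c(0, 1, 1.5, 2.5, 5)) {
    n_now <- nrow(suppressWarnings(
      build_network(pairs, prev, rr_threshold = thr,
                    node_threshold = 0))$edges)
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }

  # empty result returns an empty network with a warning
  expect_warning(empty <- build_network(pairs, prev, rr_threshold = Inf),
                 "empty")
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(empty$nodes), 0L)
})

test_that("edge report ranks by co-occurrence count, as in the reference hub analysis", {
  cfg <- default_config(n_patients = 8000)
  co <- generate_cohort(cfg, seed = 19)
  ic <- ingest_cohort(co$patients, co$diagnoses, quiet = TRUE)
  dm <- build_matrix(ic)
  net <- build_network(all_pairs(dm), dm$prevalence)
  expect_true(all(diff(net$edges$co_count) <= 0))
  # the two planted pairs carry the largest co-occurrence counts
  top2 <- net$edges[1:2, ]
  expect_setequal(paste(top2$code_a, top2$code_b),
                  c("E11 I10", "I10 I70"))
  # index codes are excluded from the node set
  expect_false(any(c("M80", "M81") %in% net$nodes$code))
})

test_that("CSAD pseudo-node associations rank planted diseases first", {
  # disease A02 with a strong planted CSAD effect
  cfg <- small_cfg(12000, c(0.44, 0.20, 0.15, 0.10),
                   csad_disease_betas = c(A02 = 1.5))
  co <- generate_cohort(cfg, seed = 29)
  ic <- ingest_cohort(co$patients, co$diagnoses, quiet = TRUE)
  dm <- build_matrix(ic)
  cn <- csad_network(dm, ic$records$csad, index_codes = "M81")
  expect_equal(cn$associations$code[which(cn$associations$rank == 1)], "A02")
  # oracle: CSAD-conditional prevalence of A02 clearly exceeds marginal
  present <- co$truth$present
  expect_gt(mean(present[co$truth$csad, "A02"]),
            1.3 * mean(present[, "A02"]))
  expect_true("CSAD" %in% cn$network$nodes$code)
  expect_true(all(cn$associations$rr[cn$associations$retained] > 1))
})

test_that("CSAD ranking ties break by RR then code", {
  # constructed: two diseases with identical CSAD co-occurrence counts
  n <- 40
  csad <- rep(c(TRUE, FALSE), each = n / 2)
  A01 <- as.integer(seq_len(n) <= 10 | seq_len(n) > 30)   # co = 10, count 20
  A02 <- as.integer(seq_len(n) <= 10)                     # co = 10, count 10
  A03 <- as.integer(seq_len(n) <= 10)                     # tie with A02
  X <- cbind(A01 = A01, A02 = A02, A03 = A03)
  dm <- dm_from_matrix(X)
  cn <- csad_network(dm, csad, index_codes = character(0))
  a <- cn$associations
  # same co_count everywhere; A02/A03 have higher rr (smaller marginal count)
  expect_equal(a$co_count, c(10L, 10L, 10L))
  expect_equal(a$code, c("A02", "A03", "A01"))  # rr desc, then code
  expect_error(csad_network(dm, rep(FALSE, n)), "zero CSAD")
})

test_that("igraph conversion preserves structure and attributes", {
  pairs <- data.frame(code_a = "A01", code_b = "A02", co_count = 12L,
                      observed = 0.12, expected = 0.06, rr = 2,
                      stringsAsFactors = FALSE)
  net <- build_network(pairs, c(A01 = 0.3, A02 = 0.2))
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 12)
  expect_equal(igraph::E(g)$rr, 2)
  expect_equal(sort(igraph::V(g)$prevalence), c(0.2, 0.3))
})
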