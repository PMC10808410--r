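#' Observed/expected relative risk for one disease pair
#'
#' For diseases A and B in a cohort of N patients: the observed pair
#' prevalence O is the fraction of patients carrying both; the expected
#' prevalence under independence is E = prevalence(A) * prevalence(B); the
#' relative risk is RR = O / E. Equivalently, RR = N * co_count /
#' (count_A * count_B). RR > 1 indicates positive association.
#'
#' @param matrix_ A `disease_matrix`.
#' @param a,b Distinct 3-character codes present in the matrix.
#' @return One-row data frame: code_a, code_b (lexicographic order),
#'   co_count, observed, expected, rr. Symmetric in (a, b).
#' @export
#' @examples
#' # 100 patients, A in 50, B in 40, both in 30 -> O=0.30, E=0.20, RR=1.5
pair_stats <- function(matrix_, a, b) {
  if (a == b) stop("pair_stats requires two distinct codes")
  if (!all(c(a, b) %in% matrix_$codes))
    stop("codes not in matrix: ",
         paste(setdiff(c(a, b), matrix_$codes), collapse = ", "))
  if (matrix_$prevalence[[a]] == 0 || matrix_$prevalence[[b]] == 0)
    stop("relative risk undefined: zero prevalence for ",
         paste(c(a, b)[c(matrix_$prevalence[[a]], matrix_$prevalence[[b]]) == 0],
               collapse = ", "))
  va <- matrix_$presence[, a]
  vb <- matrix_$presence[, b]
  co <- as.integer(sum(va * vb))
  n <- matrix_$n_patients
  observed <- co / n
  expected <- matrix_$prevalence[[a]] * matrix_$prevalence[[b]]
  ord <- order(c(a, b))
  data.frame(code_a = c(a, b)[ord][1], code_b = c(a, b)[ord][2],
             co_count = co, observed = observed, expected = expected,
             rr = observed / expected, stringsAsFactors = FALSE)
}

#' All-pairs relative-risk statistics
#'
#' Computes [pair_stats()] for every unordered pair of codes with at least
#' one co-occurring patient, via the cross-product of the presence matrix.
#' Output order is deterministic: lexicographic by (code_a, code_b).
#'
#' @param matrix_ A `disease_matrix` (nonempty).
#' @return Data frame with columns code_a, code_b, co_count, observed,
#'   expected, rr.
#' @export
all_pairs <- function(matrix_) {
  if (matrix_$n_patients == 0L || length(matrix_$codes) == 0L)
    stop("empty matrix")
  X <- matrix_$presence
  co <- as.matrix(Matrix::crossprod(X))
  n <- matrix_$n_patients
  idx <- which(upper.tri(co) & co > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(code_a = character(0), code_b = character(0),
                      co_count = integer(0), observed = numeric(0),
                      expected = numeric(0), rr = numeric(0),
                      stringsAsFactors = FALSE))
  }
  code_a <- matrix_$codes[idx[, 1]]
  code_b <- matrix_$codes[idx[, 2]]
  co_count <- as.integer(co[idx])
  observed <- co_count / n
  expected <- matrix_$prevalence[code_a] * matrix_$prevalence[code_b]
  res <- data.frame(code_a = code_a, code_b = code_b, co_count = co_count,
                    observed = observed, expected = unname(expected),
                    rr = observed / unname(expected),
                    stringsAsFactors = FALSE)
  res <- res[order(res$code_a, res$code_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the multimorbidity co-occurrence network
#'
#' Applies the reference analysis's inclusion rules: a disease enters the
#' node set if its cohort prevalence exceeds `node_threshold` (default
#' 1.0%) and it is not an index-disease code; an edge joins two retained
#' diseases when their relative risk exceeds `rr_threshold` (default 1.0,
#' the bare O/E criterion — no significance test, as in the reference
#' procedure; see `fisher_alpha` for an optional filter). Nodes are the
#' endpoints of surviving edges; node degree (the color attribute in the
#' reference maps) is computed after edge filtering, and node size carries
#' prevalence. Edge weight is the raw co-occurrence count, with RR stored
#' alongside.
#'
#' @param pairs Data frame from [all_pairs()] (or rows of [pair_stats()]).
#' @param prevalences Named prevalence vector (e.g. `matrix_$prevalence`).
#' @param n_patients Cohort size; required if `fisher_alpha` is set.
#' @param node_threshold Minimum cohort prevalence, exclusive (default 0.01).
#' @param rr_threshold Minimum relative risk, exclusive (default 1.0).
#' @param index_codes Codes excluded from the node set (the network is a
#'   network of multimorbidities); set `include_index = TRUE` to keep them.
#' @param include_index Keep index codes (sensitivity analysis).
#' @param fisher_alpha Optional: additionally require a one-sided Fisher
#'   exact test of co-occurrence enrichment at this alpha (off by default;
#'   the reference criterion is the bare RR > 1).
#' @return An object of class `comorbidity_network`: list with `nodes`
#'   (data frame: code, prevalence, degree), `edges` (data frame: code_a,
#'   code_b, co_count, rr), and `thresholds`. Empty networks are returned
#'   with a warning.
#' @export
build_network <- function(pairs, prevalences, n_patients = NULL,
                          node_threshold = 0.01, rr_threshold = 1.0,
                          index_codes = c("M80", "M81"),
                          include_index = FALSE, fisher_alpha = NULL) {
  stopifnot(node_threshold >= 0, node_threshold < 1, rr_threshold >= 0)
  keep_codes <- names(prevalences)[prevalences > node_threshold]
  if (!include_index) keep_codes <- setdiff(keep_codes, index_codes)
  e <- pairs[pairs$code_a %in% keep_codes & pairs$code_b %in% keep_codes &
               pairs$rr > rr_threshold, , drop = FALSE]
  if (!is.null(fisher_alpha)) {
    if (is.null(n_patients)) stop("n_patients required for the Fisher filter")
    pvals <- vapply(seq_len(nrow(e)), function(i) {
      ca <- round(prevalences[[e$code_a[i]]] * n_patients)
      cb <- round(prevalences[[e$code_b[i]]] * n_patients)
      co <- e$co_count[i]
      tab <- matrix(c(co, ca - co, cb - co, n_patients - ca - cb + co), 2)
      stats::fisher.test(tab, alternative = "greater")$p.value
    }, numeric(1))
    e <- e[pvals < fisher_alpha, , drop = FALSE]
  }
  node_codes <- sort(unique(c(e$code_a, e$code_b)))
  deg <- table(factor(c(e$code_a, e$code_b), levels = node_codes))
  nodes <- data.frame(code = node_codes,
                      prevalence = unname(prevalences[node_codes]),
                      degree = as.integer(deg),
                      stringsAsFactors = FALSE)
  e <- e[order(-e$co_count, -e$rr, e$code_a, e$code_b),
         c("code_a", "code_b", "co_count", "rr"), drop = FALSE]
  rownames(e) <- NULL
  if (nrow(e) == 0L) warning("no edges survive the filters; empty network")
  structure(list(nodes = nodes, edges = e,
                 thresholds = list(node = node_threshold, rr = rr_threshold,
                                   fisher_alpha = fisher_alpha)),
            class = "comorbidity_network")
}

#' Highest-degree nodes (network hubs)
#'
#' @param network A `comorbidity_network`.
#' @param k Number of hubs to report.
#' @return Data frame of the top-`k` nodes by degree (ties by prevalence
#'   then code).
#' @export
hubs <- function(network, k = 5L) {
  nd <- network$nodes
  nd <- nd[order(-nd$degree, -nd$prevalence, nd$code), , drop = FALSE]
  utils::head(nd, k)
}

#' Disease associations with emotional distress (CSAD network)
#'
#' Treats CSAD as a pseudo-disease: a binary column whose prevalence is the
#' cohort CSAD rate, run through the same pair-statistic machinery against
#' every disease. Diseases whose relative risk with CSAD exceeds
#' `rr_threshold` are retained and ranked by co-occurrence count
#' (descending), ties broken by RR then code; the top `k` (the reference
#' map shows eight) form the CSAD network together with the inter-disease
#' edges that pass the same thresholds.
#'
#' @param matrix_ A `disease_matrix` built on the HEI-screened subcohort.
#' @param csad_flags Logical vector aligned with `matrix_$patient_ids`; no
#'   missing values.
#' @param node_threshold,rr_threshold As in [build_network()].
#' @param index_codes Index codes excluded from the disease set.
#' @param top_k Number of top-ranked diseases to include in the network.
#' @param include_disease_edges Also include edges among the retained
#'   diseases (default TRUE).
#' @return List of class `csad_network`: `associations` (data frame of all
#'   evaluated diseases: code, co_count, observed, expected, rr, retained,
#'   rank — rank only among retained), and `network` (a
#'   `comorbidity_network` whose nodes include the pseudo-code `"CSAD"`).
#' @export
csad_network <- function(matrix_, csad_flags,
                         node_threshold = 0.01, rr_threshold = 1.0,
                         index_codes = c("M80", "M81"), top_k = 8L,
                         include_disease_edges = TRUE) {
  if (length(csad_flags) != matrix_$n_patients)
    stop("csad_flags must align with the matrix's patients")
  if (anyNA(csad_flags))
    stop("csad_flags contain missing values; build the matrix on the HEI-screened subcohort")
  if (!any(csad_flags)) stop("zero CSAD patients; association undefined")

  n <- matrix_$n_patients
  p_csad <- mean(csad_flags)
  codes <- setdiff(matrix_$codes[matrix_$prevalence > 0], index_codes)
  co <- as.integer(as.vector(Matrix::crossprod(matrix_$presence[, codes, drop = FALSE],
                                               as.numeric(csad_flags))))
  observed <- co / n
  expected <- unname(matrix_$prevalence[codes]) * p_csad
  assoc <- data.frame(code = codes, co_count = co, observed = observed,
                      expected = expected, rr = observed / expected,
                      stringsAsFactors = FALSE)
  assoc$retained <- assoc$rr > rr_threshold &
    unname(matrix_$prevalence[codes]) > node_threshold
  ord <- order(-assoc$co_count, -assoc$rr, assoc$code)
  assoc <- assoc[ord, , drop = FALSE]
  assoc$rank <- NA_integer_
  assoc$rank[assoc$retained] <- seq_len(sum(assoc$retained))
  rownames(assoc) <- NULL

  top <- assoc$code[assoc$retained & assoc$rank <= top_k]
  prevs <- c(matrix_$prevalence, CSAD = p_csad)
  csad_edges <- data.frame(
    code_a = rep("CSAD", length(top)), code_b = top,
    co_count = assoc$co_count[match(top, assoc$code)],
    observed = assoc$observed[match(top, assoc$code)],
    expected = assoc$expected[match(top, assoc$code)],
    rr = assoc$rr[match(top, assoc$code)],
    stringsAsFactors = FALSE
  )
  pairs <- csad_edges
  if (include_disease_edges && length(top) > 1L) {
    sub <- list(presence = matrix_$presence[, top, drop = FALSE],
                codes = top, patient_ids = matrix_$patient_ids,
                n_patients = n, prevalence = matrix_$prevalence[top])
    class(sub) <- "disease_matrix"
    dpairs <- all_pairs(sub)
    pairs <- rbind(pairs, dpairs)
  }
  net <- build_network(pairs, prevs, n_patients = n,
                       node_threshold = node_threshold,
                       rr_threshold = rr_threshold,
                       index_codes = index_codes)
  structure(list(associations = assoc, network = net, top_k = top_k),
            class = "csad_network")
}

#' Convert a comorbidity network to an igraph object
#'
#' @param network A `comorbidity_network`.
#' @return An undirected `igraph` graph with vertex attributes `prevalence`
#'   and `degree`, and edge attributes `weight` (co-occurrence count) and
#'   `rr`.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$code_a, to = network$edges$code_b,
                   weight = network$edges$co_count, rr = network$edges$rr,
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$nodes$code,
                          prevalence = network$nodes$prevalence,
                          degree = network$nodes$degree,
                          stringsAsFactors = FALSE)
  )
  g
}

#' @exportS3Method base::print
print.comorbidity_network <- function(x, ...) {
  cat("<comorbidity_network>", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (prevalence >", x$thresholds$node,
      ", RR >", x$thresholds$rr, ")\n")
  invisible(x)
}

#' @exportS3Method base::print
print.csad_network <- function(x, ...) {
  cat("<csad_network>", sum(x$associations$retained),
      "diseases associated with CSAD; top", x$top_k, "in network\n")
  invisible(x)
}
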