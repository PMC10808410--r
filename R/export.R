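fmt_num <- function(x) {
  # enough digits for lossless double round-trips
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

#' Write a comorbidity network as GEXF 1.3
#'
#' GEXF is the native exchange format of Gephi, the tool used to draw the
#' reference network maps. The graph is written undirected with node
#' attributes `prevalence` (double) and `degree` (integer), the edge
#' `weight` set to the co-occurrence count, and an edge attribute `rr`
#' (double) carrying the relative risk. Numeric attributes are serialized
#' with full double precision so a read-back reproduces the network
#' exactly.
#'
#' @param network A `comorbidity_network`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gexf <- function(network, path) {
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://gexf.net/1.3", version = "1.3")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  nattrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(nattrs, "attribute", id = "prevalence",
                      title = "prevalence", type = "double")
  xml2::xml_add_child(nattrs, "attribute", id = "degree",
                      title = "degree", type = "integer")
  eattrs <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(eattrs, "attribute", id = "rr",
                      title = "rr", type = "double")

  nodes <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(network$nodes))) {
    nd <- xml2::xml_add_child(nodes, "node",
                              id = network$nodes$code[i],
                              label = network$nodes$code[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "prevalence",
                        value = fmt_num(network$nodes$prevalence[i]))
    xml2::xml_add_child(av, "attvalue", `for` = "degree",
                        value = as.character(network$nodes$degree[i]))
  }
  edges <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(network$edges))) {
    ed <- xml2::xml_add_child(edges, "edge",
                              id = as.character(i - 1L),
                              source = network$edges$code_a[i],
                              target = network$edges$code_b[i],
                              weight = as.character(network$edges$co_count[i]))
    av <- xml2::xml_add_child(ed, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "rr",
                        value = fmt_num(network$edges$rr[i]))
  }
  tryCatch(xml2::write_xml(doc, path),
           error = function(e) stop("cannot write GEXF to '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a GEXF file back into a comorbidity network
#'
#' Inverse of [write_gexf()]; used for round-trip verification and to
#' re-import Gephi-edited graphs.
#'
#' @param path GEXF file path.
#' @return A `comorbidity_network` (thresholds unknown, recorded as NA).
#' @export
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = xml2::xml_ns(doc)[[1]])
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  get_att <- function(el, id) {
    v <- xml2::xml_find_first(
      el, sprintf(".//g:attvalue[@for='%s']", id), ns)
    xml2::xml_attr(v, "value")
  }
  nodes <- data.frame(
    code = xml2::xml_attr(node_els, "id"),
    prevalence = as.numeric(vapply(node_els, get_att, "", id = "prevalence")),
    degree = as.integer(vapply(node_els, get_att, "", id = "degree")),
    stringsAsFactors = FALSE
  )
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- data.frame(
    code_a = xml2::xml_attr(edge_els, "source"),
    code_b = xml2::xml_attr(edge_els, "target"),
    co_count = as.integer(xml2::xml_attr(edge_els, "weight")),
    rr = as.numeric(vapply(edge_els, get_att, "", id = "rr")),
    stringsAsFactors = FALSE
  )
  if (nrow(nodes) == 0L)
    nodes <- data.frame(code = character(0), prevalence = numeric(0),
                        degree = integer(0), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(node = NA_real_, rr = NA_real_,
                                   fisher_alpha = NULL)),
            class = "comorbidity_network")
}

#' Write a comorbidity network as GraphML
#'
#' Same contract as [write_gexf()] in the general-purpose GraphML format
#' (readable by igraph, NetworkX, Cytoscape, yEd). Written by hand with
#' full-precision numeric attributes; [read_graphml()] reads it back, and
#' the file is also readable by `igraph::read_graph(format = "graphml")`.
#'
#' @param network A `comorbidity_network`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(network, path) {
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  key <- function(id, dom, type) {
    xml2::xml_add_child(doc, "key", id = id, `for` = dom,
                        `attr.name` = id, `attr.type` = type)
  }
  key("prevalence", "node", "double")
  key("degree", "node", "int")
  key("weight", "edge", "int")
  key("rr", "edge", "double")
  graph <- xml2::xml_add_child(doc, "graph", id = "comorbidity",
                               edgedefault = "undirected")
  for (i in seq_len(nrow(network$nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = network$nodes$code[i])
    d1 <- xml2::xml_add_child(nd, "data", key = "prevalence")
    xml2::xml_text(d1) <- fmt_num(network$nodes$prevalence[i])
    d2 <- xml2::xml_add_child(nd, "data", key = "degree")
    xml2::xml_text(d2) <- as.character(network$nodes$degree[i])
  }
  for (i in seq_len(nrow(network$edges))) {
    ed <- xml2::xml_add_child(graph, "edge",
                              source = network$edges$code_a[i],
                              target = network$edges$code_b[i])
    d1 <- xml2::xml_add_child(ed, "data", key = "weight")
    xml2::xml_text(d1) <- as.character(network$edges$co_count[i])
    d2 <- xml2::xml_add_child(ed, "data", key = "rr")
    xml2::xml_text(d2) <- fmt_num(network$edges$rr[i])
  }
  tryCatch(xml2::write_xml(doc, path),
           error = function(e) stop("cannot write GraphML to '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = xml2::xml_ns(doc)[[1]])
  get_data <- function(el, id) {
    xml2::xml_text(xml2::xml_find_first(
      el, sprintf("./g:data[@key='%s']", id), ns))
  }
  node_els <- xml2::xml_find_all(doc, ".//g:graph/g:node", ns)
  nodes <- data.frame(
    code = xml2::xml_attr(node_els, "id"),
    prevalence = as.numeric(vapply(node_els, get_data, "", id = "prevalence")),
    degree = as.integer(vapply(node_els, get_data, "", id = "degree")),
    stringsAsFactors = FALSE
  )
  if (nrow(nodes) == 0L)
    nodes <- data.frame(code = character(0), prevalence = numeric(0),
                        degree = integer(0), stringsAsFactors = FALSE)
  edge_els <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  edges <- data.frame(
    code_a = xml2::xml_attr(edge_els, "source"),
    code_b = xml2::xml_attr(edge_els, "target"),
    co_count = as.integer(vapply(edge_els, get_data, "", id = "weight")),
    rr = as.numeric(vapply(edge_els, get_data, "", id = "rr")),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(node = NA_real_, rr = NA_real_,
                                   fisher_alpha = NULL)),
            class = "comorbidity_network")
}

#' Run the whole analysis pipeline
#'
#' Executes, in order: cohort simulation (or ingestion of supplied files),
#' descriptive tables, the CSAD logistic risk models, all-pairs relative
#' risks, construction of the multimorbidity and CSAD networks, and export
#' of every artifact (CSV tables, GEXF and GraphML graphs) plus a run
#' manifest recording the configuration, seed, thresholds, rejection counts
#' and versions. Identical inputs and configuration produce a byte-identical
#' bundle.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [cohort_config()]; used only when no input files are
#'   given. Default [default_config()].
#' @param seed Seed for the simulated cohort.
#' @param patients_path,diagnoses_path Optional paths to an existing cohort
#'   in the two-file interchange format; when given, simulation is skipped.
#' @param node_threshold,rr_threshold Network inclusion thresholds (cohort
#'   prevalence > 1% and RR > 1 by default, the reference criteria).
#' @param top_k Number of top CSAD-associated diseases reported/exported.
#' @param min_prevalence Filter for the prevalence table (default 0.10).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of class `export_bundle`: the cohort, tables,
#'   fits, pair statistics, both networks, the manifest, and `paths` to all
#'   written files.
#' @export
run_pipeline <- function(out_dir, config = default_config(), seed = config$seed,
                         patients_path = NULL, diagnoses_path = NULL,
                         node_threshold = 0.01, rr_threshold = 1.0,
                         top_k = 8L, min_prevalence = 0.10, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[comorbnet] ", ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  simulated <- is.null(patients_path)
  if (simulated) {
    say("simulating cohort (n = ", config$n_patients, ", seed = ", seed, ")")
    cohort_sim <- step("simulate", generate_cohort(config, seed = seed))
    paths <- write_cohort(cohort_sim, file.path(out_dir, "cohort"))
    patients_path <- paths[["patients"]]
    diagnoses_path <- paths[["diagnoses"]]
  }
  say("ingesting ", patients_path)
  cohort <- step("ingest",
                 read_cohort(patients_path, diagnoses_path, quiet = quiet))
  dm <- step("matrix", build_matrix(cohort))

  say("descriptive tables")
  t1 <- step("table_one", table_one(cohort))
  t2 <- step("prevalence_table",
             prevalence_table(dm, cohort, min_prevalence = min_prevalence))
  say("logistic risk models")
  t3 <- step("table_three", table_three(cohort))

  say("pair statistics and networks")
  hei_ok <- !is.na(cohort$records$hei_total)
  pairs <- step("all_pairs", all_pairs(dm))
  net <- step("build_network",
              build_network(pairs, dm$prevalence, n_patients = dm$n_patients,
                            node_threshold = node_threshold,
                            rr_threshold = rr_threshold,
                            index_codes = cohort$index_codes))
  sub_cohort <- list(records = cohort$records[hei_ok, , drop = FALSE],
                     diagnoses = cohort$diagnoses[
                       cohort$diagnoses$patient_id %in%
                         cohort$records$patient_id[hei_ok], , drop = FALSE],
                     index_codes = cohort$index_codes)
  dm_hei <- step("matrix_hei", build_matrix(sub_cohort))
  cnet <- step("csad_network",
               csad_network(dm_hei, sub_cohort$records$csad,
                            node_threshold = node_threshold,
                            rr_threshold = rr_threshold,
                            index_codes = cohort$index_codes,
                            top_k = top_k))

  say("writing bundle to ", out_dir)
  p <- list()
  p$table_one <- write_table(t1, file.path(out_dir, "table_one"))
  p$table_two <- write_table(t2, file.path(out_dir, "table_two"))
  p$table_three <- write_table(t3$summary, file.path(out_dir, "table_three"))
  p$edges <- file.path(out_dir, "pair_stats.csv")
  write.csv(pairs, p$edges, row.names = FALSE, fileEncoding = "UTF-8")
  p$csad_assoc <- file.path(out_dir, "csad_associations.csv")
  write.csv(cnet$associations, p$csad_assoc, row.names = FALSE,
            fileEncoding = "UTF-8")
  p$gexf <- write_gexf(net, file.path(out_dir, "multimorbidity_network.gexf"))
  p$graphml <- write_graphml(net, file.path(out_dir, "multimorbidity_network.graphml"))
  p$csad_gexf <- write_gexf(cnet$network, file.path(out_dir, "csad_network.gexf"))
  p$csad_graphml <- write_graphml(cnet$network, file.path(out_dir, "csad_network.graphml"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("comorbnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(seed),
    simulated = simulated,
    n_patients = nrow(cohort$records),
    n_hei = sum(hei_ok),
    n_rejected_rows = nrow(cohort$rejected),
    thresholds = list(node_prevalence = node_threshold, rr = rr_threshold,
                      min_prevalence_table = min_prevalence, top_k = top_k),
    index_codes = cohort$index_codes,
    network = list(nodes = nrow(net$nodes), edges = nrow(net$edges)),
    csad_network = list(nodes = nrow(cnet$network$nodes),
                        edges = nrow(cnet$network$edges),
                        retained = sum(cnet$associations$retained))
  )
  p$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(structure(
    list(cohort = cohort, matrix = dm, table_one = t1, table_two = t2,
         table_three = t3, pairs = pairs, network = net, csad = cnet,
         manifest = manifest, paths = p),
    class = "export_bundle"))
}

#' @exportS3Method base::print
print.export_bundle <- function(x, ...) {
  cat("<export_bundle>\n")
  cat("  patients:", x$manifest$n_patients,
      "| HEI-screened:", x$manifest$n_hei, "\n")
  cat("  network:", x$manifest$network$nodes, "nodes,",
      x$manifest$network$edges, "edges\n")
  cat("  CSAD network:", x$manifest$csad_network$nodes, "nodes,",
      x$manifest$csad_network$edges, "edges\n")
  invisible(x)
}
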