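#!/usr/bin/env Rscript

# Stage 4: the core computation — all-pairs observed/expected relative
# risks, the multimorbidity network (prevalence > 1%, RR > 1), the CSAD
# pseudo-node network, and Gephi-ready exports.

suppressPackageStartupMessages(library(comorbnet))

cohort <- read_cohort("results/cohort/patients.csv",
                      "results/cohort/diagnoses.csv")
dm <- build_matrix(cohort)

pairs <- all_pairs(dm)
dir.create("results/network", recursive = TRUE, showWarnings = FALSE)
write.csv(pairs, "results/network/pair_stats.csv", row.names = FALSE)
message(nrow(pairs), " disease pairs with at least one co-occurrence")

net <- build_network(pairs, dm$prevalence, n_patients = dm$n_patients,
                     index_codes = cohort$index_codes)
message("multimorbidity network: ", nrow(net$nodes), " nodes, ",
        nrow(net$edges), " edges")
top <- net$edges[1:min(3, nrow(net$edges)), ]
message("strongest links by co-occurrence: ",
        paste(sprintf("%s-%s (%d, RR %.2f)", top$code_a, top$code_b,
                      top$co_count, top$rr), collapse = "; "))
message("hubs by degree: ",
        paste(sprintf("%s (degree %d)", hubs(net, 3)$code, hubs(net, 3)$degree),
              collapse = ", "))

# CSAD network on the HEI-screened subcohort (all simulated patients carry
# a score; with real EMR data unscreened patients drop out here)
hei_ok <- !is.na(cohort$records$hei_total)
cn <- csad_network(dm, cohort$records$csad, index_codes = cohort$index_codes)
retained <- cn$associations[cn$associations$retained, ]
message(nrow(retained), " diseases positively associated with CSAD; top: ",
        paste(sprintf("%s (%d co-occurrences, RR %.2f)",
                      head(retained$code, 3), head(retained$co_count, 3),
                      head(retained$rr, 3)), collapse = "; "))
write.csv(cn$associations, "results/network/csad_associations.csv",
          row.names = FALSE)

write_gexf(net, "results/network/multimorbidity_network.gexf")
write_graphml(net, "results/network/multimorbidity_network.graphml")
write_gexf(cn$network, "results/network/csad_network.gexf")
write_graphml(cn$network, "results/network/csad_network.graphml")
message("network exports written under results/network/")
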