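#!/usr/bin/env Rscript
# Stage 3: estimate per-sample circuit activities by propagating the
# unit-scaled expression through every circuit subgraph.

suppressMessages(library(mechmap))

graphs <- read_pathway_dir("results/data/pathways")
expr <- read_matrix_tsv("results/data/expression.tsv")
truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)
map <- build_disease_map(graphs, gene_records(truth$core_genes,
                                              truth$core_genes))
act <- circuit_activities(map, expr)
write_matrix_tsv(act, "results/activities.tsv", id_col = "circuit_id")
cat(sprintf("activities: %d circuits x %d samples, range [%.3f, %.3f]\n",
            nrow(act), ncol(act), min(act), max(act)))
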