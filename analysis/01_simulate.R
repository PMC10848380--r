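#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study under the reference conditions
# (20 circuits across 5 pathways, 50 drug-target genes with 5 planted
# causal targets per circuit, 400 samples, activity noise 0.05) and
# write the raw inputs other stages read.

suppressMessages(library(mechmap))
seed <- 1
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_dataset(cfg)

write_pathway_dir(sim$paths$graphs, "results/data/pathways")
write_matrix_tsv(sim$expr, "results/data/expression.tsv", id_col = "gene_id",
                 header = sprintf("synthetic expression; seed=%d", seed))
utils::write.table(sim$paths$hallmark_table,
                   "results/data/hallmarks.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(sim$drugs, "results/data/drug_targets.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(entrez_id = names(sim$dysregulation),
                              direction = unname(sim$dysregulation)),
                   "results/data/dysregulation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
jsonlite::write_json(sim$manifest, "results/data/ground_truth.json",
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("simulated %d genes x %d samples; %d circuits over %d pathways\n",
            nrow(sim$expr), ncol(sim$expr), length(sim$map$circuits),
            length(sim$paths$graphs)))
cat(sprintf("planted %d causal target genes, %d decoys\n",
            length(sim$manifest$causal_targets),
            length(sim$manifest$decoy_targets)))
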