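#!/usr/bin/env Rscript
# Stage 5: post-process the relevance results into target clusters
# (gap-statistic k over hierarchical clustering), drug-category
# enrichment (Fisher/BH over ATC levels), reversal-filtered drug
# candidates and hallmark coverage profiles.

suppressMessages(library(mechmap))
seed <- 1

rel <- read_matrix_tsv("results/relevance.tsv")
sel <- read_matrix_tsv("results/selection.tsv") > 0
metrics <- utils::read.delim("results/metrics.tsv")
drugs <- read_drug_table("results/data/drug_targets.tsv")
truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)
hall_tab <- utils::read.delim("results/data/hallmarks.tsv")
hallmarks <- split(hall_tab$hallmark, hall_tab$circuit_id)

sel_targets <- colnames(sel)[colSums(sel) > 0]
prof <- t(rescale_relevance(rel))[sel_targets, , drop = FALSE]
k <- gap_statistic_k(prof, k_max = max(1, min(6, nrow(prof) - 1)),
                     seed = seed)
clusters <- cluster_targets(prof, k)
utils::write.table(clusters, "results/clusters.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("gap statistic chose k = %d; cluster sizes: %s\n", k,
            paste(sort(table(clusters$cluster), decreasing = TRUE),
                  collapse = "/")))

atc_map <- split(drugs$atc, drugs$drug_id)
rel_drugs <- unique(drugs$drug_id[drugs$entrez_id %in% sel_targets])
enr <- overrepresentation(rel_drugs, unique(drugs$drug_id), atc_map)
utils::write.table(enr, "results/enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
top <- enr[which.min(enr$p), ]
cat(sprintf("top enriched drug category: %s (level %d, p = %.2g, fdr = %.2g)\n",
            top$category, top$level, top$p, top$fdr))
cat(sprintf("planted enriched class was: %s\n", truth$enriched_level1))

dys_tab <- utils::read.delim("results/data/dysregulation.tsv",
                             colClasses = "character")
dys <- stats::setNames(dys_tab$direction, dys_tab$entrez_id)
rev <- filter_reversal_drugs(drugs, dys, sel_targets)
utils::write.table(rev, "results/reversal_candidates.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("reversal-filtered drug-target candidates: %d rows, %d drugs\n",
            nrow(rev), length(unique(rev$drug_id))))

shared <- hallmark_shared_influence(sel, rel, hallmarks)
write_matrix_tsv(round(shared, 10), "results/shared_influence.tsv",
                 id_col = "hallmark")
cat("wrote clusters, enrichment, reversal candidates, shared influence\n")
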