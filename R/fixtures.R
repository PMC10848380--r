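#' Path to a packaged data file
#'
#' @param file file name under the package's `extdata/`.
#' @return absolute path.
#' @export
mechmap_extdata <- function(file) {
  p <- system.file("extdata", file, package = "mechmap", mustWork = FALSE)
  if (!nzchar(p)) stop("no packaged file: ", file)
  p
}

#' Load a disease gene table
#'
#' Reads a TSV with columns `entrez_id` and `symbol` (a `disease_id`
#' column is carried through when present), deduplicates by `entrez_id`
#' and reports skipped malformed rows. The packaged
#' `rp_core_genes.tsv` is the curated OMIM/ORPHA retinitis pigmentosa
#' core gene list (93 genes).
#'
#' @param path TSV path.
#' @param source label recorded on the records (default `"core"`).
#' @return a [gene_records] data frame.
#' @export
load_gene_table <- function(path, source = "core") {
  df <- utils::read.delim(path, colClasses = "character", comment.char = "#")
  if (nrow(df) == 0) stop("empty gene table: ", path)
  miss <- setdiff(c("entrez_id", "symbol"), names(df))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  ok <- grepl("^[0-9]+$", df$entrez_id) & nzchar(df$symbol)
  if (any(!ok))
    message("skipping ", sum(!ok), " malformed gene row(s)")
  df <- df[ok, , drop = FALSE]
  dup <- duplicated(df$entrez_id)
  if (any(dup)) message("dropping ", sum(dup), " duplicated gene row(s)")
  df <- df[!dup, , drop = FALSE]
  out <- gene_records(df$entrez_id, df$symbol, source = source)
  if ("disease_id" %in% names(df)) out$disease_id <- df$disease_id
  out
}

#' Packaged retinitis pigmentosa reference tables
#'
#' Convenience loaders for the transcribed reference tables shipped with
#' the package: the curated core gene list, the disease-associated
#' phenotype terms with their specificity levels, the signaling pathways
#' of the disease map with their mapped disease genes, the combined
#' core-plus-amplified map gene list, the drug candidates targeting the
#' experimentally assessed targets, and the observed dysregulation
#' directions in the rd10 disease model.
#'
#' @return data frames mirroring the TSV layouts.
#' @name rp_tables
NULL

#' @rdname rp_tables
#' @export
rp_core_gene_table <- function()
  load_gene_table(mechmap_extdata("rp_core_genes.tsv"))

#' @rdname rp_tables
#' @export
rp_hpo_term_table <- function() {
  df <- utils::read.delim(mechmap_extdata("rp_hpo_terms.tsv"),
                          comment.char = "#")
  df$specificity <- as.integer(df$specificity)
  df
}

#' @rdname rp_tables
#' @export
rp_pathway_table <- function()
  utils::read.delim(mechmap_extdata("rp_pathways.tsv"), comment.char = "#",
                    colClasses = "character")

#' @rdname rp_tables
#' @export
rp_map_gene_table <- function() {
  df <- utils::read.delim(mechmap_extdata("rp_map_genes.tsv"),
                          colClasses = "character", comment.char = "#")
  df
}

#' @rdname rp_tables
#' @export
rp_reversal_drug_table <- function()
  utils::read.delim(mechmap_extdata("rp_reversal_drugs.tsv"),
                    colClasses = "character", comment.char = "#")

#' @rdname rp_tables
#' @export
rd10_dysregulation_table <- function() {
  df <- utils::read.delim(mechmap_extdata("rd10_dysregulation.tsv"),
                          colClasses = "character", comment.char = "#")
  stats::setNames(df$direction, df$entrez_id)
}

#' Synthetic stand-in for a parsed approved-drug interaction database
#'
#' Deterministically constructs a synthetic drug-target table at the
#' scale of a parsed DrugBank 5.1.8 export restricted to approved drugs
#' with known pharmacological action: 2688 drug-target pairs over 1410
#' drugs and 711 targets, with the five simplified effect classes
#' populated at the reference proportions (841 activator, 1530
#' inhibitor, 24 modulator, 192 ligand, 101 other rows). A designated
#' set of 109 relevant targets is reachable from exactly 284 drugs, and
#' those drugs are preferentially assigned the nervous-system ATC class
#' (`N`), planting a known over-represented category. The object is
#' synthetic: row-level content carries no real pharmacology and only
#' the marginal structure is meaningful.
#'
#' @param seed integer seed for the shuffles (default 1).
#' @return list with `drugs` (drug-target data frame), `relevant_targets`
#'   (109 ids), `relevant_drugs` (284 ids), `effect_counts`.
#' @export
synthetic_drugbank_standin <- function(seed = 1) {
  with_seed(seed + 505L, {
    n_pairs <- 2688L; n_drugs <- 1410L; n_targets <- 711L
    n_rel_t <- 109L; n_rel_d <- 284L
    drug_ids <- sprintf("SDB%05d", seq_len(n_drugs))
    target_ids <- sprintf("6%04d", seq_len(n_targets))
    rel_t <- target_ids[seq_len(n_rel_t)]
    rel_d <- drug_ids[seq_len(n_rel_d)]
    # relevant block: the 284 relevant drugs cycle over the 109 targets
    j <- seq_len(n_rel_d)
    block1 <- data.frame(drug_id = rel_d,
                         entrez_id = rel_t[(j - 1L) %% n_rel_t + 1L],
                         stringsAsFactors = FALSE)
    # remaining pairs never touch a relevant target
    rest_d <- drug_ids[-seq_len(n_rel_d)]
    rest_t <- target_ids[-seq_len(n_rel_t)]
    j <- seq_len(n_pairs - n_rel_d)
    block2 <- data.frame(drug_id = rest_d[(j - 1L) %% length(rest_d) + 1L],
                         entrez_id = rest_t[(j - 1L) %% length(rest_t) + 1L],
                         stringsAsFactors = FALSE)
    drugs <- rbind(block1, block2)
    actions <- c(rep("Agonist", 841L), rep("Inhibitor", 1530L),
                 rep("Modulator", 24L), rep("Ligand", 192L),
                 rep("Chelator", 101L))
    drugs$action <- sample(actions)
    drugs$effect <- simplify_action(drugs$action)
    drugs$drug_name <- sub("^SDB", "synthetic drug ", drugs$drug_id)
    drugs$approved <- "true"; drugs$known_action <- "true"
    atc_l1 <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N",
                "P", "R", "S", "V")
    per_drug_l1 <- ifelse(drug_ids %in% rel_d & stats::runif(n_drugs) < 0.8,
                          "N", sample(atc_l1, n_drugs, replace = TRUE))
    atc <- paste0(per_drug_l1, sprintf("%02d", sample(1:14, n_drugs, TRUE)),
                  sample(LETTERS[1:6], n_drugs, TRUE),
                  sample(LETTERS[1:6], n_drugs, TRUE))
    drugs$atc <- stats::setNames(atc, drug_ids)[drugs$drug_id]
    list(drugs = drugs, relevant_targets = rel_t, relevant_drugs = rel_d,
         effect_counts = c(activator = 841L, inhibitor = 1530L,
                           modulator = 24L, ligand = 192L, other = 101L))
  })
}

#' Synthetic stand-in for fitted-model summary tables
#'
#' Deterministically constructs synthetic per-circuit model metrics and a
#' selection matrix at the scale of the reference disease-map fit: 226
#' circuits of which 207 exceed the 0.4 stability threshold, a boolean
#' circuit-by-target selection matrix whose selected targets are exactly
#' the 109 relevant stand-in targets, and a relevance-profile matrix for
#' those targets built from three separated prototypes of sizes 4, 15
#' and 90 (the cluster structure recovered by hierarchical clustering at
#' k = 3). All values are synthetic; only the marginal structure is
#' meaningful.
#'
#' @param seed integer seed (default 1).
#' @return list with `metrics` (circuit_id, r2_low, r2_high, stability),
#'   `selection` (logical matrix), `profiles` (109-target score matrix),
#'   `cluster_sizes`.
#' @export
synthetic_model_standin <- function(seed = 1) {
  with_seed(seed + 606L, {
    n_circ <- 226L; n_stable <- 207L
    circ_ids <- sprintf("synpath:%03d", seq_len(n_circ))
    stability <- c(stats::runif(n_stable, 0.45, 0.95),
                   stats::runif(n_circ - n_stable, -0.1, 0.35))
    stability <- sample(stability)
    r2_low <- ifelse(stability > 0.4, stats::runif(n_circ, 0.05, 0.5),
                     stats::runif(n_circ, -0.4, 0))
    metrics <- data.frame(circuit_id = circ_ids, r2_low = r2_low,
                          r2_high = r2_low + stats::runif(n_circ, 0.1, 0.3),
                          stability = stability, stringsAsFactors = FALSE)
    db <- synthetic_drugbank_standin(seed)
    targets <- sprintf("6%04d", seq_len(711L))
    stable_ids <- circ_ids[stability > 0.4]
    selection <- matrix(FALSE, length(stable_ids), length(targets),
                        dimnames = list(stable_ids, targets))
    for (t in db$relevant_targets)
      selection[sample(length(stable_ids), sample(3:12, 1)), t] <- TRUE
    sizes <- c(4L, 15L, 90L)
    proto <- matrix(stats::rnorm(3 * 20, mean = c(-6, 0, 6)), 3, 20)
    profiles <- proto[rep(1:3, sizes), ] +
      matrix(stats::rnorm(sum(sizes) * 20, sd = 0.3), sum(sizes), 20)
    rownames(profiles) <- db$relevant_targets
    list(metrics = metrics, selection = selection, profiles = profiles,
         cluster_sizes = sizes)
  })
}
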