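#' Default pipeline configuration
#'
#' Nested key-value configuration for [run_pipeline()]. The `seed` is
#' mandatory and feeds every stochastic stage; stage blocks mirror the
#' tunable parameters of the underlying functions.
#'
#' @param seed master integer seed.
#' @param out_dir output directory.
#' @param sim overrides passed to [sim_config()] (the synthetic study
#'   conditions).
#' @param relevance overrides for [stability_selection()] (`n_splits`,
#'   `fraction`, `stability_min`, `n_trees`, `max_depth`).
#' @param prioritize overrides (`k_max`, `n_ref`, `alpha`, `levels`).
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1, out_dir = "results",
                            sim = list(), relevance = list(),
                            prioritize = list()) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    sim = utils::modifyList(list(), sim),
    relevance = utils::modifyList(
      list(n_splits = 20, test_frac = 0.2, fraction = 0.05,
           stability_min = 0.4, r2_min = 0, n_trees = 100, max_depth = 6),
      relevance),
    prioritize = utils::modifyList(
      list(k_max = 6, n_ref = 50, alpha = 0.05, levels = 1:4), prioritize))
  validate_pipeline_config(cfg)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [pipeline_config()] structure.
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    stop("configuration error: an integer 'seed' is mandatory")
  if (!is.null(cfg$relevance$n_splits) && cfg$relevance$n_splits < 2)
    stop("configuration error: n_splits must be >= 2")
  invisible(cfg)
}

run_header <- function(cfg, stage) {
  c(sprintf("mechmap %s", as.character(utils::packageVersion("mechmap"))),
    sprintf("stage: %s", stage),
    sprintf("seed: %d", as.integer(cfg$seed)))
}

write_table_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in order - synthetic data generation, disease-map
#' construction, circuit-activity estimation, stability-validated
#' relevance learning, and target/drug prioritization - and writes every
#' output table under `cfg$out_dir` with a run-metadata header. All
#' randomness flows from `cfg$seed`, so re-running with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a manifest list with the output paths, per-stage
#'   summary counts and the ground-truth manifest of the generated data.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  stage <- "simulate"
  res <- tryCatch({
    sim_cfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
    sim <- simulate_dataset(sim_cfg)

    stage <- "build-map"
    map_tab <- disease_map_table(sim$map)
    write_table_with_header(map_tab, out("circuits.tsv"),
                            run_header(cfg, stage))

    stage <- "activities"
    write_matrix_tsv(sim$observed, out("activities.tsv"),
                     id_col = "circuit_id",
                     header = run_header(cfg, stage))

    stage <- "relevance"
    rl <- cfg$relevance
    fit <- stability_selection(sim$X, t(sim$observed),
                               n_splits = rl$n_splits,
                               test_frac = rl$test_frac,
                               fraction = rl$fraction,
                               stability_min = rl$stability_min,
                               r2_min = rl$r2_min, n_trees = rl$n_trees,
                               max_depth = rl$max_depth, seed = cfg$seed)
    write_matrix_tsv(round(fit$relevance, 10), out("relevance.tsv"),
                     id_col = "circuit_id", header = run_header(cfg, stage))
    write_matrix_tsv(fit$selection * 1, out("selection.tsv"),
                     id_col = "circuit_id", header = run_header(cfg, stage))
    metrics <- data.frame(circuit_id = rownames(fit$relevance),
                          r2_low = fit$r2_ci[, "low"],
                          r2_high = fit$r2_ci[, "high"],
                          stability = fit$stability)
    write_table_with_header(metrics, out("metrics.tsv"),
                            run_header(cfg, stage))

    stage <- "prioritize"
    pz <- cfg$prioritize
    sel_targets <- selected_targets(fit)
    clusters <- NULL
    if (length(sel_targets) >= 2) {
      prof <- t(rescale_relevance(fit$relevance))[sel_targets, , drop = FALSE]
      k <- gap_statistic_k(prof, k_max = max(1, min(pz$k_max, nrow(prof) - 1)),
                           n_ref = pz$n_ref, seed = cfg$seed)
      clusters <- cluster_targets(prof, k)
    } else {
      clusters <- data.frame(target = sel_targets,
                             cluster = rep(1L, length(sel_targets)))
    }
    write_table_with_header(clusters, out("clusters.tsv"),
                            run_header(cfg, stage))
    atc_map <- split(sim$drugs$atc, sim$drugs$drug_id)
    rel_drugs <- unique(sim$drugs$drug_id[sim$drugs$entrez_id %in%
                                            sel_targets])
    enr <- overrepresentation(rel_drugs, unique(sim$drugs$drug_id), atc_map,
                              levels = pz$levels, alpha = pz$alpha)
    write_table_with_header(enr, out("enrichment.tsv"),
                            run_header(cfg, stage))
    rev <- filter_reversal_drugs(sim$drugs, sim$dysregulation, sel_targets)
    write_table_with_header(rev, out("reversal_candidates.tsv"),
                            run_header(cfg, stage))
    cov_rows <- lapply(unique(rev$drug_id), function(d) {
      cv <- drug_hallmark_coverage(rev$entrez_id[rev$drug_id == d],
                                   fit$selection, sim$map$hallmarks)
      data.frame(drug_id = d, hallmark = names(cv), coverage = unname(cv))
    })
    cov <- do.call(rbind, c(cov_rows, list(make.row.names = FALSE)))
    if (is.null(cov)) cov <- data.frame(drug_id = character(),
                                        hallmark = character(),
                                        coverage = numeric())
    write_table_with_header(cov, out("hallmark_coverage.tsv"),
                            run_header(cfg, stage))
    shared <- hallmark_shared_influence(fit$selection, fit$relevance,
                                        sim$map$hallmarks)
    write_matrix_tsv(round(shared, 10), out("shared_influence.tsv"),
                     id_col = "hallmark", header = run_header(cfg, stage))

    manifest <- list(
      seed = cfg$seed,
      outputs = basename(c(out("circuits.tsv"), out("activities.tsv"),
                           out("relevance.tsv"), out("selection.tsv"),
                           out("metrics.tsv"), out("clusters.tsv"),
                           out("enrichment.tsv"),
                           out("reversal_candidates.tsv"),
                           out("hallmark_coverage.tsv"),
                           out("shared_influence.tsv"))),
      n_circuits = nrow(map_tab),
      n_stable_circuits = sum(!is.na(fit$stability) &
                                fit$stability > rl$stability_min),
      n_selected_targets = length(sel_targets),
      n_reversal_candidates = nrow(rev),
      ground_truth = sim$manifest[c("causal_targets", "decoy_targets",
                                    "rp_terms", "amplifiable",
                                    "enriched_level1")])
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    manifest
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  invisible(res)
}
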