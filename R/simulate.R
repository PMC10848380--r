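with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The defaults are
#' the package's reference study conditions: 5 pathways of 32 nodes
#' yielding 20 circuits, 50 known-drug-target genes with 5 planted causal
#' targets per circuit, 400 samples and activity noise of 0.05 on the
#' unit scale - a desk-scale analogue of a normal-tissue expression
#' compendium feeding the learner.
#'
#' @param seed master integer seed; every generator derives its stream
#'   from it.
#' @param n_samples number of samples (default 400).
#' @param n_genes total gene universe size (default 200; padded with
#'   inert background genes).
#' @param n_pathways number of synthetic pathways (default 5).
#' @param nodes_per_pathway nodes per pathway (default 32; each circuit
#'   block consumes `n_causal_per_circuit + 2` nodes).
#' @param edge_density probability of an extra shortcut edge from a
#'   planted target straight to the effector (default 0.1).
#' @param inhibition_prob probability that a target feeds its circuit
#'   through an inhibition edge (default 0.25).
#' @param n_core_genes curated core disease genes planted on circuit
#'   backbones (default 10).
#' @param ontology_depth depth of the synthetic phenotype DAG (default 8).
#' @param branching ontology branching factor (default 2).
#' @param n_targets number of known-drug-target genes (default 50; the
#'   causal pool is the first 80 percent, the remainder are guaranteed
#'   decoys).
#' @param n_causal_per_circuit planted causal targets per circuit
#'   (default 5).
#' @param noise_sd Gaussian noise added to the true circuit activities,
#'   clipped back to `[0, 1]` (default 0.05).
#' @param n_drugs number of synthetic drugs (default 200).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_samples = 400, n_genes = 200,
                       n_pathways = 5, nodes_per_pathway = 32,
                       edge_density = 0.1, inhibition_prob = 0.25,
                       n_core_genes = 10, ontology_depth = 8, branching = 2,
                       n_targets = 50, n_causal_per_circuit = 5,
                       noise_sd = 0.05, n_drugs = 200) {
  cfg <- list(seed = seed, n_samples = n_samples, n_genes = n_genes,
              n_pathways = n_pathways, nodes_per_pathway = nodes_per_pathway,
              edge_density = edge_density, inhibition_prob = inhibition_prob,
              n_core_genes = n_core_genes, ontology_depth = ontology_depth,
              branching = branching, n_targets = n_targets,
              n_causal_per_circuit = n_causal_per_circuit,
              noise_sd = noise_sd, n_drugs = n_drugs)
  counts <- cfg[c("n_samples", "n_genes", "n_pathways", "nodes_per_pathway",
                  "n_core_genes", "ontology_depth", "branching", "n_targets",
                  "n_causal_per_circuit", "n_drugs")]
  stopifnot(all(unlist(counts) >= 1), noise_sd >= 0,
            edge_density >= 0, edge_density <= 1,
            inhibition_prob >= 0, inhibition_prob <= 1)
  structure(cfg, class = "sim_config")
}

target_gene_ids <- function(cfg) sprintf("9%03d", seq_len(cfg$n_targets))
core_gene_ids <- function(cfg) sprintf("5%02d", seq_len(cfg$n_core_genes))
causal_pool <- function(cfg)
  target_gene_ids(cfg)[seq_len(ceiling(0.8 * cfg$n_targets))]

#' Simulate a phenotype ontology with planted amplifiable genes
#'
#' Builds a seeded DAG of the configured depth and branching (a term may
#' acquire a second parent, so shared ancestors are exercised), annotates
#' a synthetic disease to a band of terms - 22 deep terms with TAS
#' evidence, a few shallow or non-TAS terms that the selection filters
#' must reject - and annotates target genes so that a known subset shares
#' at least `min_shared` of the disease terms. The manifest records the
#' ground truth the round-trip tests check against.
#'
#' @param cfg a [sim_config] (`ontology_depth >= 2`).
#' @param min_shared phenotype-sharing threshold recorded in the manifest
#'   (default 10).
#' @return list with `ontology`, `core_genes` ([gene_records]) and
#'   `manifest` (`disease_id`, `rp_terms`, `spec_window`, `amplifiable` -
#'   the genes passing the sharing screen, before any intersection with a
#'   pathway gene universe - and `min_shared`).
#' @export
simulate_ontology <- function(cfg, min_shared = 10) {
  stopifnot(cfg$ontology_depth >= 2)
  with_seed(cfg$seed + 101L, {
    depth <- cfg$ontology_depth
    levels <- lapply(seq_len(depth) - 1L, function(l)
      min(cfg$branching^l, 40L))
    ids <- list(); parents <- list(); counter <- 0L
    for (l in seq_len(depth)) {
      n_l <- levels[[l]]
      ids[[l]] <- sprintf("SYN:%07d", counter + seq_len(n_l))
      counter <- counter + n_l
      if (l > 1) {
        for (t in ids[[l]]) {
          par <- sample(ids[[l - 1]], 1)
          if (length(ids[[l - 1]]) > 1 && stats::runif(1) < 0.2)
            par <- unique(c(par, sample(setdiff(ids[[l - 1]], par), 1)))
          parents[[t]] <- par
        }
      }
    }
    all_terms <- unlist(ids)
    disease <- "DIS:RP"
    deep_levels <- which(seq_len(depth) >= min(4L, depth))
    deep_terms <- unlist(ids[deep_levels])
    n_deep <- min(22L, length(deep_terms))
    tas_terms <- sample(deep_terms, n_deep)
    shallow_pool <- setdiff(ids[[min(2L, depth)]], tas_terms)
    shallow <- sample(shallow_pool, min(2L, length(shallow_pool)))
    iea_pool <- setdiff(deep_terms, tas_terms)
    iea_terms <- sample(iea_pool, min(2L, length(iea_pool)))
    dis_ann <- data.frame(
      term_id = c(tas_terms, shallow, iea_terms),
      disease_id = disease,
      evidence = c(rep("TAS", length(tas_terms) + length(shallow)),
                   rep("IEA", length(iea_terms))),
      stringsAsFactors = FALSE)
    genes <- target_gene_ids(cfg)
    n_amp <- min(5L, length(genes))
    amplifiable <- sample(genes, n_amp)
    gene_ann <- list()
    lo <- min(min_shared, n_deep)
    pick1 <- function(v) v[sample.int(length(v), 1)]  # safe for length 1
    for (g in genes) {
      n_share <- if (g %in% amplifiable)
        pick1(lo:n_deep) else pick1(0:(lo - 1L))
      if (n_share > 0)
        gene_ann[[g]] <- data.frame(term_id = sample(tas_terms, n_share),
                                    gene_id = g, evidence = "TAS",
                                    stringsAsFactors = FALSE)
    }
    # a gene passing the screen but absent from any pathway
    gene_ann[["77777"]] <- data.frame(term_id = sample(tas_terms, n_deep),
                                      gene_id = "77777", evidence = "TAS",
                                      stringsAsFactors = FALSE)
    gene_ann <- do.call(rbind, c(gene_ann, list(make.row.names = FALSE)))
    ont <- ontology(all_terms, parents,
                    gene_annotations = gene_ann,
                    disease_annotations = dis_ann)
    spec <- vapply(tas_terms, compute_specificity, integer(1), ont = ont)
    window <- c(min(spec), max(spec))
    shallow_spec <- vapply(shallow, compute_specificity, integer(1),
                           ont = ont)
    if (any(shallow_spec >= window[1])) window[1] <- max(shallow_spec) + 1L
    rp_terms <- sort(tas_terms[spec >= window[1] & spec <= window[2]])
    core <- gene_records(core_gene_ids(cfg),
                         sprintf("CORE%d", seq_len(cfg$n_core_genes)),
                         source = "core")
    list(ontology = ont, core_genes = core,
         manifest = list(disease_id = disease, rp_terms = rp_terms,
                         spec_window = window,
                         amplifiable = sort(amplifiable),
                         min_shared = min_shared))
  })
}

#' Simulate signed pathway graphs with planted causal circuits
#'
#' Every pathway is an acyclic signed digraph assembled from circuit
#' blocks: `n_causal_per_circuit` receptor nodes, each carrying one
#' planted target gene, feed a two-node backbone ending in the effector,
#' alternating between the upstream node and the effector so every
#' planted effect stays identifiable. Backbone nodes carry scaffold
#' genes; one curated core disease gene rides along on each circuit's
#' upstream node so the whole map survives the disease-gene membership
#' filter. Edge signs are
#' inhibition with probability `inhibition_prob`; `edge_density` adds
#' shortcut edges from targets straight to the effector.
#'
#' @param cfg a [sim_config] (`nodes_per_pathway >= 2`).
#' @return list with `graphs` (named list of [pathway_graph]),
#'   `hallmark_table` (seeded circuit-to-hallmark annotation) and
#'   `manifest` (`circuits` data frame with planted targets,
#'   `target_genes`, `causal_targets`, `decoy_targets`, `core_genes`,
#'   `scaffold_genes`).
#' @export
simulate_pathways <- function(cfg) {
  stopifnot(cfg$nodes_per_pathway >= 2)
  with_seed(cfg$seed + 202L, {
    block <- cfg$n_causal_per_circuit + 2L
    cpp <- max(1L, cfg$nodes_per_pathway %/% block)
    pool <- causal_pool(cfg)
    core <- core_gene_ids(cfg)
    graphs <- list(); rows <- list(); scaffold <- character()
    filler_counter <- 0L; ci <- 0L
    for (p in seq_len(cfg$n_pathways)) {
      pid <- sprintf("syn%02d", p)
      nodes <- list(); edges <- list()
      for (cc in seq_len(cpp)) {
        ci <- ci + 1L
        tg <- sample(pool, cfg$n_causal_per_circuit)
        mts <- sprintf("c%d_t%d", cc, seq_along(tg))
        mbs <- sprintf("c%d_m%d", cc, 1:2)
        for (i in seq_along(tg)) nodes[[mts[i]]] <- tg[i]
        for (i in 1:2) {
          filler_counter <- filler_counter + 1L
          fg <- sprintf("1%03d", filler_counter)
          scaffold <- c(scaffold, fg)
          nodes[[mbs[i]]] <- fg
        }
        core_g <- core[(ci - 1L) %% length(core) + 1L]
        nodes[[mbs[1]]] <- c(nodes[[mbs[1]]], core_g)
        for (i in seq_along(tg)) {
          sign <- if (stats::runif(1) < cfg$inhibition_prob)
            "inhibition" else "activation"
          # drivers alternate between the upstream backbone node and the
          # effector itself, keeping every planted effect identifiable
          to <- mbs[(i - 1L) %% 2L + 1L]
          edges[[length(edges) + 1L]] <- data.frame(
            from = mts[i], to = to, sign = sign)
          if (stats::runif(1) < cfg$edge_density && to != mbs[2])
            edges[[length(edges) + 1L]] <- data.frame(
              from = mts[i], to = mbs[2], sign = "activation")
        }
        edges[[length(edges) + 1L]] <- data.frame(from = mbs[1], to = mbs[2],
                                                  sign = "activation")
        rows[[ci]] <- data.frame(
          circuit_id = paste0(pid, ":", mbs[2]), pathway_id = pid,
          effector = mbs[2],
          causal_targets = paste(sort(tg), collapse = ";"),
          core_gene = core_g, stringsAsFactors = FALSE)
      }
      graphs[[pid]] <- pathway_graph(
        pid, nodes, do.call(rbind, c(edges, list(make.row.names = FALSE))))
    }
    circuits <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    planted <- unique(unlist(strsplit(circuits$causal_targets, ";")))
    hallmark_table <- do.call(rbind, lapply(circuits$circuit_id, function(id)
      data.frame(circuit_id = id,
                 hallmark = sample(RP_HALLMARKS, sample(1:3, 1)),
                 stringsAsFactors = FALSE)))
    list(graphs = graphs, hallmark_table = hallmark_table,
         manifest = list(circuits = circuits,
                         target_genes = target_gene_ids(cfg),
                         causal_targets = sort(planted),
                         decoy_targets = sort(setdiff(target_gene_ids(cfg),
                                                      planted)),
                         core_genes = core, scaffold_genes = scaffold))
  })
}

#' Simulate expression and circuit activities with known ground truth
#'
#' Target genes are drawn from a wide Beta(2, 2) (they carry the signal);
#' scaffold and core genes from a tight Beta(40, 40) around mid-scale
#' (low-variance housekeeping behaviour, so planted targets dominate the
#' circuit activities); background padding genes from Beta(2, 2). True
#' activities are computed by propagating the signal over the generated
#' map; observed activities add clipped Gaussian noise, or are replaced
#' by pure uniform noise when `null_activities = TRUE` (the negative
#' control in which no target is predictive).
#'
#' @param cfg a [sim_config].
#' @param paths result of [simulate_pathways()].
#' @param core_genes [gene_records] of the planted core genes.
#' @param null_activities replace activities by noise (default `FALSE`).
#' @return list with `expr` (gene-by-sample, unit scale), `X`
#'   (sample-by-target feature matrix), `map` (the [disease_map]),
#'   `truth` and `observed` (circuit-by-sample activity matrices).
#' @export
simulate_expression <- function(cfg, paths, core_genes,
                                null_activities = FALSE) {
  stopifnot(length(paths$graphs) > 0)
  with_seed(cfg$seed + 303L, {
    man <- paths$manifest
    genes <- unique(c(man$target_genes, man$scaffold_genes, man$core_genes))
    n_bg <- max(0L, cfg$n_genes - length(genes))
    bg <- if (n_bg) sprintf("8%03d", seq_len(n_bg)) else character()
    all_genes <- c(genes, bg)
    samples <- sprintf("s%04d", seq_len(cfg$n_samples))
    expr <- matrix(NA_real_, length(all_genes), cfg$n_samples,
                   dimnames = list(all_genes, samples))
    wide <- c(man$target_genes, bg)
    tight <- c(man$scaffold_genes, man$core_genes)
    expr[wide, ] <- stats::rbeta(length(wide) * cfg$n_samples, 2, 2)
    expr[tight, ] <- stats::rbeta(length(tight) * cfg$n_samples, 40, 40)
    map <- build_disease_map(paths$graphs, core_genes)
    map <- attach_hallmarks(map, paths$hallmark_table)
    truth <- circuit_activities(map, expr)
    observed <- if (null_activities) {
      matrix(stats::runif(length(truth)), nrow(truth), ncol(truth),
             dimnames = dimnames(truth))
    } else {
      pmin(pmax(truth + stats::rnorm(length(truth), 0, cfg$noise_sd), 0), 1)
    }
    X <- t(expr[man$target_genes, , drop = FALSE])
    list(expr = expr, X = X, map = map, truth = truth, observed = observed)
  })
}

.action_vocab <- c(Agonist = "activator", Potentiator = "activator",
                   Inducer = "activator", Antagonist = "inhibitor",
                   Inhibitor = "inhibitor", Blocker = "inhibitor",
                   Modulator = "modulator", Ligand = "ligand",
                   Binder = "ligand", Chelator = "other",
                   Cofactor = "other")

#' Simulate a drug-target table with planted enrichment and reversals
#'
#' Drugs receive 1-2 targets, an action string from the DrugBank action
#' vocabulary and a 5-character 4-level ATC-like code. Drugs hitting a
#' relevant target are preferentially assigned the planted anatomical
#' class (level-1 code `N`), creating a known over-represented category.
#' A dysregulation direction is drawn for every relevant target, and the
#' manifest records which drug-target rows counteract it (the reversal
#' ground truth).
#'
#' @param cfg a [sim_config] (`n_drugs >= 1`).
#' @param relevant_targets character vector of relevant target gene ids.
#' @return list with `drugs` (data frame of drug-target records),
#'   `dysregulation` (named up/down vector) and `manifest`
#'   (`enriched_level1`, `reversal_rows` row keys, `relevant_drugs`).
#' @export
simulate_drug_table <- function(cfg, relevant_targets) {
  stopifnot(cfg$n_drugs >= 1)
  with_seed(cfg$seed + 404L, {
    atc_l1 <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N",
                "P", "R", "S", "V")
    genes <- target_gene_ids(cfg)
    rows <- list()
    for (k in seq_len(cfg$n_drugs)) {
      did <- sprintf("DB%05d", k)
      tg <- sample(genes, sample(1:2, 1))
      hits_relevant <- any(tg %in% relevant_targets)
      l1 <- if (hits_relevant && stats::runif(1) < 0.8) "N"
      else sample(atc_l1, 1)
      atc <- paste0(l1, sprintf("%02d", sample(1:14, 1)),
                    sample(LETTERS[1:6], 1), sample(LETTERS[1:6], 1))
      for (g in tg) {
        action <- sample(names(.action_vocab), 1)
        rows[[length(rows) + 1L]] <- data.frame(
          drug_id = did, drug_name = paste0("drug_", k), entrez_id = g,
          action = action, approved = "true", known_action = "true",
          atc = atc, stringsAsFactors = FALSE)
      }
    }
    drugs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    drugs$effect <- simplify_action(drugs$action)
    dys <- stats::setNames(sample(c("up", "down"), length(relevant_targets),
                                  replace = TRUE), relevant_targets)
    opposing <- (dys[drugs$entrez_id] == "up" & drugs$effect == "inhibitor") |
      (dys[drugs$entrez_id] == "down" & drugs$effect == "activator")
    reversal <- drugs$entrez_id %in% relevant_targets &
      !is.na(opposing) & opposing
    list(drugs = drugs, dysregulation = dys,
         manifest = list(
           enriched_level1 = "N",
           reversal_rows = paste(drugs$drug_id, drugs$entrez_id,
                                 sep = ":")[reversal],
           relevant_drugs = sort(unique(
             drugs$drug_id[drugs$entrez_id %in% relevant_targets]))))
  })
}

#' Generate a complete synthetic study
#'
#' Runs every generator under the single configuration seed and returns
#' the assembled inputs plus the combined ground-truth manifest.
#'
#' @param cfg a [sim_config].
#' @param null_activities see [simulate_expression()].
#' @return list with `ontology`, `core_genes`, `paths`, `map`, `expr`,
#'   `X`, `truth`, `observed`, `drugs`, `dysregulation`, `manifest`.
#' @export
simulate_dataset <- function(cfg = sim_config(), null_activities = FALSE) {
  ont <- simulate_ontology(cfg)
  paths <- simulate_pathways(cfg)
  ex <- simulate_expression(cfg, paths, ont$core_genes,
                            null_activities = null_activities)
  dt <- simulate_drug_table(cfg, paths$manifest$causal_targets)
  list(ontology = ont$ontology, core_genes = ont$core_genes, paths = paths,
       map = ex$map, expr = ex$expr, X = ex$X, truth = ex$truth,
       observed = ex$observed, drugs = dt$drugs,
       dysregulation = dt$dysregulation,
       manifest = c(ont$manifest, paths$manifest, dt$manifest,
                    list(seed = cfg$seed)))
}
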