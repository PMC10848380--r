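# small hand-checkable objects shared across tests

toy_chain_graph <- function() {
  pathway_graph("toy",
                list(R = "1", A = "2", E = "3"),
                data.frame(from = c("R", "A"), to = c("A", "E"),
                           sign = "activation"))
}

toy_diamond_ontology <- function() {
  # r -> x, r -> y, x -> z, y -> z
  ontology(c("r", "x", "y", "z"),
           parents = list(x = "r", y = "r", z = c("x", "y")))
}

random_dag <- function(n, p = 0.35) {
  # edges only from lower to higher index: acyclic by construction
  e <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p)
      e[[length(e) + 1L]] <- data.frame(
        from = paste0("n", i), to = paste0("n", j),
        sign = sample(c("activation", "inhibition"), 1))
  edges <- if (length(e)) do.call(rbind, e) else
    data.frame(from = character(), to = character(), sign = character())
  nodes <- stats::setNames(as.list(as.character(seq_len(n))),
                           paste0("n", seq_len(n)))
  pathway_graph("rnd", nodes, edges)
}

# independent oracle: nodes on some receptor->effector path, by
# exhaustive simple-path enumeration
path_nodes_bruteforce <- function(graph) {
  adj <- split(graph$edges$to, graph$edges$from)
  nodes <- names(graph$nodes)
  indeg <- table(factor(graph$edges$to, levels = nodes))
  outdeg <- table(factor(graph$edges$from, levels = nodes))
  receptors <- nodes[indeg == 0]
  effectors <- nodes[outdeg == 0]
  on_path <- character()
  walk <- function(v, path) {
    if (v %in% effectors) { on_path <<- union(on_path, c(path, v)); }
    for (w in adj[[v]]) if (!w %in% path) walk(w, c(path, v))
  }
  for (r in receptors) walk(r, character())
  sort(on_path)
}

# independent oracle: one-sided enrichment p by hypergeometric counting
fisher_enrich_oracle <- function(a, K, n, N) {
  xs <- max(0, n + K - N):min(K, n)
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(probs[xs >= a])
}

small_sim_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_samples = 80, n_genes = 80, n_pathways = 2,
         nodes_per_pathway = 14, n_targets = 12, n_causal_per_circuit = 4,
         n_drugs = 60),
    list(...))
  do.call(sim_config, args)
}
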