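#' Trimmed-mean-of-M-values (TMM) size factors
#'
#' Between-sample normalization factors for raw count matrices, computed
#' with the TMM method of edgeR: the reference is the sample whose upper
#' quartile is closest to the mean upper quartile; each sample's factor is
#' the precision-weighted mean of log2 fold changes (M values) against the
#' reference after trimming the most extreme M and A values, and factors
#' are rescaled to have zero log-mean.
#'
#' @param counts non-negative gene-by-sample count matrix (>= 2 samples).
#' @param trim_m fraction of M values trimmed from each tail (default 0.30).
#' @param trim_a fraction of A values trimmed from each tail (default 0.05).
#' @return named positive numeric vector, one factor per sample.
#' @export
tmm_size_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Counts-per-million with TMM-adjusted library sizes
#'
#' @param counts raw count matrix.
#' @param factors size factors from [tmm_size_factors()].
#' @return CPM matrix.
#' @export
tmm_cpm <- function(counts, factors = tmm_size_factors(counts)) {
  counts <- as.matrix(counts)
  eff <- colSums(counts) * factors[colnames(counts)]
  sweep(counts, 2, eff, "/") * 1e6
}

#' Rescale an expression matrix to the unit interval
#'
#' Per gene: values are clipped at the `truncate_q` quantile across
#' samples (guarding against single extreme samples dominating the range)
#' and then min-max scaled to `[0, 1]`. Constant genes map to 0. A
#' single-sample matrix has no within-gene range; all values become 0.5
#' with a warning.
#'
#' @param expr normalized non-negative gene-by-sample matrix.
#' @param truncate_q upper clipping quantile (default 0.99; use 1 to
#'   disable truncation).
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
scale_unit <- function(expr, truncate_q = 0.99) {
  expr <- as.matrix(expr)
  if (ncol(expr) == 1) {
    warning("single-sample matrix: min-max scaling undefined, returning 0.5")
    expr[] <- 0.5
    return(expr)
  }
  out <- t(apply(expr, 1, function(x) {
    hi <- stats::quantile(x, truncate_q, names = FALSE, type = 7)
    x <- pmin(x, hi)
    rng <- range(x)
    if (rng[2] - rng[1] <= 0) return(rep(0, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }))
  dimnames(out) <- dimnames(expr)
  out
}

#' Full count-normalization chain
#'
#' Raw counts -> TMM-scaled CPM -> optional `log1p` -> quantile truncation
#' -> per-gene min-max to `[0, 1]`. This is the expression scale expected
#' by the propagation engine.
#'
#' @param counts raw gene-by-sample count matrix.
#' @param log1p apply `log1p` after CPM (default `TRUE`).
#' @param truncate_q see [scale_unit()].
#' @return unit-scaled matrix.
#' @export
normalize_expression <- function(counts, log1p = TRUE, truncate_q = 0.99) {
  x <- tmm_cpm(counts)
  if (log1p) x <- log1p(x)
  scale_unit(x, truncate_q = truncate_q)
}

#' Summarize gene expression into node values
#'
#' Pathway nodes may carry several genes (protein families, complexes) or
#' none (metabolites). Multi-gene nodes are summarized by the chosen
#' statistic; genes absent from the expression matrix are imputed at
#' `missing_value`, and gene-less nodes are fixed at `missing_value`
#' (mid-scale, uninformative).
#'
#' @param expr unit-scaled gene-by-sample matrix.
#' @param graph a [pathway_graph].
#' @param summary one of `"mean"`, `"median"`, `"p90"` (default mean).
#' @param missing_value value for missing genes and gene-less nodes
#'   (default 0.5).
#' @return node-by-sample matrix.
#' @export
node_values <- function(expr, graph, summary = c("mean", "median", "p90"),
                        missing_value = 0.5) {
  summary <- match.arg(summary)
  fun <- switch(summary,
                mean = colMeans,
                median = function(m) apply(m, 2, stats::median),
                p90 = function(m) apply(m, 2, stats::quantile, probs = 0.9,
                                        names = FALSE))
  ns <- ncol(expr)
  out <- matrix(missing_value, nrow = length(graph$nodes), ncol = ns,
                dimnames = list(names(graph$nodes), colnames(expr)))
  for (nd in names(graph$nodes)) {
    genes <- graph$nodes[[nd]]
    if (!length(genes)) next
    vals <- matrix(missing_value, nrow = length(genes), ncol = ns)
    hit <- genes %in% rownames(expr)
    if (any(hit)) vals[hit, ] <- expr[genes[hit], , drop = FALSE]
    out[nd, ] <- fun(vals)
  }
  out
}

#' Propagate signal through a signed pathway graph
#'
#' Implements the recursive signal-propagation rule: for a node n with
#' normalized expression value v_n, incoming activating signals A and
#' incoming inhibiting signals I,
#' \deqn{S_n = v_n (1 - \prod_{a \in A}(1 - S_a)) \prod_{i \in I}(1 - S_i).}
#' Receptor nodes (no incoming edges) take `S = v`. A node with inhibiting
#' but no activating inputs uses activation factor 1 (the empty product
#' convention), so signal can still flow through it. Updates are
#' synchronous sweeps repeated to a fixed point, which on acyclic graphs
#' coincides with a single topological-order pass and on cyclic graphs
#' guarantees termination via `max_iter`.
#'
#' @param graph a [pathway_graph].
#' @param node_vals node-by-sample matrix in `[0, 1]` (see [node_values()]).
#' @param tol convergence tolerance on the max per-node change (default 1e-6).
#' @param max_iter maximum number of sweeps (default 100).
#' @return list with `signal` (node-by-sample matrix in `[0, 1]`),
#'   `iterations`, `converged`, `tolerance`.
#' @export
propagate <- function(graph, node_vals, tol = 1e-6, max_iter = 100) {
  stopifnot(tol > 0, all(node_vals >= 0 & node_vals <= 1))
  nodes <- names(graph$nodes)
  v <- node_vals[nodes, , drop = FALSE]
  e <- graph$edges
  act_in <- lapply(stats::setNames(nodes, nodes), function(nd)
    e$from[e$to == nd & e$sign == "activation"])
  inh_in <- lapply(stats::setNames(nodes, nodes), function(nd)
    e$from[e$to == nd & e$sign == "inhibition"])
  is_receptor <- lengths(act_in) + lengths(inh_in) == 0
  s <- v
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    s_old <- s
    for (nd in nodes[!is_receptor]) {
      a <- act_in[[nd]]; i <- inh_in[[nd]]
      act <- if (length(a)) {
        1 - apply(1 - s_old[a, , drop = FALSE], 2, prod)
      } else 1
      inh <- if (length(i)) {
        apply(1 - s_old[i, , drop = FALSE], 2, prod)
      } else 1
      s[nd, ] <- v[nd, ] * act * inh
    }
    if (max(abs(s - s_old)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("propagation did not converge within ", max_iter, " sweeps")
  list(signal = s, iterations = iter, converged = converged, tolerance = tol)
}

circuit_subgraph <- function(circuit, graph) {
  e <- graph$edges
  keep <- e$from %in% circuit$members & e$to %in% circuit$members
  pathway_graph(graph$pathway_id, graph$nodes[circuit$members],
                e[keep, , drop = FALSE])
}

#' Estimate circuit activities across samples
#'
#' For every circuit of the disease map the signal is propagated over the
#' circuit's member subgraph and the effector node's converged signal is
#' reported per sample.
#'
#' @param map a [disease_map].
#' @param expr unit-scaled gene-by-sample matrix.
#' @param summary,missing_value see [node_values()].
#' @param tol,max_iter see [propagate()].
#' @return circuit-by-sample activity matrix with values in `[0, 1]`.
#' @export
circuit_activities <- function(map, expr, summary = "mean",
                               missing_value = 0.5, tol = 1e-6,
                               max_iter = 100) {
  out <- matrix(NA_real_, nrow = length(map$circuits), ncol = ncol(expr),
                dimnames = list(names(map$circuits), colnames(expr)))
  nv_cache <- list()
  for (cc in map$circuits) {
    graph <- map$pathways[[cc$pathway_id]]
    if (is.null(graph)) stop("circuit ", cc$circuit_id,
                             " references unknown pathway ", cc$pathway_id)
    if (is.null(nv_cache[[cc$pathway_id]]))
      nv_cache[[cc$pathway_id]] <- node_values(expr, graph, summary = summary,
                                               missing_value = missing_value)
    sub <- circuit_subgraph(cc, graph)
    nv <- nv_cache[[cc$pathway_id]][cc$members, , drop = FALSE]
    st <- propagate(sub, nv, tol = tol, max_iter = max_iter)
    out[cc$circuit_id, ] <- st$signal[cc$effector, ]
  }
  out
}

#' Read / write activity and expression matrices
#'
#' TSV layout: first column holds row ids (`gene_id` or `circuit_id`),
#' remaining columns are samples; comment lines starting `#` are skipped,
#' gzip-compressed files are handled transparently by R.
#'
#' @param path TSV path.
#' @return numeric matrix with row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param m matrix to write.
#' @param id_col name for the row-id column.
#' @param header optional character vector of `#`-prefixed metadata lines.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id", header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
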