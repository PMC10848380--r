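#' The nine disease hallmark labels
#'
#' Fixed vocabulary of functional hallmark modules used to tag circuits of
#' the retinitis pigmentosa disease map.
#'
#' @export
RP_HALLMARKS <- c("Apoptosis", "Necrosis", "Stress Response",
                  "Inflammatory response", "DNA integrity",
                  "Fatty acids and lipid metabolism",
                  "Sensory and stimuli response",
                  "Development processes", "Neuronal processes")

#' Construct a signed directed pathway graph
#'
#' Nodes carry a (possibly empty) list of gene ids; metabolite or complex
#' nodes without genes are allowed and receive a fixed mid-scale value
#' during propagation. Edges are signed `activation`/`inhibition`
#' interactions; self-loops are rejected.
#'
#' @param pathway_id pathway identifier (e.g. an `hsa`-prefixed KEGG id).
#' @param nodes named list: node id to character vector of gene ids
#'   (use `character(0)` for gene-less nodes).
#' @param edges data frame with columns `from`, `to`, `sign`.
#' @return object of class `pathway_graph`.
#' @export
pathway_graph <- function(pathway_id, nodes, edges) {
  stopifnot(is.list(nodes), length(nodes) >= 1, !is.null(names(nodes)))
  if (anyDuplicated(names(nodes))) stop("duplicated node ids")
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    stopifnot(all(c("from", "to", "sign") %in% names(edges)))
    edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
    bad <- setdiff(unique(c(edges$from, edges$to)), names(nodes))
    if (length(bad)) stop("edge endpoint(s) not in nodes: ",
                          paste(bad, collapse = ", "))
    if (any(edges$from == edges$to)) stop("self-loop edges are not allowed")
    if (!all(edges$sign %in% c("activation", "inhibition")))
      stop("edge sign must be 'activation' or 'inhibition'")
  } else {
    edges <- data.frame(from = character(), to = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  structure(list(pathway_id = as.character(pathway_id),
                 nodes = lapply(nodes, as.character), edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %s: %d nodes, %d edges\n",
              x$pathway_id, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

pathway_igraph <- function(graph) {
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(names(graph$nodes))
  if (nrow(graph$edges))
    g <- g + igraph::edges(rbind(graph$edges$from, graph$edges$to))
  g
}

#' All gene ids appearing in a pathway collection
#'
#' @param pathways list of [pathway_graph] objects.
#' @return character vector of unique gene ids.
#' @export
pathway_gene_universe <- function(pathways) {
  unique(unlist(lapply(pathways, function(p) unlist(p$nodes, use.names = FALSE))))
}

#' Extract receptor-to-effector circuits from a pathway graph
#'
#' Receptors are nodes with no incoming signed edge, effectors nodes with
#' no outgoing edge. One circuit is built per effector that is reachable
#' from at least one receptor; its members are all nodes lying on some
#' directed receptor-to-effector path (descendants of receptors
#' intersected with ancestors of the effector, plus the effector itself).
#' An isolated node is both receptor and effector and yields a trivial
#' single-node circuit, later removed by the disease-map size filter.
#'
#' @param graph a [pathway_graph].
#' @return list of circuit objects (`circuit_id`, `pathway_id`,
#'   `effector`, `members`, `receptors`).
#' @export
extract_circuits <- function(graph) {
  stopifnot(length(graph$nodes) >= 1)
  g <- pathway_igraph(graph)
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  receptors <- names(indeg)[indeg == 0]
  effectors <- names(outdeg)[outdeg == 0]
  desc <- unique(unlist(lapply(receptors, function(r)
    names(igraph::subcomponent(g, r, mode = "out")))))
  out <- list()
  for (ef in effectors) {
    anc <- names(igraph::subcomponent(g, ef, mode = "in"))
    members <- union(intersect(desc, anc), ef)
    if (!any(receptors %in% members)) next   # unreachable effector
    out[[length(out) + 1L]] <- structure(list(
      circuit_id = paste0(graph$pathway_id, ":", ef),
      pathway_id = graph$pathway_id,
      effector = ef,
      members = sort(members),
      receptors = sort(intersect(receptors, members))), class = "circuit")
  }
  out
}

circuit_genes <- function(circuit, graph) {
  unique(unlist(graph$nodes[circuit$members], use.names = FALSE))
}

#' Build a mechanistic disease map from pathways and disease genes
#'
#' Extracts circuits from every pathway, keeps circuits whose member nodes
#' carry at least one disease gene, and applies two pathway-level quality
#' filters designed to protect the signal-propagation estimates: a pathway
#' is dropped when the fraction of its nodes lying on no circuit exceeds
#' `max_disconnected_frac`, or when its largest circuit has at most
#' `min_circuit_nodes` nodes.
#'
#' @param pathways non-empty list of [pathway_graph] objects.
#' @param rp_genes [gene_records] of disease genes.
#' @param max_disconnected_frac maximum tolerated fraction of off-circuit
#'   nodes per pathway (default 0.5).
#' @param min_circuit_nodes pathways whose largest circuit has at most
#'   this many nodes are dropped (default 3).
#' @return object of class `disease_map` with slots `circuits`,
#'   `rp_genes`, `hallmarks` (initially empty per circuit) and `pathways`
#'   (the retained [pathway_graph] objects, keyed by pathway id).
#' @export
build_disease_map <- function(pathways, rp_genes,
                              max_disconnected_frac = 0.5,
                              min_circuit_nodes = 3) {
  if (!length(pathways)) stop("empty pathway list")
  stopifnot(min_circuit_nodes >= 1)
  ids <- vapply(pathways, function(p) p$pathway_id, character(1))
  pathways <- pathways[order(ids)]   # input-order invariance
  circuits <- list(); kept <- list()
  for (p in pathways) {
    circ <- extract_circuits(p)
    sizes <- vapply(circ, function(cc) length(cc$members), integer(1))
    covered <- unique(unlist(lapply(circ, `[[`, "members")))
    disc_frac <- 1 - length(covered) / length(p$nodes)
    if (disc_frac > max_disconnected_frac) next
    if (!length(sizes) || max(sizes) <= min_circuit_nodes) next
    has_gene <- vapply(circ, function(cc)
      any(circuit_genes(cc, p) %in% rp_genes$entrez_id), logical(1))
    circ <- circ[has_gene]
    if (!length(circ)) next
    kept[[p$pathway_id]] <- p
    circuits <- c(circuits, circ)
  }
  if (!length(circuits))
    warning("no circuit contains a disease gene; the map is empty")
  names(circuits) <- vapply(circuits, `[[`, character(1), "circuit_id")
  hall <- stats::setNames(rep(list(character()), length(circuits)),
                          names(circuits))
  structure(list(circuits = circuits, rp_genes = rp_genes,
                 hallmarks = hall, pathways = kept),
            class = "disease_map")
}

#' @export
print.disease_map <- function(x, ...) {
  cat(sprintf("<disease_map> %d circuits across %d pathways, %d disease genes\n",
              length(x$circuits), length(x$pathways), nrow(x$rp_genes)))
  invisible(x)
}

#' Attach hallmark annotations to a disease map
#'
#' @param map a [disease_map].
#' @param annotation_table data frame with columns `circuit_id`,
#'   `hallmark` (one row per label); labels must come from
#'   [RP_HALLMARKS]. Unknown circuit ids are skipped with a warning;
#'   circuits absent from the table keep an empty label set.
#' @return the annotated [disease_map].
#' @export
attach_hallmarks <- function(map, annotation_table) {
  annotation_table <- as.data.frame(annotation_table)
  bad <- setdiff(unique(annotation_table$hallmark), RP_HALLMARKS)
  if (length(bad))
    stop("unknown hallmark label(s): ", paste(bad, collapse = ", "))
  unknown <- setdiff(unique(annotation_table$circuit_id), names(map$circuits))
  if (length(unknown)) {
    warning("skipping unknown circuit id(s): ", paste(unknown, collapse = ", "))
    annotation_table <-
      annotation_table[!annotation_table$circuit_id %in% unknown, , drop = FALSE]
  }
  for (cid in unique(annotation_table$circuit_id))
    map$hallmarks[[cid]] <- sort(unique(
      annotation_table$hallmark[annotation_table$circuit_id == cid]))
  map
}

#' Per-hallmark circuit coverage of a disease map
#'
#' Fraction of the map's circuits tagged by each hallmark; a circuit with
#' several hallmarks counts once towards each.
#'
#' @param map an annotated [disease_map].
#' @return named numeric vector over [RP_HALLMARKS].
#' @export
hallmark_coverage <- function(map) {
  n <- length(map$circuits)
  tags <- unlist(map$hallmarks, use.names = FALSE)
  cnt <- table(factor(tags, levels = RP_HALLMARKS))
  stats::setNames(as.vector(cnt) / max(n, 1), RP_HALLMARKS)
}

#' Read pathway graphs from node/edge TSV pairs
#'
#' Each pathway is stored as `<id>_nodes.tsv` (columns `node_id`,
#' `genes` with comma-separated entrez ids, empty for gene-less nodes) and
#' `<id>_edges.tsv` (columns `from`, `to`, `sign`).
#'
#' @param dir directory containing the TSV pairs.
#' @return named list of [pathway_graph] objects.
#' @export
read_pathway_dir <- function(dir) {
  node_files <- sort(list.files(dir, pattern = "_nodes\\.tsv$",
                                full.names = TRUE))
  out <- list()
  for (nf in node_files) {
    pid <- sub("_nodes\\.tsv$", "", basename(nf))
    nd <- utils::read.delim(nf, colClasses = "character", comment.char = "#")
    ed <- utils::read.delim(file.path(dir, paste0(pid, "_edges.tsv")),
                            colClasses = "character", comment.char = "#")
    nodes <- lapply(nd$genes, function(s)
      if (is.na(s) || !nzchar(s)) character() else strsplit(s, ",")[[1]])
    names(nodes) <- nd$node_id
    out[[pid]] <- pathway_graph(pid, nodes, ed)
  }
  out
}

#' Write pathway graphs as node/edge TSV pairs
#'
#' @param pathways list of [pathway_graph] objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_pathway_dir <- function(pathways, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in pathways) {
    nd <- data.frame(node_id = names(p$nodes),
                     genes = vapply(p$nodes, paste, character(1),
                                    collapse = ","))
    utils::write.table(nd, file.path(dir, paste0(p$pathway_id, "_nodes.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(p$edges,
                       file.path(dir, paste0(p$pathway_id, "_edges.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Export a disease map as a circuits table
#'
#' One row per circuit: id, pathway, effector, members, receptors, the
#' disease genes found among member nodes, and hallmark labels
#' (semicolon-separated list columns).
#'
#' @param map a [disease_map].
#' @return data frame.
#' @export
disease_map_table <- function(map) {
  rows <- lapply(map$circuits, function(cc) {
    p <- map$pathways[[cc$pathway_id]]
    genes <- intersect(circuit_genes(cc, p), map$rp_genes$entrez_id)
    data.frame(circuit_id = cc$circuit_id, pathway_id = cc$pathway_id,
               effector = cc$effector,
               member_nodes = paste(cc$members, collapse = ";"),
               receptors = paste(cc$receptors, collapse = ";"),
               rp_genes = paste(sort(genes), collapse = ";"),
               hallmarks = paste(map$hallmarks[[cc$circuit_id]],
                                 collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(circuit_id = character(), pathway_id = character(),
                      effector = character(), member_nodes = character(),
                      receptors = character(), rp_genes = character(),
                      hallmarks = character())
  out
}
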