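#' Construct a phenotype ontology
#'
#' An ontology is a directed acyclic graph of phenotype terms (`is_a`
#' parent edges) together with term-to-gene and term-to-disease annotation
#' tables carrying evidence codes. Term identifiers follow the HPO pattern
#' (`HP:NNNNNNN`) or any synthetic scheme.
#'
#' @param terms character vector of term ids.
#' @param parents named list mapping a term id to the character vector of
#'   its parent term ids (missing or empty entries denote roots).
#' @param gene_annotations data frame with columns `term_id`, `gene_id`,
#'   `evidence`; may be empty.
#' @param disease_annotations data frame with columns `term_id`,
#'   `disease_id`, `evidence`; may be empty.
#' @return an object of class `ontology`.
#' @export
ontology <- function(terms, parents = list(),
                     gene_annotations = empty_annotation("gene_id"),
                     disease_annotations = empty_annotation("disease_id")) {
  terms <- as.character(terms)
  stopifnot(!anyDuplicated(terms))
  parents <- parents[intersect(names(parents), terms)]
  edge_child <- rep(names(parents), lengths(parents))
  edge_parent <- unlist(parents, use.names = FALSE)
  if (length(edge_parent) && !all(edge_parent %in% terms))
    stop("parent term(s) absent from 'terms'")
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(terms)
  if (length(edge_child))
    g <- g + igraph::edges(rbind(edge_child, edge_parent))
  if (!igraph::is_dag(g)) stop("parent relation contains a cycle")
  for (ann in list(gene_annotations, disease_annotations)) {
    bad <- setdiff(unique(ann$term_id), terms)
    if (length(bad))
      stop("annotated term(s) not in ontology: ", paste(bad, collapse = ", "))
  }
  structure(list(terms = terms, parents = parents, graph = g,
                 gene_annotations = gene_annotations,
                 disease_annotations = disease_annotations),
            class = "ontology")
}

empty_annotation <- function(object_col) {
  out <- data.frame(term_id = character(), object = character(),
                    evidence = character(), stringsAsFactors = FALSE)
  names(out)[2] <- object_col
  out
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, %d gene annotations, %d disease annotations\n",
              length(x$terms), nrow(x$gene_annotations),
              nrow(x$disease_annotations)))
  invisible(x)
}

#' Read a minimal OBO file
#'
#' Parses `[Term]` stanzas keeping `id`, `name` and `is_a` lines, which is
#' sufficient for `is_a` transitive-closure reasoning. Other relationship
#' types and stanza kinds are ignored. Obsolete terms are dropped.
#'
#' @param path path to an OBO file.
#' @return an [ontology] with empty annotation tables.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  term_starts <- starts[lines[starts] == "[Term]"]
  ids <- character(); nms <- character(); parents <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (s in term_starts) {
    e <- min(bounds[bounds > s]) - 1L
    blk <- lines[s:e]
    if (any(grepl("^is_obsolete: *true", blk))) next
    id <- sub("^id: *", "", grep("^id:", blk, value = TRUE)[1])
    nm <- sub("^name: *", "", grep("^name:", blk, value = TRUE)[1])
    isa <- sub("^is_a: *([^ !]+).*$", "\\1", grep("^is_a:", blk, value = TRUE))
    ids <- c(ids, id); nms <- c(nms, nm)
    if (length(isa)) parents[[id]] <- isa
  }
  ont <- ontology(ids, parents)
  ont$term_names <- stats::setNames(nms, ids)
  ont
}

#' Read a 3-column annotation TSV
#'
#' Expects columns `term_id`, the object id (gene entrez id or disease id)
#' and `evidence`; comment lines starting with `#` are skipped.
#'
#' @param path TSV path.
#' @param object_col name for the object column (`"gene_id"` or
#'   `"disease_id"`).
#' @return data frame suitable for [ontology()] annotation slots.
#' @export
read_annotation_tsv <- function(path, object_col = "gene_id") {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 3) stop("annotation file needs 3 columns: ", path)
  df <- df[, 1:3]
  names(df) <- c("term_id", object_col, "evidence")
  df
}

term_ancestors <- function(ont, term) {
  if (!term %in% ont$terms) stop("unknown term: ", term)
  anc <- igraph::subcomponent(ont$graph, term, mode = "out")
  setdiff(names(anc), term)
}

#' Specificity of an ontology term
#'
#' The specificity level of a term is the number of distinct ancestor
#' terms it has under the transitive closure of the `is_a` relation
#' (the term itself is excluded; in a multi-parent DAG shared ancestors
#' count once). Roots have specificity 0; more specific phenotypes sit
#' deeper and have larger values.
#'
#' @param ont an [ontology].
#' @param term a term id present in `ont`.
#' @return a non-negative integer count.
#' @export
compute_specificity <- function(ont, term) {
  length(term_ancestors(ont, term))
}

#' Select disease-annotated terms inside a specificity window
#'
#' Returns the terms annotated to a disease whose specificity falls in
#' `[spec_min, spec_max]` and whose disease annotation carries one of the
#' accepted evidence codes. Very unspecific terms (few ancestors) tag
#' broad phenotypes shared by many diseases, while overly deep terms are
#' too isolated; the window keeps the informative band.
#'
#' @param ont an [ontology] with disease annotations.
#' @param disease_id disease identifier to look up.
#' @param spec_min,spec_max inclusive specificity window (defaults 7 and 15).
#' @param evidence accepted evidence codes (default `"TAS"`, traceable
#'   author statement).
#' @return character vector of term ids (possibly empty, with a warning
#'   when the disease has no annotations at all).
#' @export
select_disease_terms <- function(ont, disease_id, spec_min = 7, spec_max = 15,
                                 evidence = "TAS") {
  stopifnot(spec_min <= spec_max)
  ann <- ont$disease_annotations
  ann <- ann[ann$disease_id == disease_id, , drop = FALSE]
  if (nrow(ann) == 0) {
    warning("no annotations for disease ", disease_id)
    return(character())
  }
  ann <- ann[ann$evidence %in% evidence, , drop = FALSE]
  terms <- unique(ann$term_id)
  if (!length(terms)) return(character())
  spec <- vapply(terms, compute_specificity, integer(1), ont = ont)
  sort(terms[spec >= spec_min & spec <= spec_max])
}

#' Amplify a disease gene set through shared phenotype terms
#'
#' Screens the ontology's gene annotations for genes annotated to at least
#' `min_shared` of the disease phenotype terms and present in the pathway
#' gene universe. Such genes plausibly participate in the disease
#' mechanism even when not listed in the curated core set. Genes already
#' in `core_genes` keep their `core` label and are not duplicated.
#'
#' @param ont an [ontology] with gene annotations.
#' @param rp_terms non-empty character vector of disease phenotype terms.
#' @param min_shared minimum number of shared terms (default 10).
#' @param pathway_gene_universe gene ids present in the pathway collection.
#' @param core_genes optional [gene_records] of curated core genes.
#' @param evidence optional evidence-code filter for gene annotations
#'   (default `NULL`: accept all).
#' @return a [gene_records] data frame with `source = "hpo_amplified"`.
#' @export
amplify_genes <- function(ont, rp_terms, min_shared = 10,
                          pathway_gene_universe, core_genes = NULL,
                          evidence = NULL) {
  stopifnot(min_shared >= 1, length(rp_terms) > 0)
  if (min_shared > length(rp_terms)) {
    warning("min_shared exceeds the number of disease terms; nothing can pass")
    return(gene_records(character(), character(), source = "hpo_amplified"))
  }
  ann <- ont$gene_annotations
  if (!is.null(evidence)) ann <- ann[ann$evidence %in% evidence, , drop = FALSE]
  ann <- unique(ann[ann$term_id %in% rp_terms, c("term_id", "gene_id")])
  shared <- table(ann$gene_id)
  hits <- names(shared)[shared >= min_shared]
  hits <- intersect(hits, as.character(pathway_gene_universe))
  if (!is.null(core_genes)) hits <- setdiff(hits, core_genes$entrez_id)
  gene_records(hits, symbol = hits, source = "hpo_amplified")
}

#' Gene record sets
#'
#' A gene record set is a data frame with columns `entrez_id` (unique,
#' stored as character), `symbol` and `source` (`"core"` for curated
#' disease genes, `"hpo_amplified"` for phenotype-sharing additions).
#'
#' @param entrez_id gene identifiers.
#' @param symbol gene symbols (must be non-empty strings).
#' @param source `"core"` or `"hpo_amplified"` (recycled).
#' @return data frame of class `gene_records`.
#' @export
gene_records <- function(entrez_id, symbol, source = "core") {
  entrez_id <- as.character(entrez_id)
  symbol <- as.character(symbol)
  stopifnot(length(entrez_id) == length(symbol))
  if (anyDuplicated(entrez_id)) stop("duplicated entrez_id in gene set")
  if (length(symbol) && any(!nzchar(symbol))) stop("empty gene symbol")
  source <- rep_len(source, length(entrez_id))
  if (!all(source %in% c("core", "hpo_amplified")))
    stop("source must be 'core' or 'hpo_amplified'")
  structure(data.frame(entrez_id = entrez_id, symbol = symbol,
                       source = source, stringsAsFactors = FALSE),
            class = c("gene_records", "data.frame"))
}

#' Merge core and amplified gene sets
#'
#' Core membership wins on conflicts: a gene present in both sets keeps the
#' `core` label.
#'
#' @param core,amplified [gene_records] sets.
#' @return combined [gene_records].
#' @export
merge_gene_records <- function(core, amplified) {
  add <- amplified[!amplified$entrez_id %in% core$entrez_id, , drop = FALSE]
  out <- rbind(as.data.frame(core), as.data.frame(add))
  rownames(out) <- NULL
  structure(out, class = c("gene_records", "data.frame"))
}
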