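#' Rescale a relevance matrix to [-1, 1]
#'
#' Divides by the global maximum absolute value, preserving signs and the
#' relative magnitudes across the whole matrix; an all-zero matrix is
#' returned unchanged. The operation is idempotent.
#'
#' @param relevance non-empty circuit-by-target numeric matrix.
#' @return matrix of the same shape with values in `[-1, 1]`.
#' @export
rescale_relevance <- function(relevance) {
  relevance <- as.matrix(relevance)
  stopifnot(length(relevance) > 0)
  m <- max(abs(relevance))
  if (m == 0) return(relevance)
  relevance / m
}

within_dispersion <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(idx) {
    xs <- x[idx, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(1)))
}

log_w <- function(w) log(max(w, 1e-300))   # guards all-singleton zero dispersion

hclust_cut <- function(x, k, distance = "euclidean", linkage = "complete") {
  hc <- stats::hclust(stats::dist(x, method = distance), method = linkage)
  stats::cutree(hc, k = k)
}

#' Choose the number of clusters with the gap statistic
#'
#' For k = 1..`k_max` the log within-cluster dispersion of a hierarchical
#' clustering of the rows is compared against its expectation under
#' `n_ref` uniform reference samples drawn over the data's bounding box:
#' `Gap(k) = mean_ref log W*_k - log W_k`. The default rule picks k at
#' the biggest jump of the gap curve: the largest rise of `Gap(k)` above
#' the best gap achieved at any smaller k, counting only rises that
#' exceed the reference Monte-Carlo standard error (smaller wobbles are
#' sampling noise, not jumps); when no rise qualifies, k = 1.
#' Tibshirani's first-max standard-error rule is available via
#' `rule = "firstSEmax"`.
#'
#' @param x targets-by-scores numeric matrix.
#' @param k_max maximum number of clusters (<= number of rows).
#' @param n_ref reference samples (default 50).
#' @param seed integer seed for the reference draws.
#' @param rule `"jump"` (default) or `"firstSEmax"`.
#' @param distance,linkage hierarchical-clustering options.
#' @return the chosen k; the gap curve is attached as attribute `gap`.
#' @export
gap_statistic_k <- function(x, k_max, n_ref = 50, seed = 1,
                            rule = c("jump", "firstSEmax"),
                            distance = "euclidean", linkage = "complete") {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  stopifnot(k_max >= 1, n_ref >= 1)
  if (k_max > nrow(x)) stop("k_max exceeds the number of rows")
  if (k_max == 1) return(structure(1L, gap = 0))
  logw <- vapply(seq_len(k_max), function(k)
    log_w(within_dispersion(x, if (k == 1) rep(1L, nrow(x))
                            else hclust_cut(x, k, distance, linkage))),
    numeric(1))
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  ref_logw <- matrix(NA_real_, n_ref, k_max)
  set.seed(seed)
  for (b in seq_len(n_ref)) {
    xr <- sapply(seq_along(lo), function(j)
      stats::runif(nrow(x), lo[j], hi[j]))
    ref_logw[b, ] <- vapply(seq_len(k_max), function(k)
      log_w(within_dispersion(xr, if (k == 1) rep(1L, nrow(xr))
                              else hclust_cut(xr, k, distance, linkage))),
      numeric(1))
  }
  gap <- colMeans(ref_logw) - logw
  se <- apply(ref_logw, 2, stats::sd) * sqrt(1 + 1 / n_ref)
  k <- if (rule == "jump") {
    run <- cummax(gap)
    inc <- gap[-1] - run[-k_max]
    ok <- inc > se[-1]
    if (!any(ok)) 1L else which.max(ifelse(ok, inc, -Inf)) + 1L
  } else {
    hit <- which(gap[-k_max] >= gap[-1] - se[-1])
    if (length(hit)) hit[1] else k_max
  }
  structure(as.integer(k), gap = gap, se = se)
}

#' Cluster targets by their relevance profiles
#'
#' Agglomerative hierarchical clustering of the rows (default Euclidean
#' distance, complete linkage; Ward available via `linkage = "ward.D2"`),
#' cut at `k` clusters. Deterministic given its inputs.
#'
#' @param x targets-by-scores matrix with row names.
#' @param k number of clusters (<= rows).
#' @param distance,linkage see [stats::dist()] and [stats::hclust()].
#' @return data frame `target`, `cluster` plus attributes `k`, `linkage`,
#'   `distance`.
#' @export
cluster_targets <- function(x, k, distance = "euclidean",
                            linkage = "complete") {
  x <- as.matrix(x)
  stopifnot(k >= 1, k <= nrow(x))
  labels <- hclust_cut(x, k, distance, linkage)
  structure(data.frame(target = rownames(x), cluster = as.integer(labels),
                       stringsAsFactors = FALSE),
            k = k, linkage = linkage, distance = distance)
}

#' Over-representation of drug categories in a selection
#'
#' One-sided Fisher exact test (enrichment) per category at each
#' requested ATC truncation level, with Benjamini-Hochberg correction
#' across the categories of a level. Category membership of an id is
#' determined by truncating any of its codes to the level prefix
#' (ATC levels 1-4 correspond to 1, 3, 4 and 5 leading characters).
#'
#' @param selected ids of the selected drugs (subset of `background`).
#' @param background ids of all parsed drugs.
#' @param categories named list mapping an id to its character vector of
#'   full ATC codes (ids without codes count as uncategorized).
#' @param levels integer ATC levels to test (default `1:4`).
#' @param alpha FDR significance threshold used for the `significant`
#'   flag (default 0.05).
#' @return data frame `category`, `level`, `selected_in`, `selected_out`,
#'   `background_in`, `p`, `fdr`, `significant`.
#' @export
overrepresentation <- function(selected, background, categories,
                               levels = 1:4, alpha = 0.05) {
  if (!all(selected %in% background))
    stop("'selected' must be a subset of 'background'")
  atc_nchar <- c(1L, 3L, 4L, 5L)
  out <- list()
  for (lev in levels) {
    w <- atc_nchar[lev]
    memb <- lapply(categories, function(codes)
      unique(substr(codes, 1, w)[nchar(codes) >= w]))
    cats <- sort(unique(unlist(memb[background])))
    for (cat in cats) {
      in_cat <- names(memb)[vapply(memb, function(cc) cat %in% cc, logical(1))]
      a <- sum(selected %in% in_cat)
      b <- length(selected) - a
      cc <- sum(background %in% in_cat & !background %in% selected)
      dd <- length(background) - length(selected) - cc
      p <- if (length(selected) == 0) 1 else
        stats::fisher.test(matrix(c(a, b, cc, dd), 2, byrow = TRUE),
                           alternative = "greater")$p.value
      out[[length(out) + 1L]] <- data.frame(
        category = cat, level = lev, selected_in = a, selected_out = b,
        background_in = a + cc, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(category = character(), level = integer(),
                      selected_in = integer(), selected_out = integer(),
                      background_in = integer(), p = numeric(),
                      fdr = numeric(), significant = logical()))
  out$fdr <- NA_real_
  for (lev in unique(out$level)) {
    i <- out$level == lev
    out$fdr[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  out$significant <- out$fdr <= alpha
  rownames(out) <- NULL
  out
}

.action_map <- list(
  activator = c("agonist", "activator", "potentiator", "inducer",
                "stimulator", "positive allosteric modulator"),
  inhibitor = c("antagonist", "inhibitor", "blocker",
                "negative allosteric modulator", "suppressor"),
  modulator = c("modulator", "regulator"),
  ligand    = c("ligand", "binder"))

#' Simplify a pharmacological action string into five effect classes
#'
#' Case-insensitive mapping of DrugBank-style action strings onto
#' `activator`, `inhibitor`, `modulator`, `ligand`; anything unmatched
#' falls through to `other`.
#'
#' @param action character vector of action strings.
#' @return character vector of effect classes.
#' @export
simplify_action <- function(action) {
  a <- trimws(tolower(as.character(action)))
  out <- rep("other", length(a))
  for (eff in names(.action_map)) out[a %in% .action_map[[eff]]] <- eff
  out
}

#' Parse a drug-target table
#'
#' Expects columns `drug_id`, `drug_name`, `entrez_id`, `action`,
#' optionally `approved`, `known_action` and `atc` (semicolon-separated
#' codes). Adds the simplified `effect` column.
#'
#' @param path TSV path.
#' @return data frame of drug-target records.
#' @export
read_drug_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", comment.char = "#")
  need <- c("drug_id", "drug_name", "entrez_id", "action")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("drug table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$effect <- simplify_action(df$action)
  df
}

#' Keep drugs whose effect opposes the observed dysregulation
#'
#' A drug-target record passes when its target is among the relevant
#' targets, has a known dysregulation direction in the disease model, and
#' the drug's simplified effect counteracts it: upregulated targets
#' require an inhibitor, downregulated ones an activator. Ambiguous
#' effects (`modulator`, `ligand`, `other`) never pass.
#'
#' @param drugs drug-target data frame with columns `entrez_id` and
#'   `effect` (see [read_drug_table()]).
#' @param dysregulation named character vector, target gene id to
#'   `"up"`/`"down"`.
#' @param relevant_targets character vector of relevant target gene ids.
#' @return the passing subset of `drugs`, in input order.
#' @export
filter_reversal_drugs <- function(drugs, dysregulation, relevant_targets) {
  tg <- as.character(drugs$entrez_id)
  dir <- dysregulation[tg]
  keep <- tg %in% relevant_targets & !is.na(dir) &
    ((dir == "up" & drugs$effect == "inhibitor") |
     (dir == "down" & drugs$effect == "activator"))
  drugs[keep, , drop = FALSE]
}

hallmark_circuits <- function(hallmarks) {
  labs <- sort(unique(unlist(hallmarks, use.names = FALSE)))
  stats::setNames(lapply(labs, function(h)
    names(hallmarks)[vapply(hallmarks, function(x) h %in% x, logical(1))]),
    labs)
}

#' Hallmark coverage of a single drug
#'
#' For each hallmark module: the fraction of its circuits in which at
#' least one of the drug's targets is a selected (relevant) target.
#'
#' @param drug_targets character vector of the drug's target gene ids.
#' @param selection circuit-by-target logical selection matrix.
#' @param hallmarks named list circuit id to hallmark labels.
#' @return named numeric vector over the hallmarks present.
#' @export
drug_hallmark_coverage <- function(drug_targets, selection, hallmarks) {
  hc <- hallmark_circuits(hallmarks)
  tg <- intersect(drug_targets, colnames(selection))
  vapply(hc, function(circs) {
    circs <- intersect(circs, rownames(selection))
    if (!length(circs)) return(0)
    if (!length(tg)) return(0)
    hit <- rowSums(selection[circs, tg, drop = FALSE]) > 0
    mean(hit)
  }, numeric(1))
}

#' Shared influence of selected targets between hallmark modules
#'
#' For hallmark h and target t the weight is
#' `coverage(h, t) * mean |relevance|` over h's circuits where t is
#' selected, coverage being the selected-circuit fraction. The shared
#' influence of two hallmarks sums the minimum of the two weights over
#' targets selected in both; the diagonal holds each hallmark's total
#' weight.
#'
#' @param selection circuit-by-target logical matrix.
#' @param relevance circuit-by-target signed relevance matrix.
#' @param hallmarks named list circuit id to hallmark labels.
#' @return symmetric hallmark-by-hallmark weight matrix.
#' @export
hallmark_shared_influence <- function(selection, relevance, hallmarks) {
  hc <- hallmark_circuits(hallmarks)
  labs <- names(hc)
  targets <- colnames(selection)
  w <- matrix(0, length(labs), length(targets),
              dimnames = list(labs, targets))
  for (h in labs) {
    circs <- intersect(hc[[h]], rownames(selection))
    if (!length(circs)) next
    for (t in targets) {
      sel <- selection[circs, t]
      if (!any(sel)) next
      cov <- mean(sel)
      w[h, t] <- cov * mean(abs(relevance[circs, t][sel]))
    }
  }
  out <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (h1 in labs) for (h2 in labs) {
    if (h1 == h2) { out[h1, h2] <- sum(w[h1, ]); next }
    both <- w[h1, ] > 0 & w[h2, ] > 0
    out[h1, h2] <- sum(pmin(w[h1, both], w[h2, both]))
  }
  out
}
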