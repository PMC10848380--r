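test_that("relevance rescaling divides by the global maximum magnitude", {
  m <- matrix(c(4, -2, 1, 0), 2, 2)
  r <- rescale_relevance(m)
  expect_equal(r[1, 1], 1)
  expect_equal(r[2, 1], -0.5)
  expect_equal(rescale_relevance(r), r)          # idempotent
  z <- matrix(0, 2, 2)
  expect_equal(rescale_relevance(z), z)
})

test_that("the gap statistic separates one cloud from two", {
  two_clouds <- function(seed) {
    set.seed(seed)
    rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
          matrix(rnorm(40, 8, 0.3), 20, 2))
  }
  one_cloud <- function(seed) {
    set.seed(seed + 100)
    matrix(rnorm(80, 0, 1), 40, 2)
  }
  for (seed in 1:5) {
    expect_identical(as.integer(gap_statistic_k(two_clouds(seed), k_max = 6,
                                                seed = seed)), 2L)
    expect_identical(as.integer(gap_statistic_k(one_cloud(seed), k_max = 6,
                                                seed = seed)), 1L)
  }
  expect_identical(as.integer(gap_statistic_k(one_cloud(1), k_max = 1,
                                              seed = 1)), 1L)
  expect_error(gap_statistic_k(one_cloud(1)[1:3, ], k_max = 5, seed = 1),
               "k_max")
})

test_that("hierarchical clustering of targets is deterministic and exact on separated groups", {
  set.seed(12)
  x <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
             matrix(rnorm(20, 5, 0.1), 10, 2),
             matrix(rnorm(20, 10, 0.1), 10, 2))
  rownames(x) <- sprintf("t%02d", 1:30)
  cl <- cluster_targets(x, 3)
  expect_identical(length(unique(cl$cluster[1:10])), 1L)
  expect_identical(length(unique(cl$cluster[11:20])), 1L)
  expect_identical(length(unique(cl$cluster[21:30])), 1L)
  expect_identical(length(unique(cl$cluster)), 3L)
  # permuting rows permutes labels consistently
  perm <- sample(30)
  cl2 <- cluster_targets(x[perm, ], 3)
  joined <- merge(cl, cl2, by = "target")
  tab <- table(joined$cluster.x, joined$cluster.y)
  expect_true(all(rowSums(tab > 0) == 1))   # one-to-one label mapping
  # duplicated rows co-cluster; k = n gives singletons
  dup <- x[c(1, 1, 15, 25), ]; rownames(dup) <- paste0("d", 1:4)
  cld <- cluster_targets(dup, 3)
  expect_identical(cld$cluster[1], cld$cluster[2])
  expect_identical(length(unique(cluster_targets(dup, 4)$cluster)), 4L)
})

test_that("over-representation p-values match exhaustive hypergeometric enumeration", {
  # worked example: N = 10 drugs, 4 in the category, 4 selected, 3 inside
  ids <- paste0("d", 1:10)
  categories <- stats::setNames(as.list(c(rep("A01AA", 4), rep("B02BB", 6))),
                                ids)
  res <- overrepresentation(c("d1", "d2", "d3", "d5"), ids, categories,
                            levels = 1)
  expect_equal(res$p[res$category == "A"], 25 / 210, tolerance = 1e-12)

  # property: agreement with brute-force enumeration over random draws
  set.seed(33)
  for (rep in 1:15) {
    N <- sample(8:30, 1)
    ids <- paste0("x", seq_len(N))
    K <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    categories <- stats::setNames(
      as.list(c(rep("C01AA", K), rep("D01AA", N - K))), ids)
    selected <- sample(ids, n)
    res <- overrepresentation(selected, ids, categories, levels = 1)
    a <- sum(selected %in% ids[1:K])
    expect_equal(res$p[res$category == "C"],
                 fisher_enrich_oracle(a, K, n, N), tolerance = 1e-10)
  }

  # degenerate situations
  res <- overrepresentation(character(), ids, categories, levels = 1)
  expect_true(all(res$p == 1))
  res <- overrepresentation(ids, ids, categories, levels = 1)
  expect_true(all(res$p == 1))
})

test_that("BH adjustment is monotone within each ATC level", {
  set.seed(7)
  ids <- paste0("d", 1:40)
  codes <- paste0(sample(LETTERS[1:5], 40, TRUE),
                  sprintf("%02d", sample(1:3, 40, TRUE)), "A", "A")
  categories <- stats::setNames(as.list(codes), ids)
  res <- overrepresentation(sample(ids, 12), ids, categories, levels = 1:4)
  for (lev in 1:4) {
    sub <- res[res$level == lev, ]
    sub <- sub[order(sub$p), ]
    expect_true(all(diff(sub$fdr) >= -1e-12))
    expect_true(all(sub$fdr >= sub$p - 1e-12))
  }
})

test_that("action strings simplify into the five effect classes", {
  expect_identical(simplify_action(c("Antagonist", "Potentiator", "chelator",
                                     "Positive allosteric modulator",
                                     "Ligand", "modulator", "binder")),
                   c("inhibitor", "activator", "other", "activator",
                     "ligand", "modulator", "ligand"))
})

test_that("reversal filtering keeps only counteracting drugs on relevant targets", {
  drugs <- rp_reversal_drug_table()
  drugs$effect <- simplify_action(drugs$action)
  dys <- rd10_dysregulation_table()
  kept <- filter_reversal_drugs(drugs, dys,
                                relevant_targets = names(dys))
  # the upregulated GABA-A receptor subunit keeps its antagonists
  expect_true("Flumazenil" %in% kept$drug_name)
  # the downregulated elongase keeps its potentiator
  expect_true("Omega-3-carboxylic acids" %in% kept$drug_name)
  # an agonist of an upregulated target is dropped
  expect_false("Taurine" %in% kept$drug_name)
  expect_true(all(kept$drug_id %in% drugs$drug_id))
  # subset and order invariance
  perm <- sample(nrow(drugs))
  kept2 <- filter_reversal_drugs(drugs[perm, ], dys, names(dys))
  expect_setequal(paste(kept2$drug_id, kept2$entrez_id),
                  paste(kept$drug_id, kept$entrez_id))
  # targets outside the relevant set never pass
  expect_identical(nrow(filter_reversal_drugs(drugs, dys, character())), 0L)
})

test_that("drug hallmark coverage counts affected circuits per module", {
  sel <- matrix(FALSE, 6, 2, dimnames = list(paste0("c", 1:6),
                                             c("t1", "t2")))
  sel[c("c1"), "t1"] <- TRUE
  sel[, "t2"] <- TRUE
  hall <- list(c1 = "Apoptosis", c2 = "Apoptosis", c3 = "Apoptosis",
               c4 = c("Apoptosis", "Necrosis"), c5 = "Necrosis",
               c6 = "Necrosis")
  cov <- drug_hallmark_coverage("t1", sel, hall)
  expect_equal(unname(cov["Apoptosis"]), 0.25)   # 1 of 4 circuits
  expect_equal(unname(cov["Necrosis"]), 0)
  expect_equal(unname(drug_hallmark_coverage("t2", sel, hall)),
               c(1, 1))
  expect_equal(unname(drug_hallmark_coverage("t9", sel, hall)), c(0, 0))
})

test_that("shared hallmark influence follows the min-weight rule", {
  sel <- matrix(FALSE, 4, 2, dimnames = list(paste0("c", 1:4),
                                             c("t1", "t2")))
  sel[c("c1", "c2"), "t1"] <- TRUE    # t1 selected in both modules
  sel["c3", "t2"] <- TRUE             # t2 only in h2
  rel <- matrix(0, 4, 2, dimnames = dimnames(sel))
  rel["c1", "t1"] <- 0.8; rel["c2", "t1"] <- -0.4; rel["c3", "t2"] <- 0.5
  hall <- list(c1 = "Apoptosis", c2 = "Necrosis", c3 = "Necrosis",
               c4 = "Necrosis")
  sh <- hallmark_shared_influence(sel, rel, hall)
  w_h1_t1 <- 1 * 0.8                 # full coverage of h1, |rel| = 0.8
  w_h2_t1 <- (1 / 3) * 0.4           # one of three circuits, |rel| = 0.4
  w_h2_t2 <- (1 / 3) * 0.5
  expect_equal(sh["Apoptosis", "Necrosis"], min(w_h1_t1, w_h2_t1))
  expect_equal(sh["Necrosis", "Apoptosis"], sh["Apoptosis", "Necrosis"])
  expect_equal(sh["Apoptosis", "Apoptosis"], w_h1_t1)
  expect_equal(sh["Necrosis", "Necrosis"], w_h2_t1 + w_h2_t2)
  # disjoint target sets share nothing
  sel2 <- sel; sel2[c("c1", "c2"), "t1"] <- FALSE; sel2["c4", "t1"] <- TRUE
  expect_equal(hallmark_shared_influence(sel2, rel, hall)["Apoptosis",
                                                          "Necrosis"], 0)
})
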