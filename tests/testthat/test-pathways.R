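test_that("circuits are extracted per effector with full path membership", {
  circ <- extract_circuits(toy_chain_graph())
  expect_length(circ, 1)
  expect_identical(circ[[1]]$effector, "E")
  expect_setequal(circ[[1]]$members, c("R", "A", "E"))
  expect_identical(circ[[1]]$receptors, "R")
  expect_identical(circ[[1]]$circuit_id, "toy:E")

  # two receptors converging on one effector merge into one circuit
  g <- pathway_graph("p2", list(R1 = "1", R2 = "2", A = "3", E = "4"),
                     data.frame(from = c("R1", "R2", "A"),
                                to = c("A", "A", "E"), sign = "activation"))
  circ <- extract_circuits(g)
  expect_length(circ, 1)
  expect_setequal(circ[[1]]$members, c("R1", "R2", "A", "E"))
  expect_setequal(circ[[1]]$receptors, c("R1", "R2"))

  # isolated node: trivial single-node circuit
  g1 <- pathway_graph("p3", list(N = character()),
                      data.frame(from = character(), to = character(),
                                 sign = character()))
  circ <- extract_circuits(g1)
  expect_length(circ, 1)
  expect_identical(circ[[1]]$members, "N")
})

test_that("circuit membership matches brute-force path enumeration", {
  set.seed(42)
  for (rep in 1:20) {
    g <- random_dag(sample(4:9, 1))
    circ <- extract_circuits(g)
    got <- sort(unique(unlist(lapply(circ, `[[`, "members"))))
    expect_identical(got, path_nodes_bruteforce(g))
  }
})

test_that("circuit ids are globally unique across a pathway collection", {
  paths <- simulate_pathways(small_sim_config())
  ids <- unlist(lapply(paths$graphs,
                       function(g) vapply(extract_circuits(g), `[[`,
                                          character(1), "circuit_id")))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("disease-map filters drop small and disconnected pathways", {
  rp <- gene_records("7", "G7")
  # largest circuit has 3 nodes -> whole pathway excluded at the default
  small <- pathway_graph("small", list(R = "7", A = "8", E = "9"),
                         data.frame(from = c("R", "A"), to = c("A", "E"),
                                    sign = "activation"))
  big <- pathway_graph("big", list(R = "7", A = "8", B = "10", E = "9"),
                       data.frame(from = c("R", "A", "B"),
                                  to = c("A", "B", "E"),
                                  sign = "activation"))
  map <- build_disease_map(list(small, big), rp)
  expect_identical(names(map$pathways), "big")
  expect_identical(length(map$circuits), 1L)

  # disconnected-node fraction filter
  nodes <- c(list(R = "7", A = "8", B = "10", E = "9"),
             stats::setNames(replicate(5, character(), simplify = FALSE),
                             paste0("iso_x", 1:5)))
  # nodes inside receptor-less 2-cycles lie on no receptor->effector
  # path: 4 of the 9 nodes are off-circuit, beyond the 0.3 tolerance
  edges <- data.frame(from = c("R", "A", "B", "iso_x1", "iso_x2",
                               "iso_x3", "iso_x4"),
                      to = c("A", "B", "E", "iso_x2", "iso_x1",
                             "iso_x4", "iso_x3"),
                      sign = "activation")
  messy <- pathway_graph("messy", nodes, edges)
  expect_identical(names(build_disease_map(list(messy, big), rp,
                                           max_disconnected_frac = 0.3)$pathways),
                   "big")

  # only circuits carrying a disease gene are kept
  other <- pathway_graph("other", list(R = "77", A = "88", B = "99", E = "66"),
                         data.frame(from = c("R", "A", "B"),
                                    to = c("A", "B", "E"),
                                    sign = "activation"))
  map <- build_disease_map(list(big, other), rp)
  expect_identical(names(map$circuits), "big:E")
  expect_warning(build_disease_map(list(other), rp), "empty")
  expect_error(build_disease_map(list(), rp), "empty pathway list")
})

test_that("disease-map construction is invariant to pathway order", {
  cfg <- small_sim_config()
  paths <- simulate_pathways(cfg)
  core <- gene_records(paths$manifest$core_genes,
                       paths$manifest$core_genes)
  m1 <- build_disease_map(paths$graphs, core)
  m2 <- build_disease_map(rev(paths$graphs), core)
  expect_identical(disease_map_table(m1), disease_map_table(m2))
})

test_that("hallmark annotation validates labels and skips unknown circuits", {
  rp <- gene_records("7", "G7")
  big <- pathway_graph("big", list(R = "7", A = "8", B = "10", E = "9"),
                       data.frame(from = c("R", "A", "B"),
                                  to = c("A", "B", "E"),
                                  sign = "activation"))
  map <- build_disease_map(list(big), rp)
  tab <- data.frame(circuit_id = "big:E",
                    hallmark = c("Apoptosis", "Neuronal processes"))
  map2 <- attach_hallmarks(map, tab)
  expect_length(map2$hallmarks[["big:E"]], 2)
  expect_error(attach_hallmarks(map, data.frame(circuit_id = "big:E",
                                                hallmark = "Metabolism")),
               "Metabolism")
  expect_warning(attach_hallmarks(map, data.frame(circuit_id = "nope:X",
                                                  hallmark = "Apoptosis")),
                 "unknown circuit")
  # empty table leaves circuits unannotated
  expect_identical(map$hallmarks[["big:E"]], character())
  # a multi-hallmark circuit counts once per hallmark in the coverage
  cov <- hallmark_coverage(map2)
  expect_identical(unname(cov[c("Apoptosis", "Neuronal processes")]),
                   c(1, 1))
  expect_identical(sum(cov), 2)
})

test_that("pathway graphs round-trip through the TSV layout", {
  paths <- simulate_pathways(small_sim_config())
  dir <- withr::local_tempdir()
  write_pathway_dir(paths$graphs, dir)
  back <- read_pathway_dir(dir)
  expect_identical(names(back), names(paths$graphs))
  g0 <- paths$graphs[[1]]; g1 <- back[[1]]
  expect_identical(g1$nodes[names(g0$nodes)], g0$nodes)
  expect_identical(g1$edges$from, g0$edges$from)
  expect_identical(g1$edges$sign, g0$edges$sign)
})

test_that("pathway graph validation rejects malformed input", {
  expect_error(pathway_graph("p", list(A = "1"),
                             data.frame(from = "A", to = "B",
                                        sign = "activation")),
               "not in nodes")
  expect_error(pathway_graph("p", list(A = "1"),
                             data.frame(from = "A", to = "A",
                                        sign = "activation")),
               "self-loop")
  expect_error(pathway_graph("p", list(A = "1", B = "2"),
                             data.frame(from = "A", to = "B", sign = "up")),
               "sign")
})
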