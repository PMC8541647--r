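test_that("bond labels classify into backbone and tailoring", {
  expect_identical(classify_edge("amide"), "backbone")
  expect_identical(classify_edge(c("double-amide", "thiazole", "oxazole",
                                   "pyrimidine")),
                   rep("backbone", 4))
  expect_identical(classify_edge("ester"), "tailoring")
  expect_identical(classify_edge("unrecognized_xyz"), "tailoring")
  expect_error(classify_edge(""), "empty")
})

test_that("backbone components split at tailoring edges and drop small ones", {
  g <- path_graph("cpd", c("ala", "gly", "val", "leu", "ser"),
                  bonds = c("amide", "amide", "ester", "amide"))
  comps <- backbone_components(g)
  expect_length(comps, 2)
  expect_identical(sort(vapply(comps, function(c) nrow(c$nodes), 0L)),
                   c(2L, 3L))

  # 1 supported + 2 unsupported monomers: discarded at min_supported = 2
  nodes <- data.frame(id = c("a", "b", "c"),
                      residue = c("ala", "xx1", "xx2"),
                      supported = c(TRUE, FALSE, FALSE),
                      methylated = -1L, stereo = 0L)
  edges <- data.frame(from = c("a", "b"), to = c("b", "c"), bond = "amide")
  g2 <- monomer_graph("cpd2", nodes, edges)
  expect_length(backbone_components(g2, min_supported = 2), 0)
  expect_length(backbone_components(g2, min_supported = 1), 1)

  # no tailoring edges: one component equal to the whole graph
  g3 <- path_graph("cpd3", c("ala", "gly", "val"))
  comps3 <- backbone_components(g3)
  expect_length(comps3, 1)
  expect_identical(nrow(comps3[[1]]$nodes), 3L)
})

test_that("paths, cycles and branched components linearize as specified", {
  alpha <- toy_alphabet()
  # directed path -> single candidate in edge direction
  p <- backbone_components(path_graph("p", c("ala", "gly", "val")))[[1]]
  cands <- linearize_component(p, alpha)
  expect_length(cands, 1)
  expect_identical(cands[[1]]$monomers$residue, c("ala", "gly", "val"))

  # directed 4-cycle -> 4 rotations in edge direction
  cy <- backbone_components(cycle_graph("c", c("ala", "gly", "val",
                                               "leu")))[[1]]
  cands <- linearize_component(cy, alpha)
  expect_length(cands, 4)
  seqs <- sort(vapply(cands, function(x)
    paste(x$monomers$residue, collapse = ""), ""))
  expect_identical(seqs, sort(c("alaglyvalleu", "glyvalleuala",
                                "valleualagly", "leualaglyval")))
  expect_true(all(vapply(cands, `[[`, TRUE, "cyclic")))

  # "Y" component (two in-edges into one node): no Hamiltonian path
  nodes <- data.frame(id = c("a", "b", "c"), residue = "ala",
                      supported = TRUE, methylated = -1L, stereo = 0L)
  edges <- data.frame(from = c("a", "b"), to = c("c", "c"), bond = "amide")
  y <- monomer_graph("y", nodes, edges)
  expect_warning(cands <- linearize_component(y, alpha), "Hamiltonian")
  expect_length(cands, 0)
})

test_that("linearization agrees with brute-force permutation enumeration", {
  alpha <- toy_alphabet()
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(2:7, 1)
    type <- sample(c("path", "cycle", "random"), 1)
    ids <- sprintf("n%d", seq_len(n))
    nodes <- data.frame(id = ids,
                        residue = sample(as.character(alpha), n, TRUE),
                        supported = TRUE, methylated = -1L, stereo = 0L)
    edges <- switch(type,
      path = data.frame(from = ids[-n], to = ids[-1], bond = "amide"),
      cycle = data.frame(from = ids, to = ids[c(2:n, 1)], bond = "amide"),
      random = {
        all_pairs <- expand.grid(from = ids, to = ids,
                                 stringsAsFactors = FALSE)
        all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
        take <- sample(nrow(all_pairs), min(n + 2, nrow(all_pairs)))
        cbind(all_pairs[take, ], bond = "amide")
      })
    g <- monomer_graph("r", nodes, edges)
    comps <- backbone_components(g, min_supported = 1)
    for (comp in comps) {
      got <- suppressWarnings(
        linearize_component(comp, alpha, max_candidates = 50000L))
      got_keys <- sort(unique(vapply(got, function(x)
        paste(x$node_ids, collapse = ">"), "")))
      expect_identical(got_keys, oracle_component_orderings(comp),
                       label = paste("type", type, "n", n, "rep", rep))
    }
  }
})

test_that("every candidate visits each source node exactly once", {
  alpha <- toy_alphabet()
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    g <- if (runif(1) < 0.5)
      path_graph("h", sample(as.character(alpha), n, TRUE))
    else cycle_graph("h", sample(as.character(alpha), n, TRUE))
    for (comp in backbone_components(g))
      for (cand in linearize_component(comp, alpha))
        expect_setequal(cand$node_ids, comp$nodes$id)
  }
})

test_that("component permutation follows the acyclic-and-at-most-3 rule", {
  alpha <- toy_alphabet()
  one <- function(res) list(list(
    monomers = toy_nrp_seq(res), node_ids = paste0(res, seq_along(res)),
    component_id = paste(res, collapse = ""), cyclic = FALSE,
    cycle_start = NA_character_))
  # 2 acyclic components X, Y -> X, Y, XY, YX
  out <- combine_components(list(one("ala"), one("gly")), TRUE)
  expect_length(out, 4)
  seqs <- vapply(out, function(x) paste(x$monomers$residue,
                                        collapse = "+"), "")
  expect_setequal(seqs, c("ala", "gly", "ala+gly", "gly+ala"))

  # candidate counts k + k! for k = 2, 3; k singletons for k = 4
  for (k in 2:4) {
    comps <- lapply(seq_len(k), function(i) one(as.character(alpha)[i]))
    got <- length(combine_components(comps, TRUE))
    expect_equal(got, if (k <= 3) k + factorial(k) else k)
  }

  # cyclic graph suppresses permutations, singles still emitted
  expect_length(combine_components(list(one("ala"), one("gly")), FALSE), 2)
  # 1 component -> unchanged
  expect_length(combine_components(list(one("ala")), TRUE), 1)
})

test_that("unsupported residues map to the unsupported sign", {
  alpha <- toy_alphabet()
  nodes <- data.frame(id = c("a", "b", "c"),
                      residue = c("ala", "weirdstuff", "gly"),
                      supported = c(TRUE, FALSE, TRUE),
                      methylated = -1L, stereo = 0L)
  edges <- data.frame(from = c("a", "b"), to = c("b", "c"), bond = "amide")
  g <- monomer_graph("u", nodes, edges)
  cands <- linearize_graph(g, alpha)
  expect_length(cands, 1)
  expect_identical(cands[[1]]$monomers$residue, c("ala", "unk", "gly"))
})

test_that("monomer graphs round-trip through the JSON format", {
  g1 <- path_graph("cpd_a", c("ala", "gly", "val"))
  g2 <- cycle_graph("cpd_b", c("leu", "ser", "ala"))
  f <- withr::local_tempfile(fileext = ".json")
  write_monomer_graphs(list(g1, g2), f)
  back <- read_monomer_graphs(f)
  expect_length(back, 2)
  expect_identical(back[[1]]$nodes$residue, g1$nodes$residue)
  expect_identical(back[[2]]$edges$bond, g2$edges$bond)
  expect_identical(back[[2]]$id, "cpd_b")
})
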