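test_that("residue match and mismatch probabilities follow the model", {
  p <- toy_params()
  # match at top level: log PmatchA(5) = log 0.6
  expect_equal(residue_log_p("ala", 5, "ala", p), log(0.6))
  # mismatch: log((1 - 0.6) * PA(ala) / (1 - PA(val)))
  expect_equal(residue_log_p("ala", 5, "val", p),
               log(0.4 * 0.10 / (1 - 0.05)))
  # two unsupported residues never match
  expect_equal(residue_log_p("unk", 5, "unk", p),
               log(0.4 * 0.20 / (1 - 0.20)))
})

test_that("null-model residue probabilities normalize", {
  p <- toy_params()
  # direct value: PA(ala) / (1 - PA(unk)) = 0.10 / 0.8
  expect_equal(null_residue_log_p("ala", p), log(0.125))
  # sum over the alphabet (excluding unk) of the null probabilities is 1
  named <- names(p$p_a)[names(p$p_a) != "unk"]
  total <- sum(vapply(named, function(a)
    exp(null_residue_log_p(a, p)), 0))
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("methylation and stereo terms branch on the trit states", {
  p <- toy_params()
  # undetermined NRP stereo contributes exactly zero
  expect_identical(modification_log_p(0L, 1L, "stereo", p), 0)
  expect_identical(modification_log_p(0L, 0L, "stereo", p), 0)
  # agreement / disagreement / undefined-BGC branches
  expect_equal(modification_log_p(1L, 1L, "methylation", p), log(0.2))
  expect_equal(modification_log_p(1L, -1L, "methylation", p), log(0.1))
  expect_equal(modification_log_p(1L, 0L, "methylation", p), log(0.3))
  expect_equal(modification_log_p(-1L, 1L, "stereo", p), log(0.2))
  expect_equal(modification_log_p(-1L, -1L, "stereo", p), log(0.4))
})

test_that("column probabilities compose additively", {
  p <- toy_params()
  nrp <- toy_nrp_seq("ala", m = -1, e = -1)
  bgc <- toy_bgc_seq("ala", s = 95, m = -1, e = -1)
  cl <- column_log_p(nrp, bgc, p)
  expect_equal(cl$log_p, sum(cl$parts))
  expect_equal(cl$parts[["a"]], residue_log_p("ala", 5, "ala", p))
  expect_equal(cl$parts[["m"]],
               modification_log_p(-1L, -1L, "methylation", p))
  expect_equal(cl$parts[["e"]], modification_log_p(-1L, -1L, "stereo", p))

  # deletion: log Pdeletion regardless of the BGC monomer
  for (bg in list(toy_bgc_seq("gly", s = 10), toy_bgc_seq("val", s = 99)))
    expect_equal(column_log_p(NULL, bg, p)$log_p, log(0.04))

  # insertion: log(Pins * PA * PM * PE)
  expect_equal(column_log_p(toy_nrp_seq("ala", m = -1, e = -1), NULL,
                            p)$log_p,
               log(0.05 * 0.10 * 0.7 * 0.6))
  expect_error(column_log_p(NULL, NULL, p), "gap-vs-gap")
})

test_that("aligning against an all-undefined line scores exactly zero", {
  p <- toy_params()
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(1:6, 1)
    nrp <- toy_nrp_seq(sample(names(p$p_a), n, TRUE),
                       m = sample(c(-1, 1), n, TRUE),
                       e = sample(c(-1, 0, 1), n, TRUE))
    null_line <- do.call(rbind,
                         replicate(n, bgc_monomer(undefined = TRUE),
                                   simplify = FALSE))
    forced <- align_sequences(nrp, null_line, p, allow_gaps = FALSE)
    expect_equal(forced$score, 0)
    free <- align_sequences(nrp, null_line, p)
    expect_gte(free$score, -1e-12)
  }
})

test_that("NW alignment equals exhaustive enumeration on short pairs", {
  p <- toy_params()
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(1:4, 1); m <- sample(1:4, 1)
    nrp <- toy_nrp_seq(sample(c("ala", "gly", "val"), n, TRUE),
                       m = sample(c(-1, 1), n, TRUE),
                       e = sample(c(-1, 0, 1), n, TRUE))
    bgc <- toy_bgc_seq(sample(c("ala", "gly", "val"), m, TRUE),
                       s = sample(0:100, m, TRUE),
                       m = sample(c(-1, 1), m, TRUE),
                       e = sample(c(-1, 1), m, TRUE))
    al <- align_sequences(nrp, bgc, p)
    expect_equal(al$aligned_log_p, oracle_best_aligned_log_p(nrp, bgc, p),
                 tolerance = 1e-9)
    # traceback reproduces the score from its own columns
    expect_equal(sum(al$columns$log_p) - al$null_log_p, al$score,
                 tolerance = 1e-12)
    # column counts: non-deletion columns = n, non-insertion = m
    expect_identical(sum(al$columns$kind != "deletion"), n)
    expect_identical(sum(al$columns$kind != "insertion"), m)
  }
})

test_that("length-1 alignment is the best of match vs indel pair", {
  p <- toy_params()
  nrp <- toy_nrp_seq("ala", m = -1, e = -1)
  bgc <- toy_bgc_seq("val", s = 80, m = -1, e = -1)
  al <- align_sequences(nrp, bgc, p)
  match_lp <- column_log_p(nrp, bgc, p)$log_p
  indel_lp <- column_log_p(nrp, NULL, p)$log_p +
    column_log_p(NULL, bgc, p)$log_p
  expect_equal(al$aligned_log_p, max(match_lp, indel_lp))
})

test_that("score decomposes into residue, methylation and stereo parts", {
  p <- generate_params(2, toy_alphabet())
  set.seed(4)
  nrp <- toy_nrp_seq(sample(names(p$p_a), 6, TRUE),
                     m = sample(c(-1, 1), 6, TRUE),
                     e = sample(c(-1, 0, 1), 6, TRUE))
  bgc <- toy_bgc_seq(sample(as.character(toy_alphabet()), 5, TRUE),
                     s = sample(1:100, 5, TRUE),
                     m = sample(c(-1, 1), 5, TRUE),
                     e = sample(c(-1, 1), 5, TRUE))
  al <- align_sequences(nrp, bgc, p)
  expect_equal(sum(al$columns$a_part + al$columns$m_part +
                     al$columns$e_part),
               al$aligned_log_p, tolerance = 1e-9)
})

test_that("raising the match probability never lowers a matched column", {
  p <- toy_params()
  nrp <- toy_nrp_seq(c("ala", "gly"), e = c(-1, -1))
  bgc <- toy_bgc_seq(c("ala", "gly"), s = c(95, 95), e = c(-1, -1))
  base <- align_sequences(nrp, bgc, p, allow_gaps = FALSE)$score
  for (up in c(0.7, 0.8, 0.95)) {
    p2 <- p; p2$p_match_a[["5"]] <- up
    expect_gte(align_sequences(nrp, bgc, p2, allow_gaps = FALSE)$score,
               base)
    base <- align_sequences(nrp, bgc, p2, allow_gaps = FALSE)$score
  }
})

test_that("insertion columns contribute a monomer-independent constant", {
  p <- toy_params()
  konst <- log(p$p_insertion * (1 - p$p_a[["unk"]]))
  set.seed(9)
  for (rep in 1:20) {
    res <- sample(names(p$p_a), 1)
    nrp <- toy_nrp_seq(res, m = sample(c(-1, 1), 1),
                       e = sample(c(-1, 0, 1), 1))
    ins <- column_log_p(nrp, NULL, p)$log_p
    null <- nrpslink:::null_log_p_terms(nrp, p)
    expect_equal(ins - null, konst, tolerance = 1e-9)
  }
})

test_that("best_pair_score selects the planted pair deterministically", {
  p <- toy_params()
  cand1 <- toy_nrp_seq(c("gly", "gly", "gly"), e = rep(-1, 3))
  cand2 <- toy_nrp_seq(c("ala", "val", "leu"), e = rep(-1, 3))
  line <- toy_bgc_seq(c("ala", "val", "leu"), s = c(95, 95, 95),
                      e = rep(-1, 3))
  bp <- best_pair_score(list(cand1, cand2), list(line), p)
  expect_identical(attr(bp$best, "nrp_index"), 2L)
  expect_identical(nrow(bp$table), 2L)
  # identical candidates: lexicographically first index wins
  bp2 <- best_pair_score(list(cand2, cand2), list(line), p)
  expect_identical(attr(bp2$best, "nrp_index"), 1L)
  # single pair
  bp3 <- best_pair_score(list(cand1), list(line), p)
  expect_identical(attr(bp3$best, "nrp_index"), 1L)
})
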