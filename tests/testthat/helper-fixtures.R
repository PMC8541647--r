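# Shared toy fixtures and independent oracles used across the suite.

toy_alphabet <- function() {
  residue_alphabet(c("ala", "gly", "val", "leu", "ser"))
}

# Small hand-specified parameter set over the toy alphabet.
toy_params <- function(p_ins = 0.05, p_del = 0.04) {
  p_a <- c(ala = 0.10, gly = 0.25, val = 0.05, leu = 0.20, ser = 0.20,
           unk = 0.20)
  nrps_params(
    p_match_a = c(0, 0.3, 0.45, 0.6, 0.5, 0.6),
    p_a = p_a,
    p_m = c("-1" = 0.7, "1" = 0.3),
    p_e = c("-1" = 0.6, "1" = 0.4),
    p_match_m = c("-1" = 0.55, "1" = 0.2),
    p_mismatch_m = c("-1" = 0.15, "1" = 0.1),
    p_match_e = c("-1" = 0.4, "1" = 0.3),
    p_mismatch_e = c("-1" = 0.2, "1" = 0.1),
    p_insertion = p_ins, p_deletion = p_del)
}

toy_nrp_seq <- function(residues, m = NULL, e = NULL) {
  n <- length(residues)
  data.frame(residue = residues,
             methylated = if (is.null(m)) rep(-1L, n) else as.integer(m),
             stereo = if (is.null(e)) rep(0L, n) else as.integer(e),
             stringsAsFactors = FALSE)
}

toy_bgc_seq <- function(residues, s = NULL, m = NULL, e = NULL) {
  n <- length(residues)
  data.frame(specificity = if (is.null(s)) rep(90L, n) else as.integer(s),
             residue = residues,
             methylated = if (is.null(m)) rep(-1L, n) else as.integer(m),
             stereo = if (is.null(e)) rep(-1L, n) else as.integer(e),
             undefined = FALSE, stringsAsFactors = FALSE)
}

# Independent oracle: best summed column log-probability over *all* global
# alignments, by exhaustive recursion over column structures.
oracle_best_aligned_log_p <- function(nrp, bgc, params) {
  n <- nrow(nrp); m <- nrow(bgc)
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, column_log_p(nrp[i, , drop = FALSE],
                                     bgc[j, , drop = FALSE],
                                     params)$log_p + rec(i + 1, j + 1))
    if (i <= n)
      best <- max(best, column_log_p(nrp[i, , drop = FALSE], NULL,
                                     params)$log_p + rec(i + 1, j))
    if (j <= m)
      best <- max(best, column_log_p(NULL, bgc[j, , drop = FALSE],
                                     params)$log_p + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Independent oracle: Hamiltonian orderings of a component by brute force
# over all node permutations, keeping those whose consecutive pairs are all
# directed edges. Returns a character vector of "id>id>..." keys.
oracle_component_orderings <- function(component) {
  ids <- component$nodes$id
  edges <- component$edges
  n <- length(ids)
  if (n == 1) return(ids)
  has_edge <- function(a, b) any(edges$from == a & edges$to == b)
  perms <- perms_of(seq_len(n))
  keys <- character(0)
  for (p in perms) {
    ord <- ids[p]
    if (all(mapply(has_edge, ord[-n], ord[-1])))
      keys <- c(keys, paste(ord, collapse = ">"))
  }
  sort(unique(keys))
}

perms_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in perms_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

path_graph <- function(id, residues, bonds = NULL) {
  n <- length(residues)
  ids <- sprintf("n%d", seq_len(n))
  if (is.null(bonds)) bonds <- rep("amide", n - 1)
  monomer_graph(id,
                data.frame(id = ids, residue = residues, supported = TRUE,
                           methylated = -1L, stereo = 0L,
                           stringsAsFactors = FALSE),
                data.frame(from = ids[-n], to = ids[-1], bond = bonds,
                           stringsAsFactors = FALSE))
}

cycle_graph <- function(id, residues) {
  n <- length(residues)
  ids <- sprintf("n%d", seq_len(n))
  monomer_graph(id,
                data.frame(id = ids, residue = residues, supported = TRUE,
                           methylated = -1L, stereo = 0L,
                           stringsAsFactors = FALSE),
                data.frame(from = ids, to = ids[c(2:n, 1)], bond = "amide",
                           stringsAsFactors = FALSE))
}

# Strip stub with given optional-domain flags (monomers irrelevant for
# consistency checks).
flag_strip <- function(gene_id, cs = FALSE, te = FALSE, com_n = FALSE,
                       com_c = FALSE) {
  list(gene_id = gene_id,
       monomers = toy_bgc_seq("ala"),
       flags = list(has_CS = cs, has_TE = te, has_COM_N = com_n,
                    has_COM_C = com_c),
       variant_tag = "base")
}

# A minimal typical module predicting `residue` with given scores.
toy_module <- function(residue, stach = 90, svm = 90, extra = character(0)) {
  dom <- list(list(kind = "C"),
              list(kind = "A",
                   predictions = data.frame(residue = residue,
                                            stachelhaus = stach, svm = svm,
                                            stringsAsFactors = FALSE)))
  for (k in extra) dom <- c(dom, list(list(kind = k)))
  c(dom, list(list(kind = "PCP")))
}
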