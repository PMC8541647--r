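#' @title Synthetic fixtures with planted ground truth
#' @description Seeded generators for every input the pipeline consumes:
#'   scoring parameters, curated-alignment training sets drawn from the
#'   scoring model's own generative form, and paired monomer-graph / BGC
#'   fixtures in which a known compound is planted into a known cluster
#'   (optionally perturbed by residue mismatches, indels, gene shuffling,
#'   stuttering, tailoring edges or cyclization). Decoy compounds are drawn
#'   from the same residue background, so fixture difficulty scales with
#'   the entropy of the background table.
#' @name synthetic_fixtures
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Generate random valid scoring parameters
#'
#' Values are drawn around ranges realistic for bacterial NRPs (match
#' probabilities increasing with specificity level, methylation a minority
#' state, L-configuration more common than D) and always pass
#' [validate_params()]. The four methylation (and stereo) agreement /
#' disagreement frequencies are drawn as a joint distribution summing to 1,
#' matching the plug-in estimators of the training module.
#'
#' @param seed integer seed.
#' @param alphabet a [residue_alphabet()].
#' @return an [nrps_params()] object.
#' @export
generate_params <- function(seed = 1L, alphabet = default_alphabet()) {
  with_seed(seed, {
    res <- c(as.character(alphabet), unsupported_sign(alphabet))
    w <- stats::rgamma(length(res) - 1L, shape = 1.2)
    w <- c(w / sum(w) * 0.92, 0.08)   # ~8% unsupported mass
    p_a <- stats::setNames(w / sum(w), res)
    pm1 <- stats::runif(1, 0.15, 0.35)
    p_m <- c("-1" = 1 - pm1, "1" = pm1)
    pe1 <- stats::runif(1, 0.25, 0.45)
    p_e <- c("-1" = 1 - pe1, "1" = pe1)
    p_match_a <- c(0, sort(stats::runif(5, 0.35, 0.95)))
    dirich <- function(alpha) {
      g <- stats::rgamma(length(alpha), shape = alpha)
      g / sum(g)
    }
    jm <- dirich(c(12, 3, 1.5, 1))
    je <- dirich(c(8, 4, 2, 1))
    nrps_params(
      p_match_a = p_match_a, p_a = p_a, p_m = p_m, p_e = p_e,
      p_match_m = c("-1" = jm[1], "1" = jm[2]),
      p_mismatch_m = c("-1" = jm[3], "1" = jm[4]),
      p_match_e = c("-1" = je[1], "1" = je[2]),
      p_mismatch_e = c("-1" = je[3], "1" = je[4]),
      p_insertion = stats::runif(1, 0.02, 0.08),
      p_deletion = stats::runif(1, 0.02, 0.08),
      unk = unsupported_sign(alphabet))
  })
}

sample_residue <- function(n, params, supported_only = TRUE,
                           exclude = NULL) {
  p <- params$p_a
  if (supported_only) p <- p[names(p) != params$unk]
  if (!is.null(exclude)) p <- p[names(p) != exclude]
  sample(names(p), n, replace = TRUE, prob = p / sum(p))
}

sample_trit <- function(n, tab) {
  as.integer(sample(c(-1L, 1L), n, replace = TRUE, prob = tab))
}

level_interval <- function(level, boundaries) {
  lo <- c(1, boundaries + 1)[level]
  hi <- c(boundaries, 100)[level]
  c(lo, hi)
}

#' Generate a synthetic curated-alignment training set
#'
#' Columns are drawn independently from the generative form of the scoring
#' model: column kinds occur at rates matching the per-monomer insertion /
#' deletion probabilities; non-indel columns draw a specificity level
#' uniformly, match the BGC residue with probability `PmatchA(level)`, and
#' draw the methylation / stereo state pairs from the joint agreement
#' tables (a fixed 15% of columns carry an undetermined NRP stereo state,
#' which the estimators ignore). Plug-in estimation on the output is
#' therefore consistent for the generating values.
#'
#' @param n_alignments number of alignments.
#' @param params generating [nrps_params()].
#' @param seed integer seed.
#' @param columns_per_alignment columns per alignment (default 25).
#' @param alphabet a [residue_alphabet()].
#' @return list of curated alignments (see [read_curated_alignments()]).
#' @export
generate_training_set <- function(n_alignments, params, seed = 1L,
                                  columns_per_alignment = 25L,
                                  alphabet = default_alphabet()) {
  stopifnot(n_alignments >= 1)
  with_seed(seed, {
    pins <- params$p_insertion; pdel <- params$p_deletion
    kind_p <- c(match = 1, insertion = pins / (1 - pins),
                deletion = pdel / (1 - pdel))
    kind_p <- kind_p / sum(kind_p)
    jm <- c(params$p_match_m, params$p_mismatch_m)   # -1,+1 match; -1,+1 mis
    je <- c(params$p_match_e, params$p_mismatch_e)
    p_zero_e <- 0.15
    lapply(seq_len(n_alignments), function(al) {
      n <- columns_per_alignment
      kind <- sample(names(kind_p), n, replace = TRUE, prob = kind_p)
      cols <- lapply(seq_len(n), function(i) {
        if (kind[i] == "deletion") {
          return(data.frame(kind = "deletion", nrp_residue = "-",
                            nrp_m = NA_integer_, nrp_e = NA_integer_,
                            bgc_residue = sample_residue(1, params),
                            bgc_s = sample.int(100, 1),
                            bgc_m = sample(c(-1L, 1L), 1),
                            bgc_e = sample(c(-1L, 1L), 1),
                            stringsAsFactors = FALSE))
        }
        if (kind[i] == "insertion") {
          return(data.frame(kind = "insertion",
                            nrp_residue = sample_residue(1, params,
                                                         FALSE),
                            nrp_m = sample_trit(1, params$p_m),
                            nrp_e = sample_trit(1, params$p_e),
                            bgc_residue = "-", bgc_s = NA_integer_,
                            bgc_m = NA_integer_, bgc_e = NA_integer_,
                            stringsAsFactors = FALSE))
        }
        lev <- sample.int(5, 1)
        iv <- level_interval(lev, params$level_boundaries)
        s <- sample(iv[1]:iv[2], 1)
        a_bgc <- sample_residue(1, params)
        is_match <- stats::runif(1) < params$p_match_a[[as.character(lev)]]
        a_nrp <- if (is_match) a_bgc
          else sample_residue(1, params, supported_only = FALSE,
                              exclude = a_bgc)
        mcat <- sample.int(4, 1, prob = jm)
        m_nrp <- c(-1L, 1L, -1L, 1L)[mcat]
        m_bgc <- if (mcat <= 2) m_nrp else -m_nrp
        if (stats::runif(1) < p_zero_e) {
          e_nrp <- 0L; e_bgc <- sample(c(-1L, 1L), 1)
        } else {
          ecat <- sample.int(4, 1, prob = je)
          e_nrp <- c(-1L, 1L, -1L, 1L)[ecat]
          e_bgc <- if (ecat <= 2) e_nrp else -e_nrp
        }
        data.frame(kind = "match", nrp_residue = a_nrp, nrp_m = m_nrp,
                   nrp_e = e_nrp, bgc_residue = a_bgc, bgc_s = s,
                   bgc_m = m_bgc, bgc_e = e_bgc, stringsAsFactors = FALSE)
      })
      list(bgc_id = sprintf("synthetic_bgc_%03d", al),
           compound_id = sprintf("synthetic_cpd_%03d", al),
           columns = do.call(rbind, cols))
    })
  })
}

#' Generate a planted BGC-NRP fixture pair
#'
#' Draws a supported residue sequence from the background, builds (a) a
#' monomer graph for the compound (a backbone path, or cycle when
#' `cyclic`, plus optional tailoring edges) and (b) a 1-3 gene BGC whose
#' modules predict the same residues with high specificity scores, then
#' applies the requested perturbations to the NRP side. With zero
#' perturbation the planted alignment is gap-free and fully matched.
#'
#' @param length number of planted monomers (>= 2).
#' @param params an [nrps_params()] object.
#' @param seed integer seed.
#' @param mismatch_rate per-monomer probability of replacing the NRP
#'   residue with a random background residue.
#' @param indel_rate per-monomer probability of an indel (split evenly
#'   between dropping the monomer from the NRP and inserting an extra one).
#' @param n_genes number of NRPS genes (1-3; capped at `length`).
#' @param strip_shuffle permute the annotated gene order (CS/TE flags keep
#'   the planted order recoverable).
#' @param stutter_copies extra copies of one residue recruited through an
#'   A-less deficient module (0 = off; the NRP carries the copies and the
#'   gene the deficient module).
#' @param tailoring_edges number of extra tailoring (ester) edges.
#' @param cyclic close the backbone into a cycle (incompatible with
#'   `n_genes`-component permutation fixtures; a cyclic compound still maps
#'   to a linear assembly line).
#' @param alphabet a [residue_alphabet()].
#' @param compound_id,genome_id,bgc_id identifiers.
#' @return list with `graph` ([monomer_graph()]), `genome` (one-genome
#'   annotation list), `truth` (curated alignment), `params`, `seed` and
#'   the perturbation settings.
#' @export
generate_planted_pair <- function(length, params, seed = 1L,
                                  mismatch_rate = 0, indel_rate = 0,
                                  n_genes = 2L, strip_shuffle = FALSE,
                                  stutter_copies = 0L,
                                  tailoring_edges = 0L, cyclic = FALSE,
                                  alphabet = default_alphabet(),
                                  compound_id = "planted_cpd",
                                  genome_id = "planted_genome",
                                  bgc_id = "planted_bgc") {
  stopifnot(length >= 2)
  if (cyclic && tailoring_edges > 0 && length < 4)
    stop("cyclization with tailoring edges needs length >= 4",
         call. = FALSE)
  with_seed(seed, {
    res <- sample_residue(length, params)
    m <- sample_trit(length, params$p_m)
    e <- sample_trit(length, params$p_e)

    # ---- BGC side: modules carry the true residues -------------------
    n_genes <- max(1L, min(n_genes, length, 3L))
    cut <- sort(sample(seq_len(length - 1L),
                       n_genes - 1L))
    gene_of <- findInterval(seq_len(length), c(0, cut),
                            left.open = TRUE) |> as.integer()
    stutter_gene <- if (stutter_copies > 0)
      sample.int(n_genes, 1) else 0L
    genes <- list()
    pos <- 1
    for (g in seq_len(n_genes)) {
      idx <- which(gene_of == g)
      modules <- lapply(idx, function(i) {
        decoys <- sample_residue(2, params, exclude = res[i])
        preds <- data.frame(
          residue = c(res[i], decoys),
          stachelhaus = c(round(stats::runif(1, 85, 100)),
                          round(stats::runif(2, 20, 70))),
          svm = c(round(stats::runif(1, 85, 100)),
                  round(stats::runif(2, 20, 70))),
          stringsAsFactors = FALSE)
        dom <- list(list(kind = "C"), list(kind = "A", predictions = preds))
        if (m[i] == 1L) dom <- c(dom, list(list(kind = "M")))
        if (e[i] == 1L) dom <- c(dom, list(list(kind = "E")))
        c(dom, list(list(kind = "PCP")))
      })
      if (g == 1L)
        modules[[1]] <- c(list(list(kind = "CS")), modules[[1]])
      if (g == n_genes)
        modules[[length(modules)]] <- c(modules[[length(modules)]],
                                        list(list(kind = "TE")))
      if (g == stutter_gene)
        modules <- c(modules, list(list(list(kind = "C"),
                                        list(kind = "PCP"))))
      glen <- 3000 * length(modules)
      genes[[g]] <- gene_annotation(
        sprintf("%s_g%d", bgc_id, g), start = pos, end = pos + glen,
        strand = "+", modules = modules)
      pos <- pos + glen + sample(200:800, 1)
    }
    if (strip_shuffle && n_genes > 1L) {
      perm <- sample(n_genes)
      while (identical(perm, seq_len(n_genes))) perm <- sample(n_genes)
      # reassign coordinates so the annotated (genomic) order is permuted
      pos <- 1
      for (k in seq_len(n_genes)) {
        g <- genes[[perm[k]]]
        glen <- g$end - g$start
        g$start <- pos; g$end <- pos + glen
        genes[[perm[k]]] <- g
        pos <- pos + glen + 500
      }
      genes <- genes[perm]
    }
    genome <- list(genome_id = genome_id,
                   bgcs = list(list(bgc_id = bgc_id, genes = genes)))

    # ---- NRP side: perturb, then build the monomer graph -------------
    nrp_res <- res; nrp_m <- m; nrp_e <- e
    truth_kind <- rep("match", length)
    if (stutter_gene > 0L) {
      i <- max(which(gene_of == stutter_gene))
      reps <- rep(1L, length); reps[i] <- 1L + stutter_copies
      keep <- rep(seq_len(length), times = reps)
      nrp_res <- nrp_res[keep]; nrp_m <- nrp_m[keep]; nrp_e <- nrp_e[keep]
      truth_kind <- truth_kind[keep]
    }
    n_now <- base::length(nrp_res)
    mism <- stats::runif(n_now) < mismatch_rate
    if (any(mism))
      nrp_res[mism] <- vapply(which(mism), function(i)
        sample_residue(1, params, exclude = nrp_res[i]), "")
    drop <- stats::runif(n_now) < indel_rate / 2
    if (sum(!drop) < 2) drop[] <- FALSE   # keep a scoreable compound
    truth <- data.frame(kind = truth_kind, nrp_residue = nrp_res,
                        nrp_m = nrp_m, nrp_e = nrp_e,
                        bgc_residue = nrp_res, bgc_s = NA_integer_,
                        bgc_m = nrp_m, bgc_e = nrp_e,
                        stringsAsFactors = FALSE)
    truth$kind[drop] <- "deletion"
    nrp_res <- nrp_res[!drop]; nrp_m <- nrp_m[!drop]; nrp_e <- nrp_e[!drop]
    ins <- stats::runif(base::length(nrp_res)) < indel_rate / 2
    for (i in rev(which(ins))) {
      extra_res <- sample_residue(1, params, supported_only = FALSE)
      nrp_res <- append(nrp_res, extra_res, after = i)
      nrp_m <- append(nrp_m, sample_trit(1, params$p_m), after = i)
      nrp_e <- append(nrp_e, sample_trit(1, params$p_e), after = i)
    }
    n_fin <- base::length(nrp_res)
    node_ids <- sprintf("n%02d", seq_len(n_fin))
    nodes <- data.frame(id = node_ids, residue = nrp_res,
                        supported = nrp_res %in% as.character(alphabet),
                        methylated = nrp_m, stereo = nrp_e,
                        stringsAsFactors = FALSE)
    edges <- if (n_fin >= 2)
      data.frame(from = node_ids[-n_fin], to = node_ids[-1],
                 bond = "amide", stringsAsFactors = FALSE)
    else data.frame(from = character(0), to = character(0),
                    bond = character(0))
    if (cyclic && n_fin >= 3)
      edges <- rbind(edges, data.frame(from = node_ids[n_fin],
                                       to = node_ids[1], bond = "amide"))
    k <- 0L
    while (k < tailoring_edges && n_fin >= 3) {
      pick <- sort(sample.int(n_fin, 2))
      if (pick[2] - pick[1] >= 2) {
        edges <- rbind(edges, data.frame(from = node_ids[pick[1]],
                                         to = node_ids[pick[2]],
                                         bond = "ester"))
        k <- k + 1L
      }
    }
    graph <- monomer_graph(compound_id, nodes, edges)
    list(graph = graph, genome = genome,
         truth = list(bgc_id = bgc_id, compound_id = compound_id,
                      columns = truth),
         params = params, seed = seed,
         settings = list(mismatch_rate = mismatch_rate,
                         indel_rate = indel_rate, n_genes = n_genes,
                         strip_shuffle = strip_shuffle,
                         stutter_copies = stutter_copies,
                         tailoring_edges = tailoring_edges,
                         cyclic = cyclic))
  })
}

#' Generate decoy compounds from the residue background
#'
#' @param n number of decoys.
#' @param lengths integer vector of lengths to sample from (with
#'   replacement).
#' @param params an [nrps_params()] object.
#' @param seed integer seed.
#' @param alphabet a [residue_alphabet()].
#' @return list of [monomer_graph()] path graphs.
#' @export
generate_decoys <- function(n, lengths, params, seed = 1L,
                            alphabet = default_alphabet()) {
  with_seed(seed, {
    lapply(seq_len(n), function(d) {
      len <- sample(rep(lengths, 2L), 1)
      res <- sample_residue(len, params)
      ids <- sprintf("n%02d", seq_len(len))
      nodes <- data.frame(id = ids, residue = res,
                          supported = res %in% as.character(alphabet),
                          methylated = sample_trit(len, params$p_m),
                          stereo = sample_trit(len, params$p_e),
                          stringsAsFactors = FALSE)
      edges <- data.frame(from = ids[-len], to = ids[-1], bond = "amide",
                          stringsAsFactors = FALSE)
      monomer_graph(sprintf("decoy_%03d", d), nodes, edges)
    })
  })
}

#' Planted-pair recovery rate under decoy competition
#'
#' For each replicate, plants one compound into one BGC, adds `n_decoys`
#' background compounds, runs the full matching pipeline with no score
#' threshold, and checks whether the planted compound is the reciprocal
#' best hit of the planted BGC. Returns the fraction of successful
#' replicates.
#'
#' @param n_replicates number of replicates.
#' @param n_decoys decoys per replicate (default 20).
#' @param length planted compound length (default 8).
#' @param params an [nrps_params()] object.
#' @param seed integer base seed (replicate r uses `seed + r`).
#' @param mismatch_rate,indel_rate perturbation rates (defaults 0.1 / 0.05:
#'   mild perturbation).
#' @param alphabet a [residue_alphabet()].
#' @return list with `rate` and the per-replicate logical vector `hit`.
#' @export
planted_recovery_rate <- function(n_replicates = 100L, n_decoys = 20L,
                                  length = 8L, params = default_params(),
                                  seed = 1L, mismatch_rate = 0.1,
                                  indel_rate = 0.05,
                                  alphabet = default_alphabet()) {
  hit <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    pp <- generate_planted_pair(length, params, seed = seed + r,
                                mismatch_rate = mismatch_rate,
                                indel_rate = indel_rate,
                                n_genes = 2L, alphabet = alphabet)
    decoys <- generate_decoys(n_decoys, lengths = c(length - 1L, length,
                                                    length + 1L),
                              params, seed = seed + r + 100000L,
                              alphabet = alphabet)
    run <- nrps_match(c(list(pp$graph), decoys), list(pp$genome),
                      params = params, alphabet = alphabet,
                      min_score = -Inf)
    comb <- run$combined
    hit[r] <- nrow(comb) >= 1 &&
      pp$graph$id %in% comb$compound_id[comb$bgc_id == "planted_bgc"]
  }
  list(rate = mean(hit), hit = hit)
}
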