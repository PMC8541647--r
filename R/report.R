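#' @title All-vs-all matching, reciprocal filtering and FDR benchmarking
#' @name matching_report
NULL

#' Match every compound against every BGC
#'
#' For each (compound, BGC) pair the best-scoring candidate/assembly-line
#' alignment is computed; matches scoring strictly below `min_score` are
#' discarded (a score equal to the threshold survives); the remainder is
#' sorted by score descending with deterministic (compound, genome, bgc)
#' lexicographic tie-breaking.
#'
#' @param nrp_records list of `list(compound_id, candidates)` where
#'   `candidates` comes from [linearize_graph()].
#' @param bgc_records list of `list(genome_id, bgc_id, lines)` where
#'   `lines` comes from [process_bgc()].
#' @param params an [nrps_params()] object.
#' @param min_score score threshold (default 6).
#' @return object of class `nrps_matches`: list with `results` (data.frame
#'   compound_id, genome_id, bgc_id, score, nrp_index, bgc_index) and
#'   `alignments` (parallel list of `nrps_alignment`).
#' @export
match_all <- function(nrp_records, bgc_records, params, min_score = 6) {
  if (!length(nrp_records) || !length(bgc_records)) {
    warning("empty input; no matches computed", call. = FALSE)
    return(structure(list(results = empty_results(), alignments = list()),
                     class = "nrps_matches"))
  }
  rows <- list(); aligns <- list()
  for (nr in nrp_records) {
    if (!length(nr$candidates)) next
    for (br in bgc_records) {
      if (!length(br$lines)) next
      bp <- best_pair_score(nr$candidates, br$lines, params)
      if (bp$score < min_score) next
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = nr$compound_id, genome_id = br$genome_id,
        bgc_id = br$bgc_id, score = bp$score,
        nrp_index = attr(bp$best, "nrp_index"),
        bgc_index = attr(bp$best, "bgc_index"),
        stringsAsFactors = FALSE)
      aligns[[length(aligns) + 1L]] <- bp$best
    }
  }
  if (!length(rows))
    return(structure(list(results = empty_results(), alignments = list()),
                     class = "nrps_matches"))
  results <- do.call(rbind, rows)
  ord <- order(-results$score, results$compound_id, results$genome_id,
               results$bgc_id)
  structure(list(results = results[ord, , drop = FALSE] |>
                   (\(d) { rownames(d) <- NULL; d })(),
                 alignments = aligns[ord]),
            class = "nrps_matches")
}

empty_results <- function() {
  data.frame(compound_id = character(0), genome_id = character(0),
             bgc_id = character(0), score = numeric(0),
             nrp_index = integer(0), bgc_index = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.nrps_matches <- function(x, ...) {
  cat("All-vs-all match results:", nrow(x$results), "retained matches\n")
  if (nrow(x$results)) print(utils::head(x$results, 10))
  invisible(x)
}

#' Reciprocal combined report
#'
#' Keeps a match iff the compound ranks at most `k_best` among its BGC's
#' hits *and* the BGC ranks at most `k_best` among the compound's hits
#' (default: strict reciprocal best). Ranks follow the deterministic
#' ordering of [match_all()].
#'
#' @param matches an `nrps_matches` object (or its `results` data.frame).
#' @param k_best rank cutoff on both sides (default 1).
#' @return the filtered results data.frame.
#' @export
combined_report <- function(matches, k_best = 1L) {
  results <- if (inherits(matches, "nrps_matches")) matches$results
    else matches
  if (!nrow(results)) return(results)
  bgc_key <- paste(results$genome_id, results$bgc_id, sep = "\r")
  rank_in <- function(key) stats::ave(seq_len(nrow(results)), key,
                                      FUN = seq_along)
  # results are already score-descending, so within-group order is rank
  rank_bgc <- rank_in(bgc_key)
  rank_nrp <- rank_in(results$compound_id)
  keep <- rank_bgc <= k_best & rank_nrp <= k_best
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build benchmark records from match results and ground truth
#'
#' A BGC counts as correctly identified if its ground-truth compound is
#' among the `rank_cutoff` best-scoring hits for that BGC. The record
#' carries the ground-truth hit and its score as the BGC representative
#' when correct, otherwise the best hit.
#'
#' @param matches an `nrps_matches` object (or a results data.frame).
#' @param truth data.frame with columns `bgc_id`, `compound_id` (the
#'   ground-truth product), optionally `genome_id`.
#' @param rank_cutoff correctness rank cutoff (default 10).
#' @return data.frame with `bgc_id`, `correct`, `score` (representative),
#'   `s_gt`, `s_best`, `r_gt`.
#' @export
benchmark_records <- function(matches, truth, rank_cutoff = 10L) {
  results <- if (inherits(matches, "nrps_matches")) matches$results
    else matches
  out <- lapply(seq_len(nrow(truth)), function(t) {
    hits <- results[results$bgc_id == truth$bgc_id[t], , drop = FALSE]
    if (!nrow(hits))
      return(data.frame(bgc_id = truth$bgc_id[t], correct = FALSE,
                        score = NA_real_, s_gt = NA_real_,
                        s_best = NA_real_, r_gt = NA_integer_))
    r_gt <- match(truth$compound_id[t], hits$compound_id)
    correct <- !is.na(r_gt) && r_gt <= rank_cutoff
    s_gt <- if (is.na(r_gt)) NA_real_ else hits$score[r_gt]
    data.frame(bgc_id = truth$bgc_id[t], correct = correct,
               score = if (correct) s_gt else hits$score[1],
               s_gt = s_gt, s_best = hits$score[1],
               r_gt = r_gt)
  })
  do.call(rbind, out)
}

#' False discovery rate curve over ranked benchmark records
#'
#' Sorts records by representative score descending and computes, for every
#' prefix of length i, `FDR[i] = (i - Numcor[i]) / i` where `Numcor[i]` is
#' the number of correctly identified BGCs in the prefix. Records with tied
#' scores share the FDR computed over the whole tie group.
#'
#' @param records data.frame with columns `score` and `correct` (see
#'   [benchmark_records()]); `NA` scores are dropped.
#' @return data.frame with `rank`, `score`, `correct`, `num_correct`,
#'   `fdr`.
#' @export
fdr_curve <- function(records) {
  records <- records[!is.na(records$score), , drop = FALSE]
  if (!nrow(records))
    return(data.frame(rank = integer(0), score = numeric(0),
                      correct = logical(0), num_correct = integer(0),
                      fdr = numeric(0)))
  ord <- order(-records$score)
  sc <- records$score[ord]
  corr <- as.logical(records$correct[ord])
  i <- seq_along(sc)
  numcor <- cumsum(corr)
  # tied scores share the FDR computed over the whole tie group
  grp_last <- vapply(sc, function(s) max(which(sc == s)), integer(1))
  fdr <- (grp_last - numcor[grp_last]) / grp_last
  data.frame(rank = i, score = sc, correct = corr, num_correct = numcor,
             fdr = fdr)
}

#' Write report files
#'
#' Emits the combined TSV, an all-matches TSV, per-compound and per-genome
#' grouped text reports with rendered alignments, and a run log echoing the
#' configuration and seed.
#'
#' @param matches an `nrps_matches` object.
#' @param combined combined-report data.frame from [combined_report()].
#' @param output_dir output directory (created if absent).
#' @param config named list echoed into the run log.
#' @param seed seed echoed into the run log.
#' @return `output_dir`, invisibly.
#' @export
write_reports <- function(matches, combined, output_dir,
                          config = list(), seed = NA) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(d) {
    d$score <- sprintf("%.6f", d$score)
    d
  }
  utils::write.table(fmt(combined),
                     file.path(output_dir, "combined_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fmt(matches$results),
                     file.path(output_dir, "all_matches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res <- matches$results
  grouped <- function(key, file) {
    con <- file(file.path(output_dir, file), "w")
    on.exit(close(con))
    for (k in unique(res[[key]])) {
      idx <- which(res[[key]] == k)
      writeLines(paste0("## ", key, ": ", k), con)
      for (i in idx) {
        writeLines(sprintf("# %s ~ %s/%s", res$compound_id[i],
                           res$genome_id[i], res$bgc_id[i]), con)
        writeLines(render_alignment(matches$alignments[[i]]), con)
        writeLines("", con)
      }
    }
  }
  if (nrow(res)) {
    grouped("compound_id", "per_compound.txt")
    grouped("genome_id", "per_genome.txt")
  } else {
    file.create(file.path(output_dir, "per_compound.txt"),
                file.path(output_dir, "per_genome.txt"))
  }
  log <- c(sprintf("seed: %s", seed),
           sprintf("matches: %d; combined: %d", nrow(res), nrow(combined)),
           vapply(names(config), function(k)
             sprintf("%s: %s", k, paste(config[[k]], collapse = ",")), ""))
  writeLines(log, file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}

#' Run the full matching pipeline
#'
#' Linearizes monomer graphs, expands BGC annotations into assembly lines,
#' scores all pairs, and builds the reciprocal combined report.
#'
#' @param graphs list of [monomer_graph()] objects, or a path to a monomer
#'   graph JSON file.
#' @param genomes list of genome annotation objects (see
#'   [read_bgc_annotations()]), or a path to a BGC JSON file.
#' @param params an [nrps_params()] object or a path to a params file
#'   (default: shipped parameters).
#' @param alphabet a [residue_alphabet()] or path to an alphabet file.
#' @param min_score score threshold (default 6).
#' @param max_bgc_dist gap threshold for BGC splitting (default 10000 nt).
#' @param min_supported minimum supported monomers per backbone component
#'   (default 2).
#' @param max_copies deficient-module copy cap (default 3).
#' @param max_permuted component-permutation cap (default 3).
#' @param k_best reciprocal rank cutoff for the combined report (default 1).
#' @param max_sequences assembly-line cap per BGC (default 720).
#' @return list with `matches` (an `nrps_matches`) and `combined`
#'   (data.frame).
#' @export
nrps_match <- function(graphs, genomes, params = default_params(),
                       alphabet = default_alphabet(), min_score = 6,
                       max_bgc_dist = 10000, min_supported = 2L,
                       max_copies = 3L, max_permuted = 3L, k_best = 1L,
                       max_sequences = 720L) {
  if (is.character(graphs)) graphs <- read_monomer_graphs(graphs)
  if (is.character(genomes)) genomes <- read_bgc_annotations(genomes)
  if (is.character(params)) params <- read_params(params)
  if (is.character(alphabet) && !inherits(alphabet, "residue_alphabet"))
    alphabet <- load_alphabet(alphabet)
  nrp_records <- lapply(graphs, function(g) list(
    compound_id = g$id,
    candidates = linearize_graph(g, alphabet = alphabet,
                                 min_supported = min_supported,
                                 max_permuted = max_permuted)))
  bgc_records <- list()
  for (genome in genomes) {
    for (bgc in genome$bgcs) {
      lines <- process_bgc(bgc$genes, bgc_id = bgc$bgc_id,
                           alphabet = alphabet, max_dist = max_bgc_dist,
                           max_copies = max_copies,
                           max_sequences = max_sequences)
      bgc_records[[length(bgc_records) + 1L]] <- list(
        genome_id = genome$genome_id, bgc_id = bgc$bgc_id, lines = lines)
    }
  }
  matches <- match_all(nrp_records, bgc_records, params,
                       min_score = min_score)
  list(matches = matches, combined = combined_report(matches, k_best))
}
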