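#' @title Parameter learning from curated alignments
#' @description All scoring probabilities are plug-in event frequencies.
#'   Background tables (`PA`, `PM`, `PE`) come from a corpus of NRP monomer
#'   sequences; match/mismatch and indel probabilities come from curated
#'   BGC-NRP alignments. Each estimate is the count of the corresponding
#'   event divided by its documented denominator, e.g. the stereo mismatch
#'   frequency at NRP state -1 is the number of non-indel sites with
#'   (eNRP, eBGC) = (-1, +1) over the number of non-indel sites whose NRP
#'   stereo is determined (eNRP != 0). Uncertainty is assessed by
#'   bootstrapping whole alignments.
#' @name training
NULL

#' Estimate background frequencies from an NRP corpus
#'
#' `PA` pools every out-of-alphabet residue into the unsupported sign; `PM`
#' is estimated over all monomers; `PE` only over stereo-determined
#' monomers (`stereo != 0`).
#'
#' @param nrp_sequences list of NRP monomer data.frames (`residue`,
#'   `methylated`, `stereo`).
#' @param alphabet a [residue_alphabet()].
#' @param floor lower bound applied to zero frequencies (`PA` is
#'   re-normalized after flooring).
#' @return list with named numerics `p_a`, `p_m`, `p_e`.
#' @export
estimate_background <- function(nrp_sequences,
                                alphabet = default_alphabet(),
                                floor = PROB_FLOOR) {
  if (!length(nrp_sequences))
    stop("empty NRP corpus", call. = FALSE)
  all <- do.call(rbind, lapply(nrp_sequences, function(s)
    if (is.data.frame(s)) s else s$monomers))
  unk <- unsupported_sign(alphabet)
  res <- tolower(all$residue)
  res[!res %in% as.character(alphabet)] <- unk
  lev <- c(as.character(alphabet), unk)
  p_a <- table(factor(res, levels = lev)) / length(res)
  p_a <- pmax(as.numeric(p_a), floor)
  p_a <- stats::setNames(p_a / sum(p_a), lev)
  p_m <- table(factor(all$methylated, levels = c(-1L, 1L)))
  p_m <- pmax(as.numeric(p_m) / max(sum(p_m), 1L), floor)
  p_m <- stats::setNames(p_m / sum(p_m), c("-1", "1"))
  e <- all$stereo[all$stereo != 0L]
  p_e <- table(factor(e, levels = c(-1L, 1L)))
  p_e <- pmax(as.numeric(p_e) / max(sum(p_e), 1L), floor)
  p_e <- stats::setNames(p_e / sum(p_e), c("-1", "1"))
  list(p_a = p_a, p_m = p_m, p_e = p_e)
}

# Internal: stack curated alignments into one column table.
stack_alignment_columns <- function(alignments) {
  do.call(rbind, lapply(alignments, `[[`, "columns"))
}

#' Estimate match/mismatch and indel probabilities from curated alignments
#'
#' Counting scheme per event class (all over curated alignment columns):
#' * `PmatchA(level)`: residue-matched non-indel columns at the level /
#'   non-indel columns at the level (level 0 forced to 0);
#' * `PmatchM(m)` / `PmismatchM(m)`: non-indel columns with equal / opposite
#'   methylation states at NRP state `m`, over all non-indel columns;
#' * `PmatchE(e)` / `PmismatchE(e)`: the analogous stereo events over
#'   non-indel columns whose NRP stereo is determined;
#' * `Pinsertion`: insertion columns per NRP monomer (non-deletion column);
#' * `Pdeletion`: deletion columns per BGC monomer (non-insertion column).
#' Zero-event estimates are floored with a warning.
#'
#' @param alignments list of curated alignments: `list(bgc_id, compound_id,
#'   columns)` where `columns` is a data.frame with `kind`
#'   (match/insertion/deletion), `nrp_residue`, `nrp_m`, `nrp_e`,
#'   `bgc_residue`, `bgc_s`, `bgc_m`, `bgc_e` (gaps `"-"`/`NA`).
#' @param level_boundaries score-level cut points.
#' @param background optional background tables (`p_a`, `p_m`, `p_e`) used
#'   to assemble a full parameter object; if `NULL`, estimated from the NRP
#'   side of the alignment columns themselves.
#' @param alphabet a [residue_alphabet()].
#' @param floor probability floor for zero-event estimates.
#' @return an [nrps_params()] object.
#' @export
estimate_alignment_params <- function(alignments,
                                      level_boundaries = c(60L, 70L, 80L,
                                                           90L),
                                      background = NULL,
                                      alphabet = default_alphabet(),
                                      floor = PROB_FLOOR) {
  stopifnot(length(alignments) >= 1)
  co <- stack_alignment_columns(alignments)
  unk <- unsupported_sign(alphabet)
  ni <- co[co$kind == "match", , drop = FALSE]      # non-indel sites
  if (!nrow(ni))
    warning("no non-indel columns in curated alignments", call. = FALSE)

  # residue matches by level
  lev <- discretize_specificity(ni$bgc_s, level_boundaries)
  matched <- ni$nrp_residue == ni$bgc_residue & ni$nrp_residue != unk
  p_match_a <- stats::setNames(numeric(6), as.character(0:5))
  for (L in 1:5) {
    at <- lev == L
    if (!any(at)) {
      warning("no non-indel columns at score level ", L,
              "; estimate floored", call. = FALSE)
      p_match_a[[as.character(L)]] <- floor
    } else {
      p_match_a[[as.character(L)]] <- max(mean(matched[at]), floor)
    }
  }

  frac <- function(num, den) if (den == 0) floor else max(num / den, floor)
  n_ni <- nrow(ni)
  p_match_m <- p_mismatch_m <- stats::setNames(numeric(2), c("-1", "1"))
  for (m in c(-1L, 1L)) {
    p_match_m[[as.character(m)]] <-
      frac(sum(ni$nrp_m == m & ni$bgc_m == m), n_ni)
    p_mismatch_m[[as.character(m)]] <-
      frac(sum(ni$nrp_m == m & ni$bgc_m == -m), n_ni)
  }
  det <- ni[ni$nrp_e != 0L, , drop = FALSE]
  n_det <- nrow(det)
  p_match_e <- p_mismatch_e <- stats::setNames(numeric(2), c("-1", "1"))
  for (e in c(-1L, 1L)) {
    p_match_e[[as.character(e)]] <-
      frac(sum(det$nrp_e == e & det$bgc_e == e), n_det)
    p_mismatch_e[[as.character(e)]] <-
      frac(sum(det$nrp_e == e & det$bgc_e == -e), n_det)
  }

  n_nrp <- sum(co$kind != "deletion")    # NRP monomers in the data
  n_bgc <- sum(co$kind != "insertion")   # BGC monomers in the data
  p_insertion <- frac(sum(co$kind == "insertion"), n_nrp)
  p_deletion <- frac(sum(co$kind == "deletion"), n_bgc)

  if (is.null(background)) {
    nrp_side <- co[co$kind != "deletion",
                   c("nrp_residue", "nrp_m", "nrp_e")]
    names(nrp_side) <- c("residue", "methylated", "stereo")
    background <- estimate_background(list(nrp_side), alphabet = alphabet,
                                      floor = floor)
  }
  nrps_params(p_match_a = p_match_a,
              p_a = background$p_a, p_m = background$p_m,
              p_e = background$p_e,
              p_match_m = p_match_m, p_mismatch_m = p_mismatch_m,
              p_match_e = p_match_e, p_mismatch_e = p_mismatch_e,
              p_insertion = p_insertion, p_deletion = p_deletion,
              level_boundaries = level_boundaries,
              unk = unk)
}

#' Flatten a parameter object into a named numeric vector
#' @param params an [nrps_params()] object.
#' @return named numeric vector of every probability.
#' @export
flatten_params <- function(params) {
  num <- c(
    stats::setNames(params$p_match_a,
                    paste0("p_match_a.", names(params$p_match_a))),
    stats::setNames(params$p_a, paste0("p_a.", names(params$p_a))),
    stats::setNames(params$p_m, paste0("p_m.", names(params$p_m))),
    stats::setNames(params$p_e, paste0("p_e.", names(params$p_e))),
    stats::setNames(params$p_match_m,
                    paste0("p_match_m.", names(params$p_match_m))),
    stats::setNames(params$p_mismatch_m,
                    paste0("p_mismatch_m.", names(params$p_mismatch_m))),
    stats::setNames(params$p_match_e,
                    paste0("p_match_e.", names(params$p_match_e))),
    stats::setNames(params$p_mismatch_e,
                    paste0("p_mismatch_e.", names(params$p_mismatch_e))),
    p_insertion = params$p_insertion,
    p_deletion = params$p_deletion)
  num
}

#' Bootstrap parameter estimation
#'
#' Resamples whole curated alignments with replacement (preserving
#' within-alignment correlation) to the original count, re-estimates per
#' sample, and reports the per-parameter distribution plus a point estimate
#' (mean by default, median optional). Fully reproducible from `seed`.
#'
#' @inheritParams estimate_alignment_params
#' @param n_samples number of bootstrap replicates (default 100).
#' @param seed integer RNG seed.
#' @param point `"mean"` or `"median"` aggregation for the point estimate.
#' @return list with `samples` (list of `nrps_params`), `summary`
#'   (data.frame parameter/mean/sd), `point` (an `nrps_params`).
#' @export
bootstrap_params <- function(alignments, n_samples = 100L, seed = 1L,
                             level_boundaries = c(60L, 70L, 80L, 90L),
                             background = NULL,
                             alphabet = default_alphabet(),
                             point = c("mean", "median"),
                             floor = PROB_FLOOR) {
  point <- match.arg(point)
  stopifnot(n_samples >= 1)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  n <- length(alignments)
  samples <- vector("list", n_samples)
  for (b in seq_len(n_samples)) {
    idx <- sample.int(n, n, replace = TRUE)
    samples[[b]] <- suppressWarnings(estimate_alignment_params(
      alignments[idx], level_boundaries = level_boundaries,
      background = background, alphabet = alphabet, floor = floor))
  }
  flat <- do.call(rbind, lapply(samples, flatten_params))
  agg <- if (point == "mean") colMeans(flat)
    else apply(flat, 2, stats::median)
  summary <- data.frame(parameter = colnames(flat),
                        mean = colMeans(flat),
                        sd = apply(flat, 2, stats::sd),
                        row.names = NULL)
  tmpl <- samples[[1]]
  pick <- function(prefix, names_)
    stats::setNames(agg[paste0(prefix, ".", names_)], names_)
  pt <- nrps_params(
    p_match_a = pick("p_match_a", as.character(0:5)),
    p_a = pick("p_a", names(tmpl$p_a)),
    p_m = pick("p_m", c("-1", "1")), p_e = pick("p_e", c("-1", "1")),
    p_match_m = pick("p_match_m", c("-1", "1")),
    p_mismatch_m = pick("p_mismatch_m", c("-1", "1")),
    p_match_e = pick("p_match_e", c("-1", "1")),
    p_mismatch_e = pick("p_mismatch_e", c("-1", "1")),
    p_insertion = unname(agg["p_insertion"]),
    p_deletion = unname(agg["p_deletion"]),
    level_boundaries = level_boundaries, unk = tmpl$unk)
  # a mean of floored PmatchA(0) values can drift off exact zero
  pt$p_match_a[["0"]] <- 0
  list(samples = samples, summary = summary, point = pt)
}

#' Read curated alignments from TSV
#'
#' One column pair per row: `bgc_id`, `compound_id`, `nrp_residue`,
#' `nrp_m`, `nrp_e`, `bgc_residue`, `bgc_s`, `bgc_m`, `bgc_e`,
#' `column_kind`; gaps encoded as `-`. Consecutive rows sharing
#' (`bgc_id`, `compound_id`) form one alignment.
#'
#' @param path TSV file path.
#' @return list of curated alignments.
#' @export
read_curated_alignments <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("bgc_id", "compound_id", "nrp_residue", "nrp_m", "nrp_e",
            "bgc_residue", "bgc_s", "bgc_m", "bgc_e", "column_kind")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("curated alignment file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  key <- paste(tab$bgc_id, tab$compound_id, sep = "\r")
  grp <- rle(key)
  ends <- cumsum(grp$lengths)
  starts <- ends - grp$lengths + 1L
  lapply(seq_along(ends), function(g) {
    rows <- tab[starts[g]:ends[g], , drop = FALSE]
    toint <- function(x) suppressWarnings(as.integer(x))
    list(bgc_id = rows$bgc_id[1], compound_id = rows$compound_id[1],
         columns = data.frame(
           kind = rows$column_kind,
           nrp_residue = rows$nrp_residue,
           nrp_m = toint(rows$nrp_m), nrp_e = toint(rows$nrp_e),
           bgc_residue = rows$bgc_residue,
           bgc_s = toint(rows$bgc_s),
           bgc_m = toint(rows$bgc_m), bgc_e = toint(rows$bgc_e),
           stringsAsFactors = FALSE))
  })
}

#' Write curated alignments to TSV
#'
#' Inverse of [read_curated_alignments()].
#'
#' @param alignments list of curated alignments.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curated_alignments <- function(alignments, path) {
  rows <- do.call(rbind, lapply(alignments, function(al) {
    co <- al$columns
    data.frame(bgc_id = al$bgc_id, compound_id = al$compound_id,
               nrp_residue = co$nrp_residue, nrp_m = co$nrp_m,
               nrp_e = co$nrp_e, bgc_residue = co$bgc_residue,
               bgc_s = co$bgc_s, bgc_m = co$bgc_m, bgc_e = co$bgc_e,
               column_kind = co$kind, stringsAsFactors = FALSE)
  }))
  rows[] <- lapply(rows, function(x) {
    x <- as.character(x); x[is.na(x)] <- "-"; x
  })
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
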