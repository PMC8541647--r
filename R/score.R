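#' @title Log-odds alignment scoring
#' @description A BGC-NRP pair is scored as the log odds of the probability
#'   that the assembly line encoded by the BGC synthesizes the NRP as
#'   prescribed by a global alignment, against a null model in which every
#'   NRP monomer is produced by an undefined module. Aligned monomer pairs
#'   are independent, and within a pair the residue, methylation and stereo
#'   components contribute independently, so the score decomposes into
#'   per-column residue/methylation/stereo parts minus the per-NRP-monomer
#'   null terms. The optimal alignment is found with the Needleman-Wunsch
#'   algorithm under a linear (per-column) gap model. All logarithms are
#'   natural.
#' @name alignment_scoring
NULL

PROB_FLOOR <- 1e-9

clamp_prob <- function(p) pmax(p, PROB_FLOOR)

pa_of <- function(params, residue) {
  p <- params$p_a[residue]
  p[is.na(p)] <- params$p_a[[params$unk]]  # out-of-table => unsupported
  unname(p)
}

#' Residue component of a column log-probability
#'
#' A match (equal residues, neither the unsupported sign — two unsupported
#' residues are never equal) contributes `log PmatchA(level)`; a mismatch
#' contributes `log((1 - PmatchA(level)) * PA(a_nrp) / (1 - PA(a_bgc)))`.
#' Probabilities are floored at `1e-9` before taking logs.
#'
#' @param a_nrp NRP residue name (alphabet member or the unsupported sign).
#' @param level discretized specificity level 0..5 of the BGC prediction.
#' @param a_bgc BGC residue name.
#' @param params an [nrps_params()] object.
#' @return log-probability (natural log).
#' @export
residue_log_p <- function(a_nrp, level, a_bgc, params) {
  pm <- params$p_match_a[[as.character(level)]]
  is_match <- identical(a_nrp, a_bgc) && !identical(a_nrp, params$unk)
  if (is_match) {
    log(clamp_prob(pm))
  } else {
    log(clamp_prob(1 - pm)) + log(clamp_prob(pa_of(params, a_nrp))) -
      log(clamp_prob(1 - pa_of(params, a_bgc)))
  }
}

#' Null-model residue log-probability
#'
#' Probability of observing residue `a_nrp` under an undefined module:
#' `PA(a_nrp) / (1 - PA(unk))` (the mismatch branch at level 0, where the
#' match probability is 0 by convention).
#'
#' @inheritParams residue_log_p
#' @return log-probability.
#' @export
null_residue_log_p <- function(a_nrp, params) {
  denom <- 1 - params$p_a[[params$unk]]
  if (denom <= 0)
    stop("PA(unsupported) must be < 1", call. = FALSE)
  log(clamp_prob(pa_of(params, a_nrp))) - log(clamp_prob(denom))
}

#' Methylation / stereo component of a column log-probability
#'
#' Equal non-zero states contribute `log Pmatch(state)`; opposite non-zero
#' states `log Pmismatch(nrp_state)`; an undefined BGC state (0) falls back
#' to the background `log P(nrp_state)`. For stereo, an undetermined NRP
#' state (0) is uninformative and contributes exactly 0.
#'
#' @param x_nrp NRP-side trit (`-1`/`+1`; stereo may be `0`).
#' @param x_bgc BGC-side trit (`-1`/`0`/`+1`).
#' @param kind `"methylation"` or `"stereo"`.
#' @param params an [nrps_params()] object.
#' @return log-probability.
#' @export
modification_log_p <- function(x_nrp, x_bgc, kind = c("methylation",
                                                      "stereo"), params) {
  kind <- match.arg(kind)
  if (kind == "stereo" && x_nrp == 0L) return(0)
  key <- as.character(x_nrp)
  if (x_bgc == 0L) {
    bg <- if (kind == "methylation") params$p_m else params$p_e
    return(log(clamp_prob(bg[[key]])))
  }
  tab <- if (x_nrp == x_bgc) {
    if (kind == "methylation") params$p_match_m else params$p_match_e
  } else {
    if (kind == "methylation") params$p_mismatch_m else params$p_mismatch_e
  }
  log(clamp_prob(tab[[key]]))
}

#' Log-probability of one alignment column
#'
#' @param nrp one-row NRP monomer data.frame, or `NULL` for an NRP gap
#'   (deletion column).
#' @param bgc one-row BGC monomer data.frame, or `NULL` for a BGC gap
#'   (insertion column).
#' @param params an [nrps_params()] object.
#' @return list with `log_p` and `parts` (named numeric: `a`, `m`, `e`);
#'   insertion columns book the gap and residue/modification factors under
#'   `a`/`m`/`e`, deletion columns book `log Pdeletion` under `a`.
#' @export
column_log_p <- function(nrp, bgc, params) {
  if (is.null(nrp) && is.null(bgc))
    stop("gap-vs-gap column is not a valid alignment column", call. = FALSE)
  if (is.null(nrp)) {              # deletion: module without product
    lp <- log(clamp_prob(params$p_deletion))
    return(list(log_p = lp, parts = c(a = lp, m = 0, e = 0)))
  }
  if (is.null(bgc)) {              # insertion: monomer without module
    a <- log(clamp_prob(params$p_insertion)) +
      log(clamp_prob(pa_of(params, nrp$residue)))
    m <- log(clamp_prob(params$p_m[[as.character(nrp$methylated)]]))
    e <- if (nrp$stereo == 0L) 0 else
      log(clamp_prob(params$p_e[[as.character(nrp$stereo)]]))
    return(list(log_p = a + m + e, parts = c(a = a, m = m, e = e)))
  }
  level <- discretize_specificity(bgc$specificity,
                                  params$level_boundaries)
  a <- residue_log_p(nrp$residue, level, bgc$residue, params)
  m <- modification_log_p(nrp$methylated, bgc$methylated, "methylation",
                          params)
  e <- modification_log_p(nrp$stereo, bgc$stereo, "stereo", params)
  list(log_p = a + m + e, parts = c(a = a, m = m, e = e))
}

# Internal: per-monomer null log-probabilities for an NRP sequence
# (residue, methylation and stereo background terms).
null_log_p_terms <- function(nrp_seq, params) {
  vapply(seq_len(nrow(nrp_seq)), function(i) {
    a <- null_residue_log_p(nrp_seq$residue[i], params)
    m <- log(clamp_prob(params$p_m[[as.character(nrp_seq$methylated[i])]]))
    e <- if (nrp_seq$stereo[i] == 0L) 0 else
      log(clamp_prob(params$p_e[[as.character(nrp_seq$stereo[i])]]))
    a + m + e
  }, numeric(1))
}

#' Align an NRP sequence to a BGC assembly line
#'
#' Global alignment maximizing the summed column log-probabilities via
#' Needleman-Wunsch (the null term does not depend on the alignment, so
#' this also maximizes the log-odds score). Traceback tie-breaking prefers
#' match/mismatch over deletion over insertion.
#'
#' @param nrp_seq NRP monomer data.frame (`residue`, `methylated`, `stereo`)
#'   or a candidate list with a `monomers` field.
#' @param bgc_seq BGC monomer data.frame (`specificity`, `residue`,
#'   `methylated`, `stereo`, optionally `gene_id`, `module`) or an assembly
#'   line list with a `monomers` field.
#' @param params an [nrps_params()] object.
#' @param allow_gaps set `FALSE` to force the gap-free diagonal alignment
#'   (requires equal lengths).
#' @return an object of class `nrps_alignment`: list with `columns`
#'   (data.frame: kind, nrp/bgc fields, per-column `log_p` and `a`/`m`/`e`
#'   parts), `score`, `aligned_log_p`, `null_log_p`.
#' @export
align_sequences <- function(nrp_seq, bgc_seq, params, allow_gaps = TRUE) {
  if (is.list(nrp_seq) && !is.data.frame(nrp_seq)) nrp_seq <- nrp_seq$monomers
  if (is.list(bgc_seq) && !is.data.frame(bgc_seq)) bgc_seq <- bgc_seq$monomers
  n <- nrow(nrp_seq); m <- nrow(bgc_seq)
  stopifnot(n >= 1, m >= 1)
  null_terms <- null_log_p_terms(nrp_seq, params)

  M <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    M[i, j] <- column_log_p(nrp_seq[i, , drop = FALSE],
                            bgc_seq[j, , drop = FALSE], params)$log_p
  ins <- vapply(seq_len(n), function(i)
    column_log_p(nrp_seq[i, , drop = FALSE], NULL, params)$log_p,
    numeric(1))
  del <- column_log_p(NULL, bgc_seq[1, , drop = FALSE], params)$log_p

  if (!allow_gaps) {
    if (n != m)
      stop("gap-free alignment requires equal lengths", call. = FALSE)
    steps <- data.frame(kind = rep("match", n), i = seq_len(n),
                        j = seq_len(n))
  } else {
    D <- matrix(-Inf, n + 1L, m + 1L)
    D[1, 1] <- 0
    for (j in seq_len(m)) D[1, j + 1L] <- D[1, j] + del
    for (i in seq_len(n)) D[i + 1L, 1] <- D[i, 1] + ins[i]
    for (i in seq_len(n)) for (j in seq_len(m))
      D[i + 1L, j + 1L] <- max(D[i, j] + M[i, j],
                               D[i + 1L, j] + del,
                               D[i, j + 1L] + ins[i])
    # traceback, preferring match > deletion > insertion
    steps <- list()
    i <- n; j <- m
    eps <- 1e-12
    while (i > 0L || j > 0L) {
      here <- D[i + 1L, j + 1L]
      if (i > 0L && j > 0L && abs(D[i, j] + M[i, j] - here) <= eps) {
        steps[[length(steps) + 1L]] <- c(1L, i, j); i <- i - 1L; j <- j - 1L
      } else if (j > 0L && abs(D[i + 1L, j] + del - here) <= eps) {
        steps[[length(steps) + 1L]] <- c(2L, i, j); j <- j - 1L
      } else {
        steps[[length(steps) + 1L]] <- c(3L, i, j); i <- i - 1L
      }
    }
    steps <- do.call(rbind, rev(steps))
    steps <- data.frame(kind = c("match", "deletion", "insertion")[steps[, 1]],
                        i = steps[, 2], j = steps[, 3])
  }

  cols <- lapply(seq_len(nrow(steps)), function(r) {
    kind <- steps$kind[r]; i <- steps$i[r]; j <- steps$j[r]
    nrp <- if (kind != "deletion") nrp_seq[i, , drop = FALSE] else NULL
    bgc <- if (kind != "insertion") bgc_seq[j, , drop = FALSE] else NULL
    cl <- column_log_p(nrp, bgc, params)
    data.frame(
      kind = kind,
      nrp_residue = if (is.null(nrp)) "-" else nrp$residue,
      nrp_m = if (is.null(nrp)) NA_integer_ else nrp$methylated,
      nrp_e = if (is.null(nrp)) NA_integer_ else nrp$stereo,
      bgc_residue = if (is.null(bgc)) "-" else bgc$residue,
      bgc_s = if (is.null(bgc)) NA_integer_ else bgc$specificity,
      bgc_m = if (is.null(bgc)) NA_integer_ else bgc$methylated,
      bgc_e = if (is.null(bgc)) NA_integer_ else bgc$stereo,
      gene_id = if (!is.null(bgc) && "gene_id" %in% names(bgc))
        bgc$gene_id else NA_character_,
      module = if (!is.null(bgc) && "module" %in% names(bgc))
        bgc$module else NA_integer_,
      log_p = cl$log_p,
      a_part = cl$parts[["a"]], m_part = cl$parts[["m"]],
      e_part = cl$parts[["e"]],
      stringsAsFactors = FALSE)
  })
  columns <- do.call(rbind, cols)
  aligned_log_p <- sum(columns$log_p)
  null_log_p <- sum(null_terms)
  structure(list(columns = columns,
                 score = aligned_log_p - null_log_p,
                 aligned_log_p = aligned_log_p,
                 null_log_p = null_log_p,
                 n = n, m = m),
            class = "nrps_alignment")
}

#' @export
print.nrps_alignment <- function(x, ...) {
  cat(render_alignment(x), sep = "\n")
  invisible(x)
}

#' Render an alignment as two-row text
#'
#' Per column: the BGC residue with its specificity level and m/e flags over
#' the NRP residue with its m/e flags, followed by the per-column score
#' parts.
#'
#' @param alignment an `nrps_alignment`.
#' @return character vector of report lines.
#' @export
render_alignment <- function(alignment) {
  co <- alignment$columns
  flag <- function(v, chr) ifelse(is.na(v) | v != 1L, "", chr)
  ecode <- function(v) ifelse(is.na(v), "", ifelse(v == 1L, ":D",
                                            ifelse(v == -1L, ":L", "")))
  bgc_lab <- ifelse(co$kind == "insertion", "-",
                    paste0(co$bgc_residue,
                           ifelse(is.na(co$bgc_s), "",
                                  paste0("(", co$bgc_s, ")")),
                           flag(co$bgc_m, "*"), ecode(co$bgc_e)))
  nrp_lab <- ifelse(co$kind == "deletion", "-",
                    paste0(co$nrp_residue, flag(co$nrp_m, "*"),
                           ecode(co$nrp_e)))
  gene <- ifelse(is.na(co$gene_id), "", paste0(co$gene_id, ":",
                                               co$module))
  w <- pmax(nchar(bgc_lab), nchar(nrp_lab), nchar(gene))
  pad <- function(s) formatC(s, width = max(w), flag = "-")
  c(sprintf("score %.4f  (aligned %.4f - null %.4f); columns: %d",
            alignment$score, alignment$aligned_log_p, alignment$null_log_p,
            nrow(co)),
    paste("GENE", paste(vapply(gene, pad, ""), collapse = " ")),
    paste("BGC ", paste(vapply(bgc_lab, pad, ""), collapse = " ")),
    paste("NRP ", paste(vapply(nrp_lab, pad, ""), collapse = " ")),
    paste("dSc ", paste(vapply(sprintf("%.2f", co$log_p), pad, ""),
                        collapse = " ")))
}

#' Best-scoring pair among candidate sequences and assembly lines
#'
#' Evaluates [align_sequences()] on the full cross product and returns the
#' argmax with deterministic (index-lexicographic) tie-breaking, plus the
#' all-pairs score table.
#'
#' @param nrp_candidates list of candidate NRP sequences (from
#'   [linearize_graph()], or plain monomer data.frames).
#' @param assembly_lines list of assembly lines (from [process_bgc()], or
#'   plain BGC monomer data.frames).
#' @param params an [nrps_params()] object.
#' @return list with `best` (an `nrps_alignment` carrying `nrp_index` /
#'   `bgc_index` attributes), `score`, and `table`
#'   (data.frame nrp_index, bgc_index, score).
#' @export
best_pair_score <- function(nrp_candidates, assembly_lines, params) {
  stopifnot(length(nrp_candidates) >= 1, length(assembly_lines) >= 1)
  best <- NULL; best_score <- -Inf; best_i <- NA; best_j <- NA
  tab <- expand.grid(bgc_index = seq_along(assembly_lines),
                     nrp_index = seq_along(nrp_candidates))[, 2:1]
  scores <- numeric(nrow(tab))
  r <- 0L
  for (i in seq_along(nrp_candidates)) {
    for (j in seq_along(assembly_lines)) {
      r <- r + 1L
      al <- align_sequences(nrp_candidates[[i]], assembly_lines[[j]],
                            params)
      scores[r] <- al$score
      if (al$score > best_score) {   # strict: first index pair wins ties
        best <- al; best_score <- al$score; best_i <- i; best_j <- j
      }
    }
  }
  tab$score <- scores
  attr(best, "nrp_index") <- best_i
  attr(best, "bgc_index") <- best_j
  list(best = best, score = best_score, table = tab)
}
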