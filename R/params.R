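#' Scoring parameters for the log-odds alignment model
#'
#' Container for all probabilities of the match/mismatch/indel model plus
#' the specificity score-level boundaries. The residue match probability
#' depends only on the discretized specificity level of the adenylation
#' domain prediction, not on the underlying residue; methylation and stereo
#' events are modelled with small per-state tables.
#'
#' @param p_match_a numeric length 6, named `"0"`..`"5"`: probability that a
#'   module whose prediction falls in a given score level incorporates
#'   exactly the predicted residue. Level 0 (unreliable prediction) must be 0.
#' @param p_a named numeric: background frequency of each residue in NRPs,
#'   over the alphabet plus the unsupported sign; sums to 1.
#' @param p_m named numeric `c("-1", "1")`: background methylation
#'   frequencies; sums to 1.
#' @param p_e named numeric `c("-1", "1")`: background L/D frequencies among
#'   stereo-determined monomers; sums to 1.
#' @param p_match_m,p_mismatch_m named numeric `c("-1", "1")`: frequencies of
#'   methylation agreement/disagreement events, indexed by the NRP state.
#' @param p_match_e,p_mismatch_e named numeric `c("-1", "1")`: frequencies of
#'   stereo agreement/disagreement events, indexed by the NRP state (for a
#'   mismatch the BGC state is the negation).
#' @param p_insertion probability of an NRP monomer without a matching
#'   module (per NRP monomer).
#' @param p_deletion probability of a skipped module (per BGC monomer).
#' @param level_boundaries ascending integer cut points (default
#'   `c(60, 70, 80, 90)`) splitting the score scale `[1..100]` into exactly
#'   5 levels: `[1,60], (60,70], (70,80], (80,90], (90,100]`.
#' @param unk the unsupported-residue sign used in `p_a`.
#' @return an object of class `nrps_params` (a named list).
#' @export
nrps_params <- function(p_match_a, p_a, p_m, p_e,
                        p_match_m, p_mismatch_m, p_match_e, p_mismatch_e,
                        p_insertion, p_deletion,
                        level_boundaries = c(60L, 70L, 80L, 90L),
                        unk = "unk") {
  names(p_match_a) <- as.character(0:5)
  obj <- structure(list(
    p_match_a = as.numeric(p_match_a) |> stats::setNames(as.character(0:5)),
    p_a = p_a,
    p_m = p_m[c("-1", "1")],
    p_e = p_e[c("-1", "1")],
    p_match_m = p_match_m[c("-1", "1")],
    p_mismatch_m = p_mismatch_m[c("-1", "1")],
    p_match_e = p_match_e[c("-1", "1")],
    p_mismatch_e = p_mismatch_e[c("-1", "1")],
    p_insertion = as.numeric(p_insertion),
    p_deletion = as.numeric(p_deletion),
    level_boundaries = as.integer(level_boundaries),
    unk = unk
  ), class = "nrps_params")
  obj
}

#' @export
print.nrps_params <- function(x, ...) {
  cat("Log-odds scoring parameters\n")
  cat("  residues in background table:", length(x$p_a),
      "(incl. '", x$unk, "')\n", sep = "")
  cat("  P_matchA by level 0..5:",
      paste(signif(x$p_match_a, 3), collapse = " "), "\n")
  cat("  level boundaries:", paste(x$level_boundaries, collapse = " "), "\n")
  cat("  P_insertion:", signif(x$p_insertion, 4),
      " P_deletion:", signif(x$p_deletion, 4), "\n")
  invisible(x)
}

#' Discretize a specificity score into a level
#'
#' Maps the raw specificity score scale to six levels: the reserved level 0
#' for `s = 0` (a completely unreliable prediction) and levels 1..5 for
#' `s` in `[1..100]`, cut at `boundaries` (intervals are left-closed at 1 and
#' right-closed at each boundary). The map is monotone non-decreasing.
#'
#' @param s integer score(s) in `[0, 100]` (vectorized).
#' @param boundaries ascending cut points, default `c(60, 70, 80, 90)`.
#' @return integer level(s) in `0..5`.
#' @export
discretize_specificity <- function(s, boundaries = c(60L, 70L, 80L, 90L)) {
  s <- as.numeric(s)
  if (any(is.na(s) | s < 0 | s > 100))
    stop("specificity score out of range [0, 100]", call. = FALSE)
  boundaries <- sort(as.numeric(boundaries))
  if (length(boundaries) != 4 || any(boundaries <= 0) ||
      any(boundaries >= 100) || anyDuplicated(boundaries))
    stop("boundaries must be 4 distinct cut points inside (0, 100)",
         call. = FALSE)
  lev <- findInterval(s, boundaries, left.open = TRUE) + 1L
  lev[s == 0] <- 0L
  lev
}

#' Validate scoring parameters
#'
#' Checks every structural invariant of [nrps_params()] and returns the list
#' of violations (empty character vector when valid).
#'
#' @param params an `nrps_params` object.
#' @param tol absolute tolerance for normalization checks.
#' @return character vector of violation messages.
#' @export
validate_params <- function(params, tol = 1e-9) {
  v <- character(0)
  probs <- c(params$p_match_a, params$p_a, params$p_m, params$p_e,
             params$p_match_m, params$p_mismatch_m,
             params$p_match_e, params$p_mismatch_e,
             params$p_insertion, params$p_deletion)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    v <- c(v, "probability out of range [0, 1]")
  if (length(params$p_match_a) != 6)
    v <- c(v, "p_match_a must have 6 entries (levels 0..5)")
  else if (abs(params$p_match_a[["0"]]) > tol)
    v <- c(v, "PmatchA(0) must be 0")
  if (!params$unk %in% names(params$p_a))
    v <- c(v, sprintf("p_a must include the unsupported sign '%s'",
                      params$unk))
  if (abs(sum(params$p_a) - 1) > tol)
    v <- c(v, "p_a must sum to 1")
  if (abs(sum(params$p_m) - 1) > tol)
    v <- c(v, "p_m must sum to 1")
  if (abs(sum(params$p_e) - 1) > tol)
    v <- c(v, "p_e must sum to 1")
  lb <- params$level_boundaries
  if (length(lb) != 4 || is.unsorted(lb, strictly = TRUE) ||
      any(lb <= 0) || any(lb >= 100))
    v <- c(v, "level_boundaries must be 4 ascending cut points in (0, 100)")
  v
}

#' Write scoring parameters to a YAML file
#'
#' Probabilities are printed with 15 significant digits so that a read-back
#' reproduces them at the stated precision.
#'
#' @param params an `nrps_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  doc <- list(
    unk = params$unk,
    level_boundaries = params$level_boundaries,
    p_match_a = as.list(params$p_match_a),
    p_a = as.list(params$p_a),
    p_m = as.list(params$p_m),
    p_e = as.list(params$p_e),
    p_match_m = as.list(params$p_match_m),
    p_mismatch_m = as.list(params$p_mismatch_m),
    p_match_e = as.list(params$p_match_e),
    p_mismatch_e = as.list(params$p_mismatch_e),
    p_insertion = params$p_insertion,
    p_deletion = params$p_deletion
  )
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' Read scoring parameters from a YAML file
#'
#' @param path path to a file written by [write_params()] (or hand-edited in
#'   the same schema).
#' @param validate stop on invariant violations?
#' @return an `nrps_params` object.
#' @export
read_params <- function(path, validate = TRUE) {
  doc <- yaml::read_yaml(path)
  need <- c("p_match_a", "p_a", "p_m", "p_e", "p_match_m", "p_mismatch_m",
            "p_match_e", "p_mismatch_e", "p_insertion", "p_deletion",
            "level_boundaries")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("params file missing section(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  unl <- function(x) unlist(x)
  params <- nrps_params(
    p_match_a = unl(doc$p_match_a),
    p_a = unl(doc$p_a),
    p_m = unl(doc$p_m), p_e = unl(doc$p_e),
    p_match_m = unl(doc$p_match_m), p_mismatch_m = unl(doc$p_mismatch_m),
    p_match_e = unl(doc$p_match_e), p_mismatch_e = unl(doc$p_mismatch_e),
    p_insertion = doc$p_insertion, p_deletion = doc$p_deletion,
    level_boundaries = unl(doc$level_boundaries),
    unk = if (is.null(doc$unk)) "unk" else doc$unk
  )
  if (validate) {
    v <- validate_params(params)
    if (length(v))
      stop("invalid params file: ", paste(v, collapse = "; "),
           call. = FALSE)
  }
  params
}

#' Path to the default scoring-parameter file
#'
#' The shipped values are documented placeholders chosen to be realistic for
#' bacterial NRPs; they are meant to be re-learned from curated alignments
#' with [estimate_params()] / [bootstrap_params()].
#' @return a file path
#' @export
default_params_file <- function() {
  system.file("extdata", "params_default.yaml", package = "nrpslink",
              mustWork = TRUE)
}

#' Load the default scoring parameters
#' @return an `nrps_params` object
#' @export
default_params <- function() read_params(default_params_file())
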