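#' NRP monomer
#'
#' A monomer obtained from the decomposition of an NRP chemical structure:
#' a core residue name, a methylation flag and a D/L stereo flag. Flags use
#' the trit encoding `-1` / `0` / `+1`: methylation is `-1` (absent) or `+1`
#' (present); stereo is `-1` (L), `+1` (D) or `0` when the configuration is
#' undetermined or irrelevant (e.g. achiral glycine).
#'
#' @param residue residue name; either a member of the alphabet or its
#'   unsupported sign.
#' @param methylated `-1` or `+1`.
#' @param stereo `-1`, `0` or `+1`.
#' @param alphabet optional [residue_alphabet()] to validate against.
#' @return a one-row data.frame with columns `residue`, `methylated`,
#'   `stereo`.
#' @export
nrp_monomer <- function(residue, methylated = -1L, stereo = 0L,
                        alphabet = NULL) {
  residue <- tolower(as.character(residue))
  methylated <- as.integer(methylated)
  stereo <- as.integer(stereo)
  if (!methylated %in% c(-1L, 1L))
    stop("methylated must be -1 or +1", call. = FALSE)
  if (!stereo %in% c(-1L, 0L, 1L))
    stop("stereo must be -1, 0 or +1", call. = FALSE)
  if (!is.null(alphabet) &&
      !residue %in% c(as.character(alphabet), unsupported_sign(alphabet)))
    stop("residue '", residue, "' is neither in the alphabet nor its ",
         "unsupported sign", call. = FALSE)
  data.frame(residue = residue, methylated = methylated, stereo = stereo,
             stringsAsFactors = FALSE)
}

#' BGC monomer
#'
#' A monomer predicted from an NRPS module: the specificity score `s` of the
#' adenylation-domain prediction (integer 0-100; 0 marks a completely
#' unreliable prediction), the predicted core residue, and methylation /
#' epimerization flags derived from M and E (or downstream C/E) domains.
#' The special *undefined* monomer (`undefined = TRUE`) has
#' `(s, residue, m, e) = (0, unk, 0, 0)` and is the unit of the null model.
#'
#' @param residue residue name in the alphabet (ignored when `undefined`).
#' @param specificity integer in `[0, 100]`.
#' @param methylated `-1` or `+1` (`0` only for the undefined monomer).
#' @param stereo `-1` or `+1` (`0` only for the undefined monomer).
#' @param undefined logical; construct the undefined monomer.
#' @param alphabet optional [residue_alphabet()] to validate against.
#' @param unk unsupported sign used when `undefined` and no alphabet given.
#' @return a one-row data.frame with columns `specificity`, `residue`,
#'   `methylated`, `stereo`, `undefined`.
#' @export
bgc_monomer <- function(residue = NULL, specificity = 0L, methylated = -1L,
                        stereo = -1L, undefined = FALSE, alphabet = NULL,
                        unk = "unk") {
  if (undefined) {
    sign <- if (!is.null(alphabet)) unsupported_sign(alphabet) else unk
    return(data.frame(specificity = 0L, residue = sign,
                      methylated = 0L, stereo = 0L, undefined = TRUE,
                      stringsAsFactors = FALSE))
  }
  residue <- tolower(as.character(residue))
  specificity <- as.integer(specificity)
  methylated <- as.integer(methylated)
  stereo <- as.integer(stereo)
  if (is.na(specificity) || specificity < 0L || specificity > 100L)
    stop("specificity must be an integer in [0, 100]", call. = FALSE)
  if (!methylated %in% c(-1L, 1L))
    stop("methylated must be -1 or +1 for a defined BGC monomer",
         call. = FALSE)
  if (!stereo %in% c(-1L, 1L))
    stop("stereo must be -1 or +1 for a defined BGC monomer", call. = FALSE)
  if (!is.null(alphabet)) {
    if (identical(residue, unsupported_sign(alphabet)))
      stop("a defined BGC monomer cannot carry the unsupported sign",
           call. = FALSE)
    if (!residue %in% as.character(alphabet))
      stop("residue '", residue, "' not in alphabet", call. = FALSE)
  }
  data.frame(specificity = specificity, residue = residue,
             methylated = methylated, stereo = stereo, undefined = FALSE,
             stringsAsFactors = FALSE)
}

#' Bind monomer rows into a sequence
#'
#' @param ... one-row monomer data.frames (or multi-row sequences).
#' @return a data.frame; rows in order of incorporation.
#' @export
monomer_sequence <- function(...) {
  do.call(rbind, list(...))
}

# Internal: a BGC sequence of n undefined monomers (the null model).
null_bgc_sequence <- function(n, unk = "unk") {
  do.call(rbind, replicate(n, bgc_monomer(undefined = TRUE, unk = unk),
                           simplify = FALSE))
}
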