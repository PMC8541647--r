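#' Residue alphabet
#'
#' The set of supported core residue names used on both the NRP and the BGC
#' side of a match. Any residue outside the set is represented by a single
#' reserved symbol (`unsupported_sign`, default `"unk"`). Because many
#' distinct unsupported residues exist, two `unk` residues are never
#' considered equal during scoring.
#'
#' @param residues character vector of residue names (case-insensitive,
#'   stored lower-case).
#' @param unsupported_sign reserved symbol for out-of-alphabet residues.
#' @param frequencies optional numeric vector of background frequencies,
#'   same length as `residues` (not required to be normalized here).
#' @return an object of class `residue_alphabet`: a character vector of
#'   residue names with attributes `unsupported_sign` and (optionally)
#'   `frequencies`.
#' @export
residue_alphabet <- function(residues, unsupported_sign = "unk",
                             frequencies = NULL) {
  residues <- tolower(trimws(as.character(residues)))
  if (any(!nzchar(residues)))
    stop("empty residue name in alphabet", call. = FALSE)
  dup <- unique(residues[duplicated(residues)])
  if (length(dup))
    stop("duplicate residue name(s) in alphabet: ",
         paste(dup, collapse = ", "), call. = FALSE)
  if (unsupported_sign %in% residues)
    stop("unsupported_sign '", unsupported_sign,
         "' must not be a member of the alphabet", call. = FALSE)
  if (!is.null(frequencies)) {
    if (length(frequencies) != length(residues))
      stop("frequencies must match residues in length", call. = FALSE)
    names(frequencies) <- residues
  }
  structure(residues,
            unsupported_sign = unsupported_sign,
            frequencies = frequencies,
            class = "residue_alphabet")
}

#' @export
print.residue_alphabet <- function(x, ...) {
  cat("Residue alphabet:", length(x), "residues (unsupported sign: '",
      attr(x, "unsupported_sign"), "')\n", sep = "")
  cat(strwrap(paste(unclass(x), collapse = " "), width = 76,
              prefix = "  "), sep = "\n")
  invisible(x)
}

#' Symbol used for out-of-alphabet residues
#' @param alphabet a `residue_alphabet`
#' @return the reserved symbol (a string)
#' @export
unsupported_sign <- function(alphabet) attr(alphabet, "unsupported_sign")

#' Load a residue alphabet from a TSV file
#'
#' The file has one residue per row: column 1 the residue name, optional
#' column 2 a background frequency. Lines starting with `#` are comments.
#'
#' @param path path to the alphabet file.
#' @param unsupported_sign reserved symbol for out-of-alphabet residues.
#' @return a [residue_alphabet()].
#' @export
load_alphabet <- function(path, unsupported_sign = "unk") {
  if (!file.exists(path))
    stop("alphabet file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (!length(keep)) stop("alphabet file is empty: ", path, call. = FALSE)
  res <- character(length(keep))
  freq <- rep(NA_real_, length(keep))
  for (k in seq_along(keep)) {
    fields <- strsplit(lines[keep[k]], "\t| +")[[1]]
    fields <- fields[nzchar(fields)]
    if (!length(fields) || length(fields) > 2)
      stop("malformed alphabet row at line ", keep[k], ": '",
           lines[keep[k]], "'", call. = FALSE)
    res[k] <- fields[1]
    if (length(fields) == 2) {
      f <- suppressWarnings(as.numeric(fields[2]))
      if (is.na(f))
        stop("malformed frequency at line ", keep[k], ": '",
             fields[2], "'", call. = FALSE)
      freq[k] <- f
    }
  }
  residue_alphabet(res, unsupported_sign = unsupported_sign,
                   frequencies = if (all(is.na(freq))) NULL else freq)
}

#' Path to the default residue alphabet shipped with the package
#' @return a file path
#' @export
default_alphabet_file <- function() {
  system.file("extdata", "alphabet.tsv", package = "nrpslink",
              mustWork = TRUE)
}

#' Load the default residue alphabet (58 residues)
#' @return a [residue_alphabet()]
#' @export
default_alphabet <- function() load_alphabet(default_alphabet_file())
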