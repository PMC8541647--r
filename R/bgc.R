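#' @title BGC assembly: from module annotations to candidate monomer
#'   sequences
#' @description Each NRPS gene is annotated as an ordered list of modules,
#'   each module an ordered list of domains. An adenylation (A) domain
#'   carries substrate predictions (residue, Stachelhaus score, SVM score);
#'   M domains methylate, E domains epimerize, and a dual C/E domain acts as
#'   an E domain on the *previous* module. A gene yields a *strip*: the
#'   ordered run of predicted BGC monomers, never internally permuted.
#'   Deficient modules (no A domain) expand the strip into stutter /
#'   iterative-reuse variants; distance and starter/termination domains
#'   split erroneously merged clusters; and consistency rules on CS, TE and
#'   COM domains constrain how strips are ordered into candidate assembly
#'   lines.
#' @name bgc_assembly
NULL

MODULE_DOMAIN_KINDS <- c("A", "C", "C/E", "E", "M", "PCP", "CS", "TE",
                         "COM_N", "COM_C")

#' Construct a gene annotation
#'
#' @param gene_id gene identifier.
#' @param start,end 1-based inclusive nucleotide coordinates (`start < end`).
#' @param strand `"+"` or `"-"` (module order is taken as annotated, i.e.
#'   translation order, for either strand).
#' @param modules list of modules; each module is a list of domains, a
#'   domain being `list(kind = ..., predictions = data.frame(residue,
#'   stachelhaus, svm))` with predictions present iff `kind == "A"`.
#' @return an object of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, start, end, strand = "+",
                            modules = list()) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!isTRUE(start < end))
    stop("gene '", gene_id, "': start must be < end", call. = FALSE)
  kinds <- unlist(lapply(modules, function(m)
    vapply(m, `[[`, "", "kind")))
  bad <- setdiff(kinds, MODULE_DOMAIN_KINDS)
  if (length(bad))
    stop("gene '", gene_id, "': unknown domain kind(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (m in modules) for (d in m) {
    has_pred <- !is.null(d$predictions) && nrow(d$predictions) > 0
    if (identical(d$kind, "A") && !has_pred)
      stop("gene '", gene_id, "': A domain without predictions",
           call. = FALSE)
    if (!identical(d$kind, "A") && has_pred)
      stop("gene '", gene_id, "': predictions on non-A domain",
           call. = FALSE)
  }
  structure(list(gene_id = as.character(gene_id), start = start, end = end,
                 strand = strand, modules = modules,
                 has_CS = "CS" %in% kinds, has_TE = "TE" %in% kinds,
                 has_COM_N = "COM_N" %in% kinds,
                 has_COM_C = "COM_C" %in% kinds),
            class = "gene_annotation")
}

module_kinds <- function(module) vapply(module, `[[`, "", "kind")

module_has_A <- function(module) "A" %in% module_kinds(module)

is_sole_pcp <- function(module) identical(module_kinds(module), "PCP")

#' Convert one typical module into a BGC monomer
#'
#' Predicted residues are ranked by the mean of their Stachelhaus and SVM
#' scores and the top one becomes the core residue; the specificity score is
#' that mean, rounded half-up to an integer. Methylation is `+1` iff the
#' module carries an M domain. Stereo is `+1` iff the module carries an E
#' domain or the *next* module carries a dual C/E domain (which epimerizes
#' the previous residue), else `-1`. A predicted residue outside the
#' alphabet is first looked up in `synonyms`; if still unknown the monomer
#' is flagged undefined.
#'
#' @param module an ordered list of domains containing exactly one A domain.
#' @param next_module_has_CE does the following module carry a C/E domain?
#' @param alphabet a [residue_alphabet()].
#' @param synonyms optional named character vector mapping out-of-alphabet
#'   prediction names to alphabet residues.
#' @return one-row BGC monomer data.frame (see [bgc_monomer()]).
#' @export
module_to_monomer <- function(module, next_module_has_CE = FALSE,
                              alphabet = default_alphabet(),
                              synonyms = NULL) {
  kinds <- module_kinds(module)
  a_idx <- which(kinds == "A")
  if (length(a_idx) != 1)
    stop("module must contain exactly one A domain", call. = FALSE)
  preds <- module[[a_idx]]$predictions
  means <- (as.numeric(preds$stachelhaus) + as.numeric(preds$svm)) / 2
  best <- which.max(means)  # ties: first listed prediction wins
  residue <- tolower(as.character(preds$residue[best]))
  spec <- floor(means[best] + 0.5)  # half-up, platform-stable
  if (!residue %in% as.character(alphabet) && !is.null(synonyms) &&
      residue %in% names(synonyms))
    residue <- tolower(synonyms[[residue]])
  methylated <- if ("M" %in% kinds) 1L else -1L
  stereo <- if ("E" %in% kinds || isTRUE(next_module_has_CE)) 1L else -1L
  if (!residue %in% as.character(alphabet)) {
    warning("predicted residue '", residue,
            "' not in alphabet; module treated as undefined",
            call. = FALSE)
    return(bgc_monomer(undefined = TRUE, alphabet = alphabet))
  }
  bgc_monomer(residue, specificity = spec, methylated = methylated,
              stereo = stereo, alphabet = alphabet)
}

# Internal: monomers of all typical modules of a gene, in module order.
gene_base_monomers <- function(gene, alphabet, synonyms = NULL) {
  mods <- gene$modules
  out <- list()
  for (j in seq_along(mods)) {
    if (!module_has_A(mods[[j]])) next
    nxt_ce <- j < length(mods) && "C/E" %in% module_kinds(mods[[j + 1]])
    mono <- module_to_monomer(mods[[j]], next_module_has_CE = nxt_ce,
                              alphabet = alphabet, synonyms = synonyms)
    mono$gene_id <- gene$gene_id
    mono$module <- j
    out[[length(out) + 1L]] <- mono
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

strip_flags <- function(gene) {
  list(has_CS = gene$has_CS, has_TE = gene$has_TE,
       has_COM_N = gene$has_COM_N, has_COM_C = gene$has_COM_C)
}

#' Expand a gene into its strip variants
#'
#' The initial strip holds one monomer per typical (A-domain-bearing)
#' module. Each A-less deficient module may *stutter*, reusing the previous
#' typical module's A domain, so variants repeat that monomer 1..`max_copies`
#' times (1 copy = the unexpanded strip). A deficient module consisting of a
#' sole PCP domain and located last in the gene signals iterative reuse of
#' the whole gene: variants repeat the entire strip 1..`max_copies` times.
#' Multiple deficient modules expand multiplicatively.
#'
#' @param gene a [gene_annotation()].
#' @param max_copies maximum copy count per deficient module (default 3).
#' @param alphabet a [residue_alphabet()].
#' @param synonyms optional synonym map, see [module_to_monomer()].
#' @return list of strips: `list(gene_id, monomers, flags, variant_tag)`.
#' @export
expand_deficient_modules <- function(gene, max_copies = 3L,
                                     alphabet = default_alphabet(),
                                     synonyms = NULL) {
  mods <- gene$modules
  base <- gene_base_monomers(gene, alphabet, synonyms)
  if (is.null(base)) {
    warning("gene '", gene$gene_id, "' has no typical module; empty strip",
            call. = FALSE)
    return(list())
  }
  n_mod <- length(mods)
  typical <- vapply(mods, module_has_A, logical(1))
  stutter_sites <- integer(0)   # deficient module index -> prev typical idx
  iterative <- FALSE
  for (j in seq_len(n_mod)) {
    if (typical[j]) next
    if (j == n_mod && is_sole_pcp(mods[[j]])) {
      iterative <- TRUE
      next
    }
    prev <- which(typical[seq_len(j - 1L)])
    if (!length(prev)) {
      warning("gene '", gene$gene_id, "': deficient module ", j,
              " has no preceding typical module; variant skipped",
              call. = FALSE)
      next
    }
    stutter_sites <- c(stutter_sites, max(prev))
  }
  copy_grid <- if (length(stutter_sites))
    cross_indices(rep(max_copies, length(stutter_sites)))
  else list(integer(0))
  iter_counts <- if (iterative) seq_len(max_copies) else 1L

  strips <- list()
  for (copies in copy_grid) {
    reps <- rep(1L, nrow(base))
    for (k in seq_along(stutter_sites)) {
      row <- which(base$module == stutter_sites[k])
      reps[row] <- reps[row] + (copies[k] - 1L)
    }
    monomers <- base[rep(seq_len(nrow(base)), times = reps), , drop = FALSE]
    rownames(monomers) <- NULL
    for (it in iter_counts) {
      mono_it <- monomers[rep(seq_len(nrow(monomers)), times = it), ,
                          drop = FALSE]
      rownames(mono_it) <- NULL
      tag <- paste0(
        if (length(copies)) paste0("stutter=",
                                   paste(copies, collapse = ","))
        else "",
        if (iterative) paste0(if (length(copies)) ";" else "",
                              "iter=", it) else "")
      if (!nzchar(tag)) tag <- "base"
      strips[[length(strips) + 1L]] <- list(
        gene_id = gene$gene_id, monomers = mono_it,
        flags = strip_flags(gene), variant_tag = tag)
    }
  }
  strips
}

#' Split a BGC into sub-clusters
#'
#' Two heuristics against erroneously merged clusters: (1) split at
#' inter-gene gaps larger than `max_dist` nucleotides; (2) within each
#' piece, split immediately before any CS-bearing gene that is not first
#' and immediately after any TE-bearing gene that is not last. When a CS/TE
#' split fires, the unsplit piece is also retained (flagged) because the
#' inconsistent domain placement may instead indicate a non-collinear
#' assembly line.
#'
#' @param genes list of [gene_annotation()], sorted by genomic coordinate.
#' @param max_dist gap threshold in nucleotides (default 10000).
#' @return list of `list(genes = <gene list>, unsplit_copy = <flag>)`.
#' @export
split_bgc <- function(genes, max_dist = 10000) {
  if (!length(genes)) return(list())
  starts <- vapply(genes, `[[`, 0, "start")
  if (is.unsorted(starts))
    genes <- genes[order(starts)]
  # pass 1: distance splitting
  pieces <- list()
  cur <- list(genes[[1]])
  for (i in seq_along(genes)[-1]) {
    gap <- genes[[i]]$start - genes[[i - 1]]$end
    if (gap > max_dist) {
      pieces[[length(pieces) + 1L]] <- cur
      cur <- list()
    }
    cur[[length(cur) + 1L]] <- genes[[i]]
  }
  pieces[[length(pieces) + 1L]] <- cur
  # pass 2: CS/TE splitting within each piece
  out <- list()
  for (piece in pieces) {
    n <- length(piece)
    cut_after <- logical(max(n - 1L, 0L))  # boundary between i and i+1
    for (i in seq_len(n)) {
      if (piece[[i]]$has_CS && i > 1L) cut_after[i - 1L] <- TRUE
      if (piece[[i]]$has_TE && i < n) cut_after[i] <- TRUE
    }
    if (!any(cut_after)) {
      out[[length(out) + 1L]] <- list(genes = piece, unsplit_copy = FALSE)
    } else {
      bounds <- c(0L, which(cut_after), n)
      for (b in seq_len(length(bounds) - 1L))
        out[[length(out) + 1L]] <- list(
          genes = piece[(bounds[b] + 1L):bounds[b + 1L]],
          unsplit_copy = FALSE)
      out[[length(out) + 1L]] <- list(genes = piece, unsplit_copy = TRUE)
    }
  }
  out
}

#' Check consistency of an ordered strip sequence
#'
#' A strip order is consistent iff (i) any CS-bearing strip is first;
#' (ii) any TE-bearing strip is last; (iii) the first strip lacks an
#' N-terminal COM domain; and (iv) the last strip lacks a C-terminal COM
#' domain.
#'
#' @param strip_order non-empty list of strips (each with a `flags` list).
#' @return logical.
#' @export
check_consistency <- function(strip_order) {
  n <- length(strip_order)
  stopifnot(n >= 1)
  fl <- function(name) vapply(strip_order, function(s)
    isTRUE(s$flags[[name]]), logical(1), USE.NAMES = FALSE)
  cs <- which(fl("has_CS")); te <- which(fl("has_TE"))
  if (length(cs) && !identical(cs, 1L)) return(FALSE)
  if (length(te) && !identical(te, n)) return(FALSE)
  if (isTRUE(strip_order[[1]]$flags$has_COM_N)) return(FALSE)
  if (isTRUE(strip_order[[n]]$flags$has_COM_C)) return(FALSE)
  TRUE
}

# Internal: which of the four conditions does an order violate?
consistency_violations <- function(strip_order) {
  n <- length(strip_order)
  fl <- function(name) vapply(strip_order, function(s)
    isTRUE(s$flags[[name]]), logical(1), USE.NAMES = FALSE)
  v <- character(0)
  cs <- which(fl("has_CS")); te <- which(fl("has_TE"))
  if (length(cs) && !identical(cs, 1L)) v <- c(v, "i")
  if (length(te) && !identical(te, n)) v <- c(v, "ii")
  if (isTRUE(strip_order[[1]]$flags$has_COM_N)) v <- c(v, "iii")
  if (isTRUE(strip_order[[n]]$flags$has_COM_C)) v <- c(v, "iv")
  v
}

#' Enumerate candidate assembly lines for one (sub-)BGC
#'
#' The collinear gene order is tried first; if consistent, only collinear
#' orderings are used. If the inconsistency is caused solely by a misplaced
#' CS and/or TE strip (conditions i/ii), the offending strip is moved to the
#' very beginning / end. Otherwise all strip permutations passing
#' [check_consistency()] are used. Each retained order is crossed with the
#' per-gene strip variants; output is capped at `max_sequences` in
#' deterministic order.
#'
#' @param strips_per_gene named list: gene_id -> list of strip variants.
#' @param bgc_gene_order character vector of gene ids in genomic order.
#' @param bgc_id cluster identifier attached to the output.
#' @param max_sequences output cap (default 720); gene counts whose
#'   factorial exceeds the cap skip the permutation stage.
#' @return list of assembly lines: `list(bgc_id, monomers, strip_order)`.
#' @export
enumerate_assembly_lines <- function(strips_per_gene, bgc_gene_order,
                                     bgc_id = "bgc", max_sequences = 720L) {
  stopifnot(length(bgc_gene_order) >= 1,
            all(bgc_gene_order %in% names(strips_per_gene)),
            all(lengths(strips_per_gene[bgc_gene_order]) > 0))
  k <- length(bgc_gene_order)
  rep_strips <- lapply(strips_per_gene[bgc_gene_order], `[[`, 1L)

  orders <- NULL
  coll <- seq_len(k)
  if (check_consistency(rep_strips[coll])) {
    orders <- list(coll)
  } else {
    viol <- consistency_violations(rep_strips[coll])
    if (all(viol %in% c("i", "ii"))) {
      ord <- coll
      fl <- function(name) vapply(rep_strips, function(s)
        isTRUE(s$flags[[name]]), logical(1), USE.NAMES = FALSE)
      cs <- which(fl("has_CS")); te <- which(fl("has_TE"))
      if ("i" %in% viol && length(cs) == 1L)
        ord <- c(cs, ord[ord != cs])
      if ("ii" %in% viol && length(te) == 1L &&
          !(length(cs) == 1L && te == cs))
        ord <- c(ord[ord != te], te)
      if (check_consistency(rep_strips[ord])) orders <- list(ord)
    }
    if (is.null(orders)) {
      if (factorial(k) > max_sequences) {
        warning("BGC '", bgc_id, "': ", k,
                " strips exceed the permutation cap; using collinear order",
                call. = FALSE)
        orders <- list(coll)
      } else {
        orders <- Filter(function(p) check_consistency(rep_strips[p]),
                         all_permutations(coll))
        if (!length(orders)) {
          warning("BGC '", bgc_id,
                  "': no consistent strip permutation; ",
                  "falling back to collinear order", call. = FALSE)
          orders <- list(coll)
        }
      }
    }
  }

  out <- list()
  for (ord in orders) {
    gene_ids <- bgc_gene_order[ord]
    variant_lists <- strips_per_gene[gene_ids]
    for (combo in cross_indices(lengths(variant_lists))) {
      if (length(out) >= max_sequences) return(out)
      strips <- Map(function(lst, i) lst[[i]], variant_lists, combo)
      monomers <- do.call(rbind, lapply(strips, `[[`, "monomers"))
      rownames(monomers) <- NULL
      out[[length(out) + 1L]] <- list(
        bgc_id = bgc_id,
        monomers = monomers,
        strip_order = data.frame(
          gene_id = gene_ids,
          variant_tag = vapply(strips, `[[`, "", "variant_tag"),
          stringsAsFactors = FALSE))
    }
  }
  out
}

#' Process one annotated BGC into candidate assembly lines
#'
#' Applies [split_bgc()], expands strip variants per gene, and enumerates
#' consistent assembly lines for every (sub-)cluster.
#'
#' @param genes list of [gene_annotation()] for one BGC.
#' @param bgc_id cluster identifier.
#' @param alphabet a [residue_alphabet()].
#' @param max_dist see [split_bgc()].
#' @param max_copies see [expand_deficient_modules()].
#' @param max_sequences see [enumerate_assembly_lines()].
#' @param synonyms see [module_to_monomer()].
#' @return list of assembly lines across all sub-clusters; sub-cluster ids
#'   are suffixed `/s<k>`, retained unsplit copies `/unsplit`.
#' @export
process_bgc <- function(genes, bgc_id = "bgc",
                        alphabet = default_alphabet(),
                        max_dist = 10000, max_copies = 3L,
                        max_sequences = 720L, synonyms = NULL) {
  pieces <- split_bgc(genes, max_dist = max_dist)
  out <- list()
  for (k in seq_along(pieces)) {
    piece <- pieces[[k]]
    sub_id <- if (length(pieces) == 1L) bgc_id
      else if (piece$unsplit_copy) paste0(bgc_id, "/unsplit")
      else paste0(bgc_id, "/s", k)
    strips_per_gene <- list()
    gene_ids <- character(0)
    for (g in piece$genes) {
      strips <- expand_deficient_modules(g, max_copies = max_copies,
                                         alphabet = alphabet,
                                         synonyms = synonyms)
      if (!length(strips)) next
      strips_per_gene[[g$gene_id]] <- strips
      gene_ids <- c(gene_ids, g$gene_id)
    }
    if (!length(gene_ids)) next
    out <- c(out, enumerate_assembly_lines(strips_per_gene, gene_ids,
                                           bgc_id = sub_id,
                                           max_sequences = max_sequences))
  }
  out
}

#' Read BGC annotations from JSON
#'
#' One JSON document:
#' `[{genome_id, bgcs: [{bgc_id, genes: [{gene_id, start, end, strand,
#'   modules: [[{kind, predictions?}]]}]}]}, ...]`
#' with coordinates 1-based inclusive and `predictions` a list of
#' `{residue, stachelhaus, svm}` present exactly on A domains. This is the
#' package's interchange stand-in for genome-mining output.
#'
#' @param path JSON file path.
#' @return list of genomes: `list(genome_id, bgcs = list(list(bgc_id,
#'   genes = list of gene_annotation)))`.
#' @export
read_bgc_annotations <- function(path) {
  docs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(docs, function(genome) {
    bgcs <- lapply(genome$bgcs, function(bgc) {
      genes <- lapply(bgc$genes, function(g) {
        modules <- lapply(g$modules, function(mod) {
          lapply(mod, function(d) {
            dom <- list(kind = d$kind)
            if (!is.null(d$predictions))
              dom$predictions <- do.call(rbind, lapply(
                d$predictions, function(p)
                  data.frame(residue = p$residue,
                             stachelhaus = as.numeric(p$stachelhaus),
                             svm = as.numeric(p$svm),
                             stringsAsFactors = FALSE)))
            dom
          })
        })
        gene_annotation(g$gene_id, g$start, g$end,
                        strand = if (is.null(g$strand)) "+" else g$strand,
                        modules = modules)
      })
      list(bgc_id = bgc$bgc_id, genes = genes)
    })
    list(genome_id = genome$genome_id, bgcs = bgcs)
  })
}

#' Write BGC annotations to JSON
#'
#' Inverse of [read_bgc_annotations()].
#'
#' @param genomes list of genomes as returned by [read_bgc_annotations()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bgc_annotations <- function(genomes, path) {
  docs <- lapply(genomes, function(genome) {
    list(genome_id = genome$genome_id,
         bgcs = lapply(genome$bgcs, function(bgc) {
           list(bgc_id = bgc$bgc_id,
                genes = lapply(bgc$genes, function(g) {
                  list(gene_id = g$gene_id, start = g$start, end = g$end,
                       strand = g$strand,
                       modules = lapply(g$modules, function(mod) {
                         lapply(mod, function(d) {
                           if (is.null(d$predictions)) list(kind = d$kind)
                           else list(kind = d$kind, predictions = lapply(
                             seq_len(nrow(d$predictions)), function(i)
                               as.list(d$predictions[i, ])))
                         })
                       }))
                }))
         }))
  })
  jsonlite::write_json(docs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
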