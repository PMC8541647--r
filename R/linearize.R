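#' @title Monomer graphs and their linearization
#' @description A monomer graph represents one NRP structure as a directed
#'   graph: nodes are monomers (residue, methylation, stereo, and whether the
#'   residue is supported by the alphabet), edges are inter-monomer bonds
#'   labelled with a bond type. Bonds attributable to core NRPS module
#'   activity (amide and double-amide bonds, and the thiazole / oxazole /
#'   pyrimidine heterocycles) form the *backbone* class; all other bond
#'   types (ester, glycosidic, carbon-carbon, disulfide, ...) are
#'   *tailoring* bonds laid down after chain assembly. Linearization removes
#'   tailoring bonds, takes weakly connected components of what remains, and
#'   reads candidate residue sequences off Hamiltonian paths (or, for
#'   cycles, off every rotation of the cycle).
#' @name linearization
NULL

BACKBONE_BONDS <- c("amide", "double-amide", "thiazole", "oxazole",
                    "pyrimidine")

#' Construct a monomer graph
#'
#' @param id compound identifier.
#' @param nodes data.frame with columns `id`, `residue`, `supported`
#'   (logical), `methylated` (-1/+1), `stereo` (-1/0/+1).
#' @param edges data.frame with columns `from`, `to`, `bond` (bond-type
#'   label); may have zero rows.
#' @return an object of class `monomer_graph`.
#' @export
monomer_graph <- function(id, nodes, edges) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  need_n <- c("id", "residue", "supported", "methylated", "stereo")
  if (!all(need_n %in% names(nodes)))
    stop("nodes must have columns ", paste(need_n, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids in monomer graph '", id, "'", call. = FALSE)
  if (nrow(edges)) {
    if (!all(c("from", "to", "bond") %in% names(edges)))
      stop("edges must have columns from, to, bond", call. = FALSE)
    bad <- !(edges$from %in% nodes$id) | !(edges$to %in% nodes$id)
    if (any(bad))
      stop("edge references unknown node in graph '", id, "'",
           call. = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        bond = character(0), stringsAsFactors = FALSE)
  }
  nodes$id <- as.character(nodes$id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  structure(list(id = as.character(id), nodes = nodes, edges = edges),
            class = "monomer_graph")
}

#' @export
print.monomer_graph <- function(x, ...) {
  cat("Monomer graph '", x$id, "': ", nrow(x$nodes), " monomers, ",
      nrow(x$edges), " bonds\n", sep = "")
  invisible(x)
}

#' Classify a bond label as backbone or tailoring
#'
#' Amide, double-amide and the thiazole/oxazole/pyrimidine heterocycles are
#' backbone bonds; every other (including unrecognized) label is tailoring.
#'
#' @param bond_label character vector of bond labels.
#' @return character vector, `"backbone"` or `"tailoring"`.
#' @export
classify_edge <- function(bond_label) {
  if (any(!nzchar(bond_label)))
    stop("empty bond label", call. = FALSE)
  ifelse(tolower(bond_label) %in% BACKBONE_BONDS, "backbone", "tailoring")
}

#' Backbone components of a monomer graph
#'
#' Removes tailoring edges, takes weakly connected components, and discards
#' components with fewer than `min_supported` supported monomers.
#'
#' @param graph a [monomer_graph()].
#' @param min_supported minimum number of supported monomers a component
#'   must contain to be retained (default 2).
#' @return list of `monomer_graph` components (ids suffixed `/c<k>`).
#' @export
backbone_components <- function(graph, min_supported = 2L) {
  stopifnot(inherits(graph, "monomer_graph"), min_supported >= 1L)
  keep <- classify_edge(graph$edges$bond) == "backbone"
  edges <- graph$edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to"), drop = FALSE],
    directed = TRUE, vertices = graph$nodes$id)
  comp <- igraph::components(g, mode = "weak")
  membership <- comp$membership[graph$nodes$id]
  out <- list()
  for (k in sort(unique(membership))) {
    ids <- graph$nodes$id[membership == k]
    nodes_k <- graph$nodes[graph$nodes$id %in% ids, , drop = FALSE]
    if (sum(nodes_k$supported) < min_supported) next
    edges_k <- edges[edges$from %in% ids & edges$to %in% ids, , drop = FALSE]
    out[[length(out) + 1L]] <- monomer_graph(
      paste0(graph$id, "/c", k), nodes_k, edges_k)
  }
  out
}

# Internal: does a directed edge set contain a cycle? (DFS colouring)
has_directed_cycle <- function(node_ids, edges) {
  adj <- split(edges$to, factor(edges$from, levels = node_ids))
  colour <- stats::setNames(rep(0L, length(node_ids)), node_ids)
  visit <- function(v) {
    colour[v] <<- 1L
    for (w in adj[[v]]) {
      if (colour[w] == 1L) return(TRUE)
      if (colour[w] == 0L && visit(w)) return(TRUE)
    }
    colour[v] <<- 2L
    FALSE
  }
  for (v in node_ids) if (colour[v] == 0L && visit(v)) return(TRUE)
  FALSE
}

# Internal: exhaustive backtracking search for directed Hamiltonian paths.
# Returns a list of node-id vectors, capped at max_paths.
hamiltonian_paths <- function(node_ids, edges, max_paths = 100L) {
  n <- length(node_ids)
  adj <- split(edges$to, factor(edges$from, levels = node_ids))
  indeg <- table(factor(edges$to, levels = node_ids))
  paths <- list()
  used <- stats::setNames(rep(FALSE, n), node_ids)
  path <- character(n)
  extend <- function(v, depth) {
    if (length(paths) >= max_paths) return()
    used[v] <<- TRUE
    path[depth] <<- v
    if (depth == n) {
      paths[[length(paths) + 1L]] <<- path
    } else {
      for (w in adj[[v]]) if (!used[w]) extend(w, depth + 1L)
    }
    used[v] <<- FALSE
  }
  # start preferentially from in-degree-0 nodes; fall back to all nodes
  starts <- node_ids[indeg[node_ids] == 0]
  if (!length(starts)) starts <- node_ids
  for (s in starts) extend(s, 1L)
  paths
}

#' Linearize one backbone component into candidate sequences
#'
#' A component that is a directed simple path yields one sequence; a
#' directed simple cycle of n nodes yields n sequences, one starting at each
#' node and following edge direction. General components are searched for
#' all directed Hamiltonian paths by exhaustive backtracking (edges are
#' traversed source-to-target only). Components with no Hamiltonian path
#' yield an empty list with a warning.
#'
#' @param component a `monomer_graph` from [backbone_components()].
#' @param alphabet [residue_alphabet()] used to map unsupported residues to
#'   the unsupported sign.
#' @param max_nodes node-count bound for the exhaustive search (default 20).
#' @param max_candidates cap on candidates per component (default 100).
#' @return list of candidate sequences; each is a list with `monomers`
#'   (an NRP monomer data.frame), `node_ids`, `cyclic` (flag) and
#'   `cycle_start`.
#' @export
linearize_component <- function(component, alphabet = default_alphabet(),
                                max_nodes = 20L, max_candidates = 100L) {
  nodes <- component$nodes
  edges <- component$edges
  n <- nrow(nodes)
  if (n > max_nodes) {
    warning("component '", component$id, "' exceeds ", max_nodes,
            " nodes; enumeration capped", call. = FALSE)
  }
  outdeg <- table(factor(edges$from, levels = nodes$id))
  indeg <- table(factor(edges$to, levels = nodes$id))
  is_cycle <- n >= 2 && nrow(edges) == n &&
    all(outdeg == 1) && all(indeg == 1)
  orders <- list()
  cyclic <- FALSE
  if (is_cycle) {
    cyclic <- TRUE
    nxt <- stats::setNames(edges$to, edges$from)
    for (start in nodes$id) {
      ord <- character(n)
      v <- start
      for (k in seq_len(n)) {
        ord[k] <- v
        v <- nxt[[v]]
      }
      orders[[length(orders) + 1L]] <- ord
    }
  } else {
    orders <- hamiltonian_paths(nodes$id, edges,
                                max_paths = max_candidates)
  }
  if (!length(orders)) {
    warning("component '", component$id,
            "' has no Hamiltonian path; dropped", call. = FALSE)
    return(list())
  }
  if (length(orders) > max_candidates)
    orders <- orders[seq_len(max_candidates)]
  unk <- unsupported_sign(alphabet)
  lapply(orders, function(ord) {
    idx <- match(ord, nodes$id)
    res <- tolower(nodes$residue[idx])
    res[!nodes$supported[idx] | !(res %in% as.character(alphabet))] <- unk
    list(monomers = data.frame(residue = res,
                               methylated = as.integer(nodes$methylated[idx]),
                               stereo = as.integer(nodes$stereo[idx]),
                               stringsAsFactors = FALSE),
         node_ids = ord,
         component_id = component$id,
         cyclic = cyclic,
         cycle_start = if (cyclic) ord[1] else NA_character_)
  })
}

#' Combine per-component candidates into the final candidate set
#'
#' Every per-component candidate is always emitted on its own (this supports
#' short iterative NRPs whose product is a fraction of the assembly line).
#' When the backbone graph is acyclic and has at most `max_permuted`
#' components, every concatenation over every permutation of the components
#' is additionally emitted, which supports non-collinear assembly lines.
#'
#' @param component_sequences list (per component) of candidate lists from
#'   [linearize_component()].
#' @param graph_is_acyclic does the backbone graph lack directed cycles?
#' @param max_permuted maximum component count for permutation expansion
#'   (default 3).
#' @return flat list of candidates; concatenations carry a `permutation`
#'   field listing the component order.
#' @export
combine_components <- function(component_sequences, graph_is_acyclic,
                               max_permuted = 3L) {
  k <- length(component_sequences)
  out <- list()
  for (cand_list in component_sequences)
    for (cand in cand_list) out[[length(out) + 1L]] <- cand
  if (k >= 2 && k <= max_permuted && graph_is_acyclic) {
    for (perm in all_permutations(seq_len(k))) {
      choice_lists <- component_sequences[perm]
      for (combo in cross_indices(lengths(choice_lists))) {
        parts <- Map(function(lst, i) lst[[i]], choice_lists, combo)
        out[[length(out) + 1L]] <- list(
          monomers = do.call(rbind, lapply(parts, `[[`, "monomers")),
          node_ids = unlist(lapply(parts, `[[`, "node_ids")),
          component_id = paste(vapply(parts, `[[`, "", "component_id"),
                               collapse = "+"),
          cyclic = FALSE,
          cycle_start = NA_character_,
          permutation = perm)
      }
    }
  }
  out
}

#' Linearize a monomer graph into candidate NRP sequences
#'
#' Runs the full linearization: edge classification, backbone components,
#' per-component Hamiltonian enumeration, and component permutation.
#'
#' @inheritParams linearize_component
#' @param graph a [monomer_graph()].
#' @param min_supported minimum supported monomers per retained component.
#' @param max_permuted maximum component count for permutation expansion.
#' @return list of candidate sequences (possibly empty).
#' @export
linearize_graph <- function(graph, alphabet = default_alphabet(),
                            min_supported = 2L, max_permuted = 3L,
                            max_nodes = 20L, max_candidates = 100L) {
  comps <- backbone_components(graph, min_supported = min_supported)
  if (!length(comps)) return(list())
  per_comp <- lapply(comps, linearize_component, alphabet = alphabet,
                     max_nodes = max_nodes, max_candidates = max_candidates)
  keep <- lengths(per_comp) > 0
  per_comp <- per_comp[keep]
  comps <- comps[keep]
  if (!length(per_comp)) return(list())
  acyclic <- !any(vapply(comps, function(cp)
    has_directed_cycle(cp$nodes$id, cp$edges), logical(1)))
  combine_components(per_comp, graph_is_acyclic = acyclic,
                     max_permuted = max_permuted)
}

# Internal: all permutations of a vector (small n only).
all_permutations <- function(x) {
  n <- length(x)
  if (n <= 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# Internal: cross product of index ranges, lexicographic order.
cross_indices <- function(lens) {
  grids <- do.call(expand.grid, rev(lapply(lens, seq_len)))
  lapply(seq_len(nrow(grids)), function(r) rev(as.integer(grids[r, ])))
}
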