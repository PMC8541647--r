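#' Read NRP monomer graphs from JSON
#'
#' One JSON document holding a list of compounds:
#' `[{id, nodes: [{id, residue, supported, methylated, stereo}],
#'    edges: [{from, to, bond}]}, ...]`.
#' This is the package's interchange stand-in for retro-biosynthesis output:
#' nodes arrive pre-annotated with residue identity, methylation and D/L
#' stereo flags; no chemistry is performed here.
#'
#' @param path JSON file path.
#' @return list of [monomer_graph()] objects.
#' @export
read_monomer_graphs <- function(path) {
  docs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                             simplifyVector = TRUE)
  if (is.data.frame(docs))
    docs <- lapply(seq_len(nrow(docs)), function(i) {
      list(id = docs$id[i], nodes = docs$nodes[[i]],
           edges = docs$edges[[i]])
    })
  lapply(docs, function(d) {
    nodes <- as.data.frame(d$nodes)
    nodes$supported <- as.logical(nodes$supported)
    nodes$methylated <- as.integer(nodes$methylated)
    nodes$stereo <- as.integer(nodes$stereo)
    edges <- if (is.null(d$edges) || !length(d$edges))
      data.frame(from = character(0), to = character(0),
                 bond = character(0))
    else as.data.frame(d$edges)
    monomer_graph(d$id, nodes, edges)
  })
}

#' Write NRP monomer graphs to JSON
#'
#' @param graphs list of [monomer_graph()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_monomer_graphs <- function(graphs, path) {
  docs <- lapply(graphs, function(g)
    list(id = g$id, nodes = g$nodes, edges = g$edges))
  jsonlite::write_json(docs, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
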