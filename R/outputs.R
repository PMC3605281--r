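edge_key <- function(edges) paste(edges$source, edges$sign, edges$target)

dot_node_color <- c(stimulated = "green", inhibited = "red",
                    measured = "lightblue", compressed = "grey",
                    unknown = "white")

#' Write a network with node and edge annotations
#'
#' Exports a trained or annotated network in the formats downstream graph
#' tools consume: a SIF file, a Graphviz DOT file (node fill colors encode
#' experimental status, edge width encodes selection frequency, dashed
#' edges are never-selected candidates), and two plain-text attribute
#' tables (`element<TAB>value`, one row per node / per edge).
#'
#' @param net a [pkn] object.
#' @param path_prefix output files are `<prefix>.sif`, `<prefix>.dot`,
#'   `<prefix>_nodes.txt`, `<prefix>_edges.txt`.
#' @param node_status optional named character vector, node name to status
#'   (`"measured"`, `"stimulated"`, `"inhibited"`, `"compressed"`, ...).
#'   Nodes without an entry are written with status `"unknown"`.
#' @param edge_frequency optional numeric vector in \[0,1\], named by edge
#'   key `"source sign target"` (see the `_edges.txt` output for the keys),
#'   typically the selection frequency of the edge across a model family.
#'   Missing edges default to `NA`.
#' @return named character vector of the four file paths, invisibly.
#' @export
write_network_outputs <- function(net, path_prefix, node_status = NULL,
                                  edge_frequency = NULL) {
  stopifnot(inherits(net, "pkn"))
  if (!is.null(node_status)) {
    bad <- setdiff(names(node_status), net$nodes)
    if (length(bad))
      stop(sprintf("node attribute keys not in network: %s",
                   paste(bad, collapse = ", ")))
  }
  keys <- edge_key(net$edges)
  if (!is.null(edge_frequency)) {
    bad <- setdiff(names(edge_frequency), keys)
    if (length(bad))
      stop(sprintf("edge attribute keys not in network: %s",
                   paste(bad, collapse = ", ")))
  }
  status <- stats::setNames(rep("unknown", length(net$nodes)), net$nodes)
  if (!is.null(node_status)) status[names(node_status)] <- node_status
  freq <- stats::setNames(rep(NA_real_, length(keys)), keys)
  if (!is.null(edge_frequency)) freq[names(edge_frequency)] <- edge_frequency

  paths <- c(sif = paste0(path_prefix, ".sif"),
             dot = paste0(path_prefix, ".dot"),
             nodes = paste0(path_prefix, "_nodes.txt"),
             edges = paste0(path_prefix, "_edges.txt"))
  write_sif(net, paths["sif"])
  writeLines(paste0(net$nodes, "\t", status), paths["nodes"])
  writeLines(paste0(keys, "\t", ifelse(is.na(freq), "NA", freq)),
             paths["edges"])

  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  fill <- dot_node_color[status]
  fill[is.na(fill)] <- "white"
  lines <- c("digraph logic_model {",
             "  node [style=filled];",
             sprintf("  %s [fillcolor=%s];", q(net$nodes), fill))
  if (nrow(net$edges)) {
    pw <- ifelse(is.na(freq), 1, 0.5 + 2.5 * freq)
    style <- ifelse(!is.na(freq) & freq == 0, "dashed", "solid")
    lines <- c(lines, sprintf(
      "  %s -> %s [arrowhead=%s, penwidth=%.2f, style=%s];",
      q(net$edges$source), q(net$edges$target),
      ifelse(net$edges$sign > 0, "normal", "tee"), pw, style))
  }
  writeLines(c(lines, "}"), paths["dot"])
  invisible(paths)
}
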