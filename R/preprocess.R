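resolve_names <- function(wanted, nodes, aliases = NULL, what = "name") {
  out <- character(length(wanted))
  for (i in seq_along(wanted)) {
    w <- wanted[i]
    if (!is.null(aliases) && w %in% names(aliases)) w <- unname(aliases[w])
    hit <- nodes[tolower(nodes) == tolower(w)]
    if (length(hit) != 1L)
      stop(sprintf("%s '%s' cannot be matched to a network node",
                   what, wanted[i]))
    out[i] <- hit
  }
  stats::setNames(out, wanted)
}

#' Map the experimental design onto the network
#'
#' Matches the cue and signal names of a dataset to network nodes
#' (case-insensitively, with an optional explicit alias map) and labels
#' each node with its experimental status. Designated nodes (stimulated,
#' inhibited or measured) are the ones preprocessing must never remove.
#'
#' @param net a [pkn] object.
#' @param data a [midas] object.
#' @param aliases optional named character vector mapping dataset names to
#'   network node names, for cases the case-insensitive match cannot solve.
#' @return a data.frame (class `node_status`) with one row per node and
#'   logical columns `stimulated`, `inhibited`, `measured`, `designated`.
#' @export
mark_status <- function(net, data, aliases = NULL) {
  stopifnot(inherits(net, "pkn"), inherits(data, "midas"))
  stim <- resolve_names(data$stimuli, net$nodes, aliases, "stimulus")
  inh <- if (length(data$inhibitors))
    resolve_names(data$inhibitors, net$nodes, aliases, "inhibitor")
  else character()
  sig <- resolve_names(data$signals, net$nodes, aliases, "signal")
  st <- data.frame(node = net$nodes,
                   stimulated = net$nodes %in% stim,
                   inhibited = net$nodes %in% inh,
                   measured = net$nodes %in% sig,
                   stringsAsFactors = FALSE)
  st$designated <- st$stimulated | st$inhibited | st$measured
  attr(st, "stimulus_nodes") <- stim
  attr(st, "inhibitor_nodes") <- inh
  attr(st, "signal_nodes") <- sig
  class(st) <- c("node_status", "data.frame")
  st
}

status_lookup <- function(status, nodes, col) {
  status[[col]][match(nodes, status$node)]
}

#' Remove non-controllable and non-observable species
#'
#' Drops nodes that no cue can reach (their state can never be changed by
#' the experiment) and nodes from which no signal can be reached (their
#' state can never be confronted with a measurement). Designated nodes are
#' always kept; a designated node that is disconnected from the rest of the
#' experiment triggers a warning.
#'
#' @param net a [pkn] object.
#' @param status a [mark_status()] result for `net`.
#' @return a [pkn] object on the retained nodes.
#' @export
cut_unreachable <- function(net, status) {
  stopifnot(inherits(net, "pkn"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = net$nodes))
  cues <- status$node[status$stimulated | status$inhibited]
  sigs <- status$node[status$measured]
  from_cue <- rep(FALSE, length(net$nodes))
  to_sig <- rep(FALSE, length(net$nodes))
  names(from_cue) <- names(to_sig) <- net$nodes
  if (length(cues)) {
    reach <- unique(unlist(lapply(cues, function(cu)
      names(igraph::subcomponent(g, cu, mode = "out")))))
    from_cue[reach] <- TRUE
  }
  if (length(sigs)) {
    reach <- unique(unlist(lapply(sigs, function(sg)
      names(igraph::subcomponent(g, sg, mode = "in")))))
    to_sig[reach] <- TRUE
  }
  designated <- status_lookup(status, net$nodes, "designated")
  keep <- (from_cue & to_sig) | designated
  dropped_designated <- designated & !(from_cue & to_sig)
  if (any(dropped_designated))
    warning(sprintf("designated node(s) disconnected from the experiment: %s",
                    paste(net$nodes[dropped_designated], collapse = ", ")))
  kept <- net$nodes[keep]
  edges <- net$edges[net$edges$source %in% kept & net$edges$target %in% kept, ]
  pkn(edges, nodes = kept)
}

#' Compress pass-through species
#'
#' Iteratively removes species that are neither measured nor perturbed
#' whenever doing so cannot change the input-output logic of the network: a
#' non-designated node with exactly one incoming or exactly one outgoing
#' edge is spliced out, each (incoming, outgoing) edge pair being rewired
#' into a direct edge whose sign is the product of the two signs. A removal
#' is skipped if it would create a self-loop or an edge contradicting an
#' existing one (same source and target, opposite sign). Runs to fixpoint.
#'
#' @param net a [pkn] object (after [cut_unreachable()]).
#' @param status a [mark_status()] result.
#' @return a [pkn] object with an attribute `compressed` listing removed
#'   nodes.
#' @export
compress_network <- function(net, status) {
  stopifnot(inherits(net, "pkn"))
  edges <- net$edges
  nodes <- net$nodes
  compressed <- character()
  repeat {
    changed <- FALSE
    for (nd in nodes) {
      if (isTRUE(status_lookup(status, nd, "designated"))) next
      ins <- which(edges$target == nd)
      outs <- which(edges$source == nd)
      if (!length(ins) || !length(outs)) next
      if (length(ins) != 1L && length(outs) != 1L) next
      new <- expand.grid(i = ins, o = outs)
      cand <- data.frame(source = edges$source[new$i],
                         sign = edges$sign[new$i] * edges$sign[new$o],
                         target = edges$target[new$o],
                         stringsAsFactors = FALSE)
      if (any(cand$source == cand$target)) next  # self-loop guard
      rest <- edges[-c(ins, outs), , drop = FALSE]
      pool <- rbind(rest, cand)
      # rewiring must not introduce a contradictory duplicate of any pair
      # it touches (same source and target, both signs present)
      cand_pairs <- unique(paste(cand$source, cand$target))
      pairkey <- paste(pool$source, pool$target)
      touched <- pairkey %in% cand_pairs
      if (any(tapply(pool$sign[touched], pairkey[touched],
                     function(s) length(unique(s))) > 1L))
        next
      edges <- unique(pool)
      rownames(edges) <- NULL
      nodes <- setdiff(nodes, nd)
      compressed <- c(compressed, nd)
      changed <- TRUE
      break
    }
    if (!changed) break
  }
  out <- pkn(edges, nodes = nodes)
  attr(out, "compressed") <- compressed
  out
}

gate_label <- function(inputs, output) {
  lits <- ifelse(inputs$sign < 0, paste0("!", inputs$node), inputs$node)
  # radix ordering is locale-independent, keeping labels portable
  paste0(paste(lits[order(inputs$node, method = "radix")], collapse = "+"),
         "=", output)
}

#' Expand a compressed network into a scaffold of candidate logic gates
#'
#' Every incoming edge of a target becomes a single-input gate, and every
#' combination of up to `max_and_arity` distinct inputs becomes an AND
#' gate (negative edges enter as negated literals). OR logic is encoded
#' implicitly: co-selecting several gates with the same target ORs them.
#' For a node with two inputs B and C this yields three hyperedges --
#' `B -> A`, `C -> A` and `B AND C -> A` -- which together span the four
#' logic options (B, C, B AND C, and B OR C by co-selection). Gates are
#' sorted deterministically (by output node, then arity, then label) so
#' that bitstring positions are stable across runs.
#'
#' @param net a compressed [pkn] object.
#' @param max_and_arity maximum number of inputs of an AND gate
#'   (default 2; higher arities enlarge the search space combinatorially).
#' @return an object of class `scaffold`: list with `nodes`, `gates` (each
#'   gate a list with `inputs` data.frame (`node`, `sign`), `output`,
#'   `label`), `v_e` (inputs per gate), `v_es` (total input count) and
#'   `provenance` (gate to originating PKN edge keys).
#' @export
expand_gates <- function(net, max_and_arity = 2) {
  stopifnot(inherits(net, "pkn"))
  if (max_and_arity < 1) stop("max_and_arity must be >= 1")
  gates <- list()
  for (tgt in sort(unique(net$edges$target), method = "radix")) {
    ins <- net$edges[net$edges$target == tgt, , drop = FALSE]
    ins <- ins[order(ins$source, ins$sign, method = "radix"), , drop = FALSE]
    n_in <- nrow(ins)
    for (arity in seq_len(min(max_and_arity, n_in))) {
      combos <- utils::combn(seq_len(n_in), arity, simplify = FALSE)
      for (cb in combos) {
        sub <- ins[cb, , drop = FALSE]
        if (anyDuplicated(sub$source)) next  # same node twice in one AND
        inputs <- data.frame(node = sub$source, sign = sub$sign,
                             stringsAsFactors = FALSE)
        gates[[length(gates) + 1L]] <- list(
          inputs = inputs, output = tgt,
          label = gate_label(inputs, tgt),
          provenance = edge_key(data.frame(source = sub$source,
                                           sign = sub$sign, target = tgt)))
      }
    }
  }
  if (length(gates)) {
    ord <- order(vapply(gates, `[[`, "", "output"),
                 vapply(gates, function(g) nrow(g$inputs), 0L),
                 vapply(gates, `[[`, "", "label"), method = "radix")
    gates <- gates[ord]
  }
  scaffold_new(sort(net$nodes, method = "radix"), gates, net)
}

scaffold_new <- function(nodes, gates, net = NULL) {
  v_e <- vapply(gates, function(g) nrow(g$inputs), 0L)
  idx <- function(x) match(x, nodes)
  structure(list(
    nodes = nodes,
    gates = gates,
    v_e = v_e,
    v_es = sum(v_e),
    n_gates = length(gates),
    gate_target = vapply(gates, function(g) idx(g$output), 0L),
    gate_inputs = lapply(gates, function(g) idx(g$inputs$node)),
    gate_neg = lapply(gates, function(g) g$inputs$sign < 0),
    provenance = lapply(gates, `[[`, "provenance"),
    pkn = net), class = "scaffold")
}

#' @export
print.scaffold <- function(x, ...) {
  cat(sprintf("Scaffold: %d nodes, %d candidate gates (total inputs v_es = %d)\n",
              length(x$nodes), x$n_gates, x$v_es))
  labs <- vapply(x$gates, `[[`, "", "label")
  cat(paste0("  ", utils::head(labs, 15), collapse = "\n"), "\n")
  if (length(labs) > 15) cat(sprintf("  ... and %d more\n", length(labs) - 15))
  invisible(x)
}

#' Full preprocessing pipeline
#'
#' Convenience wrapper: [mark_status()], optionally [cut_unreachable()],
#' [compress_network()] and [expand_gates()] in sequence.
#'
#' @inheritParams mark_status
#' @inheritParams expand_gates
#' @param cut whether to prune non-controllable/non-observable nodes first.
#' @return a `scaffold`, with attributes `status` (recomputed on the
#'   compressed network) and `compressed` (removed node names).
#' @export
preprocess <- function(net, data, aliases = NULL, cut = TRUE,
                       max_and_arity = 2) {
  status <- mark_status(net, data, aliases)
  if (cut) net <- cut_unreachable(net, status)
  comp <- compress_network(net, status)
  sc <- expand_gates(comp, max_and_arity = max_and_arity)
  attr(sc, "status") <- status[status$node %in% sc$nodes, , drop = FALSE]
  attr(sc, "compressed") <- attr(comp, "compressed")
  sc
}

#' Serialize a scaffold
#'
#' Writes the scaffold as an extended SIF dialect in which each AND gate is
#' routed through an auxiliary `and_<k>` node (the convention
#' Cytoscape-oriented tools use for hyperedges), plus a JSON sidecar with
#' the ordered gate list and the provenance of each gate.
#'
#' @param scaffold a `scaffold`.
#' @param path_prefix writes `<prefix>.sif` and `<prefix>.json`.
#' @return the two paths, invisibly.
#' @export
write_scaffold <- function(scaffold, path_prefix) {
  rows <- character()
  and_k <- 0L
  for (g in scaffold$gates) {
    if (nrow(g$inputs) == 1L) {
      rows <- c(rows, sprintf("%s\t%d\t%s", g$inputs$node, g$inputs$sign,
                              g$output))
    } else {
      and_k <- and_k + 1L
      aux <- sprintf("and_%d", and_k)
      rows <- c(rows,
                sprintf("%s\t%d\t%s", g$inputs$node, g$inputs$sign, aux),
                sprintf("%s\t1\t%s", aux, g$output))
    }
  }
  sif <- paste0(path_prefix, ".sif")
  json <- paste0(path_prefix, ".json")
  writeLines(unique(rows), sif)
  jsonlite::write_json(
    list(nodes = scaffold$nodes,
         gates = lapply(scaffold$gates, function(g)
           list(label = g$label, output = g$output,
                inputs = g$inputs, provenance = g$provenance))),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(sif = sif, json = json))
}
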