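#' Construct a prior knowledge network
#'
#' A prior knowledge network (PKN) is a signed directed graph of known
#' (de)activating interactions between signaling species, typically curated
#' from literature or pathway databases. It is the search-space constraint
#' for all model training in this package.
#'
#' @param edges a data.frame with columns `source` (character), `sign`
#'   (integer, `+1` for activation, `-1` for inhibition) and `target`
#'   (character). Duplicate (source, sign, target) triples are dropped.
#' @param nodes optional character vector of species names; defaults to the
#'   union of edge endpoints. Extra isolated nodes may be listed.
#' @return an object of class `pkn`: a list with elements `nodes`
#'   (character) and `edges` (data.frame `source`, `sign`, `target`).
#' @examples
#' net <- pkn(data.frame(source = c("EGF", "ERK"), sign = c(1, -1),
#'                       target = c("SOS-1", "SOS-1")))
#' net
#' @export
pkn <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), sign = integer(),
                        target = character(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges),
            all(c("source", "sign", "target") %in% names(edges)))
  edges <- data.frame(source = as.character(edges$source),
                      sign = as.integer(edges$sign),
                      target = as.character(edges$target),
                      stringsAsFactors = FALSE)
  if (nrow(edges) && !all(edges$sign %in% c(-1L, 1L)))
    stop("edge signs must be +1 or -1")
  edges <- unique(edges)
  rownames(edges) <- NULL
  all_nodes <- unique(c(nodes, edges$source, edges$target))
  structure(list(nodes = as.character(all_nodes), edges = edges),
            class = "pkn")
}

#' @export
print.pkn <- function(x, ...) {
  cat(sprintf("Prior knowledge network: %d nodes, %d signed directed edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    shown <- utils::head(x$edges, 10)
    cat(paste0("  ", shown$source, ifelse(shown$sign > 0, " -> ", " -| "),
               shown$target, collapse = "\n"), "\n")
    if (nrow(x$edges) > 10) cat(sprintf("  ... and %d more\n", nrow(x$edges) - 10))
  }
  invisible(x)
}

#' @export
`==.pkn` <- function(e1, e2) {
  key <- function(n) sort(paste(n$edges$source, n$edges$sign, n$edges$target))
  setequal(e1$nodes, e2$nodes) && identical(key(e1), key(e2))
}

sign_token_map <- c("1" = 1L, "+" = 1L, "activates" = 1L,
                    "-1" = -1L, "-" = -1L, "−" = -1L, "inhibits" = -1L,
                    "∣1" = -1L)

#' Read a network from a SIF file
#'
#' Parses a Simple Interaction File: one interaction per row, three
#' whitespace- or tab-separated fields `source relation target`. The middle
#' field encodes the sign of the interaction: `1`, `+` or `activates` for
#' activation; `-1`, `-` or `inhibits` for inhibition.
#'
#' @param path path to the SIF file.
#' @return a [pkn] object.
#' @seealso [write_sif()]
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  edges <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(fields) != 3L)
      stop(sprintf("SIF parse error at line %d: expected 3 fields, got %d",
                   ln, length(fields)))
    sg <- sign_token_map[fields[2]]
    if (is.na(sg))
      stop(sprintf("SIF parse error at line %d: unknown sign token '%s'",
                   ln, fields[2]))
    edges[[i]] <- data.frame(source = fields[1], sign = sg,
                             target = fields[3], stringsAsFactors = FALSE)
  }
  pkn(do.call(rbind, edges))
}

#' Write a network to a SIF file
#'
#' @param net a [pkn] object.
#' @param path output file path.
#' @return `path`, invisibly. `read_sif(write_sif(net, p))` recovers the
#'   same edge set (isolated nodes are not representable in SIF).
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "pkn"))
  lines <- sprintf("%s\t%d\t%s", net$edges$source, net$edges$sign,
                   net$edges$target)
  writeLines(lines, path)
  invisible(path)
}
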