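#' Network container
#'
#' A `fabric_network` is the in-memory network model used throughout the
#' package: an ordered set of node names plus a link table. Each link is a
#' `(source, target, relation, directed, shadow)` record, the atomic
#' drawable unit. On import all links have `shadow = FALSE`; shadow copies
#' are created explicitly by [expand_shadows()].
#'
#' Invariants enforced by the constructor:
#' * every link endpoint is a known node;
#' * relations are non-empty;
#' * no two links share `(source, target, relation)`, where for an
#'   undirected link `(A,B,rel)` and `(B,A,rel)` count as the same link;
#' * a shadow link's relation carries the literal prefix `"shdw"`.
#'
#' Lone nodes (degree 0) are permitted.
#'
#' @param nodes character vector of node names, in display order.
#' @param links data frame with columns `source`, `target`, `relation`,
#'   `directed` (logical) and optionally `shadow` (logical, default
#'   `FALSE`).
#' @return an object of class `fabric_network` with fields `nodes` and
#'   `links`.
#' @examples
#' net <- fabric_network(c("A", "B"),
#'   data.frame(source = "A", target = "B", relation = "pp",
#'              directed = FALSE))
#' network_size(net)
#' @export
fabric_network <- function(nodes = character(), links = empty_links()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes))
    validation_error("duplicate node names in node set")
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (nrow(links) == 0) links <- empty_links()
  if (!all(c("source", "target", "relation", "directed") %in% names(links)))
    validation_error("links need columns source, target, relation, directed")
  if (is.null(links$shadow)) links$shadow <- FALSE
  links <- links[c("source", "target", "relation", "directed", "shadow")]
  links$source <- as.character(links$source)
  links$target <- as.character(links$target)
  links$relation <- as.character(links$relation)
  links$directed <- as.logical(links$directed)
  links$shadow <- as.logical(links$shadow)
  rownames(links) <- NULL

  bad <- setdiff(unique(c(links$source, links$target)), nodes)
  if (length(bad))
    validation_error(paste0("link endpoint(s) not in node set: ",
                            paste(bad, collapse = ", ")))
  if (any(!nzchar(links$relation)))
    validation_error("empty relation label")
  bad_shadow <- links$shadow & !startsWith(links$relation, "shdw")
  if (any(bad_shadow))
    validation_error("shadow link without 'shdw' relation prefix")
  if (anyDuplicated(link_keys(links)))
    validation_error("duplicate links (same endpoints and relation)")

  structure(list(nodes = nodes, links = links), class = "fabric_network")
}

empty_links <- function() {
  data.frame(source = character(), target = character(),
             relation = character(), directed = logical(),
             shadow = logical(), stringsAsFactors = FALSE)
}

# Dedup keys: undirected links are canonicalized with the byte-wise smaller
# endpoint first, so (A,B,rel) and (B,A,rel) collide.
link_keys <- function(links) {
  cd <- c_codes(links$source, links$target)
  swap <- !links$directed & cd[[1]] > cd[[2]]
  a <- ifelse(swap, links$target, links$source)
  b <- ifelse(swap, links$source, links$target)
  paste(a, b, links$relation, links$directed, sep = "\r")
}

#' @export
print.fabric_network <- function(x, ...) {
  cat(sprintf("fabric_network: %d nodes, %d links (%d shadow)\n",
              length(x$nodes), nrow(x$links), sum(x$links$shadow)))
  invisible(x)
}

#' Node and link counts
#'
#' @param network a [fabric_network()].
#' @return named integer vector with elements `n` (nodes) and `e` (links,
#'   shadow copies included if present).
#' @export
network_size <- function(network) {
  stopifnot(inherits(network, "fabric_network"))
  c(n = length(network$nodes), e = nrow(network$links))
}

#' Parse a Cytoscape SIF interaction file
#'
#' Reads the tab-delimited simple interaction format: each line is
#' `source relation target [target ...]`; multi-target lines expand to one
#' link per target. A line with a single token declares a lone node. Exact
#' duplicate links (identical endpoints and relation, orientation ignored
#' for undirected relations) are dropped, first occurrence wins. Node order
#' of first appearance is preserved.
#'
#' A line containing a tab character is split on tabs only; otherwise it is
#' split on runs of whitespace, which tolerates space-separated files.
#'
#' @param x path to a SIF file, a connection, or a character vector of
#'   lines.
#' @param directed_relations character vector of relation labels to import
#'   as directed; all others are undirected.
#' @return a [fabric_network()].
#' @examples
#' parse_sif(c("A\tpp\tB\tC", "D"))
#' @export
parse_sif <- function(x, directed_relations = character()) {
  lines <- read_input_lines(x)
  nodes <- character()
  seen_node <- new.env(parent = emptyenv())
  src <- character(); tgt <- character(); rel <- character()

  add_node <- function(name) {
    if (!exists(name, envir = seen_node, inherits = FALSE)) {
      assign(name, TRUE, envir = seen_node)
      nodes[[length(nodes) + 1L]] <<- name
    }
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    fields <- split_sif_fields(line)
    if (length(fields) == 2L)
      parse_error(sprintf("line %d: two fields (need 1 or >= 3): '%s'", i, line))
    if (length(fields) == 1L) {
      add_node(fields[[1L]])
      next
    }
    if (!nzchar(fields[[2L]]))
      parse_error(sprintf("line %d: empty relation field", i))
    add_node(fields[[1L]])
    for (t in fields[-(1:2)]) {
      add_node(t)
      src[[length(src) + 1L]] <- fields[[1L]]
      tgt[[length(tgt) + 1L]] <- t
      rel[[length(rel) + 1L]] <- fields[[2L]]
    }
  }

  links <- data.frame(source = src, target = tgt, relation = rel,
                      directed = rel %in% directed_relations,
                      shadow = FALSE, stringsAsFactors = FALSE)
  links <- links[!duplicated(link_keys(links)), , drop = FALSE]
  rownames(links) <- NULL
  fabric_network(nodes, links)
}

split_sif_fields <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    trimws(fields)
  } else {
    strsplit(trimws(line), "[[:space:]]+")[[1L]]
  }
}

read_input_lines <- function(x) {
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  if (is.character(x) && length(x) == 1L && !grepl("\n", x, fixed = TRUE) &&
      file.exists(x))
    return(readLines(x, warn = FALSE))
  if (is.character(x) && length(x) == 1L && grepl("\n", x, fixed = TRUE))
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  if (is.character(x)) return(x)
  fabric_error("expected a file path, connection, or character lines")
}

#' Write a network back to canonical SIF
#'
#' One tab-delimited line per link; lone nodes as single-token lines.
#' Re-parsing the output reproduces the network exactly.
#'
#' @param network a [fabric_network()] (shadow copies are not written).
#' @param path optional output file; if `NULL` the lines are returned.
#' @return character vector of SIF lines, invisibly when written to a file.
#' @export
write_sif <- function(network, path = NULL) {
  links <- network$links[!network$links$shadow, , drop = FALSE]
  lines <- sprintf("%s\t%s\t%s", links$source, links$relation, links$target)
  lone <- setdiff(network$nodes, c(links$source, links$target))
  lines <- c(lines, lone)
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

#' Parse a node-attribute file
#'
#' The format is the Cytoscape `.noa` style: the first line is the
#' attribute name, every following line is `node = value`. Lines whose
#' name part is empty are skipped with a warning, mirroring the manual
#' cleanup such files often need.
#'
#' @inheritParams parse_sif
#' @return named character vector of attribute values; the attribute name
#'   is attached as attribute `"attribute"`.
#' @export
parse_node_attributes <- function(x) {
  lines <- read_input_lines(x)
  if (!length(lines)) parse_error("empty attribute file (missing header)")
  header <- trimws(lines[[1L]])
  out <- character(); nm <- character()
  for (i in seq_along(lines)[-1L]) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (!grepl("=", line, fixed = TRUE))
      parse_error(sprintf("line %d: missing '=' separator: '%s'", i, line))
    pos <- regexpr("=", line, fixed = TRUE)
    name <- trimws(substr(line, 1L, pos - 1L))
    value <- trimws(substr(line, pos + 1L, nchar(line)))
    if (!nzchar(name)) {
      warning(sprintf("line %d: missing first-column entry, skipped", i))
      next
    }
    nm[[length(nm) + 1L]] <- name
    out[[length(out) + 1L]] <- value
  }
  names(out) <- nm
  attr(out, "attribute") <- header
  out
}

# Distinct-neighbor pairs (node, neighbor), direction and duplicate
# relations collapsed; a self-loop yields the single pair (v, v).
neighbor_pairs <- function(network) {
  links <- network$links[!network$links$shadow, , drop = FALSE]
  if (!nrow(links))
    return(data.frame(node = character(), nb = character(),
                      stringsAsFactors = FALSE))
  p <- data.frame(node = c(links$source, links$target),
                  nb = c(links$target, links$source),
                  stringsAsFactors = FALSE)
  p[!duplicated(paste(p$node, p$nb, sep = "\r")), , drop = FALSE]
}

# Named integer vector of degrees for every node (distinct neighbors,
# self-loop counts 1, lone nodes 0).
node_degrees <- function(network) {
  deg <- integer(length(network$nodes))
  names(deg) <- network$nodes
  p <- neighbor_pairs(network)
  if (nrow(p)) {
    tab <- table(factor(p$node, levels = network$nodes))
    deg[] <- as.integer(tab)
  }
  deg
}

#' Node degree
#'
#' Degree counts distinct neighboring nodes: duplicate links between the
#' same endpoints (different relations) count once, direction is ignored,
#' and a self-loop contributes 1.
#'
#' @param network a [fabric_network()].
#' @param node node name.
#' @return integer degree.
#' @export
node_degree <- function(network, node) {
  if (!node %in% network$nodes)
    validation_error(paste0("unknown node: ", node))
  unname(node_degrees(network)[node])
}

# Adjacency as a list of integer neighbor indices per node (self excluded),
# in arbitrary order; `nodes` indexes are positions in network$nodes.
adjacency_idx <- function(network) {
  n <- length(network$nodes)
  p <- neighbor_pairs(network)
  p <- p[p$node != p$nb, , drop = FALSE]
  ni <- match(p$node, network$nodes)
  bi <- match(p$nb, network$nodes)
  adj <- split(bi, factor(ni, levels = seq_len(n)))
  unname(adj)
}
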