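#' Write a layout as node- and link-order attribute files
#'
#' A layout is fully described by two plain-text attribute files: the node
#' file ("Row" header, then `name = row` lines) and the link file
#' ("Column" header, then `source (relation) target = column` lines,
#' shadow copies keyed with their `shdw`-prefixed relation). These files
#' round-trip through [read_order_files()] and let an externally computed
#' layout (e.g. a per-cluster ordering) be imported.
#'
#' @param order node order (named integer vector, rows `1..n`).
#' @param columns a `fabric_columns` object from [assign_columns()].
#' @param node_path,link_path optional output file paths (written UTF-8,
#'   LF line endings).
#' @return invisibly, a list with character vectors `node` and `link` (the
#'   file lines).
#' @export
write_order_files <- function(order, columns, node_path = NULL,
                              link_path = NULL) {
  stopifnot(inherits(columns, "fabric_columns"))
  ord <- order[order(unname(order))]
  node_lines <- c("Row", sprintf("%s = %d", names(ord), unname(ord)))
  tab <- columns$table[order(columns$table$column), , drop = FALSE]
  link_lines <- c("Column",
                  if (nrow(tab)) sprintf("%s = %d", copy_keys(tab), tab$column))
  if (!is.null(node_path)) writeLines(node_lines, node_path, useBytes = TRUE)
  if (!is.null(link_path)) writeLines(link_lines, link_path, useBytes = TRUE)
  invisible(list(node = node_lines, link = link_lines))
}

#' Read a layout from node- and link-order files
#'
#' Parses and validates the files written by [write_order_files()] (or
#' produced externally) against a network: rows must be a bijection onto
#' `1..n` over exactly the network's nodes, and columns a bijection onto
#' `1..E` over exactly the network's link copies. If any link key carries
#' a `shdw` relation prefix, the layout is taken to be in shadow mode and
#' the network is shadow-expanded before matching.
#'
#' @param node_stream,link_stream file paths, connections, or character
#'   vectors of lines.
#' @param network the [fabric_network()] the layout refers to (without
#'   shadow links).
#' @return list with elements `order` (named integer vector), `columns`
#'   (a `fabric_columns`), and `mode`.
#' @export
read_order_files <- function(node_stream, link_stream, network) {
  stopifnot(inherits(network, "fabric_network"))
  node_rec <- parse_assignment_lines(read_input_lines(node_stream),
                                     "node order file")
  link_rec <- parse_assignment_lines(read_input_lines(link_stream),
                                     "link order file")

  n <- length(network$nodes)
  order <- node_rec$value
  names(order) <- node_rec$key
  if (anyDuplicated(names(order)))
    validation_error(paste0("node order file: duplicate node(s): ",
      paste(unique(names(order)[duplicated(names(order))]), collapse = ", ")))
  unknown <- setdiff(names(order), network$nodes)
  if (length(unknown))
    validation_error(paste0("node order file: unknown node(s): ",
                            paste(unknown, collapse = ", ")))
  missing <- setdiff(network$nodes, names(order))
  if (length(missing))
    validation_error(paste0("node order file: missing node(s): ",
                            paste(missing, collapse = ", ")))
  dup_rows <- unique(order[duplicated(order)])
  if (length(dup_rows))
    validation_error(paste0("node order file: duplicate row(s): ",
                            paste(dup_rows, collapse = ", ")))
  if (!setequal(order, seq_len(n)))
    validation_error("node order file: rows are not contiguous 1..n")

  shadow_mode <- any(grepl("^[^(]* \\(shdw", link_rec$key))
  net <- if (shadow_mode) expand_shadows(network) else network
  tab <- net$links
  keys <- copy_keys(tab)
  # Undirected links may be keyed in either orientation.
  alt <- sprintf("%s (%s) %s", tab$target, tab$relation, tab$source)
  idx <- match(link_rec$key, keys)
  na <- is.na(idx)
  if (any(na)) {
    ai <- match(link_rec$key[na], alt)
    ai[!is.na(ai) & tab$directed[ai]] <- NA_integer_  # directed keys are exact
    idx[na] <- ai
  }
  unknown <- link_rec$key[is.na(idx)]
  if (length(unknown))
    validation_error(paste0("link order file: unknown link key(s): ",
                            paste(unknown, collapse = ", ")))
  if (anyDuplicated(idx))
    validation_error("link order file: a link is assigned more than once")
  if (length(idx) < nrow(tab)) {
    left_out <- setdiff(keys, keys[idx])
    validation_error(paste0("link order file: missing link(s): ",
                            paste(left_out, collapse = ", ")))
  }
  cols <- link_rec$value
  if (anyDuplicated(cols))
    validation_error(paste0("link order file: duplicate column(s): ",
      paste(unique(cols[duplicated(cols)]), collapse = ", ")))
  if (nrow(tab) && !setequal(cols, seq_len(nrow(tab))))
    validation_error("link order file: columns are not contiguous 1..E")

  column <- integer(nrow(tab))
  column[idx] <- cols
  rs <- unname(order[tab$source]); rt <- unname(order[tab$target])
  u <- pmin(rs, rt); d <- pmax(rs, rt)
  owner_row <- ifelse(tab$shadow, d, u)
  tab2 <- cbind(tab, data.frame(
    column = column,
    owner = names(order)[match(owner_row, unname(order))],
    owner_row = owner_row,
    distal = ifelse(tab$shadow, u, d),
    stringsAsFactors = FALSE))
  columns <- new_fabric_columns(tab2, nrow(tab),
                                if (shadow_mode) "shadow" else "standard",
                                net$nodes, order)
  list(order = order, columns = columns,
       mode = if (shadow_mode) "shadow" else "standard")
}

# "key = value" records after a single header line; value must be integer.
parse_assignment_lines <- function(lines, what) {
  if (!length(lines)) parse_error(paste0(what, ": empty (missing header)"))
  keys <- character(); values <- integer()
  for (i in seq_along(lines)[-1L]) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    pos <- regexpr(" = [0-9]+[[:space:]]*$", line)
    if (pos < 0L)
      parse_error(sprintf("%s, line %d: expected 'key = integer': '%s'",
                          what, i, line))
    keys[[length(keys) + 1L]] <- substr(line, 1L, pos - 1L)
    values[[length(values) + 1L]] <-
      as.integer(trimws(substr(line, pos + 3L, nchar(line))))
  }
  list(key = keys, value = values)
}
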