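#' First-neighbor selection
#'
#' Builds the selection used for subset views: the seed nodes, all their
#' neighbors, and every link copy incident on at least one seed.
#' Neighbor-to-neighbor links that touch no seed are excluded.
#'
#' @param network a [fabric_network()]; pass the shadow-expanded network
#'   to select both copies of each link.
#' @param seeds character vector of seed node names.
#' @return an object of class `fabric_selection`: list with `seeds`,
#'   `nodes` (seeds plus neighbors) and `links` (logical index into
#'   `network$links`).
#' @examples
#' net <- canonical_network("triangle_pendant")
#' first_neighbors(net, "D")   # picks up D, A and the D-A link only
#' @export
first_neighbors <- function(network, seeds) {
  stopifnot(inherits(network, "fabric_network"))
  seeds <- as.character(seeds)
  unknown <- setdiff(seeds, network$nodes)
  if (length(unknown))
    validation_error(paste0("unknown seed node(s): ",
                            paste(unknown, collapse = ", ")))
  links <- network$links
  incident <- links$source %in% seeds | links$target %in% seeds
  nodes <- union(seeds, c(links$source[incident], links$target[incident]))
  nodes <- network$nodes[network$nodes %in% nodes]   # display order
  structure(list(seeds = seeds, nodes = nodes, links = incident),
            class = "fabric_selection")
}

#' @export
print.fabric_selection <- function(x, ...) {
  cat(sprintf("fabric_selection: %d seed(s), %d nodes, %d link copies\n",
              length(x$seeds), length(x$nodes), sum(x$links)))
  invisible(x)
}

#' Compress a selection into a subset layout
#'
#' Squeezes out all unused rows and columns while retaining the relative
#' positioning of everything selected: selected nodes are renumbered
#' `1..k` preserving row order and selected link copies `1..m` preserving
#' column order. Which node owns each surviving copy's zone is unchanged.
#'
#' With `drop_duplicate_copies = TRUE` on a shadow-mode layout, each link
#' keeps exactly one copy — the one residing in a seed node's zone, so a
#' seed still shows its complete edge inventory; when both copies sit in
#' seed zones the real one is kept.
#'
#' @param order full-layout node order.
#' @param columns full-layout `fabric_columns`.
#' @param selection a [first_neighbors()] selection (or a manually built
#'   one with the same fields).
#' @param drop_duplicate_copies drop the off-seed copy of doubly
#'   represented links (shadow mode only).
#' @return list with `order` (named integer vector over the selected
#'   nodes) and `columns` (a `fabric_columns` for the surviving copies).
#' @export
compress_selection <- function(order, columns, selection,
                               drop_duplicate_copies = FALSE) {
  stopifnot(inherits(columns, "fabric_columns"),
            inherits(selection, "fabric_selection"))
  unknown <- setdiff(selection$nodes, names(order))
  if (length(unknown))
    validation_error(paste0("selection references unknown node(s): ",
                            paste(unknown, collapse = ", ")))
  tab <- columns$table
  if (length(selection$links) != nrow(tab))
    validation_error("selection link index does not match the layout")

  keep <- selection$links
  if (drop_duplicate_copies && columns$mode == "shadow") {
    base_key <- paste(tab$source, tab$target,
                      ifelse(tab$shadow, substring(tab$relation, 5L),
                             tab$relation), sep = "\r")
    in_seed_zone <- tab$owner %in% selection$seeds
    for (k in unique(base_key[keep])) {
      copies <- which(keep & base_key == k)
      if (length(copies) < 2L) next
      pick <- copies[in_seed_zone[copies]]
      if (length(pick) == 0L) pick <- copies[!tab$shadow[copies]]
      if (length(pick) > 1L) pick <- pick[!tab$shadow[pick]]
      keep[setdiff(copies, pick)] <- FALSE
    }
  }

  sel_nodes <- selection$nodes
  sub_rows <- sort(unname(order[sel_nodes]))
  new_order <- structure(seq_along(sub_rows),
                         names = names(order)[match(sub_rows, unname(order))])

  sub <- tab[keep, , drop = FALSE]
  bad <- setdiff(unique(c(sub$source, sub$target)), sel_nodes)
  if (length(bad))
    validation_error(paste0("selected link endpoint(s) outside selection: ",
                            paste(bad, collapse = ", ")))
  sub <- sub[order(sub$column), , drop = FALSE]
  sub$column <- seq_len(nrow(sub))
  sub$owner_row <- unname(new_order[sub$owner])
  rs <- unname(new_order[sub$source]); rt <- unname(new_order[sub$target])
  u <- pmin(rs, rt); d <- pmax(rs, rt)
  sub$distal <- ifelse(sub$shadow, u, d)

  list(order = new_order,
       columns = new_fabric_columns(sub, nrow(sub), columns$mode,
                                    names(new_order), new_order))
}
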