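#' Duplicate every link with a shadow copy
#'
#' In shadow mode every edge of the network is duplicated and the copy's
#' relation label gains the prefix `"shdw"`. The layout then places one
#' copy in each endpoint's node zone, so every node displays a complete
#' inventory of its incident edges.
#'
#' @param network a [fabric_network()] without shadow links.
#' @return a [fabric_network()] with `2e` links; each original link is
#'   followed by its shadow twin in the link table.
#' @export
expand_shadows <- function(network) {
  stopifnot(inherits(network, "fabric_network"))
  if (any(network$links$shadow))
    validation_error("network already contains shadow links")
  links <- network$links
  if (!nrow(links)) return(network)
  twin <- links
  twin$relation <- paste0("shdw", twin$relation)
  twin$shadow <- TRUE
  fabric_network(network$nodes, rbind(links, twin))
}

#' Assign links to columns and derive node zones
#'
#' Produces the second half of a layout: a bijection from link copies onto
#' columns `1..E`, scanning rows top to bottom and filling each node's
#' *zone* — the contiguous block of columns owned by the node in that row.
#'
#' In `standard` mode a link belongs to the zone of its upper endpoint
#' (the one in the smaller row), so a zone holds the node's
#' not-yet-assigned links. In `shadow` mode (network must have been run
#' through [expand_shadows()]) the real copy goes to the upper endpoint's
#' zone and the shadow copy to the lower endpoint's zone, so every zone
#' holds exactly one copy of each incident link and, across the whole
#' layout, the real copy always sits left of its shadow.
#'
#' Within a zone, links are bucketed by the distal endpoint's row, buckets
#' in increasing row order (in standard mode this is increasing link
#' length); within a bucket links are ordered byte-wise lexicographically
#' by base relation, a real copy before its shadow, and for a directed
#' pair with the same relation the downward link before the upward one.
#' When a `groups` spec is given, each zone is first partitioned by the
#' group of the link's base relation, groups in spec order, with the above
#' ordering applied within each group.
#'
#' @param network a [fabric_network()]; already shadow-expanded when
#'   `mode = "shadow"`.
#' @param order node order from [assign_rows()] or
#'   [assign_rows_connectivity()].
#' @param mode `"standard"` (each link once) or `"shadow"`.
#' @param groups optional character vector of relation suffix tags, in
#'   display order; every base relation must end with exactly one tag.
#' @return an object of class `fabric_columns`: a list with `table` (the
#'   link copies with their `column`, zone `owner` and `distal` row),
#'   `width` (`E`), `mode`, `zones` (per node: contiguous column interval,
#'   `NA` when empty) and `extents` (per node: min/max incident column,
#'   `NA` for lone nodes).
#' @examples
#' net <- canonical_network("triangle")
#' ord <- assign_rows(net)
#' assign_columns(expand_shadows(net), ord, mode = "shadow")
#' @export
assign_columns <- function(network, order,
                           mode = c("standard", "shadow"),
                           groups = NULL) {
  mode <- match.arg(mode)
  check_node_order(order, network)
  links <- network$links
  if (mode == "standard" && any(links$shadow))
    validation_error("standard mode on a shadow-expanded network")
  if (mode == "shadow" && nrow(links) && !any(links$shadow))
    validation_error("shadow mode needs an expand_shadows() network")

  n <- length(network$nodes)
  E <- nrow(links)
  if (E == 0L) {
    return(new_fabric_columns(
      cbind(links, column = integer(), owner = character(),
            owner_row = integer(), distal = integer()),
      0L, mode, network$nodes, order))
  }

  rs <- unname(order[links$source])
  rt <- unname(order[links$target])
  u <- pmin(rs, rt)                      # upper endpoint row
  d <- pmax(rs, rt)                      # lower endpoint row
  base_rel <- ifelse(links$shadow, substring(links$relation, 5L),
                     links$relation)

  # Zone owner row and distal row per copy.
  zone_row <- ifelse(links$shadow, d, u)
  distal <- ifelse(links$shadow, u, d)

  group_idx <- rep(1L, E)
  if (!is.null(groups)) group_idx <- match_groups(base_rel, groups)

  rel_code <- c_codes(base_rel)[[1L]]
  upward <- links$directed & (rs > rt)   # arrow points to a smaller row
  ord <- order(zone_row, group_idx, distal, rel_code, links$shadow, upward,
               method = "radix")
  column <- integer(E)
  column[ord] <- seq_len(E)

  tab <- cbind(links,
               data.frame(column = column,
                          owner = names(order)[match(zone_row, unname(order))],
                          owner_row = zone_row, distal = distal,
                          stringsAsFactors = FALSE))
  new_fabric_columns(tab, E, mode, network$nodes, order)
}

match_groups <- function(base_rel, groups) {
  groups <- as.character(groups)
  if (!length(groups) || any(!nzchar(groups)) || anyDuplicated(groups))
    validation_error("group tags must be non-empty and pairwise distinct")
  hits <- vapply(base_rel, function(r) sum(endsWith(r, groups)), integer(1))
  bad <- unique(base_rel[hits != 1L])
  if (length(bad))
    validation_error(paste0(
      "relation(s) not matching exactly one group tag: ",
      paste(c_sort(bad), collapse = ", ")))
  vapply(base_rel, function(r) which(endsWith(r, groups))[1L], integer(1))
}

new_fabric_columns <- function(tab, E, mode, nodes, node_order) {
  rownames(tab) <- NULL
  zones <- data.frame(node = nodes, start = NA_integer_, end = NA_integer_,
                      stringsAsFactors = FALSE)
  extents <- data.frame(node = nodes, min = NA_integer_, max = NA_integer_,
                        stringsAsFactors = FALSE)
  if (nrow(tab)) {
    zs <- tapply(tab$column, factor(tab$owner, levels = nodes), min)
    ze <- tapply(tab$column, factor(tab$owner, levels = nodes), max)
    zones$start <- as.integer(zs)
    zones$end <- as.integer(ze)
    ends <- factor(c(tab$source, tab$target), levels = nodes)
    em <- tapply(rep(tab$column, 2L), ends, min)
    ex <- tapply(rep(tab$column, 2L), ends, max)
    extents$min <- as.integer(em)
    extents$max <- as.integer(ex)
  }
  # zones ordered by the owning node's row
  zones <- zones[order(unname(node_order[zones$node])), , drop = FALSE]
  rownames(zones) <- NULL
  structure(list(table = tab, width = E, mode = mode,
                 zones = zones, extents = extents),
            class = "fabric_columns")
}

#' @export
print.fabric_columns <- function(x, ...) {
  cat(sprintf("fabric_columns: %d columns (%s mode), %d non-empty zones\n",
              x$width, x$mode, sum(!is.na(x$zones$start))))
  invisible(x)
}

# Canonical link-copy key used in link order files: "source (relation) target"
copy_keys <- function(tab) {
  sprintf("%s (%s) %s", tab$source, tab$relation, tab$target)
}
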