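#' Default node-row assignment
#'
#' Orders the nodes by a breadth-first traversal that starts from the most
#' connected component and visits neighbors in decreasing-degree order.
#' The procedure, with row 1 as the first available row:
#'
#' 1. Seed: the highest-degree node not yet placed takes the next
#'    available row, and that row becomes the current row.
#' 2. The node in the current row has its not-yet-placed neighbors
#'    appended to the next available rows in decreasing degree order.
#' 3. The current row advances by one; if its row holds a node, step 2
#'    repeats, otherwise the traversal re-seeds (step 1), which starts the
#'    next connected component.
#'
#' All ties — between seed candidates and between equal-degree neighbors —
#' are broken by byte-wise lexicographic node name. Direction is ignored;
#' duplicate links between the same endpoints count once toward degree.
#' Self-loops contribute 1 to degree but do not add a node to its own
#' neighbor list. Lone nodes (degree 0) are seeded last, so they occupy
#' the bottom rows in lexicographic order.
#'
#' @param network a [fabric_network()].
#' @return a node order: named integer vector mapping every node name to a
#'   row, a bijection onto `1..n`.
#' @examples
#' net <- canonical_network("path3")
#' assign_rows(net)   # B gets row 1: it has the highest degree
#' @export
assign_rows <- function(network) {
  stopifnot(inherits(network, "fabric_network"))
  n <- length(network$nodes)
  if (n == 0L) return(structure(integer(), names = character()))

  deg <- node_degrees(network)
  # Global rank: decreasing degree, ties byte-wise lexicographic by name.
  name_code <- c_codes(network$nodes)[[1L]]
  seed_order <- order(-deg, name_code)           # node indices, best first
  rank <- integer(n); rank[seed_order] <- seq_len(n)

  adj <- adjacency_idx(network)
  adj <- lapply(adj, function(nb) nb[order(rank[nb])])

  placed <- logical(n)
  rows <- integer(n)        # position k = node index in row k
  len <- 0L                 # rows filled so far
  seed_ptr <- 1L            # cursor into seed_order

  append_node <- function(v) {
    len <<- len + 1L
    rows[len] <<- v
    placed[v] <<- TRUE
  }

  current <- 1L
  while (current <= n) {
    if (current > len) {
      while (placed[seed_order[seed_ptr]]) seed_ptr <- seed_ptr + 1L
      append_node(seed_order[seed_ptr])
    }
    v <- rows[current]
    for (nb in adj[[v]]) if (!placed[nb]) append_node(nb)
    current <- current + 1L
  }

  out <- integer(n)
  out[rows] <- seq_len(n)
  names(out) <- network$nodes
  out
}

# Validate that `order` is a bijection node -> 1..n over network's nodes.
check_node_order <- function(order, network) {
  n <- length(network$nodes)
  if (length(order) != n || !setequal(names(order), network$nodes))
    validation_error("node order does not cover the network's node set")
  if (!setequal(order, seq_len(n)))
    validation_error("node order rows are not a bijection onto 1..n")
  invisible(order)
}
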