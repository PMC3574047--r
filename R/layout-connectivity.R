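#' Neighborhood-similarity coefficients per linked node pair
#'
#' Tags each linked (unordered) node pair with a similarity between the
#' connectivities of its two endpoints. Direction is ignored and duplicate
#' relations collapse, so coefficients are symmetric; a node is in its own
#' neighbor set only if self-looped.
#'
#' * `cosine`: dot product of the two 0/1 connectivity n-vectors divided
#'   by the product of their Euclidean norms, i.e.
#'   `|N_u ∩ N_v| / sqrt(|N_u| |N_v|)`.
#' * `jaccard`: `|N_u ∩ N_v| / |N_u ∪ N_v|`.
#'
#' @param network a [fabric_network()] with at least one link.
#' @param measure `"cosine"` or `"jaccard"`.
#' @return data frame with columns `u`, `v` (node names, `u < v`
#'   byte-wise; `u == v` for a self-loop) and `s` (coefficient in
#'   `[0, 1]`).
#' @examples
#' similarity_coefficients(canonical_network("triangle"), "jaccard")
#' @export
similarity_coefficients <- function(network,
                                    measure = c("cosine", "jaccard")) {
  measure <- match.arg(measure)
  stopifnot(inherits(network, "fabric_network"))
  links <- network$links[!network$links$shadow, , drop = FALSE]
  if (!nrow(links)) validation_error("network has no links")

  # Distinct neighbor sets as sorted integer vectors (self kept for loops).
  p <- neighbor_pairs(network)
  nbr <- split(match(p$nb, network$nodes),
               factor(match(p$node, network$nodes),
                      levels = seq_along(network$nodes)))
  nbr <- lapply(unname(nbr), sort)

  cd <- c_codes(links$source, links$target)
  swap <- cd[[1]] > cd[[2]]
  u <- ifelse(swap, links$target, links$source)
  v <- ifelse(swap, links$source, links$target)
  pairs <- !duplicated(paste(u, v, sep = "\r"))
  u <- u[pairs]; v <- v[pairs]
  ui <- match(u, network$nodes); vi <- match(v, network$nodes)

  s <- vapply(seq_along(ui), function(k) {
    a <- nbr[[ui[k]]]; b <- nbr[[vi[k]]]
    inter <- length(intersect(a, b))
    if (measure == "cosine") {
      # sqrt of the product, not product of sqrts: keeps the self-pair
      # coefficient exactly 1 in floating point
      den <- sqrt(as.numeric(length(a)) * length(b))
      if (den == 0) 0 else inter / den
    } else {
      den <- length(union(a, b))
      if (den == 0) 0 else inter / den
    }
  }, numeric(1))
  data.frame(u = u, v = v, s = s, stringsAsFactors = FALSE)
}

#' Similarity-driven node-row assignment ("connectivity" layout)
#'
#' Orders nodes so that nodes with similar connectivity end up in adjacent
#' rows, producing extended runs of look-alike edge wedges. Nodes move one
#' at a time from the unplaced set `U` into the placed list `P`,
#' considering only the front `F` (unplaced nodes with at least one link
#' to `P`).
#'
#' A plain greedy rule would place the front node with the highest
#' coefficient on any placed-to-front link. To keep mining a richly
#' interconnected region instead of hopping away for marginal gains, the
#' algorithm is *sticky*: it keeps an ordered chain of the `chain_size`
#' most recently used placed nodes. Let `S_b` be the best placed-to-front
#' coefficient (on a link from placed node `A`) and `S_d` the best
#' chain-to-front coefficient (from chain node `C`). If
#' `S_d > S_b * threshold` the chain candidate is placed: `C` moves to the
#' chain's first slot and the new node goes into the second. Otherwise the
#' global candidate is placed and the chain is emptied before `A` and the
#' new node take the first two slots. The chain is then trimmed to
#' `chain_size` by dropping its least recently used tail. With
#' `threshold = 1` the rule degenerates to pure greedy placement.
#'
#' Seeds (the start and every new connected component, where the chain is
#' emptied) are the highest-degree unplaced node; all ties anywhere break
#' byte-wise lexicographically by node name, and among equal-coefficient
#' chain candidates the most recently used chain member wins.
#'
#' @inheritParams similarity_coefficients
#' @param chain_size positive integer: chain capacity (`r`).
#' @param threshold fraction in `[0, 1]` (`t`): how much worse the chain
#'   candidate may be and still win.
#' @return node order: named integer vector, bijection onto `1..n`.
#' @examples
#' assign_rows_connectivity(canonical_network("triangle_pendant"),
#'                          measure = "jaccard", threshold = 1)
#' @export
assign_rows_connectivity <- function(network,
                                     measure = c("cosine", "jaccard"),
                                     chain_size = 20L,
                                     threshold = 0.9) {
  measure <- match.arg(measure)
  stopifnot(inherits(network, "fabric_network"))
  chain_size <- as.integer(chain_size)
  if (is.na(chain_size) || chain_size < 1L)
    validation_error("chain_size must be a positive integer")
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    validation_error("threshold must lie in [0, 1]")

  n <- length(network$nodes)
  if (n == 0L) return(structure(integer(), names = character()))

  deg <- node_degrees(network)
  name_code <- c_codes(network$nodes)[[1L]]
  seed_order <- order(-deg, name_code)
  adj <- adjacency_idx(network)

  # Coefficient lookup for linked pairs u < v (indices).
  smat <- new.env(parent = emptyenv(), size = max(16L, nrow(network$links)))
  if (nrow(network$links)) {
    co <- similarity_coefficients(network, measure)
    ui <- match(co$u, network$nodes); vi <- match(co$v, network$nodes)
    for (k in seq_along(ui))
      assign(paste(min(ui[k], vi[k]), max(ui[k], vi[k])), co$s[k],
             envir = smat)
  }
  scoef <- function(a, b)
    get(paste(min(a, b), max(a, b)), envir = smat)

  placed <- logical(n)
  in_front <- logical(n)
  rows <- integer(n)                 # rows[k] = node placed in row k
  len <- 0L
  chain <- integer()                 # most recently used first
  seed_ptr <- 1L

  place <- function(v) {
    len <<- len + 1L
    rows[len] <<- v
    placed[v] <<- TRUE
    in_front[v] <<- FALSE
    for (nb in adj[[v]]) if (!placed[nb]) in_front[nb] <<- TRUE
  }

  reseed <- function() {
    chain <<- integer()
    while (placed[seed_order[seed_ptr]]) seed_ptr <<- seed_ptr + 1L
    place(seed_order[seed_ptr])
  }

  # Best (placed-node, front-node) link among `from` candidates; ties on
  # the coefficient prefer the lexicographically smallest front node, then
  # the earliest scan position. `from` is scanned in priority order — for
  # the chain, most recently used first, so "most recently used chain
  # member wins" falls out of the position rule.
  best_edge <- function(from) {
    best <- NULL
    for (pos in seq_along(from)) {
      pnode <- from[pos]
      for (f in adj[[pnode]]) {
        if (!in_front[f]) next
        s <- scoef(pnode, f)
        if (is.null(best) || s > best$s ||
            (s == best$s && name_code[f] < name_code[best$f]) ||
            (s == best$s && f == best$f && pos < best$pos)) {
          best <- list(s = s, p = pnode, f = f, pos = pos)
        }
      }
    }
    best
  }

  reseed()
  while (len < n) {
    if (!any(in_front)) {           # next component (or lone nodes)
      reseed()
      next
    }
    # Chain members are placed nodes, scanned most recently used first.
    gb <- best_edge(which(placed))
    cb <- if (length(chain)) best_edge(chain) else NULL
    if (!is.null(cb) && cb$s > gb$s * threshold) {
      place(cb$f)
      chain <- c(cb$p, cb$f, setdiff(chain, c(cb$p, cb$f)))
    } else {
      place(gb$f)
      chain <- c(gb$p, gb$f)
    }
    if (length(chain) > chain_size) chain <- chain[seq_len(chain_size)]
  }

  out <- integer(n)
  out[rows] <- seq_len(n)
  names(out) <- network$nodes
  out
}
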