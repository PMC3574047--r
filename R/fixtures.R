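#' Seeded Erdős–Rényi G(n, m) graph
#'
#' Uniform simple undirected graph with exactly `n` nodes and `m` edges,
#' deterministic per seed. Node names are zero-padded (`n0001`, ...) so
#' byte-wise lexicographic order equals numeric order; all relations are
#' `"ee"`.
#'
#' @param n node count.
#' @param m edge count, `0 <= m <= n(n-1)/2`.
#' @param seed integer RNG seed (the caller's RNG state is untouched).
#' @return a [fabric_network()].
#' @examples
#' network_size(er_gnm(100, 300, seed = 1))
#' @export
er_gnm <- function(n, m, seed) {
  n <- as.integer(n); m <- as.double(m)
  total <- n * (n - 1) / 2
  if (is.na(m) || m < 0 || m > total)
    validation_error(sprintf("m must lie in [0, %d]", as.integer(total)))
  idx <- with_seed(seed, sort(sample(total, m)))
  pairs <- pair_from_index(idx, n)
  fmt <- paste0("n%0", nchar(as.character(n)), "d")
  nodes <- sprintf(fmt, seq_len(n))
  links <- data.frame(source = sprintf(fmt, pairs[, 1L]),
                      target = sprintf(fmt, pairs[, 2L]),
                      relation = "ee", directed = FALSE, shadow = FALSE,
                      stringsAsFactors = FALSE)
  fabric_network(nodes, links)
}

# Map linear indices 1..n(n-1)/2 onto pairs (i < j), pairs ordered (1,2),
# (1,3), ..., (1,n), (2,3), ... Floating-point start, integer fix-up.
pair_from_index <- function(idx, n) {
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * idx))
  i <- pmax(pmin(i, n - 1L), 1L)
  off <- (i - 1) * (2 * n - i) / 2     # pairs before row i
  over <- off >= idx
  while (any(over)) {
    i[over] <- i[over] - 1L
    off <- (i - 1) * (2 * n - i) / 2
    over <- off >= idx
  }
  under <- off + (n - i) < idx
  while (any(under)) {
    i[under] <- i[under] + 1L
    off <- (i - 1) * (2 * n - i) / 2
    under <- off + (n - i) < idx
  }
  cbind(as.integer(i), as.integer(i + (idx - off)))
}

#' Seeded Barabási–Albert preferential-attachment graph
#'
#' Grows a simple undirected graph by preferential attachment: vertex 1
#' starts alone; vertex `i` (for `i >= 2`) attaches `min(m_per_step,
#' i - 1)` edges to distinct earlier vertices, chosen with probability
#' proportional to current degree + 1 (the +1 makes isolated early
#' vertices reachable). No multi-edges; total edge count has the closed
#' form `sum over i of min(m_per_step, i - 1)`.
#'
#' @param n node count, `n > m_per_step`.
#' @param m_per_step edges added per incoming vertex, `>= 1`.
#' @inheritParams er_gnm
#' @return a [fabric_network()].
#' @examples
#' network_size(ba_graph(50, 3, seed = 1))   # 3 + 47*3 = 144 edges
#' @export
ba_graph <- function(n, m_per_step, seed) {
  n <- as.integer(n); m_per_step <- as.integer(m_per_step)
  if (is.na(m_per_step) || m_per_step < 1L || n <= m_per_step)
    validation_error("need n > m_per_step >= 1")
  e_total <- sum(pmin(m_per_step, seq_len(n) - 1L))
  src <- integer(e_total); tgt <- integer(e_total)
  with_seed(seed, {
    deg <- integer(n)
    pos <- 0L
    for (i in 2:n) {
      k <- min(m_per_step, i - 1L)
      pick <- if (k == i - 1L) seq_len(i - 1L)
              else sample(i - 1L, k, prob = deg[seq_len(i - 1L)] + 1)
      src[pos + seq_len(k)] <- i
      tgt[pos + seq_len(k)] <- pick
      deg[pick] <- deg[pick] + 1L
      deg[i] <- deg[i] + k
      pos <- pos + k
    }
  })
  fmt <- paste0("n%0", nchar(as.character(n)), "d")
  fabric_network(sprintf(fmt, seq_len(n)),
                 data.frame(source = sprintf(fmt, src),
                            target = sprintf(fmt, tgt),
                            relation = "ee", directed = FALSE,
                            shadow = FALSE, stringsAsFactors = FALSE))
}

#' Canonical worked-example networks
#'
#' Tiny fixed networks used by examples and tests across the package.
#' All relations are `"pp"` except `multi_relation_pair`, whose two
#' parallel links carry suffix-taggable relations `"x-t1"` and `"y-t2"`.
#'
#' @param name one of `"single_edge"`, `"path3"`, `"star4"`,
#'   `"triangle"`, `"triangle_pendant"`, `"two_components"`,
#'   `"multi_relation_pair"`.
#' @return a [fabric_network()].
#' @export
canonical_network <- function(name) {
  pp <- function(nodes, s, t, rel = "pp")
    fabric_network(nodes, data.frame(source = s, target = t, relation = rel,
                                     directed = FALSE, shadow = FALSE,
                                     stringsAsFactors = FALSE))
  switch(name,
    single_edge = pp(c("A", "B"), "A", "B"),
    path3 = pp(c("A", "B", "C"), c("A", "B"), c("B", "C")),
    star4 = pp(c("H", "a", "b", "c"), c("H", "H", "H"), c("a", "b", "c")),
    triangle = pp(c("A", "B", "C"), c("A", "A", "B"), c("B", "C", "C")),
    triangle_pendant = pp(c("A", "B", "C", "D"),
                          c("A", "A", "B", "A"), c("B", "C", "C", "D")),
    two_components = pp(c("D", "E", "F", "A", "B"),
                        c("D", "D", "E", "A"), c("E", "F", "F", "B")),
    multi_relation_pair = pp(c("A", "B"), c("A", "A"), c("B", "B"),
                             rel = c("x-t1", "y-t2")),
    validation_error(paste0("unknown canonical network: ", name))
  )
}
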