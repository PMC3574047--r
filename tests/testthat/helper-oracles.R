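# Independent oracles: deliberately naive re-implementations used to
# cross-check the package's algorithms. They share no code with R/.

# Byte-wise (C locale) sort, same convention the package documents.
csort <- function(x) sort(x, method = "radix")

# Naive degree: scan the link table per node, count unique neighbors
# (self-loop counts once).
oracle_degree <- function(net, v) {
  links <- net$links[!net$links$shadow, , drop = FALSE]
  nb <- unique(c(links$target[links$source == v],
                 links$source[links$target == v]))
  length(nb)
}

# Queue-based breadth-first layout: explicit FIFO queue, nodes re-sorted
# by (degree desc, name asc) at every use.
oracle_bfs_rows <- function(net) {
  deg <- vapply(net$nodes, function(v) oracle_degree(net, v), integer(1))
  names(deg) <- net$nodes
  links <- net$links
  nbrs <- function(v) {
    out <- unique(c(links$target[links$source == v],
                    links$source[links$target == v]))
    setdiff(out, v)
  }
  unassigned <- net$nodes
  placed <- character()
  queue <- character()
  while (length(unassigned)) {
    if (!length(queue)) {
      cand <- unassigned[order(-deg[unassigned], unassigned,
                               method = "radix")]
      seed <- cand[[1L]]
      placed <- c(placed, seed)
      unassigned <- setdiff(unassigned, seed)
      queue <- seed
    }
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- intersect(nbrs(v), unassigned)
    nb <- nb[order(-deg[nb], nb, method = "radix")]
    placed <- c(placed, nb)
    unassigned <- setdiff(unassigned, nb)
    queue <- c(queue, nb)
  }
  structure(seq_along(placed), names = placed)
}

# Brute-force similarity from the 0/1 connectivity matrix.
oracle_similarity <- function(net, measure) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  links <- net$links[!net$links$shadow, , drop = FALSE]
  for (k in seq_len(nrow(links))) {
    A[links$source[k], links$target[k]] <- 1
    A[links$target[k], links$source[k]] <- 1
  }
  pairs <- unique(t(apply(cbind(links$source, links$target), 1L,
                          function(p) csort(p))))
  s <- apply(pairs, 1L, function(p) {
    cu <- A[, p[1L]]; cv <- A[, p[2L]]
    if (measure == "cosine") {
      den <- sqrt(sum(cu)) * sqrt(sum(cv))
      if (den == 0) 0 else sum(cu * cv) / den
    } else {
      den <- sum(cu | cv)
      if (den == 0) 0 else sum(cu & cv) / den
    }
  })
  data.frame(u = pairs[, 1L], v = pairs[, 2L], s = as.numeric(s),
             stringsAsFactors = FALSE)
}

# Pure greedy best-first placement (no chain): what the connectivity
# layout must reduce to at threshold 1.
oracle_greedy_rows <- function(net, measure) {
  deg <- vapply(net$nodes, function(v) oracle_degree(net, v), integer(1))
  names(deg) <- net$nodes
  co <- oracle_similarity(net, measure)
  skey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  smap <- structure(co$s, names = mapply(function(a, b)
    paste(csort(c(a, b)), collapse = " "), co$u, co$v))
  links <- net$links
  nbrs <- function(v) setdiff(unique(c(links$target[links$source == v],
                                       links$source[links$target == v])), v)
  placed <- character()
  unplaced <- net$nodes
  while (length(unplaced)) {
    front_edges <- NULL
    for (p in placed) for (f in intersect(nbrs(p), unplaced))
      front_edges <- rbind(front_edges,
                           data.frame(f = f,
                                      s = unname(smap[[paste(csort(c(p, f)),
                                                             collapse = " ")]]),
                                      stringsAsFactors = FALSE))
    if (is.null(front_edges)) {
      cand <- unplaced[order(-deg[unplaced], unplaced, method = "radix")]
      pick <- cand[[1L]]
    } else {
      best <- max(front_edges$s)
      pick <- csort(front_edges$f[front_edges$s == best])[[1L]]
    }
    placed <- c(placed, pick)
    unplaced <- setdiff(unplaced, pick)
  }
  structure(seq_along(placed), names = placed)
}

# Random undirected test networks (distinct from the package's ER
# generator): edge list sampled by rejection, letter-pair node names.
random_network <- function(seed, n = NULL, m = NULL) {
  set.seed(seed)
  n <- n %||% sample(5:25, 1L)
  nodes <- paste0(rep(LETTERS[1:5], each = 26)[1:n],
                  rep(letters, 5)[1:n])
  max_m <- n * (n - 1) / 2
  m <- m %||% sample.int(max_m, 1L)
  all_pairs <- t(combn(nodes, 2L))
  pick <- sample.int(nrow(all_pairs), m)
  fabric_network(nodes, data.frame(
    source = all_pairs[pick, 1L], target = all_pairs[pick, 2L],
    relation = "pp", directed = FALSE, shadow = FALSE,
    stringsAsFactors = FALSE))
}

# Messier variant: multiple relations, some directed, some self-loops.
random_multi_network <- function(seed) {
  set.seed(seed)
  n <- sample(4:12, 1L)
  nodes <- LETTERS[seq_len(n)]
  rels <- c("pp", "pd", "rx")
  rows <- list()
  seen <- character()
  for (k in seq_len(sample(3:(3 * n), 1L))) {
    s <- sample(nodes, 1L)
    t <- if (runif(1) < 0.1) s else sample(setdiff(nodes, s), 1L)
    r <- sample(rels, 1L)
    directed <- r == "pd"
    key <- if (directed) paste(s, t, r) else paste(paste(csort(c(s, t)),
                                                         collapse = " "), r)
    if (key %in% seen) next
    seen <- c(seen, key)
    rows[[length(rows) + 1L]] <- data.frame(
      source = s, target = t, relation = r, directed = directed,
      shadow = FALSE, stringsAsFactors = FALSE)
  }
  fabric_network(nodes, do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
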