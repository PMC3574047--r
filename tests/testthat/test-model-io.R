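test_that("SIF parsing handles tabs, multi-target lines and lone nodes", {
  net <- parse_sif("A\tpp\tB")
  expect_equal(net$nodes, c("A", "B"))
  expect_equal(nrow(net$links), 1L)
  expect_false(net$links$directed)

  net <- parse_sif("A\tpp\tB\tC")
  expect_equal(nrow(net$links), 2L)
  expect_equal(net$links$target, c("B", "C"))

  net <- parse_sif(c("A pp B", "X"))
  expect_equal(net$nodes, c("A", "B", "X"))
  expect_equal(node_degree(net, "X"), 0L)

  # tab-bearing lines split on tabs only; node names may contain spaces
  net <- parse_sif("node one\tpp\tnode two")
  expect_equal(net$nodes, c("node one", "node two"))
})

test_that("SIF parse errors name the offending line", {
  expect_error(parse_sif(c("A pp B", "A pp")), "line 2",
               class = "fabric_parse_error")
  expect_error(parse_sif("A\t\tB"), "relation",
               class = "fabric_parse_error")
})

test_that("duplicate links are dropped, first occurrence wins", {
  net <- parse_sif(c("A pp B", "A pp B"))
  expect_equal(nrow(net$links), 1L)

  # undirected: reversed orientation is the same link
  net <- parse_sif(c("A pp B", "B pp A"))
  expect_equal(nrow(net$links), 1L)
  expect_equal(net$links$source, "A")

  # directed relation: reversed orientation is a different link
  net <- parse_sif(c("A pd B", "B pd A"), directed_relations = "pd")
  expect_equal(nrow(net$links), 2L)

  # different relation labels are distinct links
  net <- parse_sif(c("A pp B", "A pd B"))
  expect_equal(nrow(net$links), 2L)
})

test_that("dedup count is exact and the node set is unchanged", {
  for (seed in 1:10) {
    set.seed(seed)
    base <- random_multi_network(seed)
    dup_rows <- sample(nrow(base$links), sample(nrow(base$links), 1L),
                       replace = TRUE)
    links <- base$links[c(seq_len(nrow(base$links)), dup_rows), ]
    lines <- sprintf("%s\t%s\t%s", links$source, links$relation, links$target)
    net <- parse_sif(lines, directed_relations = "pd")
    expect_equal(nrow(net$links), nrow(base$links))
    expect_setequal(net$nodes, unique(c(links$source, links$target)))
  }
})

test_that("degree counts distinct neighbors, self-loops once", {
  tri <- canonical_network("triangle")
  expect_equal(node_degree(tri, "A"), 2L)

  multi <- canonical_network("multi_relation_pair")
  expect_equal(node_degree(multi, "A"), 1L)

  net <- parse_sif(c("A pp B", "X", "L loop L"))
  expect_equal(node_degree(net, "X"), 0L)
  expect_equal(node_degree(net, "L"), 1L)
  expect_error(node_degree(net, "nope"), "unknown node",
               class = "fabric_validation_error")
})

test_that("node attribute files parse, skipping nameless rows", {
  attrs <- parse_node_attributes(c("Alias", "n1 = POLR2A", "n2 = POLR2B"))
  expect_equal(attrs[["n1"]], "POLR2A")
  expect_equal(attr(attrs, "attribute"), "Alias")

  expect_length(parse_node_attributes("Alias"), 0L)

  expect_warning(attrs <- parse_node_attributes(c("Alias", " = x", "n1 = y")),
                 "missing first-column")
  expect_equal(names(attrs), "n1")

  expect_error(parse_node_attributes(c("Alias", "n1 POLR2A")), "line 2",
               class = "fabric_parse_error")
})

test_that("SIF round-trips through write_sif", {
  for (seed in 1:10) {
    net <- random_multi_network(seed)
    again <- parse_sif(write_sif(net), directed_relations = "pd")
    expect_equal(again$links, net$links)
    expect_setequal(again$nodes, net$nodes)
    # and the canonical serialization is a fixed point
    expect_identical(write_sif(again), write_sif(net))
  }
})

test_that("order files serialize a single-edge layout as documented", {
  net <- canonical_network("single_edge")
  f <- fabric(net)
  files <- write_order_files(f$order, f$columns)
  expect_identical(files$node, c("Row", "A = 1", "B = 2"))
  expect_identical(files$link, c("Column", "A (pp) B = 1"))

  empty <- fabric(fabric_network("A"))
  files <- write_order_files(empty$order, empty$columns)
  expect_identical(files$link, "Column")
})

test_that("order files round-trip for standard, shadow and directed layouts", {
  for (seed in 1:8) {
    net <- random_multi_network(seed)
    for (shadows in c(FALSE, TRUE)) {
      f <- fabric(net, shadows = shadows)
      files <- write_order_files(f$order, f$columns)
      back <- read_order_files(files$node, files$link, net)
      expect_identical(back$order[names(f$order)], f$order)
      expect_identical(back$mode, f$columns$mode)
      key <- function(cols) {
        tab <- cols$table[order(cols$table$column), ]
        paste(tab$source, tab$target, tab$relation, tab$column)
      }
      expect_identical(key(back$columns), key(f$columns))
      # re-serialization is the identity on the file text
      again <- write_order_files(back$order, back$columns)
      expect_identical(again, files)
    }
  }
})

test_that("order file validation rejects broken inputs by name", {
  net <- canonical_network("path3")
  f <- fabric(net)
  files <- write_order_files(f$order, f$columns)

  dup <- sub("C = 3", "C = 2", files$node, fixed = TRUE)
  expect_error(read_order_files(dup, files$link, net), "duplicate row",
               class = "fabric_validation_error")

  expect_error(read_order_files(files$node[-2], files$link, net),
               "missing node", class = "fabric_validation_error")

  expect_error(read_order_files(files$node, files$link[-2], net),
               "missing link", class = "fabric_validation_error")

  alien <- c(files$link, "A (zz) Q = 3")
  expect_error(read_order_files(files$node, alien, net),
               "unknown link key\\(s\\): A \\(zz\\) Q",
               class = "fabric_validation_error")

  gap <- sub("B (pp) C = 2", "B (pp) C = 5", files$link, fixed = TRUE)
  expect_error(read_order_files(files$node, gap, net), "contiguous",
               class = "fabric_validation_error")
})
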