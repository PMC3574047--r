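test_that("shadow expansion duplicates every link with a prefixed twin", {
  net <- canonical_network("single_edge")
  ex <- expand_shadows(net)
  expect_equal(nrow(ex$links), 2L)
  expect_equal(sum(ex$links$shadow), 1L)
  expect_equal(ex$links$relation[ex$links$shadow], "shdwpp")
  expect_error(expand_shadows(ex), "already contains",
               class = "fabric_validation_error")

  empty <- fabric_network("A")
  expect_equal(nrow(expand_shadows(empty)$links), 0L)

  tri <- expand_shadows(canonical_network("triangle"))
  expect_equal(nrow(tri$links), 6L)
  expect_setequal(unique(sub("^shdw", "", tri$links$relation)), "pp")
})

test_that("standard columns on the path match the hand-derived layout", {
  net <- canonical_network("path3")
  ord <- assign_rows(net)                      # B:1, A:2, C:3
  ca <- assign_columns(net, ord, "standard")
  tab <- ca$table
  expect_equal(tab$column[tab$target == "B" | tab$source == "B"], 1:2)
  expect_equal(tab$owner, c("B", "B"))
  z <- ca$zones
  expect_equal(z[z$node == "B", c("start", "end")],
               data.frame(start = 1L, end = 2L), ignore_attr = TRUE)
  expect_true(all(is.na(z$start[z$node != "B"])))
})

test_that("shadow columns on the triangle interleave as derived by hand", {
  net <- canonical_network("triangle")
  ord <- assign_rows(net)                      # A:1, B:2, C:3
  cs <- assign_columns(expand_shadows(net), ord, "shadow")
  tab <- cs$table[order(cs$table$column), ]
  expect_identical(
    paste(ifelse(tab$shadow, "shdw", "real"), tab$source, tab$target),
    c("real A B", "real A C",        # zone A
      "shdw A B", "real B C",        # zone B
      "shdw A C", "shdw B C"))       # zone C
  expect_identical(tab$owner, c("A", "A", "B", "B", "C", "C"))
  # every zone holds one copy of each incident link
  expect_true(all(table(tab$owner) == 2L))
})

test_that("link groups reorder a zone ahead of lexicographic order", {
  net <- canonical_network("multi_relation_pair")
  ord <- assign_rows(net)
  grouped <- assign_columns(net, ord, "standard", groups = c("t2", "t1"))
  expect_equal(grouped$table$column[grouped$table$relation == "y-t2"], 1L)
  plain <- assign_columns(net, ord, "standard")
  expect_equal(plain$table$column[plain$table$relation == "x-t1"], 1L)

  # grouping survives shadow mode (shdw prefix ignored for matching)
  sh <- assign_columns(expand_shadows(net), ord, "shadow",
                       groups = c("t2", "t1"))
  tab <- sh$table[order(sh$table$column), ]
  expect_identical(sub("^shdw", "", tab$relation),
                   c("y-t2", "x-t1", "y-t2", "x-t1"))
})

test_that("a group spec missing some relation errors with the offenders", {
  net <- canonical_network("multi_relation_pair")
  ord <- assign_rows(net)
  expect_error(assign_columns(net, ord, "standard", groups = "t1"),
               "y-t2", class = "fabric_validation_error")
  expect_error(assign_columns(net, ord, "standard", groups = c("t1", "t1")),
               "distinct", class = "fabric_validation_error")
})

test_that("columns are a bijection and zones contiguous with nondecreasing distal rows", {
  for (seed in 1:12) {
    net <- random_multi_network(seed)
    ord <- assign_rows(net)
    ca <- assign_columns(net, ord, "standard")
    expect_setequal(ca$table$column, seq_len(nrow(net$links)))
    tab <- ca$table[order(ca$table$column), ]
    for (v in unique(tab$owner)) {
      cols <- tab$column[tab$owner == v]
      expect_identical(cols, seq.int(min(cols), max(cols)))
      expect_true(!is.unsorted(tab$distal[tab$owner == v]))
      # standard mode: owner is the upper endpoint
      expect_true(all(tab$owner_row[tab$owner == v] <=
                        tab$distal[tab$owner == v]))
    }
    # zones pairwise disjoint, ordered by owner row
    z <- ca$zones[!is.na(ca$zones$start), ]
    expect_true(all(diff(z$start) > 0))
    expect_true(all(z$start[-1] > z$end[-nrow(z)]))
  }
})

test_that("shadow mode doubles the width and keeps real copies left of shadows", {
  fixtures <- c("single_edge", "path3", "star4", "triangle",
                "triangle_pendant", "two_components", "multi_relation_pair")
  nets <- c(lapply(fixtures, canonical_network),
            lapply(1:8, random_multi_network))
  for (net in nets) {
    ord <- assign_rows(net)
    std <- assign_columns(net, ord, "standard")
    sh <- assign_columns(expand_shadows(net), ord, "shadow")
    expect_identical(sh$width, 2L * std$width)
    tab <- sh$table
    key <- paste(tab$source, tab$target, sub("^shdw", "", tab$relation),
                 tab$directed)
    for (k in unique(key)) {
      real_col <- tab$column[key == k & !tab$shadow]
      shdw_col <- tab$column[key == k & tab$shadow]
      expect_lt(real_col, shdw_col)
    }
    # zone completeness: each zone holds one copy per incident link
    # (a self-loop contributes both its copies to its node's zone)
    inc <- table(c(tab$source[!tab$shadow], tab$target[!tab$shadow]))
    zone_sizes <- table(factor(tab$owner, levels = names(inc)))
    expect_equal(as.integer(zone_sizes), as.integer(inc))
  }
})

test_that("adding a longer link never reorders columns in earlier zones", {
  for (seed in 1:6) {
    net <- random_network(seed, n = 12)
    ord <- assign_rows(net)
    before <- assign_columns(net, ord, "standard")

    # add a link whose upper endpoint sits strictly below row 1
    nodes_by_row <- names(sort(ord))
    pick <- csort(nodes_by_row[-1])[1:2]
    links <- net$links
    key <- paste(links$source, links$target)
    if (paste(pick[1], pick[2]) %in% key ||
        paste(pick[2], pick[1]) %in% key) next
    net2 <- fabric_network(net$nodes, rbind(links, data.frame(
      source = pick[1], target = pick[2], relation = "zz",
      directed = FALSE, shadow = FALSE)))
    after <- assign_columns(net2, ord, "standard")

    u <- min(ord[pick])
    old_keys <- function(ca, rows_below) {
      tab <- ca$table[ca$table$relation != "zz" & ca$table$owner_row < rows_below, ]
      tab <- tab[order(tab$column), ]
      paste(tab$source, tab$target, tab$relation)
    }
    expect_identical(old_keys(after, u), old_keys(before, u))
  }
})
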