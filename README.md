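# netweave

Fabric-style linear layouts for large biological networks in R.

Conventional node-link diagrams of protein interaction or association
networks collapse into "hairballs" beyond a few hundred edges: nodes are
points, edges cross arbitrarily, and nothing reliable can be read at
scale. `netweave` implements the alternative fabric representation:
**every node is a horizontal line segment in its own row, every edge is a
vertical line segment in its own column**, joining its two endpoint rows.
Because no two edges share a column, nothing ever crosses ambiguously,
and a network with `n` nodes and `e` edges becomes an `n × e` weave whose
large-scale shape — boundary slopes, edge wedges, node zones — reflects
degree structure directly.

The package is aimed at systems-biology users who want deterministic,
scriptable layouts of SIF-format networks (tens of thousands of edges)
plus publication-quality SVG/PNG output, and at anyone studying how graph
ensembles look under linear arrangements.

## The layouts

A layout is just two bijections: node → row `1..n` and edge copy →
column `1..E`.

* **Default layout** — breadth-first traversal from the most connected
  component, visiting neighbors in decreasing-degree order, all ties
  broken lexicographically. Columns are then filled top-to-bottom: each
  node's *zone* holds its still-unassigned edges, bucketed by distal row
  (shortest first), so every zone is a contiguous wedge.
* **Connectivity layout** — orders nodes by neighborhood similarity.
  Each linked pair `(j, m)` gets a coefficient, either cosine
  `S_e = C_j · C_m / |C_j||C_m|` on the 0/1 connectivity vectors, or
  Jaccard `S_e = |N_j ∩ N_m| / |N_j ∪ N_m|` on the neighbor sets. Nodes
  are placed one at a time from the front (unplaced neighbors of placed
  nodes); a *chain* of the `r` most recently used nodes and a threshold
  `t` make the placement sticky, so runs of similar nodes stay together
  instead of being abandoned for marginally better candidates elsewhere.
* **Shadow links** — optionally duplicate every edge (relation prefixed
  `shdw`) so each endpoint's zone carries a complete inventory of its
  incident edges; the width doubles and the real copy always sits left
  of its shadow.
* **Link groups** — partition relations by suffix tag and order each
  zone's edges group by group, for side-by-side comparison of networks
  sharing a node set.
* **Subset views** — select seeds plus first neighbors and compress away
  unused rows and columns while preserving all relative order.

## Worked example

```r
library(netweave)
net <- parse_sif(c("GRB2\tpp\tSOS1", "GRB2\tpp\tEGFR", "EGFR\tpp\tSHC1",
                   "SHC1\tpp\tGRB2", "PTPN11\tpp\tGRB2"))
f <- fabric(net, shadows = TRUE)
summary(f)
#> fabric layout: default with shadow links
#>   nodes (rows):       5
#>   link copies (cols): 10
#>   lone nodes:         0
#>   widest node zone:   4
#>   lower-boundary slope: 21.8 degrees
```

GRB2 has the highest degree (4), so it seeds row 1 and owns the widest
zone — with shadows on, all 4 of its edges appear together in its zone
(columns 1–4). The 10 columns are the 5 edges plus their shadow copies;
the 21.8° lower-boundary slope says new columns consume new rows at well
under the 45° one-new-node-per-edge limit, i.e. the graph is
edge-dense relative to a tree. The layout persists as two plain-text
order files:

```r
write_order_files(f$order, f$columns, "example.noa", "example.eda")
readLines("example.noa")
#> [1] "Row"        "GRB2 = 1"   "EGFR = 2"   "SHC1 = 3"   "PTPN11 = 4"
#> [6] "SOS1 = 5"
```

`plot(f, shading = TRUE)` draws the weave on the current device;
`render_svg()` / `render_raster()` produce deterministic files. The same
pipeline is scriptable from a shell via the bundled CLI
(`inst/exec/netweave`): `layout`, `render`, `subset`, `gen` and `orders`
subcommands (see `?fabric_cli`).

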