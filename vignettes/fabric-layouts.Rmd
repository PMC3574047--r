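---
title: "Fabric layouts: models, parameters, and design choices"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netweave)
```

# The representation

`netweave` draws a network on a fixed square grid: node `i` is a
horizontal segment occupying row `order(i)`, and each drawable edge copy
occupies one vertical segment in its own column. A layout is therefore a
pair of bijections — nodes onto rows `1..n`, edge copies onto columns
`1..E` — and everything else (zones, wedges, boundary shapes) is derived
geometry. Both endpoints of an edge are marked with a small square;
directed edges carry an arrowhead at the target row. Colors come from a
repeating 32-entry cycle keyed by row (nodes, light variant) and column
(edges, dark variant), so edges always read darker than the node lines
they cross.

This document records how each algorithm works, which parameters matter,
and where the design was genuinely open — in enough detail that a
maintainer can predict the output of any call without reading the code.

# Default layout

Node rows come from a breadth-first traversal that starts in the most
connected part of the network and always prefers high degree:

1. Seed: the highest-degree unplaced node takes the next free row.
2. The node in the current row appends its unplaced neighbors, in
   decreasing degree order, to the next free rows.
3. The current row advances; when it reaches an empty row the traversal
   re-seeds, which starts the next connected component.

Degree counts *distinct neighbors*: parallel edges with different
relation labels count once, direction is ignored, and a self-loop adds 1.
Every tie — seed choice and neighbor order alike — breaks byte-wise
lexicographically on node names. Byte-wise (C locale) comparison was
chosen over locale collation so layouts are reproducible across machines;
it is also why the generators zero-pad their node names.

Consequences worth knowing: components occupy contiguous row blocks,
entered in order of their maximum-degree node; lone nodes (degree 0) sink
to the bottom rows in name order; a self-loop affects its node's degree
but never the traversal (a node is not its own neighbor).

Column assignment scans rows top to bottom. The node in row `c` owns a
*zone* holding every still-unassigned edge that touches row `c` (all of
which descend to rows ≥ `c`). Within a zone, edges are bucketed by the
distal endpoint's row in increasing order — equivalently by edge length,
shortest first — then by relation label, and for a directed pair with
identical relation the downward edge precedes the upward one. Self-loops
have distal row equal to the owner's row, so they land in the zone's
first bucket.

# Shadow links

With shadows on, every edge is duplicated and the copy's relation gains
the literal prefix `shdw` (no separator). The real copy belongs to the
upper endpoint's zone, the shadow to the lower endpoint's, so each zone
becomes a complete inventory of its node's edges at the cost of doubling
the width. The same row scan applies, with buckets now running over all
distal rows `1..n`: a zone's shadow copies (pointing up) precede its real
copies (pointing down). The fabric convention fixes only that a real
copy must sit left of its shadow globally; placing the shadow block
before the real block *within* a zone is this package's choice — the
simplest single rule consistent with that constraint — and would need
revisiting only by someone chasing pixel parity with other
implementations. For a self-loop both copies sit in the same zone, real
first, bucketed at the owner's own row.

# Link grouping

A group specification is an ordered list of suffix tags that must
partition the base relations (each base relation ends with exactly one
tag; violations error with the offending relations listed). Zones are
partitioned group-first, then the ordinary bucket rules apply within each
group. Matching ignores the `shdw` prefix so an edge and its shadow
always land in the same group. An ungrouped network behaves as a single
implicit group.

# Connectivity layout

Each linked unordered pair gets a similarity coefficient computed once up
front from the static network — cosine on 0/1 connectivity vectors or
Jaccard on neighbor sets, both on distinct undirected neighbors, with a
node in its own neighbor set only when self-looped. Placement then grows
the ordered list of placed nodes `P` one node at a time from the front
`F` (unplaced nodes adjacent to `P`):

* Let `S_b` be the best coefficient on any `P`–`F` edge, from placed node
  `A`; let `S_d` be the best coefficient on any chain–`F` edge, from
  chain node `C`.
* If `S_d > S_b · t`, the chain candidate is placed; `C` moves to the
  chain's first slot and the new node enters the second.
* Otherwise the global candidate is placed; the chain is emptied, then
  `A` and the new node occupy the first two slots.
* The chain is trimmed to `r` entries by dropping its least recently
  used tail.

The chain (capacity `r`, default 20) and threshold (`t`, default 0.9)
are what make the layout "sticky": a richly interconnected region keeps
being mined as long as its internal coefficients stay within a factor
`t` of the best alternative anywhere on the front. At `t = 1` the
algorithm is exactly greedy best-first placement (the strict inequality
can never fire), which the test suite checks against an independent
greedy implementation. The defaults were fixed once: `t = 0.9` makes
stickiness visible on the engineered ladder fixture used in the tests
while staying close to greedy, and `r = 20` comfortably covers the run
lengths seen in small and mid-size networks; both are exposed on the API
and CLI.

Open points resolved here: the chain-update rule reads the same for both
branches, and after a global win the chain has just been emptied, so
adding `A` "in the first slot" is taken literally. Seeds
(initial and per component, where the chain is emptied and placement
re-seeds) are the highest-degree unplaced node, consistent with the
default layout. Tie-breaks: equal-coefficient front nodes go to the
byte-wise smallest name; equal chain candidates to the most recently used
chain member. Multiple parallel edges share their endpoint pair's single
coefficient. Edge columns reuse the standard column assignment unchanged
— only the node order differs.

# Subset views

A selection is seeds plus all their neighbors, plus every edge copy
incident on at least one seed; neighbor–neighbor edges that avoid all
seeds stay out. Compression renumbers the selected rows and surviving
columns consecutively, preserving relative order in both dimensions and
never changing which node owns a copy's zone — so a subset view is the
full layout with the unused grid lines removed, not a new layout.

When shadows are active, a seed-incident edge contributes two copies. The
`drop_duplicate_copies` option keeps exactly one: the copy residing in a
seed's own zone (the real copy when both endpoints are seeds). This
reproduces each seed's complete zone inventory while halving the
duplication; it is this package's reading of the display policy of
discarding the far-left true and far-right shadow copies, and it is
deliberately not changed silently — only one level of subset nesting is
supported.

# Rendering

Geometry is a square grid with one cell of margin: row `r` maps to
`(r + 0.5) · cell` pixels, column `c` to `(c + 0.5) · cell`, with the
cell size (default 18 px) the only scale parameter. Endpoint squares are
half a cell, arrowheads 0.6 of a cell, labels 0.8 of a cell anchored
right over the zone's end; self-loops draw as a one-column stub with the
endpoint squares offset ±0.25 cells inside the row band, and lone nodes
as a one-cell stub in the left margin. Zone shading alternates pale blue
`#E6EEF8` and pale pink `#FAE6EE` by zone parity.

The 32-color cycle is generated programmatically — evenly spaced hues,
strided so adjacent rows differ in hue, light variant at high value and
low saturation, dark at the reverse — and documented as *not* matching
any other tool's exact colors, which are unpublished. A test asserts the
dark variant has strictly lower luminance than its light partner for all
32 entries.

SVG output is assembled with fixed-point coordinates so identical scenes
are byte-identical documents. Raster output draws through the cairo PNG
device with antialiasing on, which matters because tightly spaced
parallel lines alias badly; rasters above a 4·10⁷-pixel budget are
refused with an error rather than silently truncated, since a static
image that size belongs in SVG.

# Synthetic generators

`er_gnm(n, m, seed)` samples exactly `m` distinct pairs uniformly (index
sampling over the `n(n−1)/2` pair space, no rejection loops), and
`ba_graph(n, m_per_step, seed)` grows a preferential-attachment graph:
vertex `i` attaches `min(m_per_step, i − 1)` edges to distinct earlier
vertices with probability proportional to degree + 1. The +1 keeps
isolated early vertices reachable; the exact attachment kernel is a
package decision, while the edge-count closed form
`Σ min(m_per_step, i − 1)` is kernel-independent and asserted in tests.
Both generators are seed-deterministic, restore the caller's RNG state,
and use fixed relation labels so lexicographic tie rules are exercised by
node names only.

These fixtures emulate the two ensemble extremes that matter for layout
shape — uniform degree versus heavy-tailed degree — and nothing else:
no clustering structure, no relation heterogeneity, no directionality.
Passing shape tests on them shows the layouts respond correctly to degree
structure; it says nothing about, e.g., community-rich biological
networks, which is why the similarity layout carries its own engineered
fixtures.

One empirical note on the shape statistics: under the default layout,
zone widths decline with row index for *any* input (later rows' edges
have mostly been consumed above), so a negative zone-width/row
correlation alone does not separate ensembles. What does separate them,
and what the tests assert, is the magnitude of the profile: the
scale-free graph's leading zones are far wider (hub wedges, the sawtooth)
and its maximum degree strictly exceeds the uniform graph's on every
tested seed.

The lower-boundary slope statistic `atan((max bottom-endpoint row − 1) /
E)` summarizes how fast columns consume rows: 45° means every column
reaches a new row; a G(10⁴, 10⁴) graph measures ≈ 41° because at mean
degree 2 about `e^{-2}` ≈ 13.5% of nodes are isolated and never receive
a column endpoint.

# Numerical and format conventions

* Rows and columns are 1-based everywhere, in API and files.
* All string comparison is byte-wise; names are case-sensitive.
* Undirected duplicate detection canonicalizes the smaller endpoint
  first; this orientation convention is a package decision.
* Directedness is declared per relation label at import, default
  undirected, mirroring interactive import dialogs.
* Order files are UTF-8 with LF endings: a one-word header (`Row` /
  `Column`) then `key = value` lines, link keys written
  `source (relation) target` with the `shdw` prefix kept on shadow
  copies. Reading validates full bijectivity (duplicates, gaps, unknown
  or missing entries all error by name). Externally produced files may
  encode layouts whose zones are not contiguous; they are accepted as
  long as the bijections hold, since the row/column orders are the
  layout.
* SIF lines containing a tab split on tabs only (names may contain
  spaces); otherwise runs of whitespace separate fields. A two-field
  line is always an error, reported with its line number.

# Problem sizes in the test suite

The suite cross-checks every algorithm against independent oracles on
randomized inputs: 100 graphs up to 50 nodes for the breadth-first
layout, 50 for greedy equivalence, 15–30 node graphs for brute-force
similarity, plus the full-scale shape runs (10⁴ nodes / 6·10⁴ edges for
column-bijection and boundary-slope checks, five seeds of the 2,000-node
scale-free fixture for the sawtooth profile). These sizes were chosen so
the whole suite exercises both the combinatorics and the at-scale
behavior while completing in well under a minute.

# Known limitations

* The connectivity layout's front scan is quadratic in dense regions; it
  is meant for the tens-of-thousands-of-edges scale, not millions.
* No interactive viewing, tiling, or zoom caching: output is one static
  scene per call.
* No built-in cluster layout; clustered presentations are expected to
  arrive as externally computed order files.
* Raster color fidelity follows the local cairo stack; only the SVG
  output is byte-reproducible.
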