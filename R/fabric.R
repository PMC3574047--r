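#' Lay out a network as a fabric
#'
#' High-level constructor tying the pipeline together: optional shadow
#' expansion, node-row assignment (default breadth-first or
#' similarity-driven connectivity layout), and column assignment with
#' optional link grouping. The result carries everything needed to render
#' or export the layout.
#'
#' @param network a [fabric_network()] without shadow links.
#' @param layout `"default"` ([assign_rows()]) or `"connectivity"`
#'   ([assign_rows_connectivity()]).
#' @param shadows duplicate every link with a shadow copy so each node
#'   zone holds its complete edge inventory (doubles the width).
#' @param groups optional character vector of relation suffix tags for
#'   link grouping, in display order.
#' @param measure,chain_size,threshold connectivity-layout parameters,
#'   see [assign_rows_connectivity()].
#' @return an object of class `fabric`: list with `network` (shadow-
#'   expanded when requested), `order`, `columns`, `layout` and `shadows`.
#' @examples
#' f <- fabric(canonical_network("triangle"), shadows = TRUE)
#' summary(f)
#' @export
fabric <- function(network, layout = c("default", "connectivity"),
                   shadows = FALSE, groups = NULL,
                   measure = c("cosine", "jaccard"), chain_size = 20L,
                   threshold = 0.9) {
  layout <- match.arg(layout)
  stopifnot(inherits(network, "fabric_network"))
  order <- if (layout == "default") assign_rows(network)
           else assign_rows_connectivity(network, measure = measure,
                                         chain_size = chain_size,
                                         threshold = threshold)
  net <- if (shadows) expand_shadows(network) else network
  columns <- assign_columns(net, order,
                            mode = if (shadows) "shadow" else "standard",
                            groups = groups)
  structure(list(network = net, order = order, columns = columns,
                 layout = layout, shadows = shadows),
            class = "fabric")
}

#' @export
print.fabric <- function(x, ...) {
  cat(sprintf("fabric layout (%s%s): %d nodes in rows, %d link copies in columns\n",
              x$layout, if (x$shadows) ", shadow links" else "",
              length(x$order), x$columns$width))
  invisible(x)
}

#' @export
summary.fabric <- function(object, ...) {
  zw <- zone_widths(object$columns)
  res <- list(
    layout = object$layout,
    shadows = object$shadows,
    n = length(object$order),
    width = object$columns$width,
    lone_nodes = sum(is.na(object$columns$extents$min)),
    max_zone_width = if (length(zw)) max(zw) else 0L,
    boundary_slope = lower_boundary_slope(object$order, object$columns)
  )
  class(res) <- "summary.fabric"
  res
}

#' @export
print.summary.fabric <- function(x, ...) {
  cat(sprintf("fabric layout: %s%s\n", x$layout,
              if (x$shadows) " with shadow links" else ""))
  cat(sprintf("  nodes (rows):       %d\n", x$n))
  cat(sprintf("  link copies (cols): %d\n", x$width))
  cat(sprintf("  lone nodes:         %d\n", x$lone_nodes))
  cat(sprintf("  widest node zone:   %d\n", x$max_zone_width))
  cat(sprintf("  lower-boundary slope: %.1f degrees\n", x$boundary_slope))
  invisible(x)
}

#' @param x a `fabric` object.
#' @param cell,shading,labels see [build_scene()].
#' @param ... ignored.
#' @rdname fabric
#' @export
plot.fabric <- function(x, cell = 18, shading = FALSE, labels = TRUE, ...) {
  scene <- build_scene(x$network, x$order, x$columns, cell = cell,
                       shading = shading, labels = labels)
  draw_scene(scene)
  invisible(scene)
}

#' Zone widths in row order
#'
#' Number of columns in each node's zone, ordered by row. Empty zones
#' (nodes owning no columns) count 0. Under the default layout the
#' profile of zone widths versus row is a fingerprint of the degree
#' distribution: scale-free graphs show a decreasing sawtooth, uniform
#' random graphs stay flat.
#'
#' @param columns a `fabric_columns` object.
#' @return integer vector of length `n`, one entry per row.
#' @export
zone_widths <- function(columns) {
  stopifnot(inherits(columns, "fabric_columns"))
  z <- columns$zones
  ifelse(is.na(z$start), 0L, z$end - z$start + 1L)
}

#' Average slope of the layout's lower boundary
#'
#' On the square layout grid, the lower boundary is the envelope traced by
#' the bottom endpoints of successive edge columns. Its average slope in
#' degrees is `atan((max bottom-endpoint row - 1) / columns)`. A slope at
#' the 45-degree limit means every new column consumes a new node row (a
#' tree-like frontier); a slope near zero means new columns keep landing
#' on already-visited rows.
#'
#' @param order node order.
#' @param columns `fabric_columns` for the same layout.
#' @return slope in degrees (0 for an edgeless layout).
#' @export
lower_boundary_slope <- function(order, columns) {
  stopifnot(inherits(columns, "fabric_columns"))
  if (columns$width == 0L) return(0)
  tab <- columns$table
  bottom <- pmax(unname(order[tab$source]), unname(order[tab$target]))
  atan((max(bottom) - 1) / columns$width) * 180 / pi
}
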