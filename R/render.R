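# Rendering: scene construction on a fixed square grid, SVG and raster
# output, plus the base-graphics drawing used by plot.fabric().

# 32 hues, evenly spaced; light variant for node lines, dark variant for
# edge lines (edges are drawn darker than nodes). The cycle is keyed by
# row for nodes and by column for edges. These are generated, not the
# original tool's values.
PALETTE_SIZE <- 32L

palette_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      h <- (seq_len(PALETTE_SIZE) - 1L) / PALETTE_SIZE
      # de-correlate adjacent rows/columns: stride through the hue circle
      h <- h[(seq_len(PALETTE_SIZE) * 7L) %% PALETTE_SIZE + 1L]
      tab <<- cbind(light = grDevices::hsv(h, 0.45, 0.95),
                    dark  = grDevices::hsv(h, 0.90, 0.55))
    }
    tab
  }
})

#' Repeating 32-color palette
#'
#' Colors are used in a fixed repeating cycle of 32, not randomly: entry
#' `index` equals entry `index + 32`. Each entry is a light/dark pair;
#' node lines take the light variant (keyed by row), edge lines the dark
#' variant (keyed by column), so edges are always darker than nodes.
#'
#' @param index positive integer.
#' @return named character vector `c(light = , dark = )` of hex colors.
#' @examples
#' identical(fabric_palette(1), fabric_palette(33))
#' @export
fabric_palette <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 1L))
    validation_error("palette index must be >= 1")
  tab <- palette_table()
  k <- (index - 1L) %% PALETTE_SIZE + 1L
  c(light = unname(tab[k, "light"]), dark = unname(tab[k, "dark"]))
}

# Relative luminance of a hex color (0..1, sRGB weights).
color_luminance <- function(hex) {
  rgb <- grDevices::col2rgb(hex) / 255
  drop(c(0.2126, 0.7152, 0.0722) %*% rgb)
}

ZONE_SHADE <- c(blue = "#E6EEF8", pink = "#FAE6EE")

#' Build a drawable scene from a layout
#'
#' Lays the network onto a fixed square grid (row pitch equals column
#' pitch equals `cell` pixels) and emits drawing primitives:
#'
#' * one horizontal node segment per node with a non-empty extent,
#'   spanning its leftmost to rightmost incident column (light palette
#'   color keyed by row); lone nodes get a one-cell stub;
#' * one vertical edge segment per column, spanning its two endpoint rows
#'   (dark palette color keyed by column); self-loops become a short stub
#'   within their row band;
#' * two tiny endpoint squares per edge segment;
#' * an arrowhead at the target row end of each directed edge;
#' * a node label over the right terminus of each node's zone;
#' * optional node-zone shading: alternating light blue / light pink
#'   backgrounds behind consecutive zones.
#'
#' @param network the laid-out [fabric_network()] (shadow-expanded if the
#'   columns are in shadow mode).
#' @param order node order (named integer vector).
#' @param columns `fabric_columns` from [assign_columns()].
#' @param cell grid cell size in pixels.
#' @param shading draw alternating zone backgrounds.
#' @param labels draw node labels.
#' @return an object of class `fabric_scene`: grid geometry plus data
#'   frames of primitives (`shading`, `nodes`, `edges`, `squares`,
#'   `arrows`, `labels`).
#' @export
build_scene <- function(network, order, columns, cell = 18,
                        shading = FALSE, labels = TRUE) {
  stopifnot(inherits(network, "fabric_network"),
            inherits(columns, "fabric_columns"))
  check_node_order(order, network)
  n <- length(network$nodes)
  E <- columns$width
  tab <- columns$table

  rows <- unname(order[columns$extents$node])
  ext <- columns$extents

  # Node segments: extent span, or a one-cell stub in the left margin.
  has_ext <- !is.na(ext$min)
  node_seg <- data.frame(
    node = ext$node,
    row = rows,
    x0 = ifelse(has_ext, ext$min, -0.5),
    x1 = ifelse(has_ext, ext$max, 0.5),
    color = unname(palette_table()[(rows - 1L) %% PALETTE_SIZE + 1L, "light"]),
    stringsAsFactors = FALSE)

  # Edge segments.
  if (E > 0L) {
    rs <- unname(order[tab$source]); rt <- unname(order[tab$target])
    u <- pmin(rs, rt); d <- pmax(rs, rt)
    self <- u == d
    edge_seg <- data.frame(
      column = tab$column,
      y0 = ifelse(self, u - 0.25, u),
      y1 = ifelse(self, d + 0.25, d),
      color = palette_table()[(tab$column - 1L) %% PALETTE_SIZE + 1L, "dark"],
      stringsAsFactors = FALSE)
    squares <- data.frame(
      column = rep(tab$column, 2L),
      row = c(edge_seg$y0, edge_seg$y1),
      color = rep(edge_seg$color, 2L),
      stringsAsFactors = FALSE)
    dirs <- tab$directed
    arrows <- data.frame(
      column = tab$column[dirs],
      row = rt[dirs] + ifelse(self[dirs], 0.25, 0),
      orientation = ifelse(rt[dirs] >= rs[dirs], "down", "up"),
      color = edge_seg$color[dirs],
      stringsAsFactors = FALSE)
  } else {
    edge_seg <- data.frame(column = integer(), y0 = numeric(),
                           y1 = numeric(), color = character(),
                           stringsAsFactors = FALSE)
    squares <- data.frame(column = numeric(), row = numeric(),
                          color = character(), stringsAsFactors = FALSE)
    arrows <- data.frame(column = numeric(), row = numeric(),
                         orientation = character(), color = character(),
                         stringsAsFactors = FALSE)
  }

  # Zone shading, alternating by zone parity in row order.
  shade <- data.frame(x0 = numeric(), x1 = numeric(), color = character(),
                      stringsAsFactors = FALSE)
  if (shading) {
    z <- columns$zones[!is.na(columns$zones$start), , drop = FALSE]
    if (nrow(z))
      shade <- data.frame(
        x0 = z$start, x1 = z$end,
        color = unname(ZONE_SHADE[(seq_len(nrow(z)) - 1L) %% 2L + 1L]),
        stringsAsFactors = FALSE)
  }

  lab <- data.frame(text = character(), x = numeric(), y = numeric(),
                    stringsAsFactors = FALSE)
  if (labels) {
    zl <- columns$zones[match(ext$node, columns$zones$node), , drop = FALSE]
    anchor <- ifelse(!is.na(zl$end), zl$end,
                     ifelse(has_ext, ext$max, 0))
    lab <- data.frame(text = ext$node, x = anchor, y = rows - 0.35,
                      stringsAsFactors = FALSE)
  }

  structure(list(cell = cell, n_rows = n, n_cols = E,
                 shading = shade, nodes = node_seg, edges = edge_seg,
                 squares = squares, arrows = arrows, labels = lab),
            class = "fabric_scene")
}

#' @export
print.fabric_scene <- function(x, ...) {
  cat(sprintf("fabric_scene: %d rows x %d columns, %d primitives\n",
              x$n_rows, x$n_cols, scene_primitive_count(x)))
  invisible(x)
}

scene_primitive_count <- function(scene) {
  nrow(scene$shading) + nrow(scene$nodes) + nrow(scene$edges) +
    nrow(scene$squares) + nrow(scene$arrows) + nrow(scene$labels)
}

# Grid coordinates -> pixel coordinates. Row r sits at y = (r + 0.5) cells
# from the top (1 cell margin top/left), column c at x = (c + 0.5) cells.
scene_px <- function(scene) {
  cell <- scene$cell
  list(
    x = function(col) (col + 0.5) * cell,
    y = function(row) (row + 0.5) * cell,
    width = (scene$n_cols + 2) * cell,
    height = (scene$n_rows + 2) * cell
  )
}

fmt_px <- function(x) {
  # fixed-point, deterministic, no trailing-zero variation
  s <- sprintf("%.2f", x)
  sub("\\.?0+$", "", s)
}

#' Render a scene to SVG
#'
#' Emits a standalone SVG 1.1 document. The output is byte-deterministic:
#' identical scenes produce identical documents.
#'
#' @param scene a [build_scene()] result.
#' @param path optional output file (written UTF-8, LF).
#' @return the SVG document as a single character string, invisibly when
#'   written to a file.
#' @export
render_svg <- function(scene, path = NULL) {
  stopifnot(inherits(scene, "fabric_scene"))
  if (scene$n_rows == 0L)
    validation_error("cannot render an empty scene")
  px <- scene_px(scene)
  cell <- scene$cell
  out <- character()
  add <- function(...) out[[length(out) + 1L]] <<- sprintf(...)

  add('<?xml version="1.0" encoding="UTF-8"?>')
  add(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
             'width="%s" height="%s" viewBox="0 0 %s %s">'),
      fmt_px(px$width), fmt_px(px$height), fmt_px(px$width),
      fmt_px(px$height))

  s <- scene$shading
  for (i in seq_len(nrow(s)))
    add('<rect x="%s" y="0" width="%s" height="%s" fill="%s"/>',
        fmt_px(px$x(s$x0[i]) - cell / 2),
        fmt_px((s$x1[i] - s$x0[i] + 1) * cell),
        fmt_px(px$height), s$color[i])

  nd <- scene$nodes
  for (i in seq_len(nrow(nd)))
    add('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
        fmt_px(px$x(nd$x0[i])), fmt_px(px$y(nd$row[i])),
        fmt_px(px$x(nd$x1[i])), fmt_px(px$y(nd$row[i])),
        nd$color[i], fmt_px(cell * 0.2))

  ed <- scene$edges
  for (i in seq_len(nrow(ed)))
    add('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
        fmt_px(px$x(ed$column[i])), fmt_px(px$y(ed$y0[i])),
        fmt_px(px$x(ed$column[i])), fmt_px(px$y(ed$y1[i])),
        ed$color[i], fmt_px(cell * 0.12))

  sq <- scene$squares
  half <- cell * 0.25
  for (i in seq_len(nrow(sq)))
    add('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        fmt_px(px$x(sq$column[i]) - half), fmt_px(px$y(sq$row[i]) - half),
        fmt_px(2 * half), fmt_px(2 * half), sq$color[i])

  ar <- scene$arrows
  ah <- cell * 0.3
  for (i in seq_len(nrow(ar))) {
    xx <- px$x(ar$column[i]); yy <- px$y(ar$row[i])
    tip <- if (ar$orientation[i] == "down") yy + ah else yy - ah
    add('<polygon points="%s,%s %s,%s %s,%s" fill="%s"/>',
        fmt_px(xx - ah), fmt_px(yy), fmt_px(xx + ah), fmt_px(yy),
        fmt_px(xx), fmt_px(tip), ar$color[i])
  }

  lb <- scene$labels
  for (i in seq_len(nrow(lb)))
    add(paste0('<text x="%s" y="%s" text-anchor="end" ',
               'font-family="sans-serif" font-size="%s">%s</text>'),
        fmt_px(px$x(lb$x[i]) + cell / 2), fmt_px(px$y(lb$y[i])),
        fmt_px(cell * 0.8), xml_escape(lb$text[i]))

  add('</svg>')
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(doc)
  writeLines(doc, path, sep = "", useBytes = TRUE)
  invisible(doc)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Draw a scene on the current graphics device using base graphics.
draw_scene <- function(scene) {
  px <- scene_px(scene)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, px$width), ylim = c(px$height, 0),
                        xaxs = "i", yaxs = "i", asp = 1)
  cell <- scene$cell
  s <- scene$shading
  if (nrow(s))
    graphics::rect(px$x(s$x0) - cell / 2, 0, px$x(s$x1) + cell / 2,
                   px$height, col = s$color, border = NA)
  nd <- scene$nodes
  if (nrow(nd))
    graphics::segments(px$x(nd$x0), px$y(nd$row), px$x(nd$x1),
                       px$y(nd$row), col = nd$color, lwd = cell * 0.2,
                       lend = 1)
  ed <- scene$edges
  if (nrow(ed))
    graphics::segments(px$x(ed$column), px$y(ed$y0), px$x(ed$column),
                       px$y(ed$y1), col = ed$color, lwd = cell * 0.12,
                       lend = 1)
  sq <- scene$squares
  half <- cell * 0.25
  if (nrow(sq))
    graphics::rect(px$x(sq$column) - half, px$y(sq$row) - half,
                   px$x(sq$column) + half, px$y(sq$row) + half,
                   col = sq$color, border = NA)
  ar <- scene$arrows
  if (nrow(ar)) {
    ah <- cell * 0.3
    for (i in seq_len(nrow(ar))) {
      xx <- px$x(ar$column[i]); yy <- px$y(ar$row[i])
      tip <- if (ar$orientation[i] == "down") yy + ah else yy - ah
      graphics::polygon(c(xx - ah, xx + ah, xx), c(yy, yy, tip),
                        col = ar$color[i], border = NA)
    }
  }
  lb <- scene$labels
  if (nrow(lb))
    graphics::text(px$x(lb$x) + cell / 2, px$y(lb$y), lb$text, adj = c(1, 0),
                   cex = max(0.3, cell / 20))
  invisible(scene)
}

# Hard cap on raster size; rendering above it is refused with a clear
# error (large outputs belong in SVG).
RASTER_PIXEL_CAP <- 4e7

#' Render a scene to a PNG raster
#'
#' Draws the scene with antialiasing (the tightly spaced parallel lines of
#' a fabric layout alias badly otherwise) and returns the PNG bytes.
#' Scenes above the pixel budget (`4e7` pixels by default) are refused.
#'
#' @inheritParams render_svg
#' @param scale multiplier on the scene's pixel dimensions.
#' @param max_pixels refuse rasters above this width x height budget.
#' @return raw vector of PNG bytes, invisibly when written to a file.
#' @export
render_raster <- function(scene, path = NULL, scale = 1,
                          max_pixels = RASTER_PIXEL_CAP) {
  stopifnot(inherits(scene, "fabric_scene"))
  if (scene$n_rows == 0L)
    validation_error("cannot render an empty scene")
  px <- scene_px(scene)
  w <- ceiling(px$width * scale); h <- ceiling(px$height * scale)
  if (w * h > max_pixels)
    validation_error(sprintf(
      "raster of %d x %d pixels exceeds the %g pixel budget; reduce cell size or render SVG",
      w, h, max_pixels))
  tmp <- path %||% tempfile(fileext = ".png")
  grDevices::png(tmp, width = w, height = h, type = "cairo",
                 antialias = "default")
  ok <- FALSE
  tryCatch({
    graphics::par(mar = c(0, 0, 0, 0))
    draw_scene(scene)
    ok <- TRUE
  }, finally = grDevices::dev.off())
  if (!ok) fabric_error("raster rendering failed")
  bytes <- readBin(tmp, "raw", file.info(tmp)$size)
  if (is.null(path)) {
    unlink(tmp)
    return(bytes)
  }
  invisible(bytes)
}
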