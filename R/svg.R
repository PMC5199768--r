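# Static rendering of treemap layouts: SVG documents and JSON export.

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.svgRect <- function(cells, strokeWidth = 1) {
  sprintf(paste0('<rect x="%.4f" y="%.4f" width="%.4f" height="%.4f" ',
                 'fill="%s" stroke="#333333" stroke-width="%g">',
                 '<title>%s</title></rect>'),
          cells$x, cells$y, cells$w, cells$h, cells$color, strokeWidth,
          .xmlEscape(sprintf("%s | size %.6g | value %.6g", cells$key,
                             cells$size, cells$colorValue)))
}

.svgLabel <- function(cells) {
  big <- cells$w >= 60 & cells$h >= 14
  if (!any(big)) return(character(0))
  c <- cells[big, , drop = FALSE]
  lab <- .xmlEscape(substr(c$key, 1, pmax(3, floor(c$w / 7))))
  sprintf('<text x="%.4f" y="%.4f" font-size="11" font-family="monospace" fill="#111111">%s</text>',
          c$x + 3, c$y + 12, lab)
}

#' Render a treemap layout as SVG
#'
#' Writes a deterministic standalone SVG document: one rectangle per cell
#' (with the scaffold key, size and color value in a tooltip `<title>`) and
#' a text depiction of the key in cells large enough to carry one. With
#' `depth > 1` the layout recurses: each cell is subdivided by the layout of
#' its own children, drawn inset, mirroring the zoomable-map interaction one
#' static frame at a time.
#'
#' @param layout a [TreemapLayout-class], or a [ScaffoldHierarchy-class]
#'   (then `level`/`key` select the parent node and a layout is computed).
#' @param path output SVG path.
#' @param depth nesting depth (only used when `layout` is a hierarchy).
#' @param level,key,... parent node address and layout options passed to
#'   [treemapLayout()].
#' @return invisibly, `path`.
#' @export
renderTreemapSVG <- function(layout, path, depth = 1L, level = 0L,
                             key = ROOT_KEY, ...) {
  if (is(layout, "ScaffoldHierarchy")) {
    h <- layout
    body <- .renderNested(h, level, key, rect = c(0, 0, 1000, 618),
                          depth = depth, ...)
    parent <- c(0, 0, 1000, 618)
  } else {
    stopifnot(is(layout, "TreemapLayout"))
    body <- c(.svgRect(layout@cells), .svgLabel(layout@cells))
    parent <- layout@parent
  }
  doc <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'viewBox="%.4f %.4f %.4f %.4f" width="%g" height="%g">'),
                   parent[1], parent[2], parent[3], parent[4],
                   parent[3], parent[4]),
           '<rect x="0" y="0" width="100%" height="100%" fill="#FAFAFA"/>',
           body, "</svg>")
  writeLines(doc, path)
  invisible(path)
}

.renderNested <- function(h, level, key, rect, depth, ...) {
  lay <- treemapLayout(h, level, key, rect = rect, ...)
  cl <- lay@cells
  if (nrow(cl) == 0) return(character(0))
  out <- c(.svgRect(cl, strokeWidth = max(0.4, 1.6 - 0.4 * level)),
           if (depth <= 1L) .svgLabel(cl))
  if (depth > 1L && level < 8L) {
    for (i in seq_len(nrow(cl))) {
      inset <- 0.04 * min(cl$w[i], cl$h[i])
      sub <- c(cl$x[i] + inset, cl$y[i] + inset,
               cl$w[i] - 2 * inset, cl$h[i] - 2 * inset)
      if (sub[3] <= 0 || sub[4] <= 0) next
      out <- c(out, .renderNested(h, level + 1L, cl$key[i], sub,
                                  depth - 1L, ...))
    }
  }
  out
}

#' Export / import a treemap layout as JSON
#'
#' The JSON document carries the parent rectangle, the cell level and per
#' cell the key, rectangle, size and color values, so any front end can
#' rebuild and zoom the layout. `loadTreemapJSON` round-trips to an equal
#' layout.
#'
#' @param layout a [TreemapLayout-class].
#' @param path JSON file path.
#' @return `exportTreemapJSON`: invisibly `path`; `loadTreemapJSON`: a
#'   [TreemapLayout-class].
#' @export
exportTreemapJSON <- function(layout, path) {
  stopifnot(is(layout, "TreemapLayout"))
  cl <- layout@cells
  cl$colorValue[!is.finite(cl$colorValue)] <- NA  # Inf = dataset-only scaffold
  obj <- list(parent = layout@parent, level = layout@level, cells = cl)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname exportTreemapJSON
#' @export
loadTreemapJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- as.data.frame(obj$cells, stringsAsFactors = FALSE)
  if (nrow(cells) > 0) {
    cells$colorValue[is.na(cells$colorValue)] <- Inf
  }
  new("TreemapLayout", parent = as.numeric(obj$parent),
      cells = cells, level = as.integer(obj$level))
}
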