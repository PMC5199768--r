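# Squarified treemap layout and the size/color encodings.

#' Squarified treemap layout
#'
#' Tiles a rectangle with cells whose areas are exactly proportional to the
#' given weights, using the greedy row-building squarified algorithm: cells
#' are placed in rows along the shorter side of the remaining rectangle, and
#' a row is closed as soon as adding the next cell would worsen the row's
#' worst aspect ratio. Weights are processed in non-increasing order; the
#' returned rectangles are in the order of the input weights.
#'
#' @param weights positive numeric vector.
#' @param rect numeric(4): x, y, width, height of the rectangle to fill
#'   (origin top-left, y grows downwards).
#' @return data.frame with columns x, y, w, h (one row per weight; zero rows
#'   for an empty weight vector).
#' @examples
#' squarify(c(6, 6, 4, 3, 2, 2, 1), c(0, 0, 6, 4))
#' @export
squarify <- function(weights, rect) {
  stopifnot(length(rect) == 4, rect[3] > 0, rect[4] > 0)
  n <- length(weights)
  out <- data.frame(x = numeric(n), y = numeric(n), w = numeric(n),
                    h = numeric(n))
  if (n == 0) return(out)
  if (any(weights <= 0)) stop("weights must be positive")
  ord <- order(-weights)
  areas <- weights[ord] * (rect[3] * rect[4]) / sum(weights)

  worst <- function(row, side) {
    s <- sum(row)
    max((side^2) * max(row) / s^2, s^2 / ((side^2) * min(row)))
  }

  x <- rect[1]; y <- rect[2]; w <- rect[3]; h <- rect[4]
  res <- matrix(0, n, 4)
  i <- 1L
  row <- numeric(0); rowIdx <- integer(0)

  layoutRow <- function(row, rowIdx) {
    side <- min(w, h)
    thick <- sum(row) / side
    lens <- row / thick
    if (w >= h) {            # vertical strip on the left edge
      ys <- y + c(0, cumsum(lens))[seq_along(lens)]
      res[rowIdx, ] <<- cbind(x, ys, thick, lens)
      x <<- x + thick; w <<- w - thick
    } else {                 # horizontal strip on the top edge
      xs <- x + c(0, cumsum(lens))[seq_along(lens)]
      res[rowIdx, ] <<- cbind(xs, y, lens, thick)
      y <<- y + thick; h <<- h - thick
    }
  }

  while (i <= n) {
    side <- min(w, h)
    if (length(row) == 0 ||
        worst(c(row, areas[i]), side) <= worst(row, side)) {
      row <- c(row, areas[i]); rowIdx <- c(rowIdx, i)
      i <- i + 1L
    } else {
      layoutRow(row, rowIdx)
      row <- numeric(0); rowIdx <- integer(0)
    }
  }
  layoutRow(row, rowIdx)
  res[ord, ] <- res  # back to input order
  out$x <- res[, 1]; out$y <- res[, 2]; out$w <- res[, 3]; out$h <- res[, 4]
  out
}

#' Cell sizes for a treemap
#'
#' Maps children of one hierarchy node to layout weights: the scaffold's
#' frequency in the background set (default: cell area reflects the
#' scaffold's share of the empirical chemical space) or in the user dataset,
#' optionally log-transformed (`log1p`) to damp the heavy skew of scaffold
#' frequency distributions. Zero-frequency children receive no cell.
#'
#' @param children data.frame of child nodes (as from [hierarchyChildren()]).
#' @param mode `"background"` or `"dataset"`.
#' @param log apply the logarithmic size transform.
#' @return named numeric vector of positive weights (names = keys); length
#'   zero (with a warning) when all frequencies are zero.
#' @export
computeSizes <- function(children, mode = c("background", "dataset"),
                         log = FALSE) {
  mode <- match.arg(mode)
  freq <- if (mode == "background") children$backgroundFreq else
    children$datasetFreq
  wt <- if (log) log1p(freq) else freq
  names(wt) <- children$key
  wt <- wt[wt > 0]
  if (!length(wt) && nrow(children) > 0)
    warning("all ", mode, " frequencies are zero: empty layout")
  wt
}

.GRADIENTS <- list(
  "white-red" = c("#FFFFFF", "#FF0000"),
  "white-blue" = c("#FFFFFF", "#0055CC"),
  "blue-red" = c("#0055CC", "#FFFFFF", "#CC0000"),
  "heat" = c("#FFFFCC", "#FD8D3C", "#800026"))

.gradientFun <- function(gradient) {
  cols <- if (is.character(gradient) && length(gradient) == 1 &&
              gradient %in% names(.GRADIENTS)) .GRADIENTS[[gradient]]
          else gradient
  ramp <- grDevices::colorRamp(cols)
  function(v) {
    rgb <- ramp(pmin(pmax(v, 0), 1))
    grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  }
}

#' Cell colors for a treemap
#'
#' Maps children of one node to colors. The raw value per child is its
#' dataset frequency, its background frequency, or (mode `"relative"`) the
#' enrichment ratio (datasetFreq/datasetTotal) / (backgroundFreq/
#' backgroundTotal); a scaffold present only in the user set is maximally
#' enriched and maps to the top of the gradient. Values are optionally
#' log-transformed, min-max normalized across the siblings (a constant
#' vector maps to the gradient midpoint), and passed through the gradient.
#'
#' @param children data.frame of child nodes.
#' @param mode `"dataset"` (default), `"background"` or `"relative"`.
#' @param gradient a gradient name (`"white-red"`, `"white-blue"`,
#'   `"blue-red"`, `"heat"`) or a vector of colors for
#'   [grDevices::colorRamp()].
#' @param log apply `log1p` to the raw values first.
#' @param totals list with `background` and `dataset` totals (needed for
#'   `"relative"`; defaults to the sums over `children`).
#' @return data.frame: key, value (raw), norm (0-1), color (hex).
#' @export
computeColors <- function(children, mode = c("dataset", "background",
                                             "relative"),
                          gradient = "white-red", log = FALSE,
                          totals = NULL) {
  mode <- match.arg(mode)
  bg <- children$backgroundFreq
  ds <- children$datasetFreq
  if (is.null(totals))
    totals <- list(background = sum(bg), dataset = sum(ds))
  raw <- switch(mode,
    dataset = ds,
    background = bg,
    relative = {
      dsh <- if (totals$dataset > 0) ds / totals$dataset else rep(0, length(ds))
      bgh <- if (totals$background > 0) bg / totals$background else
        rep(0, length(bg))
      r <- ifelse(bgh > 0, dsh / bgh, ifelse(dsh > 0, Inf, 0))
      r
    })
  v <- if (log) log1p(raw) else raw
  fin <- is.finite(v)
  norm <- rep(0.5, length(v))
  if (any(fin)) {
    rng <- range(v[fin])
    if (diff(rng) > 0) norm[fin] <- (v[fin] - rng[1]) / diff(rng)
  }
  norm[!fin] <- 1  # dataset-only scaffolds: maximally enriched
  colf <- .gradientFun(gradient)
  data.frame(key = children$key, value = raw, norm = norm,
             color = colf(norm), stringsAsFactors = FALSE, row.names = NULL)
}

#' Treemap layout of a scaffold's children
#'
#' Combines [hierarchyChildren()], [computeSizes()], [squarify()] and
#' [computeColors()] into a positioned [TreemapLayout-class] for one node of
#' the hierarchy.
#'
#' @param h a [ScaffoldHierarchy-class].
#' @param level,key the parent node (defaults to the root).
#' @param sizeMode,logSize see [computeSizes()].
#' @param colorMode,logColor,gradient see [computeColors()].
#' @param rect parent rectangle, `c(x, y, w, h)`.
#' @return a [TreemapLayout-class]; empty (zero cells) when no child has a
#'   positive size.
#' @export
treemapLayout <- function(h, level = 0L, key = ROOT_KEY,
                          sizeMode = c("background", "dataset"),
                          logSize = FALSE,
                          colorMode = c("dataset", "background", "relative"),
                          logColor = FALSE, gradient = "white-red",
                          rect = c(0, 0, 1000, 618)) {
  sizeMode <- match.arg(sizeMode)
  colorMode <- match.arg(colorMode)
  children <- hierarchyChildren(h, level, key)
  wt <- computeSizes(children, sizeMode, logSize)
  cells <- data.frame(key = character(), x = numeric(), y = numeric(),
                      w = numeric(), h = numeric(), size = numeric(),
                      colorValue = numeric(), color = character(),
                      stringsAsFactors = FALSE)
  if (length(wt)) {
    rc <- squarify(unname(wt), rect)
    kept <- children[match(names(wt), children$key), , drop = FALSE]
    col <- computeColors(kept, colorMode, gradient, logColor,
                         totals = list(background = h@moleculeCount,
                                       dataset = h@datasetCount))
    cells <- data.frame(key = names(wt), rc, size = unname(wt),
                        colorValue = col$value, color = col$color,
                        stringsAsFactors = FALSE)
  }
  new("TreemapLayout", parent = as.numeric(rect), cells = cells,
      level = as.integer(level + 1L))
}
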