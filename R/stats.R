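# Diversity statistics over a scaffold hierarchy: branching bins,
# child-count percentiles, top-k frequency/coverage.

.BIN_EDGES <- c(0, 100, 400, 1600, Inf)
.BIN_LABELS <- c("1-100", "101-400", "401-1600", ">1600")

#' Branching-factor bins
#'
#' For each level 0-7, counts scaffolds by their number of children in four
#' bins: optimal (1-100), good (101-400), large (401-1600) and excessive
#' (>1600). The bin edges come from square display grids (100 cells in a
#' 10x10 grid, 400 in 20x20, 1600 in 40x40). Scaffolds without children are
#' excluded (level-8 nodes have none by construction).
#'
#' @param h a [ScaffoldHierarchy-class].
#' @return data.frame with columns level, bin, count, pct (percent of the
#'   level's scaffolds with >= 1 child).
#' @export
branchingBins <- function(h) {
  stopifnot(is(h, "ScaffoldHierarchy"))
  nd <- h@nodes[h@nodes$level <= 7L & h@nodes$childCount >= 1L, , drop = FALSE]
  out <- do.call(rbind, lapply(sort(unique(nd$level)), function(lev) {
    cc <- nd$childCount[nd$level == lev]
    bin <- cut(cc, breaks = .BIN_EDGES, labels = .BIN_LABELS)
    tab <- table(bin)
    data.frame(level = lev, bin = factor(.BIN_LABELS, levels = .BIN_LABELS),
               count = as.integer(tab[.BIN_LABELS]),
               pct = round(100 * as.integer(tab[.BIN_LABELS]) / length(cc), 2),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# nearest-rank percentile: the smallest observed value with at least p% of
# the sample at or below it (P0 is the minimum)
.nearestRank <- function(x, p) {
  x <- sort(x)
  idx <- pmax(1L, ceiling(p / 100 * length(x)))
  x[idx]
}

.PCTL_POINTS <- c(0, 10, 25, 50, 75, 90, 95, 99, 100)

#' Children-per-scaffold percentiles
#'
#' Nearest-rank percentiles (P0, P10, P25, P50, P75, P90, P95, P99, P100)
#' and the arithmetic mean of the per-scaffold child counts, for each level
#' 0-7. Nearest-rank never fabricates unobserved child counts; a level with
#' a single scaffold (always level 0, the root) has all statistics equal to
#' its child count. Levels without scaffolds are absent from the result.
#'
#' @param h a [ScaffoldHierarchy-class].
#' @return data.frame: level, P0..P100, mean.
#' @export
childrenPercentiles <- function(h) {
  stopifnot(is(h, "ScaffoldHierarchy"))
  nd <- h@nodes[h@nodes$level <= 7L & h@nodes$childCount >= 1L, , drop = FALSE]
  out <- do.call(rbind, lapply(sort(unique(nd$level)), function(lev) {
    cc <- nd$childCount[nd$level == lev]
    q <- .nearestRank(cc, .PCTL_POINTS)
    df <- data.frame(level = lev, t(q), mean = round(mean(cc), 2))
    names(df)[2:10] <- paste0("P", .PCTL_POINTS)
    df
  }))
  if (is.null(out))
    out <- stats::setNames(data.frame(matrix(numeric(), 0, 11)),
                           c("level", paste0("P", .PCTL_POINTS), "mean"))
  rownames(out) <- NULL
  out
}

#' Most common scaffolds at a level
#'
#' Ranks the scaffolds of one level by background frequency (descending,
#' ties broken by lexicographic key order for deterministic output) and
#' reports each scaffold's share of the molecule count plus the cumulative
#' coverage of the top ranks.
#'
#' @param h a [ScaffoldHierarchy-class].
#' @param level hierarchy level (1-8).
#' @param k how many scaffolds to return; a `k` larger than the level
#'   returns the whole level (whose coverage is 100%).
#' @param mode rank by `"background"` (default) or `"dataset"` frequency.
#' @return data.frame: rank, key, freq, pct, coverage (cumulative percent).
#' @export
topScaffolds <- function(h, level, k = 10L, mode = c("background", "dataset")) {
  stopifnot(is(h, "ScaffoldHierarchy"), level >= 1L, level <= 8L, k >= 1L)
  mode <- match.arg(mode)
  nd <- h@nodes[h@nodes$level == level, , drop = FALSE]
  freq <- if (mode == "background") nd$backgroundFreq else nd$datasetFreq
  total <- if (mode == "background") h@moleculeCount else h@datasetCount
  ord <- order(-freq, nd$key)
  keep <- utils::head(ord, k)
  pct <- 100 * freq[keep] / total
  data.frame(rank = seq_along(keep), key = nd$key[keep], freq = freq[keep],
             pct = pct, coverage = cumsum(pct), stringsAsFactors = FALSE,
             row.names = NULL)
}
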