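# Independent oracles used by the tests. These deliberately avoid the
# package's own algorithms: contraction is done on adjacency matrices in
# random order, ring perception by exhaustive cycle enumeration, framework
# extraction by a betweenness argument, and the squarified layout by a
# direct transcription of the published recursive pseudocode.

# ---- graph scaffolding -----------------------------------------------------

edgesToAdj <- function(n, a, b) {
  A <- matrix(FALSE, n, n)
  A[cbind(a, b)] <- TRUE; A[cbind(b, a)] <- TRUE
  A
}

adjToGraph <- function(A, level) {
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  scaffoldmap:::.abstractGraph(level, nrow(A), idx[, 1], idx[, 2])
}

graphToAdj <- function(s) {
  b <- bonds(s)
  edgesToAdj(nrow(atoms(s)), b$a1, b$a2)
}

randomGraph <- function(maxV = 20L) {
  n <- sample(4:maxV, 1)
  p <- stats::runif(1, 1.2 / n, 3 / n)
  A <- matrix(stats::runif(n * n) < p, n, n)
  A <- A | t(A)
  diag(A) <- FALSE
  # add a random cycle so there is usually ring structure
  cyc <- sample(n, sample(3:min(6, n), 1))
  A[cbind(cyc, c(cyc[-1], cyc[1]))] <- TRUE
  A[cbind(c(cyc[-1], cyc[1]), cyc)] <- TRUE
  A
}

isIsomorphic <- function(s1, s2) {
  g1 <- scaffoldmap:::.graphOf(nrow(atoms(s1)), bonds(s1))
  g2 <- scaffoldmap:::.graphOf(nrow(atoms(s2)), bonds(s2))
  igraph::vcount(g1) == igraph::vcount(g2) &&
    igraph::ecount(g1) == igraph::ecount(g2) &&
    igraph::isomorphic(g1, g2, method = "vf2")
}

# ---- cycle machinery (independent of the package's BFS approach) -----------

# TRUE for each vertex that lies on some cycle: edge (u,v) is a cycle edge
# iff u and v stay connected after its removal (checked by plain BFS)
oracleRingVertices <- function(A) {
  n <- nrow(A)
  onCycle <- logical(n)
  reach <- function(B, from, to) {
    seen <- logical(n); queue <- from; seen[from] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == to) return(TRUE)
      nb <- which(B[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    FALSE
  }
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    u <- idx[k, 1]; v <- idx[k, 2]
    B <- A; B[u, v] <- B[v, u] <- FALSE
    if (reach(B, u, v)) onCycle[c(u, v)] <- TRUE
  }
  onCycle
}

# brute-force level-5 contraction: remove degree-2 non-ring vertices in
# random order, reconnecting their neighbors
oracleContractLinkers <- function(A) {
  ring <- oracleRingVertices(A)
  repeat {
    deg <- rowSums(A)
    cand <- which(deg == 2 & !ring)
    if (!length(cand)) break
    v <- if (length(cand) == 1) cand else sample(cand, 1)
    nb <- which(A[v, ])
    A[v, ] <- FALSE; A[, v] <- FALSE
    A[nb[1], nb[2]] <- A[nb[2], nb[1]] <- TRUE
    keep <- setdiff(seq_len(nrow(A)), v)
    A <- A[keep, keep, drop = FALSE]
    ring <- ring[keep]
  }
  A
}

# brute-force level-4 contraction: edge-merge degree-2 vertices with
# non-adjacent neighbors, random order, until fixed point
oracleContractTopology <- function(A) {
  repeat {
    deg <- rowSums(A)
    cand <- which(deg == 2)
    cand <- Filter(function(v) {
      nb <- which(A[v, ])
      length(nb) == 2 && !A[nb[1], nb[2]]
    }, cand)
    if (!length(cand)) break
    v <- if (length(cand) == 1) cand[[1]] else sample(cand, 1)[[1]]
    nb <- which(A[v, ])
    A[v, ] <- FALSE; A[, v] <- FALSE
    A[nb[1], nb[2]] <- A[nb[2], nb[1]] <- TRUE
    keep <- setdiff(seq_len(nrow(A)), v)
    A <- A[keep, keep, drop = FALSE]
  }
  A
}

# exhaustive enumeration of all simple cycles (vertex sets <= n), as sorted
# edge-signature strings plus lengths
oracleAllCycles <- function(A) {
  n <- nrow(A)
  found <- new.env()
  dfs <- function(start, path) {
    v <- path[length(path)]
    for (w in which(A[v, ])) {
      if (w == start && length(path) >= 3) {
        nxt <- c(path[-1], path[1])
        sig <- paste(sort(paste0(pmin(path, nxt), "-", pmax(path, nxt))),
                     collapse = ";")
        found[[sig]] <- path
      } else if (w > start && !(w %in% path)) {
        dfs(start, c(path, w))
      }
    }
  }
  for (s in seq_len(n)) dfs(s, s)
  as.list(found)
}

# CSSR by exhaustive enumeration: keep every cycle that is as short as the
# shortest cycle through at least one of its edges
oracleCSSR <- function(A) {
  cycles <- oracleAllCycles(A)
  if (!length(cycles)) return(list())
  lens <- vapply(cycles, length, 0L)
  edgeMin <- new.env()
  for (k in seq_along(cycles)) {
    p <- cycles[[k]]
    sigs <- paste0(pmin(p, c(p[-1], p[1])), "-", pmax(p, c(p[-1], p[1])))
    for (s in sigs) {
      cur <- edgeMin[[s]]
      if (is.null(cur) || lens[k] < cur) edgeMin[[s]] <- lens[k]
    }
  }
  keep <- vapply(seq_along(cycles), function(k) {
    p <- cycles[[k]]
    sigs <- paste0(pmin(p, c(p[-1], p[1])), "-", pmax(p, c(p[-1], p[1])))
    any(vapply(sigs, function(s) edgeMin[[s]] == lens[k], TRUE))
  }, TRUE)
  cycles[keep]
}

# framework oracle: ring vertices plus every vertex whose removal separates
# two ring vertices (i.e. the vertex lies between ring systems)
oracleFrameworkAtoms <- function(A) {
  n <- nrow(A)
  ring <- oracleRingVertices(A)
  keep <- ring
  comps <- function(B) {
    lab <- rep(0L, n); cl <- 0L
    for (s in seq_len(n)) {
      if (lab[s] > 0L) next
      cl <- cl + 1L
      queue <- s; lab[s] <- cl
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(B[v, ] & lab == 0L)
        lab[nb] <- cl
        queue <- c(queue, nb)
      }
    }
    lab
  }
  for (v in which(!ring)) {
    B <- A; B[v, ] <- FALSE; B[, v] <- FALSE
    lab <- comps(B)
    ringComps <- unique(lab[ring & seq_len(n) != v])
    if (length(ringComps) >= 2) keep[v] <- TRUE
  }
  which(keep)
}

# ---- treemap oracles --------------------------------------------------------

# direct transcription of the published recursive squarified algorithm
oracleSquarify <- function(weights, rect) {
  areas <- sort(weights, decreasing = TRUE) * rect[3] * rect[4] / sum(weights)
  out <- list()
  x <- rect[1]; y <- rect[2]; w <- rect[3]; h <- rect[4]

  worst <- function(row, side) {
    s <- sum(row); rmax <- max(row); rmin <- min(row)
    max(side^2 * rmax / s^2, s^2 / (side^2 * rmin))
  }
  layoutrow <- function(row) {
    side <- min(w, h)
    thick <- sum(row) / side
    off <- 0
    for (r in row) {
      len <- r / thick
      if (w >= h) out[[length(out) + 1L]] <<- c(x, y + off, thick, len)
      else out[[length(out) + 1L]] <<- c(x + off, y, len, thick)
      off <- off + len
    }
    if (w >= h) { x <<- x + thick; w <<- w - thick }
    else { y <<- y + thick; h <<- h - thick }
  }
  squarifyRec <- function(children, row) {
    if (!length(children)) { if (length(row)) layoutrow(row); return() }
    c1 <- children[1]
    side <- min(w, h)
    if (!length(row) || worst(c(row, c1), side) <= worst(row, side)) {
      squarifyRec(children[-1], c(row, c1))
    } else {
      layoutrow(row)
      squarifyRec(children, numeric(0))
    }
  }
  squarifyRec(areas, numeric(0))
  do.call(rbind, out)  # rows in non-increasing weight order
}

# slice-and-dice along the longer side, for the quality comparison
sliceAndDice <- function(weights, rect) {
  tot <- sum(weights)
  x <- rect[1]; y <- rect[2]; w <- rect[3]; h <- rect[4]
  out <- matrix(0, length(weights), 4)
  off <- 0
  for (i in seq_along(weights)) {
    f <- weights[i] / tot
    if (w >= h) out[i, ] <- c(x + off * w, y, f * w, h)
    else out[i, ] <- c(x, y + off * h, w, f * h)
    off <- off + f
  }
  out
}

worstAspect <- function(rects) {
  max(pmax(rects[, 3] / rects[, 4], rects[, 4] / rects[, 3]))
}

# nearest-rank percentile oracle by explicit counting
oraclePercentile <- function(x, p) {
  xs <- sort(x)
  if (p == 0) return(xs[1])
  for (v in xs) if (sum(xs <= v) >= p / 100 * length(xs)) return(v)
  xs[length(xs)]
}
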