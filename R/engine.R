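# The eight level transformations: molecule -> framework -> ... -> ring count.

.graphOf <- function(n, bonds) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0)
    g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  g
}

.degreesOf <- function(n, bonds) tabulate(c(bonds$a1, bonds$a2), nbins = n)

# logical mask over atoms: TRUE when the atom lies on a cycle (incident to a
# non-bridge edge)
.ringVertexMask <- function(n, bonds) {
  mask <- logical(n)
  if (nrow(bonds) == 0) return(mask)
  g <- .graphOf(n, bonds)
  br <- igraph::bridges(g)
  ringE <- setdiff(seq_len(nrow(bonds)), as.integer(br))
  mask[c(bonds$a1[ringE], bonds$a2[ringE])] <- TRUE
  mask
}

# drop atoms by index, compacting bond indices
.dropAtoms <- function(atoms, bonds, drop) {
  if (!length(drop)) return(list(atoms = atoms, bonds = bonds))
  keep <- !(seq_len(nrow(atoms)) %in% drop)
  remap <- cumsum(keep)
  kb <- !(bonds$a1 %in% drop) & !(bonds$a2 %in% drop)
  bonds <- bonds[kb, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  list(atoms = atoms, bonds = bonds)
}

#' Extract the molecular framework (level 8)
#'
#' Deletes side chains by iteratively removing terminal (degree <= 1) heavy
#' atoms until none remain, leaving the union of ring systems and the linker
#' atoms connecting them. Stereo marks that survive the deletion are kept
#' (dangling stereo descriptors are re-perceived and dropped when the
#' canonical key is generated). Acyclic molecules yield the empty scaffold.
#'
#' @param m a [Molecule-class]; standardized automatically if needed.
#' @return a level-8 [ScaffoldGraph-class].
#' @seealso [scaffoldChain()] for the full level 8..1 sequence.
#' @export
murckoFramework <- function(m) {
  if (!m@standardized) m <- standardizeMolecule(m)
  a <- m@atoms; b <- m@bonds
  repeat {
    deg <- .degreesOf(nrow(a), b)
    drop <- which(deg <= 1L)
    if (!length(drop) || nrow(a) == 0) break
    res <- .dropAtoms(a, b, drop)
    a <- res$atoms; b <- res$bonds
  }
  new("ScaffoldGraph", level = 8L, atoms = a, bonds = b)
}

#' Discard stereo information (level 7)
#'
#' Level 7 equals level 8 with all stereo descriptors removed: atom
#' parities, wedge marks and the coordinates that encode double-bond
#' geometry are cleared.
#'
#' @param s a level-8 [ScaffoldGraph-class].
#' @return a level-7 [ScaffoldGraph-class] with identical atom/bond counts.
#' @export
clearStereo <- function(s) {
  stopifnot(is(s, "ScaffoldGraph"))
  a <- s@atoms; b <- s@bonds
  if (nrow(a) > 0) { a$parity <- 0L; a$x <- 0; a$y <- 0; a$z <- 0 }
  if (nrow(b) > 0) b$wedge <- 0L
  new("ScaffoldGraph", level = 7L, atoms = a, bonds = b)
}

#' Reduce to the graph framework (level 6)
#'
#' Replaces every element by carbon and every bond by a single bond: only
#' heavy-atom connectivity remains (the classic graph framework / Murcko
#' scaffold). Vertex count equals the framework's heavy atom count.
#'
#' @param s a level-7 [ScaffoldGraph-class].
#' @return a level-6 [ScaffoldGraph-class].
#' @export
graphFramework <- function(s) {
  stopifnot(is(s, "ScaffoldGraph"))
  a <- s@atoms; b <- s@bonds
  if (nrow(a) > 0) {
    a$elem <- "C"; a$charge <- 0L; a$aromatic <- FALSE
    a$parity <- 0L; a$x <- 0; a$y <- 0; a$z <- 0
  }
  if (nrow(b) > 0) { b$order <- 1L; b$aromatic <- FALSE; b$wedge <- 0L }
  new("ScaffoldGraph", level = 6L, atoms = a, bonds = b)
}

#' Contract linker paths (level 5)
#'
#' Removes superfluous linker atoms: every maximal path of degree-2
#' non-ring vertices between two anchors is replaced by a single edge.
#' Branching linker atoms (degree >= 3) and ring atoms are untouched.
#'
#' @param s a level-6 [ScaffoldGraph-class].
#' @return a level-5 [ScaffoldGraph-class].
#' @export
pruneLinkers <- function(s) {
  stopifnot(is(s, "ScaffoldGraph"))
  a <- s@atoms; b <- s@bonds
  if (nrow(a) > 0) {
    ringV <- .ringVertexMask(nrow(a), b)
    repeat {
      deg <- .degreesOf(nrow(a), b)
      cand <- which(deg == 2L & !ringV)
      if (!length(cand)) break
      v <- cand[1]
      inc <- which(b$a1 == v | b$a2 == v)
      nb <- setdiff(c(b$a1[inc], b$a2[inc]), v)
      if (length(nb) != 2L)
        stop("parallel linker edges encountered; graph is not a valid level-6 scaffold")
      if (any((b$a1 == nb[1] & b$a2 == nb[2]) | (b$a1 == nb[2] & b$a2 == nb[1])))
        stop("linker contraction would duplicate an edge; multiple linker paths between the same anchors cannot occur at level 5")
      b <- b[-inc, , drop = FALSE]
      b <- rbind(b, data.frame(a1 = nb[1], a2 = nb[2], order = 1L,
                               wedge = 0L, aromatic = FALSE))
      res <- .dropAtoms(a, b, v)
      a <- res$atoms; b <- res$bonds
      ringV <- ringV[-v]
    }
  }
  new("ScaffoldGraph", level = 5L, atoms = a, bonds = b)
}

#' Contract to the ring topology (level 4, Oprea scaffold)
#'
#' Performs edge merging on the remaining degree-2 vertices until a fixed
#' point: a degree-2 vertex is removed and its two neighbors joined, except
#' when the neighbors are already adjacent (a triangle, where merging would
#' lose the cycle). The result is the minimum cycle topological
#' representation of the framework.
#'
#' @param s a level-5 [ScaffoldGraph-class].
#' @return a level-4 [ScaffoldGraph-class] in which every remaining degree-2
#'   vertex lies in a triangle.
#' @export
opreaScaffold <- function(s) {
  stopifnot(is(s, "ScaffoldGraph"))
  a <- s@atoms; b <- s@bonds
  if (nrow(a) > 0) {
    repeat {
      deg <- .degreesOf(nrow(a), b)
      cand <- which(deg == 2L)
      done <- TRUE
      for (v in cand) {
        inc <- which(b$a1 == v | b$a2 == v)
        nb <- setdiff(c(b$a1[inc], b$a2[inc]), v)
        if (length(nb) != 2L) next  # two parallel edges to one neighbor
        adj <- any((b$a1 == nb[1] & b$a2 == nb[2]) |
                   (b$a1 == nb[2] & b$a2 == nb[1]))
        if (adj) next  # triangle exception
        b <- b[-inc, , drop = FALSE]
        b <- rbind(b, data.frame(a1 = nb[1], a2 = nb[2], order = 1L,
                                 wedge = 0L, aromatic = FALSE))
        res <- .dropAtoms(a, b, v)
        a <- res$atoms; b <- res$bonds
        done <- FALSE
        break
      }
      if (done) break
    }
  }
  new("ScaffoldGraph", level = 4L, atoms = a, bonds = b)
}

#' Complete set of smallest rings (CSSR)
#'
#' Ring perception used for levels 1-3. The set contains, for every edge on
#' a cycle, all shortest cycles through that edge (the symmetry-complete
#' variant of SSSR: rings that are as small as any SSSR ring they could
#' replace are all kept, so e.g. the cube graph yields 6 four-membered
#' rings where SSSR reports 5). If the collected rings do not span the
#' graph's cycle space, shortest fundamental cycles are added until they do;
#' such pathological cage graphs are implementation-defined territory.
#'
#' @param s a [ScaffoldGraph-class] (any level with atom vertices).
#' @return list of rings; each ring is a list with `vertices` (cycle-ordered
#'   integer vector) and `edges` (character signatures `"i-j"`, i < j).
#' @export
cssrRings <- function(s) {
  stopifnot(is(s, "ScaffoldGraph"))
  .cssr(nrow(s@atoms), s@bonds)
}

.edgeSig <- function(i, j) paste0(pmin(i, j), "-", pmax(i, j))

.ringFromPath <- function(p) {
  # p: cycle-ordered vertices
  nxt <- c(p[-1], p[1])
  list(vertices = p, edges = sort(.edgeSig(p, nxt)))
}

.cssr <- function(n, bonds) {
  m <- nrow(bonds)
  if (n == 0 || m == 0) return(list())
  g <- .graphOf(n, bonds)
  comps <- igraph::components(g)$no
  cyclomatic <- m - n + comps
  if (cyclomatic <= 0) return(list())
  br <- as.integer(igraph::bridges(g))
  ringE <- setdiff(seq_len(m), br)
  rings <- list(); sigs <- character(0)
  for (e in ringE) {
    u <- bonds$a1[e]; v <- bonds$a2[e]
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::all_shortest_paths(g2, from = u, to = v))
    paths <- sp$vpaths
    if (is.null(paths)) paths <- sp$res
    for (p in paths) {
      ring <- .ringFromPath(as.integer(p))
      sig <- paste(ring$edges, collapse = ";")
      if (!(sig %in% sigs)) { sigs <- c(sigs, sig); rings[[length(rings) + 1L]] <- ring }
    }
  }
  # guarantee the set spans the cycle space
  allSigs <- .edgeSig(bonds$a1, bonds$a2)
  basis <- .gf2Basis(lapply(rings, function(r) match(r$edges, allSigs)), m)
  if (basis$rank < cyclomatic) {
    fund <- .fundamentalCycles(g, bonds)
    fund <- fund[order(vapply(fund, function(r) length(r$vertices), 0L))]
    for (ring in fund) {
      vec <- match(ring$edges, allSigs)
      if (.gf2Add(basis, vec)) {
        sig <- paste(ring$edges, collapse = ";")
        if (!(sig %in% sigs)) { sigs <- c(sigs, sig); rings[[length(rings) + 1L]] <- ring }
        if (basis$rank >= cyclomatic) break
      }
    }
  }
  rings
}

# GF(2) linear algebra over edge-index sets, kept in a mutable environment
.gf2Basis <- function(vecs, m) {
  env <- new.env()
  env$pivots <- list()  # reduced vectors, named by pivot index
  env$rank <- 0L
  for (v in vecs) .gf2Add(env, v)
  env
}

.gf2Add <- function(env, vec) {
  vec <- sort(unique(vec))
  for (p in names(env$pivots)) {
    pv <- env$pivots[[p]]
    if (pv[1] %in% vec) vec <- sort(setdiff(union(vec, pv), intersect(vec, pv)))
    if (!length(vec)) return(FALSE)
  }
  env$pivots[[as.character(vec[1])]] <- vec
  env$rank <- env$rank + 1L
  TRUE
}

.fundamentalCycles <- function(g, bonds) {
  tree <- igraph::mst(g)
  treeSig <- .edgeSig(igraph::ends(tree, igraph::E(tree))[, 1],
                      igraph::ends(tree, igraph::E(tree))[, 2])
  out <- list()
  for (e in seq_len(nrow(bonds))) {
    sig <- .edgeSig(bonds$a1[e], bonds$a2[e])
    if (sig %in% treeSig) next
    sp <- igraph::shortest_paths(tree, from = bonds$a1[e], to = bonds$a2[e])
    p <- as.integer(sp$vpath[[1]])
    if (length(p) < 2) next
    out[[length(out) + 1L]] <- .ringFromPath(p)
  }
  out
}

#' Ring-connectivity scaffold (level 3)
#'
#' Builds the graph whose vertices are the CSSR rings of the level-4
#' scaffold. Two rings are joined by a strong edge when they share a graph
#' edge (fused, rigid) and by a weak edge when they share a vertex (spiro)
#' or touch the same connected component of the linker-edge subgraph (ring
#' edges are excluded from the path search, so e.g. the terminal rings of a
#' linear three-ring fusion stay unconnected). Strong wins when both rules
#' apply; at most one edge per ring pair.
#'
#' @param s a level-4 [ScaffoldGraph-class].
#' @return a level-3 [ScaffoldGraph-class]: wildcard vertices, bond order 2
#'   for strong and 1 for weak connectivity.
#' @export
ringConnectivity <- function(s) {
  stopifnot(is(s, "ScaffoldGraph"))
  rings <- cssrRings(s)
  nR <- length(rings)
  a <- .emptyAtoms()
  b <- .emptyBonds()
  if (nR > 0) {
    a <- data.frame(elem = rep("*", nR), x = 0, y = 0, z = 0, charge = 0L,
                    isotope = 0L, radical = 0L, parity = 0L, aromatic = FALSE,
                    stringsAsFactors = FALSE)
    strength <- matrix(0L, nR, nR)
    # strong: shared edge; weak: shared vertex
    for (i in seq_len(nR - 1L)) for (j in (i + 1L):nR) {
      if (length(intersect(rings[[i]]$edges, rings[[j]]$edges)) > 0)
        strength[i, j] <- 2L
      else if (length(intersect(rings[[i]]$vertices, rings[[j]]$vertices)) > 0)
        strength[i, j] <- max(strength[i, j], 1L)
    }
    # weak: joined through the linker-edge subgraph
    if (nR > 1) {
      allRingEdges <- unique(unlist(lapply(rings, `[[`, "edges")))
      bs <- .edgeSig(s@bonds$a1, s@bonds$a2)
      linker <- which(!(bs %in% allRingEdges))
      if (length(linker)) {
        lb <- s@bonds[linker, , drop = FALSE]
        g <- .graphOf(nrow(s@atoms), lb)
        memb <- igraph::components(g)$membership
        touched <- vapply(seq_len(igraph::vcount(g)), function(v)
          sum(lb$a1 == v | lb$a2 == v) > 0, TRUE)
        for (comp in unique(memb[touched])) {
          inComp <- which(memb == comp & touched)
          att <- which(vapply(rings, function(r)
            length(intersect(r$vertices, inComp)) > 0, TRUE))
          if (length(att) > 1)
            for (i in att) for (j in att) if (i < j)
              strength[i, j] <- max(strength[i, j], 1L)
        }
      }
    }
    idx <- which(strength > 0, arr.ind = TRUE)
    if (nrow(idx) > 0)
      b <- data.frame(a1 = idx[, 1], a2 = idx[, 2],
                      order = strength[idx], wedge = 0L, aromatic = FALSE,
                      stringsAsFactors = FALSE)
  }
  new("ScaffoldGraph", level = 3L, atoms = a, bonds = b)
}

#' Collapse connectivity strength (level 2)
#'
#' Takes out the strong/weak distinction of the level-3 scaffold: all edges
#' become plain (weak) connections, leaving only which rings are connected.
#'
#' @param s a level-3 [ScaffoldGraph-class].
#' @return a level-2 [ScaffoldGraph-class].
#' @export
collapseConnectivity <- function(s) {
  stopifnot(is(s, "ScaffoldGraph"))
  b <- s@bonds
  if (nrow(b) > 0) b$order <- 1L
  new("ScaffoldGraph", level = 2L, atoms = s@atoms, bonds = b)
}

#' Ring count (level 1)
#'
#' The number of vertices of the ring-connectivity scaffold, i.e. the CSSR
#' ring count of the framework. Acyclic molecules have ring count 0.
#'
#' @param s a level-2 (or level-3) [ScaffoldGraph-class].
#' @return integer(1).
#' @export
ringCount <- function(s) {
  stopifnot(is(s, "ScaffoldGraph"), s@level %in% c(2L, 3L))
  nrow(s@atoms)
}
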