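#' @import methods
#' @importFrom data.table data.table as.data.table setDT setkey := .N fread fwrite rbindlist setorder
NULL

# Root sentinel key of every hierarchy (level 0) and the shared key of the
# empty scaffold (acyclic molecules, levels 2-8).
ROOT_KEY <- "ROOT"
EMPTY_KEY <- "-"

.emptyAtoms <- function() {
  data.frame(elem = character(), x = numeric(), y = numeric(), z = numeric(),
             charge = integer(), isotope = integer(), radical = integer(),
             parity = integer(), aromatic = logical(),
             stringsAsFactors = FALSE)
}

.emptyBonds <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = integer(),
             wedge = integer(), aromatic = logical(), stringsAsFactors = FALSE)
}

#' Molecule: a parsed chemical structure
#'
#' Holds one (possibly disconnected) chemical structure as plain atom and
#' bond tables, together with identity metadata. Atoms carry element symbol,
#' 2D/3D coordinates, formal charge, isotope label (0 = natural), radical
#' code (molfile convention, 0 = none), tetrahedral parity (molfile atom
#' parity, 0 = none) and an aromaticity flag (filled by
#' \code{\link{standardizeMolecule}}). Bonds carry 1-based atom indices, bond
#' order, wedge code (molfile bond stereo, 0 = none) and an aromaticity flag.
#'
#' Disconnected structures are kept whole; they are never reduced to a
#' largest fragment, because the hierarchy represents multi-fragment
#' compounds explicitly (e.g. the two-disconnected-rings topology).
#'
#' @slot id character(1), record identifier (file order index by default).
#' @slot name character(1), optional record name (NA when absent).
#' @slot atoms data.frame of atoms, see Description.
#' @slot bonds data.frame of bonds, see Description.
#' @slot standardized logical(1), TRUE after standardization.
#'
#' @seealso [readMolecules()], [standardizeMolecule()], [scaffoldChain()]
#' @export
setClass("Molecule",
  representation(id = "character", name = "character",
                 atoms = "data.frame", bonds = "data.frame",
                 standardized = "logical"),
  prototype(id = "1", name = NA_character_, atoms = .emptyAtoms(),
            bonds = .emptyBonds(), standardized = FALSE))

.validMoleculeTables <- function(atoms, bonds) {
  need_a <- c("elem", "x", "y", "z", "charge", "isotope", "radical",
              "parity", "aromatic")
  need_b <- c("a1", "a2", "order", "wedge", "aromatic")
  if (!all(need_a %in% names(atoms))) return("atoms table misses columns")
  if (!all(need_b %in% names(bonds))) return("bonds table misses columns")
  if (nrow(bonds) > 0) {
    idx <- c(bonds$a1, bonds$a2)
    if (any(idx < 1L) || any(idx > nrow(atoms)))
      return("bond refers to a nonexistent atom")
    if (any(bonds$a1 == bonds$a2)) return("self-bond")
  }
  TRUE
}

setValidity("Molecule", function(object) {
  .validMoleculeTables(object@atoms, object@bonds)
})

#' ScaffoldGraph: a scaffold at one hierarchy level
#'
#' The per-level scaffold objects. Levels 8 and 7 are chemical graphs
#' (elements, charges, bond orders, and, at level 8 only, stereo marks).
#' Levels 6-4 are plain all-carbon single-bond graphs; levels 3-2 are
#' ring-connectivity graphs whose vertices are CSSR rings (element tag
#' \code{"*"}) and whose bond order encodes connectivity strength (2 =
#' strong/fused, 1 = weak), following the convention of modelling strong
#' connectivity as double bonds.
#'
#' @slot level integer(1) in 1..8.
#' @slot atoms,bonds as in [Molecule-class]; empty tables denote the empty
#'   scaffold shared by all acyclic molecules.
#' @export
setClass("ScaffoldGraph",
  representation(level = "integer", atoms = "data.frame", bonds = "data.frame"),
  prototype(level = 8L, atoms = .emptyAtoms(), bonds = .emptyBonds()))

setValidity("ScaffoldGraph", function(object) {
  if (length(object@level) != 1L || object@level < 1L || object@level > 8L)
    return("level must be a single integer in 1..8")
  ok <- .validMoleculeTables(object@atoms, object@bonds)
  if (!isTRUE(ok)) return(ok)
  if (object@level <= 6L && nrow(object@atoms) > 0) {
    if (any(object@atoms$parity != 0L) || any(object@bonds$wedge != 0L))
      return("levels <= 6 carry no stereo marks")
    if (object@level <= 3L && !all(object@atoms$elem == "*"))
      return("levels 2-3 use wildcard ring vertices")
  }
  TRUE
})

#' ScaffoldHierarchy: the rooted background/annotated scaffold tree
#'
#' A rooted tree with a single virtual root at level 0, eight scaffold
#' levels (1-8) and molecules conceptually as leaves at level 9. Each node
#' stores its canonical key, its parent's key (one level up), the number of
#' molecules carrying the scaffold in the background set and (after
#' annotation) in the user dataset, and its child count.
#'
#' @slot nodes data.frame with columns level, key, parent, backgroundFreq,
#'   datasetFreq, childCount.
#' @slot moleculeCount numeric(1), background molecules inserted.
#' @slot datasetCount numeric(1), user molecules annotated (0 before
#'   annotation).
#' @seealso [buildHierarchy()], [annotateHierarchy()], [topScaffolds()]
#' @export
setClass("ScaffoldHierarchy",
  representation(nodes = "data.frame", moleculeCount = "numeric",
                 datasetCount = "numeric"),
  prototype(nodes = data.frame(level = 0L, key = ROOT_KEY,
                               parent = NA_character_, backgroundFreq = 0,
                               datasetFreq = 0, childCount = 0L,
                               stringsAsFactors = FALSE),
            moleculeCount = 0, datasetCount = 0))

setValidity("ScaffoldHierarchy", function(object) {
  nd <- object@nodes
  need <- c("level", "key", "parent", "backgroundFreq", "datasetFreq",
            "childCount")
  if (!all(need %in% names(nd))) return("nodes table misses columns")
  if (sum(is.na(nd$parent)) != 1L) return("exactly one root node expected")
  rootlev <- nd$level[is.na(nd$parent)]
  if (anyDuplicated(paste(nd$level, nd$key))) return("duplicate (level, key)")
  # every non-root node's parent exists one level up
  up <- paste(nd$level - 1L, nd$parent)
  known <- paste(nd$level, nd$key)
  bad <- !is.na(nd$parent) & !(up %in% known)
  if (any(bad)) return("node with missing parent (tree property violated)")
  # per-level conservation of frequencies
  for (lev in sort(unique(nd$level))) {
    tot <- sum(nd$backgroundFreq[nd$level == lev])
    ref <- sum(nd$backgroundFreq[nd$level == rootlev])
    if (tot != ref) return(sprintf("level %d frequency total %s != %s", lev,
                                   tot, ref))
  }
  TRUE
})

#' TreemapLayout: positioned cells for one scaffold's children
#'
#' The result of squarified layout over the children of a hierarchy node.
#' Coordinates are in the parent rectangle's space (origin top-left, y
#' grows downwards). Cells tile the parent: pairwise interior-disjoint and
#' summing to the parent's area.
#'
#' @slot parent numeric(4): x, y, width, height of the parent rectangle.
#' @slot cells data.frame with columns key, x, y, w, h, size, colorValue,
#'   color.
#' @slot level integer(1): hierarchy level of the cells (parent level + 1).
#' @export
setClass("TreemapLayout",
  representation(parent = "numeric", cells = "data.frame", level = "integer"),
  prototype(parent = c(0, 0, 1, 1),
            cells = data.frame(key = character(), x = numeric(),
                               y = numeric(), w = numeric(), h = numeric(),
                               size = numeric(), colorValue = numeric(),
                               color = character(), stringsAsFactors = FALSE),
            level = 1L))

setValidity("TreemapLayout", function(object) {
  if (length(object@parent) != 4 || any(object@parent[3:4] <= 0))
    return("parent must be c(x, y, w, h) with positive extent")
  cl <- object@cells
  if (nrow(cl) > 0) {
    if (any(cl$w <= 0) || any(cl$h <= 0)) return("cells must have positive extent")
    area <- sum(cl$w * cl$h)
    parea <- object@parent[3] * object@parent[4]
    if (abs(area - parea) > 1e-6 * parea)
      return("cells do not tile the parent rectangle")
  }
  TRUE
})
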