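#' Accessors for scaffoldmap classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a [Molecule-class], [ScaffoldGraph-class],
#'   [ScaffoldHierarchy-class] or [TreemapLayout-class] object.
#' @return `molId`/`molName` a character scalar; `atoms`/`bonds` the
#'   corresponding data.frame; `scaffoldLevel` an integer; `hierarchyNodes`
#'   the node table; `moleculeCount`/`datasetCount` numeric scalars;
#'   `layoutCells` the cell table of a layout.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("molId", function(x) standardGeneric("molId"))
#' @rdname accessors
#' @export
setGeneric("molName", function(x) standardGeneric("molName"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setGeneric("scaffoldLevel", function(x) standardGeneric("scaffoldLevel"))
#' @rdname accessors
#' @export
setGeneric("hierarchyNodes", function(x) standardGeneric("hierarchyNodes"))
#' @rdname accessors
#' @export
setGeneric("moleculeCount", function(x) standardGeneric("moleculeCount"))
#' @rdname accessors
#' @export
setGeneric("datasetCount", function(x) standardGeneric("datasetCount"))
#' @rdname accessors
#' @export
setGeneric("layoutCells", function(x) standardGeneric("layoutCells"))

#' @rdname accessors
setMethod("molId", "Molecule", function(x) x@id)
#' @rdname accessors
setMethod("molName", "Molecule", function(x) x@name)
#' @rdname accessors
setMethod("atoms", "Molecule", function(x) x@atoms)
#' @rdname accessors
setMethod("bonds", "Molecule", function(x) x@bonds)
#' @rdname accessors
setMethod("atoms", "ScaffoldGraph", function(x) x@atoms)
#' @rdname accessors
setMethod("bonds", "ScaffoldGraph", function(x) x@bonds)
#' @rdname accessors
setMethod("scaffoldLevel", "ScaffoldGraph", function(x) x@level)
#' @rdname accessors
setMethod("hierarchyNodes", "ScaffoldHierarchy", function(x) x@nodes)
#' @rdname accessors
setMethod("moleculeCount", "ScaffoldHierarchy", function(x) x@moleculeCount)
#' @rdname accessors
setMethod("datasetCount", "ScaffoldHierarchy", function(x) x@datasetCount)
#' @rdname accessors
setMethod("layoutCells", "TreemapLayout", function(x) x@cells)

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s'%s: %d atoms, %d bonds%s%s\n",
              object@id,
              if (is.na(object@name)) "" else sprintf(" (%s)", object@name),
              nrow(object@atoms), nrow(object@bonds),
              if (object@standardized) ", standardized" else "",
              if (nrow(object@atoms) > 0 &&
                  length(unique(.componentsOf(object))) > 1)
                ", disconnected" else ""))
})

setMethod("show", "ScaffoldGraph", function(object) {
  kind <- c("ring count", "ring connectivity", "ring connectivity extended",
            "ring topology (Oprea)", "framework rings",
            "graph framework (rings with linkers)", "rings with linkers",
            "rings with linkers + stereo")[object@level]
  cat(sprintf("ScaffoldGraph level %d [%s]: %d vertices, %d edges\n",
              object@level, kind, nrow(object@atoms), nrow(object@bonds)))
})

setMethod("show", "ScaffoldHierarchy", function(object) {
  nd <- object@nodes
  cat(sprintf("ScaffoldHierarchy: %s molecules, %d scaffold nodes\n",
              format(object@moleculeCount, big.mark = ","), nrow(nd)))
  tab <- table(factor(nd$level, levels = 0:8))
  cat("  nodes per level:", paste(sprintf("L%s=%d", names(tab), as.integer(tab)),
                                  collapse = " "), "\n")
  if (object@datasetCount > 0)
    cat(sprintf("  annotated with %s dataset molecules\n",
                format(object@datasetCount, big.mark = ",")))
})

setMethod("show", "TreemapLayout", function(object) {
  cat(sprintf("TreemapLayout: %d cells (level %d) in %.6g x %.6g rectangle\n",
              nrow(object@cells), object@level, object@parent[3],
              object@parent[4]))
})
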