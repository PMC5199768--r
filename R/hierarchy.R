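# Build, merge, persist, query and annotate the rooted scaffold hierarchy.

# chains: character matrix (n x 8, columns L1..L8) -> per-node frequency table
.chainsToNodes <- function(chains, column = "backgroundFreq") {
  n <- nrow(chains)
  if (n == 0) {
    dt <- as.data.table(list(level = integer(), key = character(),
                             parent = character(), freq = numeric()))
  } else {
    long <- as.data.table(list(
      level = rep(1:8, each = n),
      key = as.vector(chains),
      parent = as.vector(cbind(ROOT_KEY, chains[, 1:7, drop = FALSE]))))
    dt <- long[, list(freq = as.numeric(.N)), by = c("level", "key", "parent")]
  }
  dup <- dt[, list(np = length(unique(parent))), by = c("level", "key")]
  if (any(dup$np > 1))
    stop("corrupted chains: one scaffold with two distinct parents")
  root <- as.data.table(list(level = 0L, key = ROOT_KEY,
                             parent = NA_character_, freq = as.numeric(n)))
  rbind(root, dt)
}

.recountChildren <- function(nodes) {
  dt <- as.data.table(nodes)
  kids <- dt[level > 0L, list(childCount = .N), by = list(level = level - 1L,
                                                          key = parent)]
  dt[, "childCount" := NULL]
  dt <- merge(dt, kids, by = c("level", "key"), all.x = TRUE)
  dt[is.na(childCount), "childCount" := 0L]
  setorder(dt, level, key)
  as.data.frame(dt)
}

.newHierarchy <- function(nodes, moleculeCount, datasetCount = 0) {
  nodes <- .recountChildren(nodes)
  new("ScaffoldHierarchy", nodes = nodes,
      moleculeCount = as.numeric(moleculeCount),
      datasetCount = as.numeric(datasetCount))
}

#' Build a scaffold hierarchy from molecules
#'
#' Inserts each molecule's scaffold chain into a rooted tree (virtual root
#' at level 0, scaffold levels 1-8), incrementing per-node frequencies.
#' Memory is proportional to the number of distinct scaffolds, not to the
#' number of molecules. Duplicate molecules count multiply: frequencies are
#' molecule counts, not distinct-compound counts.
#'
#' @param x a list of [Molecule-class] objects, or a chains matrix as
#'   returned by [scaffoldChains()].
#' @return a [ScaffoldHierarchy-class].
#' @examples
#' \dontrun{
#' lib <- generateFixtureLibrary(100, seed = 7)
#' h <- buildHierarchy(lib$molecules)
#' }
#' @export
buildHierarchy <- function(x) {
  chains <- if (is.matrix(x)) x else scaffoldChains(x)
  nodes <- .chainsToNodes(chains)
  nodes[, c("backgroundFreq", "datasetFreq", "childCount") :=
            list(freq, 0, 0L)]
  nodes[, "freq" := NULL]
  .newHierarchy(nodes, nrow(chains))
}

#' Merge two hierarchies
#'
#' Node sets are united and frequencies added, enabling sharded background
#' builds. Merging is associative and commutative, and merging with an
#' empty hierarchy is the identity.
#'
#' @param a,b [ScaffoldHierarchy-class] objects built with the same engine
#'   configuration.
#' @return the merged [ScaffoldHierarchy-class].
#' @export
mergeHierarchies <- function(a, b) {
  stopifnot(is(a, "ScaffoldHierarchy"), is(b, "ScaffoldHierarchy"))
  la <- max(a@nodes$level); lb <- max(b@nodes$level)
  if (a@moleculeCount > 0 && b@moleculeCount > 0 && la != lb)
    stop("hierarchies span different level counts (", la, " vs ", lb, ")")
  dt <- rbind(as.data.table(a@nodes), as.data.table(b@nodes))
  chk <- dt[!is.na(parent), list(np = length(unique(parent))),
            by = c("level", "key")]
  if (any(chk$np > 1))
    stop("hierarchies disagree on a scaffold's parent; were they built with the same engine configuration?")
  out <- dt[, list(parent = parent[1],
                   backgroundFreq = sum(backgroundFreq),
                   datasetFreq = sum(datasetFreq), childCount = 0L),
            by = c("level", "key")]
  .newHierarchy(out, a@moleculeCount + b@moleculeCount,
                a@datasetCount + b@datasetCount)
}

#' Annotate a background hierarchy with a user dataset
#'
#' Computes the scaffold chains of the user molecules, populates
#' `datasetFreq` on the background tree, and adds any user scaffolds absent
#' from the background with `backgroundFreq` 0. Also returns the molecule to
#' chain mapping used by the molecule list/filter features.
#'
#' @param background a [ScaffoldHierarchy-class].
#' @param mols list of [Molecule-class] objects (or a chains matrix).
#' @return list with `hierarchy` (annotated [ScaffoldHierarchy-class]) and
#'   `chains` (data.frame: id, name, L1..L8).
#' @export
annotateHierarchy <- function(background, mols) {
  stopifnot(is(background, "ScaffoldHierarchy"))
  chains <- if (is.matrix(mols)) mols else scaffoldChains(mols)
  ds <- .chainsToNodes(chains)
  data.table::setnames(ds, "freq", "datasetFreq")
  bg <- as.data.table(background@nodes)
  bg[, "datasetFreq" := NULL]
  out <- merge(bg, ds, by = c("level", "key"), all = TRUE,
               suffixes = c("", ".ds"))
  out[is.na(backgroundFreq), "backgroundFreq" := 0]
  out[is.na(datasetFreq), "datasetFreq" := 0]
  out[is.na(parent) & level > 0L, "parent" := parent.ds]
  out[, c("parent.ds", "childCount") := list(NULL, 0L)]
  h <- .newHierarchy(out, background@moleculeCount, nrow(chains))
  chainDf <- data.frame(id = rownames(chains),
                        name = if (is.matrix(mols)) NA_character_ else
                          vapply(mols, function(m) m@name, ""),
                        chains, stringsAsFactors = FALSE, row.names = NULL)
  list(hierarchy = h, chains = chainDf)
}

#' Export / load a hierarchy as CSV
#'
#' The background hierarchy persists as a CSV with columns `level`, `key`,
#' `parent_key`, `background_freq`, `child_count` (RFC-4180 quoting, header
#' row, UTF-8); dataset frequencies of annotated hierarchies are written to
#' a `dataset_freq` column by `exportHierarchyCSV(..., dataset = TRUE)` but
#' never belong in a background file. `loadHierarchyCSV` is the lossless
#' inverse; malformed rows abort with their row number.
#'
#' @param h a [ScaffoldHierarchy-class].
#' @param path CSV file path.
#' @param dataset write the `dataset_freq` column (annotated exports).
#' @return `exportHierarchyCSV`: invisibly `path`; `loadHierarchyCSV`: a
#'   [ScaffoldHierarchy-class].
#' @export
exportHierarchyCSV <- function(h, path, dataset = FALSE) {
  stopifnot(is(h, "ScaffoldHierarchy"))
  dt <- as.data.table(h@nodes)
  out <- as.data.table(list(level = dt$level, key = dt$key,
                            parent_key = dt$parent,
                            background_freq = dt$backgroundFreq,
                            child_count = dt$childCount))
  if (dataset) out[, "dataset_freq" := dt$datasetFreq]
  fwrite(out, path, quote = "auto")
  invisible(path)
}

#' @rdname exportHierarchyCSV
#' @export
loadHierarchyCSV <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, colClasses = list(character = c("key", "parent_key")),
              na.strings = "")
  need <- c("level", "key", "parent_key", "background_freq", "child_count")
  if (!all(need %in% names(dt)))
    stop("malformed hierarchy CSV: expected columns ", paste(need, collapse = ", "))
  bad <- which(is.na(dt$level) | dt$level < 0 | dt$level > 8 |
               is.na(dt$key) | !nzchar(dt$key) |
               is.na(dt$background_freq) | dt$background_freq < 0)
  if (length(bad))
    stop("malformed hierarchy CSV row(s): ", paste(bad + 1L, collapse = ", "))
  nodes <- as.data.table(list(level = as.integer(dt$level), key = dt$key,
                              parent = dt$parent_key,
                              backgroundFreq = as.numeric(dt$background_freq),
                              datasetFreq = if ("dataset_freq" %in% names(dt))
                                as.numeric(dt$dataset_freq) else 0,
                              childCount = rep(0L, nrow(dt))))
  molecules <- nodes[level == 0L]$backgroundFreq
  if (length(molecules) != 1L)
    stop("malformed hierarchy CSV: expected exactly one level-0 root row")
  h <- .newHierarchy(nodes, molecules,
                     datasetCount = if ("dataset_freq" %in% names(dt))
                       nodes[level == 0L]$datasetFreq else 0)
  stored <- as.data.table(dt)[order(level, key)]$child_count
  if (!identical(as.integer(stored), as.integer(h@nodes$childCount)))
    stop("malformed hierarchy CSV: child_count column inconsistent with tree")
  h
}

#' Query the hierarchy: children, subtree, ancestors
#'
#' `hierarchyChildren` lists the direct children of a node;
#' `hierarchySubtree` returns the view restricted to a node and its
#' descendants (its moleculeCount is the node's background frequency);
#' `scaffoldAncestors` returns the path from the root to the node's parent
#' (length equals the node's level).
#'
#' @param h a [ScaffoldHierarchy-class].
#' @param level,key node address (canonical key at a level).
#' @return `hierarchyChildren`: data.frame of child nodes;
#'   `hierarchySubtree`: a [ScaffoldHierarchy-class] view;
#'   `scaffoldAncestors`: data.frame with columns level, key (root first).
#' @export
hierarchyChildren <- function(h, level, key) {
  .assertNode(h, level, key)
  nd <- h@nodes
  nd[nd$level == level + 1L & !is.na(nd$parent) & nd$parent == key, ,
     drop = FALSE]
}

#' @rdname hierarchyChildren
#' @export
hierarchySubtree <- function(h, level, key) {
  .assertNode(h, level, key)
  nd <- h@nodes
  keep <- nd[nd$level == level & nd$key == key, , drop = FALSE]
  keep$parent <- NA_character_
  cur <- key
  out <- list(keep)
  lev <- level
  while (lev < 8L && length(cur)) {
    nxt <- nd[nd$level == lev + 1L & !is.na(nd$parent) & nd$parent %in% cur, ,
              drop = FALSE]
    if (nrow(nxt) == 0) break
    out[[length(out) + 1L]] <- nxt
    cur <- nxt$key
    lev <- lev + 1L
  }
  sub <- do.call(rbind, out)
  new("ScaffoldHierarchy", nodes = .recountChildren(sub),
      moleculeCount = keep$backgroundFreq,
      datasetCount = if (h@datasetCount > 0) keep$datasetFreq else 0)
}

#' @rdname hierarchyChildren
#' @export
scaffoldAncestors <- function(h, level, key) {
  .assertNode(h, level, key)
  nd <- h@nodes
  out <- data.frame(level = integer(), key = character())
  cur <- key; lev <- level
  while (lev > 0L) {
    par <- nd$parent[nd$level == lev & nd$key == cur]
    lev <- lev - 1L
    cur <- par
    out <- rbind(data.frame(level = lev, key = cur), out)
  }
  out
}

.assertNode <- function(h, level, key) {
  stopifnot(is(h, "ScaffoldHierarchy"))
  if (!any(h@nodes$level == level & h@nodes$key == key))
    stop("no such scaffold node: level ", level, ", key '", key, "'")
}
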