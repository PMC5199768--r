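# Canonical scaffold keys: identity-stable string encodings per level.
#
# Levels 8-7 are chemical graphs and use OpenBabel canonical SMILES.
# Levels 6-2 are abstract graphs (vertices may exceed chemical valence), so
# they are encoded as a canonical edge list derived from a BLISS canonical
# labeling; connectivity strength at levels 3-2 is carried by an edge label
# (encoded for canonicalization as a colored subdivision vertex). Level 1 is
# the decimal ring count, level 0 the fixed root sentinel. The empty
# scaffold of acyclic molecules is "-" at every level 2-8.

#' Canonical key of a scaffold
#'
#' Produces the deterministic string identifying a scaffold node:
#' identical for isomorphic scaffold graphs, invariant under any vertex or
#' bond reordering of the input.
#'
#' @param x a [ScaffoldGraph-class] (levels 2-8), or an integer ring count
#'   (level 1).
#' @param level the hierarchy level; defaults to the graph's level.
#' @return character(1).
#' @examples
#' \dontrun{
#' m <- readMolecules(system.file("extdata", "drugs_synthetic.smi",
#'                    package = "scaffoldmap"))$molecules[[1]]
#' canonicalKey(murckoFramework(m))
#' }
#' @export
canonicalKey <- function(x, level = NULL) {
  if (is.numeric(x)) {
    stopifnot(is.null(level) || level == 1L)
    return(as.character(as.integer(x)))
  }
  stopifnot(is(x, "ScaffoldGraph"))
  if (is.null(level)) level <- x@level
  n <- nrow(x@atoms)
  if (level == 1L) return(as.character(n))
  if (n == 0) return(EMPTY_KEY)
  if (level >= 7L) {
    smi <- .canonicalSmiles(.molfileOf(x, "K"), 1L)
    return(unname(smi))
  }
  .canonGraphKey(n, x@bonds, labeled = (level <= 3L))
}

.canonGraphKey <- function(n, bonds, labeled = FALSE) {
  m <- nrow(bonds)
  if (m == 0) {
    ord <- seq_len(n)
    return(paste0(n, ":"))
  }
  if (labeled) {
    # encode the edge label (1 weak / 2 strong) as a colored subdivision
    # vertex so that plain vertex-colored canonicalization applies
    ev <- n + seq_len(m)
    edges <- rbind(cbind(bonds$a1, ev), cbind(ev, bonds$a2))
    colors <- c(rep(0L, n), as.integer(bonds$order))
    g <- igraph::make_empty_graph(n = n + m, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
  } else {
    g <- .graphOf(n, bonds)
    colors <- rep(0L, n)
  }
  lab <- igraph::canonical_permutation(g, colors = colors)$labeling
  ord <- rank(lab[seq_len(n)])  # canonical order of the original vertices
  i <- ord[bonds$a1]; j <- ord[bonds$a2]
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (labeled) {
    tag <- ifelse(bonds$order == 2L, "s", "w")
    es <- paste0(lo, "-", hi, tag)
  } else {
    es <- paste0(lo, "-", hi)
  }
  es <- es[order(lo, hi)]
  paste0(n, ":", paste(es, collapse = ","))
}

.abstractAtoms <- function(n, elem = "C") {
  if (n == 0) return(.emptyAtoms())
  data.frame(elem = rep(elem, n), x = 0, y = 0, z = 0, charge = 0L,
             isotope = 0L, radical = 0L, parity = 0L, aromatic = FALSE,
             stringsAsFactors = FALSE)
}

.abstractBonds <- function(a1, a2, order = 1L) {
  if (!length(a1)) return(.emptyBonds())
  data.frame(a1 = as.integer(a1), a2 = as.integer(a2),
             order = as.integer(rep_len(order, length(a1))), wedge = 0L,
             aromatic = FALSE, stringsAsFactors = FALSE)
}

# Build an abstract ScaffoldGraph from an edge list (used by fixtures/tests)
.abstractGraph <- function(level, n, a1 = integer(), a2 = integer(),
                           order = 1L) {
  new("ScaffoldGraph", level = as.integer(level),
      atoms = .abstractAtoms(n, if (level <= 3L) "*" else "C"),
      bonds = .abstractBonds(a1, a2, order))
}

#' Rebuild a scaffold graph from its canonical key
#'
#' The inverse of [canonicalKey()]: parses a level-2..8 key back into a
#' [ScaffoldGraph-class]. Together with the level transformations this makes
#' every level-k key computable from the level-(k+1) key alone, without the
#' original molecule.
#'
#' @param level hierarchy level of the key (2-8).
#' @param key the canonical key string.
#' @return a [ScaffoldGraph-class].
#' @export
keyToGraph <- function(level, key) {
  level <- as.integer(level)
  stopifnot(level >= 2L, level <= 8L)
  if (key == EMPTY_KEY)
    return(new("ScaffoldGraph", level = level))
  if (level >= 7L) {
    mols <- .parseSmilesVector(key)
    m <- standardizeMolecules(mols)[[1]]
    return(new("ScaffoldGraph", level = level, atoms = m@atoms,
               bonds = m@bonds))
  }
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  n <- as.integer(parts[1])
  if (length(parts) < 2L || !nzchar(parts[2]))
    return(.abstractGraph(level, n))
  es <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
  if (level <= 3L) {
    tag <- sub("^[0-9]+-[0-9]+", "", es)
    ij <- sub("[sw]$", "", es)
    ord <- ifelse(tag == "s", 2L, 1L)
  } else {
    ij <- es
    ord <- 1L
  }
  ijm <- do.call(rbind, strsplit(ij, "-", fixed = TRUE))
  .abstractGraph(level, n, as.integer(ijm[, 1]), as.integer(ijm[, 2]), ord)
}

#' Parent key of a scaffold key
#'
#' Computes the level-(k-1) key directly from a level-k key, exercising the
#' property that scaffolds at higher levels are independent of the original
#' molecule.
#'
#' @param level level of `key` (1-8).
#' @param key canonical key at `level`.
#' @return character(1), the canonical key at `level - 1`.
#' @export
parentKey <- function(level, key) {
  level <- as.integer(level)
  stopifnot(level >= 1L, level <= 8L)
  if (level == 1L) return(ROOT_KEY)
  if (key == EMPTY_KEY) return(if (level == 2L) "0" else EMPTY_KEY)
  g <- keyToGraph(level, key)
  switch(as.character(level),
         "8" = canonicalKey(clearStereo(g)),
         "7" = canonicalKey(graphFramework(g)),
         "6" = canonicalKey(pruneLinkers(g)),
         "5" = canonicalKey(opreaScaffold(g)),
         "4" = canonicalKey(ringConnectivity(g)),
         "3" = canonicalKey(collapseConnectivity(g)),
         "2" = as.character(nrow(g@atoms)))
}

#' Scaffold chain of a molecule
#'
#' Maps a molecule to its sequence of exactly eight scaffold keys, one per
#' level 1-8 (standardize, extract the framework, then apply the level
#' transformations downwards). Acyclic molecules yield ring count "0" and
#' the empty-scaffold sentinel at levels 2-8.
#'
#' @param m a [Molecule-class].
#' @return named character vector of length 8 (names `"L1"`..`"L8"`).
#' @export
scaffoldChain <- function(m) {
  stopifnot(is(m, "Molecule"))
  scaffoldChains(list(m))[1, ]
}

#' Scaffold chains for a list of molecules
#'
#' Batched variant of [scaffoldChain()]: canonical-SMILES generation is
#' batched through OpenBabel and the level 7..1 derivation is computed once
#' per distinct framework, so libraries with recurring scaffolds classify
#' quickly.
#'
#' @param mols list of [Molecule-class] objects.
#' @return character matrix, one row per molecule (rownames = molecule ids),
#'   columns `L1`..`L8`.
#' @export
scaffoldChains <- function(mols) {
  n <- length(mols)
  out <- matrix(EMPTY_KEY, nrow = n, ncol = 8,
                dimnames = list(vapply(mols, function(m) m@id, ""),
                                paste0("L", 1:8)))
  out[, "L1"] <- "0"
  if (n == 0) return(out)
  std <- which(!vapply(mols, function(m) m@standardized, TRUE))
  if (length(std)) mols[std] <- standardizeMolecules(mols[std])
  fw <- lapply(mols, murckoFramework)
  nonEmpty <- which(vapply(fw, function(s) nrow(s@atoms) > 0, TRUE))
  if (!length(nonEmpty)) return(out)
  sdf <- paste0(vapply(nonEmpty, function(i)
    .molfileOf(fw[[i]], paste0("K", i)), ""), collapse = "\n")
  key8 <- .canonicalSmiles(sdf, length(nonEmpty))
  out[nonEmpty, "L8"] <- unname(key8)
  # levels 7..1 depend only on the level-8 scaffold: compute once per
  # distinct framework
  reps <- nonEmpty[!duplicated(out[nonEmpty, "L8"])]
  l7 <- lapply(reps, function(i) clearStereo(fw[[i]]))
  sdf7 <- paste0(vapply(seq_along(reps), function(k)
    .molfileOf(l7[[k]], paste0("K", k)), ""), collapse = "\n")
  key7 <- unname(.canonicalSmiles(sdf7, length(reps)))
  sub <- matrix("", nrow = length(reps), ncol = 7,
                dimnames = list(out[reps, "L8"], paste0("L", 1:7)))
  for (k in seq_along(reps)) {
    g6 <- graphFramework(l7[[k]])
    g5 <- pruneLinkers(g6)
    g4 <- opreaScaffold(g5)
    g3 <- ringConnectivity(g4)
    g2 <- collapseConnectivity(g3)
    sub[k, ] <- c(as.character(ringCount(g2)), canonicalKey(g2),
                  canonicalKey(g3), canonicalKey(g4), canonicalKey(g5),
                  canonicalKey(g6), key7[k])
  }
  out[nonEmpty, 1:7] <- sub[out[nonEmpty, "L8"], ]
  out
}
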