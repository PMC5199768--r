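# Seeded synthetic compound libraries with known-by-construction chains.
#
# Each vocabulary core is a complete framework (ring systems plus linkers)
# whose scaffold chain is specified by hand: ring count, ring-connectivity
# edges, Oprea and framework-ring graphs are hand-derived edge lists, and
# the level 7/8 keys come from parsing the core's framework SMILES directly
# (never through side-chain deletion). Generated molecules decorate a core
# with acyclic side chains only, which cannot change the framework, so the
# returned chain table is an exact oracle for hierarchy statistics.

.cyc <- function(n, off = 0L) {
  v <- off + seq_len(n)
  list(a = v, b = c(v[-1], v[1]))
}

# hand-specified abstract graphs shared by several cores
.FIX_L4 <- list(
  mono    = list(n = 3L, a = c(1L, 1L, 2L), b = c(2L, 3L, 3L)),
  fused2  = list(n = 4L, a = c(1L, 1L, 2L, 1L, 2L), b = c(2L, 3L, 3L, 4L, 4L)),
  fused3  = list(n = 6L, a = c(1L, 1L, 2L, 4L, 4L, 5L, 2L, 1L),
                 b = c(2L, 3L, 3L, 5L, 6L, 6L, 4L, 5L)),
  fused4  = list(n = 8L, a = c(1L, 1L, 2L, 1L, 2L, 4L, 5L, 4L, 6L, 6L, 7L),
                 b = c(2L, 3L, 3L, 4L, 5L, 5L, 6L, 7L, 7L, 8L, 8L)),
  spiro2  = list(n = 5L, a = c(1L, 1L, 2L, 3L, 3L, 4L), b = c(2L, 3L, 3L, 4L, 5L, 5L)),
  linked2 = list(n = 6L, a = c(1L, 1L, 2L, 4L, 4L, 5L, 1L),
                 b = c(2L, 3L, 3L, 5L, 6L, 6L, 4L)),
  star3   = list(n = 10L, a = c(1L, 1L, 2L, 4L, 4L, 5L, 7L, 7L, 8L, 1L, 4L, 7L),
                 b = c(2L, 3L, 3L, 5L, 6L, 6L, 8L, 9L, 9L, 10L, 10L, 10L)))

.FIX_L3 <- list(
  none    = list(n = 0L, a = integer(), b = integer(), s = integer()),
  mono    = list(n = 1L, a = integer(), b = integer(), s = integer()),
  fused2  = list(n = 2L, a = 1L, b = 2L, s = 2L),
  fused3  = list(n = 3L, a = c(1L, 2L), b = c(2L, 3L), s = c(2L, 2L)),
  fused4  = list(n = 4L, a = c(1L, 2L, 3L), b = c(2L, 3L, 4L), s = c(2L, 2L, 2L)),
  spiro2  = list(n = 2L, a = 1L, b = 2L, s = 1L),
  linked2 = list(n = 2L, a = 1L, b = 2L, s = 1L),
  star3   = list(n = 3L, a = c(1L, 1L, 2L), b = c(2L, 3L, 3L), s = c(1L, 1L, 1L)))

# level-6 skeletons (hand edge lists), as list(n, a, b)
.fixL6 <- local({
  hex <- .cyc(6L)
  hex2 <- .cyc(6L, 6L)
  # naphthalene: ring1 = 1..6, ring2 = 1,2,7,8,9,10 sharing edge 1-2
  naph <- list(n = 10L,
               a = c(1L, 2L, 3L, 4L, 5L, 6L, 2L, 7L, 8L, 9L, 10L),
               b = c(2L, 3L, 4L, 5L, 6L, 1L, 7L, 8L, 9L, 10L, 1L))
  anth <- list(n = 14L,
               a = c(naph$a, 9L, 11L, 12L, 13L, 14L),
               b = c(naph$b, 11L, 12L, 13L, 14L, 8L))
  # anthracene: third hexagon 8,9,11,12,13,14 on ring2's edge 8-9
  gona <- list(n = 17L,
               a = c(1L, 2L, 3L, 4L, 5L, 6L, 5L, 7L, 8L, 9L, 10L, 10L, 11L,
                     12L, 13L, 14L, 14L, 15L, 16L, 17L),
               b = c(2L, 3L, 4L, 5L, 6L, 1L, 7L, 8L, 9L, 10L, 4L, 11L, 12L,
                     13L, 14L, 9L, 15L, 16L, 17L, 13L))
  spir <- list(n = 10L,
               a = c(1L, 2L, 3L, 4L, 5L, 5L, 6L, 7L, 8L, 9L, 10L),
               b = c(2L, 3L, 4L, 5L, 1L, 6L, 7L, 8L, 9L, 10L, 5L))
  norb <- list(n = 7L,
               a = c(1L, 2L, 3L, 4L, 5L, 6L, 6L, 7L),
               b = c(2L, 3L, 4L, 5L, 6L, 1L, 7L, 3L))
  biph <- list(n = 12L, a = c(hex$a, hex2$a, 1L), b = c(hex$b, hex2$b, 7L))
  dpm  <- list(n = 13L, a = c(hex$a, hex2$a, 1L, 13L),
               b = c(hex$b, hex2$b, 13L, 7L))
  bibz <- list(n = 14L, a = c(hex$a, hex2$a, 1L, 13L, 14L),
               b = c(hex$b, hex2$b, 13L, 14L, 7L))
  dpp  <- list(n = 15L, a = c(hex$a, hex2$a, 1L, 13L, 14L, 15L),
               b = c(hex$b, hex2$b, 13L, 14L, 15L, 7L))
  hex3 <- .cyc(6L, 12L)
  tpm  <- list(n = 19L, a = c(hex$a, hex2$a, hex3$a, 1L, 7L, 13L),
               b = c(hex$b, hex2$b, hex3$b, 19L, 19L, 19L))
  list(ring6 = list(n = 6L, a = hex$a, b = hex$b), naph = naph, anth = anth,
       gona = gona, spir = spir, norb = norb, biph = biph, dpm = dpm,
       bibz = bibz, dpp = dpp, tpm = tpm)
})

#' Fixture vocabulary
#'
#' The built-in core frameworks the synthetic library generator assembles
#' molecules from: single rings, fused systems up to the steroid nucleus,
#' spiro and bridged bicyclics, ring pairs joined by linkers of length 0-3,
#' a branched three-ring system, and an acyclic core. Each entry carries the
#' core's framework SMILES, its sampling weight, the token positions where
#' side chains may be attached, and its hand-specified scaffold structures
#' at every level.
#'
#' @return named list of core specifications.
#' @export
fixtureVocabulary <- function() {
  list(
    benzene = list(
      tokens = c("c1", "c", "c", "c", "c", "c1"), attach = 1:6, weight = 0.22,
      ringCount = 1L, l6 = .fixL6$ring6, l5 = .fixL6$ring6,
      l4 = .FIX_L4$mono, l3 = .FIX_L3$mono),
    pyridine = list(
      tokens = c("c1", "c", "c", "n", "c", "c1"), attach = c(1:3, 5:6),
      weight = 0.08, ringCount = 1L, l6 = .fixL6$ring6, l5 = .fixL6$ring6,
      l4 = .FIX_L4$mono, l3 = .FIX_L3$mono),
    cyclohexane = list(
      tokens = c("C1", "C", "C", "C", "C", "C1"), attach = 1:6, weight = 0.06,
      ringCount = 1L, l6 = .fixL6$ring6, l5 = .fixL6$ring6,
      l4 = .FIX_L4$mono, l3 = .FIX_L3$mono),
    naphthalene = list(
      tokens = c("c1", "c", "c", "c2", "c", "c", "c", "c", "c2", "c1"),
      attach = c(1:3, 5:8, 10), weight = 0.08, ringCount = 2L,
      l6 = .fixL6$naph, l5 = .fixL6$naph, l4 = .FIX_L4$fused2,
      l3 = .FIX_L3$fused2),
    anthracene = list(
      tokens = c("c1", "c", "c", "c2", "c", "c3", "c", "c", "c", "c", "c3",
                 "c", "c2", "c1"),
      attach = c(1:3, 5, 7:10, 12, 14), weight = 0.03, ringCount = 3L,
      l6 = .fixL6$anth, l5 = .fixL6$anth, l4 = .FIX_L4$fused3,
      l3 = .FIX_L3$fused3),
    gonane = list(
      tokens = c("C1", "C", "C", "C2", "C(", "C1)", "C", "C", "C1", "C2",
                 "C", "C", "C2", "C1", "C", "C", "C2"),
      attach = c(1:4, 7:17), weight = 0.05, ringCount = 4L,
      l6 = .fixL6$gona, l5 = .fixL6$gona, l4 = .FIX_L4$fused4,
      l3 = .FIX_L3$fused4),
    spirodecane = list(
      tokens = c("C1", "C", "C", "C", "C12", "C", "C", "C", "C", "C2"),
      attach = c(1:4, 6:10), weight = 0.05, ringCount = 2L,
      l6 = .fixL6$spir, l5 = .fixL6$spir, l4 = .FIX_L4$spiro2,
      l3 = .FIX_L3$spiro2),
    norbornane = list(
      tokens = c("C1", "C", "C2", "C", "C", "C1", "C2"), attach = 1:7,
      weight = 0.05, ringCount = 2L, l6 = .fixL6$norb, l5 = .fixL6$norb,
      l4 = .FIX_L4$fused2, l3 = .FIX_L3$fused2),
    biphenyl = list(
      tokens = c("c1", "c", "c", "c", "c", "c1", "-c1", "c", "c", "c", "c",
                 "c1"),
      attach = c(1:5, 8:12), weight = 0.10, ringCount = 2L,
      l6 = .fixL6$biph, l5 = .fixL6$biph, l4 = .FIX_L4$linked2,
      l3 = .FIX_L3$linked2),
    diphenylmethane = list(
      tokens = c("c1", "c", "c", "c", "c", "c1", "C", "c1", "c", "c", "c",
                 "c", "c1"),
      attach = c(1:5, 9:13), weight = 0.06, ringCount = 2L,
      l6 = .fixL6$dpm, l5 = .fixL6$biph, l4 = .FIX_L4$linked2,
      l3 = .FIX_L3$linked2),
    bibenzyl = list(
      tokens = c("c1", "c", "c", "c", "c", "c1", "C", "C", "c1", "c", "c",
                 "c", "c", "c1"),
      attach = c(1:5, 10:14), weight = 0.04, ringCount = 2L,
      l6 = .fixL6$bibz, l5 = .fixL6$biph, l4 = .FIX_L4$linked2,
      l3 = .FIX_L3$linked2),
    diphenylpropane = list(
      tokens = c("c1", "c", "c", "c", "c", "c1", "C", "C", "C", "c1", "c",
                 "c", "c", "c", "c1"),
      attach = c(1:5, 11:15), weight = 0.03, ringCount = 2L,
      l6 = .fixL6$dpp, l5 = .fixL6$biph, l4 = .FIX_L4$linked2,
      l3 = .FIX_L3$linked2),
    triphenylmethane = list(
      tokens = c("c1", "c", "c", "c", "c", "c1", "C(", "c2", "c", "c", "c",
                 "c", "c2", ")", "c3", "c", "c", "c", "c", "c3"),
      attach = c(1:5, 9:13, 16:20), weight = 0.03, ringCount = 3L,
      l6 = .fixL6$tpm, l5 = .fixL6$tpm, l4 = .FIX_L4$star3,
      l3 = .FIX_L3$star3),
    acyclic = list(
      tokens = c("C", "C", "C"), attach = 1:3, weight = 0.12,
      ringCount = 0L, l6 = NULL, l5 = NULL, l4 = NULL, l3 = .FIX_L3$none)
  )
}

.FIX_SIDECHAINS <- c("C", "CC", "CCC", "CCO", "O", "N", "F", "Cl", "Br",
                     "C(C)C", "OC", "C(=O)O", "S", "C#N")

# ground-truth chain for one core (keys only; levels 7/8 from the framework
# SMILES itself, never via side-chain deletion)
.coreChain <- function(core) {
  fw <- paste(core$tokens, collapse = "")
  if (core$ringCount == 0L)
    return(c(L1 = "0", L2 = EMPTY_KEY, L3 = EMPTY_KEY, L4 = EMPTY_KEY,
             L5 = EMPTY_KEY, L6 = EMPTY_KEY, L7 = EMPTY_KEY, L8 = EMPTY_KEY))
  m <- standardizeMolecules(.parseSmilesVector(fw))[[1]]
  g8 <- new("ScaffoldGraph", level = 8L, atoms = m@atoms, bonds = m@bonds)
  a7 <- m@atoms; a7$parity <- 0L; a7$x <- 0; a7$y <- 0; a7$z <- 0
  b7 <- m@bonds; b7$wedge <- 0L
  g7 <- new("ScaffoldGraph", level = 7L, atoms = a7, bonds = b7)
  k <- character(8)
  k[8] <- canonicalKey(g8)
  k[7] <- canonicalKey(g7)
  k[6] <- canonicalKey(.abstractGraph(6L, core$l6$n, core$l6$a, core$l6$b))
  k[5] <- canonicalKey(.abstractGraph(5L, core$l5$n, core$l5$a, core$l5$b))
  k[4] <- canonicalKey(.abstractGraph(4L, core$l4$n, core$l4$a, core$l4$b))
  k[3] <- canonicalKey(.abstractGraph(3L, core$l3$n, core$l3$a, core$l3$b,
                                      core$l3$s))
  k[2] <- canonicalKey(.abstractGraph(2L, core$l3$n, core$l3$a, core$l3$b))
  k[1] <- as.character(core$ringCount)
  names(k) <- paste0("L", 1:8)
  k
}

#' Generate a synthetic fixture library
#'
#' Deterministically (seeded) assembles `n` molecules from the built-in
#' vocabulary of ring-system cores, linkers and side chains, and returns
#' both the molecules and their known-by-construction scaffold chains, so
#' hierarchy statistics have an exact oracle.
#'
#' @param n number of molecules (>= 1).
#' @param seed integer RNG seed; the same seed reproduces the same library.
#'   The global RNG state is left untouched.
#' @param cores optional character vector restricting the vocabulary (names
#'   of [fixtureVocabulary()] entries).
#' @param sideChains optional character vector of side-chain SMILES branches.
#' @param sideChainRange integer length-2: min/max side chains per molecule.
#' @return list with `molecules` (list of [Molecule-class]), `chains`
#'   (character matrix n x 8, the ground-truth keys), and `table`
#'   (data.frame: id, core, smiles).
#' @examples
#' \dontrun{
#' lib <- generateFixtureLibrary(5, seed = 7)
#' lib$table$smiles
#' }
#' @export
generateFixtureLibrary <- function(n, seed, cores = NULL, sideChains = NULL,
                                   sideChainRange = c(0L, 3L)) {
  stopifnot(n >= 1, length(sideChainRange) == 2)
  vocab <- fixtureVocabulary()
  if (!is.null(cores)) {
    stopifnot(all(cores %in% names(vocab)))
    vocab <- vocab[cores]
  }
  if (is.null(sideChains)) sideChains <- .FIX_SIDECHAINS
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  w <- vapply(vocab, `[[`, 0, "weight")
  pick <- sample(names(vocab), n, replace = TRUE, prob = w)
  smiles <- character(n)
  for (i in seq_len(n)) {
    core <- vocab[[pick[i]]]
    tok <- core$tokens
    k <- if (sideChainRange[1] == sideChainRange[2]) sideChainRange[1] else
      sample(sideChainRange[1]:sideChainRange[2], 1)
    k <- min(k, length(core$attach))
    if (k > 0) {
      pos <- if (length(core$attach) == 1) core$attach else
        sample(core$attach, k)
      sc <- sample(sideChains, k, replace = TRUE)
      tok[pos] <- paste0(tok[pos], "(", sc, ")")
    }
    smiles[i] <- paste(tok, collapse = "")
  }
  mols <- .parseSmilesVector(smiles, names = paste0(pick, "_", seq_len(n)))
  chainByCore <- vapply(vocab[unique(pick)], .coreChain,
                        character(8))  # 8 x cores
  chains <- t(chainByCore[, pick, drop = FALSE])
  rownames(chains) <- as.character(seq_len(n))
  list(molecules = mols, chains = chains,
       table = data.frame(id = as.character(seq_len(n)), core = pick,
                          smiles = smiles, stringsAsFactors = FALSE))
}
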