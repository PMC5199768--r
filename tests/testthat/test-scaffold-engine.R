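# The eight level transformations, CSSR and the connectivity rules.

test_that("framework extraction removes side chains and matches the separation oracle", {
  # toluene reduces to benzene, acyclic molecules to the empty scaffold
  tol <- murckoFramework(parseOne("Cc1ccccc1"))
  ben <- murckoFramework(parseOne("c1ccccc1"))
  expect_equal(canonicalKey(tol), canonicalKey(ben))
  expect_equal(nrow(atoms(murckoFramework(parseOne("CCO")))), 0)

  # frameworks agree with an independent oracle (ring atoms plus atoms
  # separating ring systems) on the worked drugs and fixtures
  lib <- generateFixtureLibrary(30, seed = 13)
  mols <- c(parseSmi(unname(DRUG_SMILES)), lib$molecules)
  for (m in standardizeMolecules(mols)) {
    b <- bonds(m)
    A <- edgesToAdj(nrow(atoms(m)), b$a1, b$a2)
    fwAtoms <- oracleFrameworkAtoms(A)
    fw <- murckoFramework(m)
    expect_equal(nrow(atoms(fw)), length(fwAtoms))
    expect_equal(nrow(bonds(fw)), sum(A[fwAtoms, fwAtoms]) / 2)
  }
  # diazepam keeps the benzodiazepine + phenyl framework, chlorine gone
  dia <- murckoFramework(standardizeMolecule(parseOne(DRUG_SMILES[["diazepam"]])))
  expect_false("Cl" %in% atoms(dia)$elem)
  expect_equal(nrow(atoms(dia)), 17)  # 11-ring + 6-ring, N-methyl/C=O removed
})

test_that("stereo is kept at level 8 and cleared at level 7", {
  hc <- murckoFramework(standardizeMolecule(
    parseOne(DRUG_SMILES[["hydrocortisone"]])))
  k8 <- canonicalKey(hc)
  k7 <- canonicalKey(clearStereo(hc))
  expect_true(grepl("@", k8))         # some ring stereo survives
  expect_false(grepl("[@/\\\\]", k7)) # all stereo cleared
  # heteroatoms kept at level 7, same skeleton
  g8 <- keyToGraph(8, k8); g7 <- keyToGraph(7, k7)
  expect_equal(nrow(atoms(g7)), nrow(atoms(g8)))
  expect_equal(sort(atoms(g7)$elem), sort(atoms(g8)$elem))
  # level 7 is the identity on stereo-free input
  ben <- murckoFramework(parseOne("c1ccccc1"))
  expect_equal(canonicalKey(clearStereo(ben)), canonicalKey(ben))
})

test_that("graph framework forgets elements and bond orders only", {
  pyr <- scaffoldChain(parseOne("c1ccncc1"))
  ben <- scaffoldChain(parseOne("c1ccccc1"))
  expect_identical(pyr[["L6"]], ben[["L6"]])
  expect_false(pyr[["L7"]] == ben[["L7"]])

  naph <- graphFramework(clearStereo(murckoFramework(parseOne("c1ccc2ccccc2c1"))))
  expect_equal(nrow(atoms(naph)), 10)
  expect_equal(nrow(bonds(naph)), 11)
  expect_true(all(atoms(naph)$elem == "C"))
  expect_true(all(bonds(naph)$order == 1L))

  # sulfamethoxazole framework: two rings joined by a two-atom linker
  smx <- graphFramework(clearStereo(murckoFramework(
    standardizeMolecule(parseOne(DRUG_SMILES[["sulfamethoxazole"]])))))
  hand <- scaffoldmap:::.abstractGraph(
    6L, 13L,
    c(1L, 2L, 3L, 4L, 5L, 6L, 1L, 7L, 8L, 9L, 10L, 11L, 12L, 9L),
    c(2L, 3L, 4L, 5L, 6L, 1L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 13L))
  expect_identical(canonicalKey(smx), canonicalKey(hand))
})

test_that("linker contraction keeps branching linkers and ring atoms", {
  chainOf <- function(smi) scaffoldChain(parseOne(smi))
  dpm <- chainOf("C(c1ccccc1)c1ccccc1")
  bip <- chainOf("c1ccc(-c2ccccc2)cc1")
  expect_identical(dpm[["L5"]], bip[["L5"]])
  expect_false(dpm[["L6"]] == bip[["L6"]])
  # biphenyl is a fixed point
  expect_identical(bip[["L5"]], bip[["L6"]])
  # triphenylmethane keeps its degree-3 central linker atom
  tpm <- keyToGraph(5, chainOf("C(c1ccccc1)(c1ccccc1)c1ccccc1")[["L5"]])
  expect_equal(nrow(atoms(tpm)), 19)
  expect_equal(sort(scaffoldmap:::.degreesOf(19, bonds(tpm))),
               c(rep(2L, 15), rep(3L, 4)))
})

test_that("topology contraction matches the spec graphs and halts at triangles", {
  # any isolated n-cycle contracts to a triangle
  for (n in 3:12) {
    cyc <- scaffoldmap:::.abstractGraph(5L, n, seq_len(n),
                                        c(seq_len(n)[-1], 1L))
    out <- opreaScaffold(cyc)
    expect_equal(nrow(atoms(out)), 3)
    expect_equal(nrow(bonds(out)), 3)
  }
  l4Of <- function(smi) keyToGraph(4, scaffoldChain(parseOne(smi))[["L4"]])
  naph <- l4Of("c1ccc2ccccc2c1")
  expect_equal(c(nrow(atoms(naph)), nrow(bonds(naph))), c(4, 5))
  expect_true(isIsomorphic(naph, scaffoldmap:::.abstractGraph(
    4L, 4L, c(1L, 1L, 2L, 1L, 2L), c(2L, 3L, 3L, 4L, 4L))))
  spiro <- l4Of("C1CCCC12CCCCC2")
  expect_equal(c(nrow(atoms(spiro)), nrow(bonds(spiro))), c(5, 6))
  expect_true(isIsomorphic(spiro, scaffoldmap:::.abstractGraph(
    4L, 5L, c(1L, 1L, 2L, 3L, 3L, 4L), c(2L, 3L, 3L, 4L, 5L, 5L))))
})

test_that("contraction agrees with the random-order brute-force oracle", {
  set.seed(99)
  lib <- generateFixtureLibrary(40, seed = 31)
  frameworks <- lapply(lib$molecules, function(m)
    graphFramework(clearStereo(murckoFramework(m))))
  graphs <- c(lapply(frameworks, graphToAdj),
              lapply(1:60, function(i) randomGraph(20)))
  for (A in graphs) {
    g6 <- adjToGraph(A, 6L)
    g5 <- pruneLinkers(g6)
    g4 <- opreaScaffold(g5)
    expect_true(isIsomorphic(g5, adjToGraph(oracleContractLinkers(A), 5L)))
    expect_true(isIsomorphic(g4, adjToGraph(oracleContractTopology(
      oracleContractLinkers(A)), 4L)))
    # level-5/4 outputs are fixed points; level 6/7 transforms idempotent
    expect_identical(canonicalKey(pruneLinkers(g5), 5L), canonicalKey(g5))
    g4b <- opreaScaffold(new("ScaffoldGraph", level = 5L, atoms = atoms(g4),
                             bonds = bonds(g4)))
    expect_identical(canonicalKey(g4b, 4L), canonicalKey(g4))
    # Oprea minimality: every remaining degree-2 vertex sits in a triangle
    B <- graphToAdj(g4)
    for (v in which(rowSums(B) == 2)) {
      nb <- which(B[v, ])
      expect_true(B[nb[1], nb[2]])
    }
  }
})

test_that("CSSR finds complete smallest-ring sets", {
  ringsOf <- function(smi) cssrRings(graphFramework(clearStereo(
    murckoFramework(parseOne(smi)))))
  expect_length(ringsOf("c1ccccc1"), 1)
  expect_length(ringsOf("c1ccc2ccccc2c1"), 2)
  # cube graph: 6 four-membered rings where SSSR keeps 5
  cube <- scaffoldmap:::.abstractGraph(
    6L, 8L, c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L),
    c(2L, 3L, 4L, 1L, 5L, 6L, 7L, 8L, 6L, 7L, 8L, 5L))
  rings <- cssrRings(cube)
  expect_length(rings, 6)
  expect_true(all(vapply(rings, function(r) length(r$vertices), 0L) == 4))
  # matches the exhaustive-enumeration oracle on random graphs
  set.seed(7)
  for (i in 1:40) {
    A <- randomGraph(12)
    got <- cssrRings(adjToGraph(A, 6L))
    want <- oracleCSSR(A)
    gotSigs <- sort(unname(vapply(got, function(r)
      paste(r$edges, collapse = ";"), "")))
    wantSigs <- sort(unname(vapply(want, function(p) {
      nxt <- c(p[-1], p[1])
      paste(sort(paste0(pmin(p, nxt), "-", pmax(p, nxt))), collapse = ";")
    }, "")))
    expect_identical(gotSigs, wantSigs)
  }
})

test_that("ring connectivity distinguishes fused, spiro and linked rings", {
  l3Of <- function(smi) scaffoldChain(parseOne(smi))[["L3"]]
  expect_identical(l3Of("c1ccc2ccccc2c1"), "2:1-2s")        # fused: strong
  expect_identical(l3Of("c1ccc(-c2ccccc2)cc1"), "2:1-2w")   # linked: weak
  expect_identical(l3Of("C1CCCC12CCCCC2"), "2:1-2w")        # spiro: weak
  # anthracene: linear path, no terminal-ring edge (ring edges are excluded
  # from the linker path search)
  expect_identical(l3Of("c1ccc2cc3ccccc3cc2c1"), "3:1-3s,2-3s")
  anth <- keyToGraph(3, l3Of("c1ccc2cc3ccccc3cc2c1"))
  expect_equal(nrow(bonds(anth)), 2)
  expect_true(all(bonds(anth)$order == 2L))
})

test_that("level-3 strong edges equal shared-edge pairs (brute-force check)", {
  set.seed(23)
  reps <- 0
  while (reps < 25) {
    A <- randomGraph(14)
    g4 <- opreaScaffold(pruneLinkers(adjToGraph(A, 6L)))
    rings <- cssrRings(g4)
    if (length(rings) < 2 || length(rings) > 8) next
    reps <- reps + 1
    l3 <- ringConnectivity(g4)
    b <- bonds(l3)
    strongGot <- sort(paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))[b$order == 2L])
    strongWant <- character(0)
    for (i in seq_along(rings)) for (j in seq_along(rings)) if (i < j) {
      if (length(intersect(rings[[i]]$edges, rings[[j]]$edges)) > 0)
        strongWant <- c(strongWant, paste(i, j))
    }
    expect_identical(strongGot, sort(strongWant))
  }
})

test_that("level 2 collapses strength; level 1 counts rings", {
  naph <- scaffoldChain(parseOne("c1ccc2ccccc2c1"))
  bip <- scaffoldChain(parseOne("c1ccc(-c2ccccc2)cc1"))
  expect_identical(naph[["L2"]], bip[["L2"]])
  expect_false(naph[["L3"]] == bip[["L3"]])
  two <- scaffoldChain(parseOne("c1ccccc1.c1ccccc1"))
  expect_identical(two[["L2"]], "2:")
  expect_identical(scaffoldChain(parseOne("c1ccccc1"))[["L1"]], "1")
  expect_identical(scaffoldChain(parseOne("CC"))[["L1"]], "0")
  # hydrocortisone: ring count 4, verified against the enumeration oracle
  hc <- graphFramework(clearStereo(murckoFramework(standardizeMolecule(
    parseOne(DRUG_SMILES[["hydrocortisone"]])))))
  expect_identical(scaffoldChain(parseOne(DRUG_SMILES[["hydrocortisone"]]))[["L1"]],
                   "4")
  expect_length(oracleCSSR(graphToAdj(hc)), 4)
})

test_that("cycle counts are conserved through levels 6 -> 5 -> 4 on fixtures", {
  lib <- generateFixtureLibrary(500, seed = 77)
  reps <- !duplicated(lib$chains[, "L6"])
  for (m in lib$molecules[reps]) {
    g6 <- graphFramework(clearStereo(murckoFramework(m)))
    g5 <- pruneLinkers(g6)
    g4 <- opreaScaffold(g5)
    n6 <- length(cssrRings(g6))
    expect_equal(length(cssrRings(g5)), n6)
    expect_equal(length(cssrRings(g4)), n6)
  }
  # and across the whole library the ring-count key equals the CSSR count
  expect_identical(unname(lib$chains[, "L1"]),
                   vapply(lib$molecules, function(m)
                     as.character(length(cssrRings(graphFramework(
                       clearStereo(murckoFramework(m)))))), ""))
})

test_that("every level-k key is computable from the level-(k+1) key alone", {
  lib <- generateFixtureLibrary(120, seed = 17)
  ch <- lib$chains
  for (k in 8:2) {
    for (key in unique(ch[, k])) {
      want <- unique(ch[ch[, k] == key, k - 1])
      expect_length(want, 1)
      expect_identical(parentKey(k, key), want)
    }
  }
  expect_identical(parentKey(2, "-"), "0")
  expect_identical(parentKey(1, "0"), "ROOT")
})
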