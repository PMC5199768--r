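# Molecule I/O, standardization and canonical keys.

test_that("SMILES files read with names, skip counting and gzip support", {
  tf <- writeSmiFile(c("c1ccccc1 benzene", "CCO ethanol"))
  r <- readMolecules(tf)
  expect_length(r$molecules, 2)
  expect_equal(r$skipped, 0)
  expect_equal(vapply(r$molecules, molName, ""), c("benzene", "ethanol"))
  expect_equal(nrow(atoms(r$molecules[[1]])), 6)

  tf2 <- writeSmiFile(c("c1ccccc1 benzene", "not_a_smiles oops", "CCO ethanol"))
  expect_message(r2 <- readMolecules(tf2), "skipped")
  expect_length(r2$molecules, 2)
  expect_equal(r2$skipped, 1)
  expect_equal(vapply(r2$molecules, molName, ""), c("benzene", "ethanol"))

  expect_error(readMolecules(tempfile()), "does not exist")
})

test_that("gzipped SDF reads transparently and format is auto-detected", {
  mols <- parseSmi(c("c1ccccc1", "CCO", "Cc1ccccc1", "C1CCCCC1"),
                   names = paste0("m", 1:4))
  plain <- tempfile(fileext = ".sdf")
  writeMolecules(mols, plain, format = "sdf")
  gz <- paste0(plain, ".gz")
  con <- gzfile(gz, "w")
  writeLines(readLines(plain), con)
  close(con)
  r <- readMolecules(gz)   # extension-based detection through .gz
  expect_length(r$molecules, 4)
  expect_equal(r$skipped, 0)
  expect_equal(vapply(r$molecules, molName, ""), paste0("m", 1:4))
})

test_that("read -> write -> read round-trips count and structures", {
  lib <- generateFixtureLibrary(25, seed = 5)
  for (fmt in c("sdf", "smiles")) {
    tf <- tempfile(fileext = if (fmt == "sdf") ".sdf" else ".smi")
    writeMolecules(lib$molecules, tf, format = fmt)
    back <- readMolecules(tf)
    expect_length(back$molecules, 25)
    expect_equal(scaffoldChains(back$molecules), lib$chains)
  }
})

test_that("standardization neutralizes, strips isotopes/hydrogens, is idempotent", {
  m <- standardizeMolecule(parseOne("CC(=O)[O-]"))
  expect_true(all(atoms(m)$charge == 0L))

  m13 <- standardizeMolecule(parseOne("[13CH4]"))
  expect_true(all(atoms(m13)$isotope == 0L))

  mh <- standardizeMolecule(parseOne("[H]OC([H])([H])C"))
  expect_false(any(atoms(mh)$elem == "H"))

  # kekule benzene gains aromatic flags; graph unchanged
  mb <- standardizeMolecule(parseOne("C1=CC=CC=C1"))
  expect_equal(nrow(atoms(mb)), 6)
  expect_true(all(atoms(mb)$aromatic))
  expect_true(all(bonds(mb)$aromatic))

  # quaternary ammonium cannot be neutralized: charge kept, reported
  expect_message(mq <- standardizeMolecule(parseOne("C[N+](C)(C)C")),
                 "could not be neutralized")
  expect_equal(sum(atoms(mq)$charge), 1L)
  # ammonium and carboxylate of a zwitterion both neutralize
  mz <- standardizeMolecule(parseOne("[NH3+]CC(=O)[O-]"))
  expect_true(all(atoms(mz)$charge == 0L))

  lib <- generateFixtureLibrary(20, seed = 9)
  once <- standardizeMolecules(lib$molecules)
  twice <- standardizeMolecules(once)
  expect_equal(lapply(twice, atoms), lapply(once, atoms))
  expect_equal(lapply(twice, bonds), lapply(once, bonds))
})

test_that("disconnected structures are kept whole, never largest-fragment", {
  m <- parseOne("c1ccccc1.c1ccccc1")
  expect_equal(nrow(atoms(m)), 12)
  ch <- scaffoldChain(m)
  expect_equal(ch[["L1"]], "2")
  expect_equal(ch[["L2"]], "2:")      # two rings, zero edges
  single <- scaffoldChain(parseOne("c1ccc(-c2ccccc2)cc1"))
  expect_false(ch[["L2"]] == single[["L2"]])  # distinct from connected pair
})

test_that("canonical keys are invariant under vertex permutation", {
  set.seed(421)
  for (rep in 1:4) {
    A <- randomGraph(12)
    n <- nrow(A)
    idx <- which(A & upper.tri(A), arr.ind = TRUE)
    k0 <- canonicalKey(scaffoldmap:::.abstractGraph(6L, n, idx[, 1], idx[, 2]))
    ord <- sample(c(1L, 2L), nrow(idx), replace = TRUE)
    k0lab <- canonicalKey(scaffoldmap:::.abstractGraph(3L, n, idx[, 1],
                                                       idx[, 2], ord))
    for (i in 1:30) {
      p <- sample(n)
      expect_identical(canonicalKey(
        scaffoldmap:::.abstractGraph(6L, n, p[idx[, 1]], p[idx[, 2]])), k0)
      sh <- sample(nrow(idx))
      expect_identical(canonicalKey(
        scaffoldmap:::.abstractGraph(3L, n, p[idx[sh, 1]], p[idx[sh, 2]],
                                     ord[sh])), k0lab)
    }
  }
})

test_that("canonical key degenerate and equivalence cases", {
  empty <- new("ScaffoldGraph", level = 5L)
  expect_identical(canonicalKey(empty), "-")
  # naphthalene and decalin share the fused-pair connectivity key
  naph <- scaffoldChain(parseOne("c1ccc2ccccc2c1"))
  deca <- scaffoldChain(parseOne("C1CCC2CCCCC2C1"))
  expect_identical(naph[["L3"]], deca[["L3"]])
  expect_false(naph[["L7"]] == deca[["L7"]])
  # benzene key identical from two written forms
  k1 <- scaffoldChain(parseOne("c1ccccc1"))[["L7"]]
  k2 <- scaffoldChain(parseOne("C1=CC=CC=C1"))[["L7"]]
  expect_identical(k1, k2)
})

test_that("fixture generator is deterministic with exact 8-key chains", {
  a <- generateFixtureLibrary(100, seed = 7)
  b <- generateFixtureLibrary(100, seed = 7)
  expect_identical(a$table, b$table)
  expect_identical(a$chains, b$chains)
  expect_equal(dim(a$chains), c(100, 8))
  expect_true(all(nzchar(a$chains)))
  # pinned vocabulary: benzene plus one methyl is toluene
  tol <- generateFixtureLibrary(1, seed = 1, cores = "benzene",
                                sideChains = "C", sideChainRange = c(1L, 1L))
  toluene <- scaffoldChain(parseOne("Cc1ccccc1"))
  expect_identical(scaffoldChain(tol$molecules[[1]]), toluene)
  expect_equal(tol$chains[1, "L1"], "1")
  # chains agree with the engine
  expect_equal(scaffoldChains(a$molecules), a$chains)
})
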