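# Hierarchy store: build, merge, CSV persistence, annotation, queries.

test_that("building inserts chains with per-level conservation", {
  h0 <- buildHierarchy(list())
  expect_equal(moleculeCount(h0), 0)
  expect_equal(nrow(hierarchyNodes(h0)), 1)  # root only

  # three decorated benzenes share one chain: one node per level, freq 3
  mols <- parseSmi(c("Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1"))
  h <- buildHierarchy(mols)
  nd <- hierarchyNodes(h)
  expect_equal(moleculeCount(h), 3)
  for (lev in 1:8) {
    expect_equal(sum(nd$level == lev), 1)
    expect_equal(nd$backgroundFreq[nd$level == lev], 3)
  }

  # benzene + biphenyl + naphthalene: ring-count split 1 vs 2, and the
  # two-ring branch splits into strong and weak pairs at level 3
  mols2 <- parseSmi(c("c1ccccc1", "c1ccc(-c2ccccc2)cc1", "c1ccc2ccccc2c1"))
  h2 <- buildHierarchy(mols2)
  nd2 <- hierarchyNodes(h2)
  expect_equal(nd2$backgroundFreq[nd2$level == 1 & nd2$key == "1"], 1)
  expect_equal(nd2$backgroundFreq[nd2$level == 1 & nd2$key == "2"], 2)
  l3kids <- hierarchyChildren(h2, 2, nd2$key[nd2$level == 2 &
                                               nd2$backgroundFreq == 2])
  expect_equal(nrow(l3kids), 2)
  expect_setequal(l3kids$key, c("2:1-2s", "2:1-2w"))

  # conservation + tree property on a seeded library build
  lib <- generateFixtureLibrary(150, seed = 21)
  hb <- buildHierarchy(lib$molecules)
  ndb <- hierarchyNodes(hb)
  for (lev in 0:8)
    expect_equal(sum(ndb$backgroundFreq[ndb$level == lev]), 150)
  expect_true(validObject(hb))
  # childCount equals an independent recount of distinct children
  for (lev in 0:7) {
    for (k in ndb$key[ndb$level == lev]) {
      expect_equal(ndb$childCount[ndb$level == lev & ndb$key == k],
                   sum(ndb$level == lev + 1 & ndb$parent == k))
    }
  }
})

test_that("merge adds frequencies, is associative/commutative, identity on empty", {
  lib <- generateFixtureLibrary(120, seed = 33)
  full <- buildHierarchy(lib$molecules)
  a <- buildHierarchy(lib$molecules[1:50])
  b <- buildHierarchy(lib$molecules[51:120])
  m <- mergeHierarchies(a, b)
  expect_equal(moleculeCount(m), 120)
  expect_identical(hierarchyNodes(m), hierarchyNodes(full))
  expect_identical(hierarchyNodes(mergeHierarchies(b, a)),
                   hierarchyNodes(m))
  empty <- buildHierarchy(list())
  expect_identical(hierarchyNodes(mergeHierarchies(full, empty)),
                   hierarchyNodes(full))
  c3 <- buildHierarchy(lib$molecules[1:40])
  d3 <- buildHierarchy(lib$molecules[41:80])
  e3 <- buildHierarchy(lib$molecules[81:120])
  expect_identical(
    hierarchyNodes(mergeHierarchies(mergeHierarchies(c3, d3), e3)),
    hierarchyNodes(mergeHierarchies(c3, mergeHierarchies(d3, e3))))
})

test_that("CSV export/load round-trips losslessly and rejects malformed rows", {
  lib <- generateFixtureLibrary(80, seed = 4)
  h <- buildHierarchy(lib$molecules)
  tf <- tempfile(fileext = ".csv")
  exportHierarchyCSV(h, tf)
  h2 <- loadHierarchyCSV(tf)
  expect_identical(hierarchyNodes(h2), hierarchyNodes(h))
  expect_equal(moleculeCount(h2), moleculeCount(h))

  # root-only hierarchy: header + 1 row
  tf0 <- tempfile(fileext = ".csv")
  exportHierarchyCSV(buildHierarchy(list()), tf0)
  expect_length(readLines(tf0), 2)

  # hand-written 9-row CSV describing one benzene-chain molecule
  ch <- scaffoldChain(parseOne("c1ccccc1"))
  q <- function(x) paste0('"', x, '"')  # RFC-4180 quoting (keys hold commas)
  hand <- c("level,key,parent_key,background_freq,child_count",
            "0,ROOT,,1,1",
            paste(1, q(ch[["L1"]]), "ROOT", 1, 1, sep = ","),
            vapply(2:8, function(k)
              paste(k, q(ch[[paste0("L", k)]]), q(ch[[paste0("L", k - 1)]]),
                    1, as.integer(k < 8), sep = ","), ""))
  tfh <- tempfile(fileext = ".csv")
  writeLines(hand, tfh)
  hh <- loadHierarchyCSV(tfh)
  expect_equal(moleculeCount(hh), 1)
  expect_equal(nrow(hierarchyNodes(hh)), 9)

  # malformed row reported by number
  bad <- readLines(tf)
  bad[3] <- sub("^[0-9]+", "99", bad[3])
  tfb <- tempfile(fileext = ".csv")
  writeLines(bad, tfb)
  expect_error(loadHierarchyCSV(tfb), "row")
  expect_error(loadHierarchyCSV(tempfile()), "no such file")
})

test_that("annotation fills dataset frequencies and adds missing scaffolds", {
  bg <- buildHierarchy(parseSmi(c("c1ccccc1", "c1ccc2ccccc2c1")))
  ann <- annotateHierarchy(bg, parseSmi("Cc1ccccc1"))
  nd <- hierarchyNodes(ann$hierarchy)
  benzeneChain <- scaffoldChain(parseOne("c1ccccc1"))
  for (lev in 1:8) {
    row <- nd[nd$level == lev & nd$key == benzeneChain[[paste0("L", lev)]], ]
    expect_equal(row$datasetFreq, 1)
    expect_equal(row$backgroundFreq, 1)
  }
  expect_equal(nrow(ann$chains), 1)
  expect_match(names(ann$chains), "^(id|name|L[1-8])$", all = TRUE)

  # user scaffolds absent from the background appear with backgroundFreq 0
  ann0 <- annotateHierarchy(buildHierarchy(list()), parseSmi("c1ccccc1"))
  nd0 <- hierarchyNodes(ann0$hierarchy)
  expect_true(all(nd0$backgroundFreq[nd0$level > 0] == 0))
  expect_true(all(nd0$datasetFreq == 1))

  # per-level dataset totals equal the user molecule count
  lib <- generateFixtureLibrary(90, seed = 12)
  bg2 <- buildHierarchy(lib$molecules[1:60])
  ann2 <- annotateHierarchy(bg2, lib$molecules[31:90])
  nd2 <- hierarchyNodes(ann2$hierarchy)
  for (lev in 0:8) {
    expect_equal(sum(nd2$datasetFreq[nd2$level == lev]), 60)
    expect_equal(sum(nd2$backgroundFreq[nd2$level == lev]), 60)
  }
})

test_that("subtree views and ancestor paths follow the tree", {
  mols <- parseSmi(c("c1ccccc1", "c1ccc(-c2ccccc2)cc1", "c1ccc2ccccc2c1"))
  h <- buildHierarchy(mols)
  sub <- hierarchySubtree(h, 1, "2")
  expect_equal(moleculeCount(sub), 2)
  expect_true(all(hierarchyNodes(sub)$level >= 1))

  whole <- hierarchySubtree(h, 0, "ROOT")
  expect_identical(hierarchyNodes(whole), hierarchyNodes(h))

  ch <- scaffoldChain(parseOne("c1ccc2ccccc2c1"))
  anc <- scaffoldAncestors(h, 8, ch[["L8"]])
  expect_equal(nrow(anc), 8)
  expect_equal(anc$level, 0:7)
  expect_equal(anc$key[1], "ROOT")
  expect_equal(anc$key[-1],
               unname(ch[paste0("L", 1:7)]))
  expect_error(hierarchySubtree(h, 3, "no-such-key"), "no such scaffold")
})
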