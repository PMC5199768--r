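# Low-level molfile/OpenBabel plumbing.
#
# Structures travel to and from OpenBabel as V2000 molfile text. Parsing of
# SDF records is done by ChemmineR::read.SDFset; the charge / isotope /
# radical property lines (M CHG, M ISO, M RAD), which ChemmineR does not
# surface, are re-read from the raw record text. Writing is done by a small
# formatter here because no installed package builds molfiles from
# programmatic atom/bond tables.

# molfile charge codes <-> formal charges (code 4 is a doublet radical)
.CHG_FROM_CODE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)

.obConvert <- function(from, to, text) {
  if (!nzchar(text)) return("")
  ChemmineOB::convertFormat(from, to, source = text)
}

# Canonical SMILES for one or more molfile records (text must end in $$$$).
# Returns a character vector of one SMILES per record, aligned via titles.
.canonicalSmiles <- function(sdfText, n) {
  out <- .obConvert("SDF", "CAN", sdfText)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, "", 1L)
  ttl <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  if (!missing(n) && length(smi) != n)
    stop("canonical SMILES conversion lost records (", length(smi), "/", n, ")")
  names(smi) <- ttl
  smi
}

.molfileText <- function(atoms, bonds, title = "") {
  na <- nrow(atoms); nb <- nrow(bonds)
  chiral <- as.integer(any(atoms$parity > 0L))
  counts <- sprintf("%3d%3d  0  0%3d  0  0  0  0  0999 V2000", na, nb, chiral)
  head <- c(title, " scaffoldmap", "", counts)
  alines <- character(na)
  if (na > 0) {
    code <- integer(na)
    code[atoms$charge == 3L] <- 1L; code[atoms$charge == 2L] <- 2L
    code[atoms$charge == 1L] <- 3L; code[atoms$charge == -1L] <- 5L
    code[atoms$charge == -2L] <- 6L; code[atoms$charge == -3L] <- 7L
    alines <- sprintf("%10.4f%10.4f%10.4f %-3s 0%3d%3d  0  0  0  0  0  0  0  0  0",
                      atoms$x, atoms$y, atoms$z, atoms$elem, code, atoms$parity)
  }
  blines <- character(nb)
  if (nb > 0)
    blines <- sprintf("%3d%3d%3d%3d  0  0  0", bonds$a1, bonds$a2,
                      pmin(bonds$order, 4L), bonds$wedge)
  prop <- character(0)
  .mprop <- function(tag, idx, val) {
    out <- character(0)
    while (length(idx) > 0) {
      k <- min(8L, length(idx))
      out <- c(out, paste0("M  ", tag, sprintf("%3d", k),
                           paste0(sprintf("%4d%4d", idx[seq_len(k)],
                                          val[seq_len(k)]), collapse = "")))
      idx <- idx[-seq_len(k)]; val <- val[-seq_len(k)]
    }
    out
  }
  ic <- which(atoms$charge != 0L)
  if (length(ic)) prop <- c(prop, .mprop("CHG", ic, atoms$charge[ic]))
  ii <- which(atoms$isotope != 0L)
  if (length(ii)) prop <- c(prop, .mprop("ISO", ii, atoms$isotope[ii]))
  ir <- which(atoms$radical != 0L)
  if (length(ir)) prop <- c(prop, .mprop("RAD", ir, atoms$radical[ir]))
  paste(c(head, alines, blines, prop, "M  END", "$$$$"), collapse = "\n")
}

.molfileOf <- function(x, title = "") {
  .molfileText(x@atoms, x@bonds, title)
}

# Parse the M CHG / M ISO / M RAD property lines of one raw sdf record.
.parsePropLines <- function(lines, tag) {
  sel <- grep(paste0("^M  ", tag), lines, value = TRUE)
  if (!length(sel)) return(NULL)
  out <- integer(0); idx <- integer(0)
  for (ln in sel) {
    flds <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    k <- flds[1]
    pairs <- flds[-1]
    idx <- c(idx, pairs[seq(1, 2 * k, by = 2)])
    out <- c(out, pairs[seq(2, 2 * k, by = 2)])
  }
  stats::setNames(out, idx)
}

# Convert one ChemmineR::SDF record (+ its raw text lines) into a Molecule.
.sdfToMolecule <- function(sdf, rawLines, id) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  na <- nrow(ab)
  elem <- sub("_.*$", "", rownames(ab))
  chgcode <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else integer(na)
  parity <- if ("C7" %in% colnames(ab)) as.integer(ab[, "C7"]) else integer(na)
  charge <- integer(na)
  known <- as.character(chgcode) %in% names(.CHG_FROM_CODE)
  charge[known] <- .CHG_FROM_CODE[as.character(chgcode[known])]
  radical <- ifelse(chgcode == 4L, 2L, 0L)
  isotope <- integer(na)
  if (!is.null(rawLines)) {
    chg <- .parsePropLines(rawLines, "CHG")
    if (!is.null(chg)) { charge[] <- 0L; charge[as.integer(names(chg))] <- chg }
    iso <- .parsePropLines(rawLines, "ISO")
    if (!is.null(iso)) isotope[as.integer(names(iso))] <- iso
    rad <- .parsePropLines(rawLines, "RAD")
    if (!is.null(rad)) { radical[] <- 0L; radical[as.integer(names(rad))] <- rad }
  }
  atomsDf <- data.frame(elem = elem, x = ab[, "C1"], y = ab[, "C2"],
                        z = ab[, "C3"], charge = charge, isotope = isotope,
                        radical = radical, parity = parity,
                        aromatic = FALSE, stringsAsFactors = FALSE)
  rownames(atomsDf) <- NULL
  if (is.null(dim(bb)) || nrow(bb) == 0) {
    bondsDf <- .emptyBonds()
  } else {
    bondsDf <- data.frame(a1 = as.integer(bb[, "C1"]),
                          a2 = as.integer(bb[, "C2"]),
                          order = as.integer(bb[, "C3"]),
                          wedge = if ("C4" %in% colnames(bb))
                            as.integer(bb[, "C4"]) else 0L,
                          aromatic = FALSE, stringsAsFactors = FALSE)
    rownames(bondsDf) <- NULL
  }
  name <- tryCatch(ChemmineR::sdfid(sdf), error = function(e) NA_character_)
  if (is.null(name) || !length(name) || !nzchar(trimws(name[1])))
    name <- NA_character_
  new("Molecule", id = as.character(id), name = trimws(name[1]),
      atoms = atomsDf, bonds = bondsDf, standardized = FALSE)
}

# Fixed-width V2000 fallback for records ChemmineR refuses (e.g. molecules
# without bonds, which validSDF flags as invalid).
.parseMolfileFallback <- function(rec, id) {
  counts <- rec[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1L) stop("no atoms")
  aLines <- rec[5:(4 + na)]
  num <- function(s, a, b) as.numeric(substr(s, a, b))
  chgcode <- as.integer(num(aLines, 37, 39))
  chgcode[is.na(chgcode)] <- 0L
  charge <- integer(na)
  known <- as.character(chgcode) %in% names(.CHG_FROM_CODE)
  charge[known] <- .CHG_FROM_CODE[as.character(chgcode[known])]
  parity <- as.integer(num(aLines, 40, 42))
  parity[is.na(parity)] <- 0L
  atomsDf <- data.frame(elem = trimws(substr(aLines, 32, 34)),
                        x = num(aLines, 1, 10), y = num(aLines, 11, 20),
                        z = num(aLines, 21, 30), charge = charge,
                        isotope = 0L,
                        radical = ifelse(chgcode == 4L, 2L, 0L),
                        parity = parity, aromatic = FALSE,
                        stringsAsFactors = FALSE)
  bondsDf <- .emptyBonds()
  if (!is.na(nb) && nb > 0L) {
    bLines <- rec[(5 + na):(4 + na + nb)]
    wedge <- as.integer(num(bLines, 10, 12))
    wedge[is.na(wedge)] <- 0L
    bondsDf <- data.frame(a1 = as.integer(num(bLines, 1, 3)),
                          a2 = as.integer(num(bLines, 4, 6)),
                          order = as.integer(num(bLines, 7, 9)),
                          wedge = wedge, aromatic = FALSE,
                          stringsAsFactors = FALSE)
  }
  chg <- .parsePropLines(rec, "CHG")
  if (!is.null(chg)) { atomsDf$charge[] <- 0L
    atomsDf$charge[as.integer(names(chg))] <- chg }
  iso <- .parsePropLines(rec, "ISO")
  if (!is.null(iso)) atomsDf$isotope[as.integer(names(iso))] <- iso
  rad <- .parsePropLines(rec, "RAD")
  if (!is.null(rad)) { atomsDf$radical[] <- 0L
    atomsDf$radical[as.integer(names(rad))] <- rad }
  name <- trimws(rec[1])
  new("Molecule", id = as.character(id),
      name = if (nzchar(name)) name else NA_character_,
      atoms = atomsDf, bonds = bondsDf, standardized = FALSE)
}

# Parse multi-record SDF text into Molecules; invalid records are skipped
# and counted, never aborting the batch. The whole batch is parsed in one
# ChemmineR call; a per-record fallback handles files that break bulk
# parsing.
.parseSdfText <- function(text, ids = NULL) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) return(list(molecules = list(), skipped = 0L))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  recs <- lapply(seq_along(ends), function(i) lines[starts[i]:ends[i]])
  if (is.null(ids)) ids <- seq_along(recs)

  parseOne <- function(rec, id) {
    tryCatch({
      tf <- tempfile(fileext = ".sdf")
      on.exit(unlink(tf))
      writeLines(rec, tf)
      sset <- suppressWarnings(ChemmineR::read.SDFset(tf))
      if (!isTRUE(ChemmineR::validSDF(sset)[1])) stop("invalid record")
      .sdfToMolecule(sset[[1]], rec, id)
    }, error = function(e)
      tryCatch(.parseMolfileFallback(rec, id), error = function(e2) NULL))
  }

  bulk <- tryCatch({
    tf <- tempfile(fileext = ".sdf")
    on.exit(unlink(tf))
    writeLines(lines, tf)
    sset <- suppressWarnings(ChemmineR::read.SDFset(tf))
    if (length(sset) != length(recs)) stop("record count mismatch")
    sset
  }, error = function(e) NULL)

  mols <- vector("list", length(recs))
  ok <- logical(length(recs))
  if (!is.null(bulk)) {
    valid <- suppressWarnings(ChemmineR::validSDF(bulk))
    for (i in seq_along(recs)) {
      m <- if (isTRUE(valid[i]))
        tryCatch(.sdfToMolecule(bulk[[i]], recs[[i]], ids[i]),
                 error = function(e) NULL)
      else
        tryCatch(.parseMolfileFallback(recs[[i]], ids[i]),
                 error = function(e) NULL)
      if (!is.null(m)) { mols[[i]] <- m; ok[i] <- TRUE }
    }
  } else {
    for (i in seq_along(recs)) {
      m <- parseOne(recs[[i]], ids[i])
      if (!is.null(m)) { mols[[i]] <- m; ok[i] <- TRUE }
    }
  }
  list(molecules = mols[ok], skipped = sum(!ok))
}

.componentsOf <- function(m) {
  n <- nrow(m@atoms)
  if (n == 0) return(integer(0))
  g <- igraph::graph_from_edgelist(as.matrix(m@bonds[, c("a1", "a2")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership
}
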