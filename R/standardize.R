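# Structure standardization: the level-8 preprocessing of every molecule.

.STD_VALENCE <- c(B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L, P = 3L,
                  S = 2L, Cl = 1L, Se = 2L, Br = 1L, I = 1L, As = 3L)

#' Standardize a molecule
#'
#' Applies the structure normalization performed before scaffold
#' extraction: aromatic perception, charge neutralization, removal of
#' explicit hydrogens and radical flags, and clearing of isotope labels.
#'
#' Neutralization adds or removes implicit protons where the resulting
#' valence is standard: anions not adjacent to a positively charged atom are
#' protonated; cations that still carry a proton are deprotonated. Charges
#' that cannot be fixed this way (e.g. quaternary ammonium, or the
#' charge-separated pair of a nitro group) are retained and reported once
#' per call via a message.
#'
#' Standardization is idempotent.
#'
#' @param m a [Molecule-class].
#' @return the standardized [Molecule-class].
#' @export
standardizeMolecule <- function(m) {
  standardizeMolecules(list(m))[[1]]
}

#' @rdname standardizeMolecule
#' @param mols list of [Molecule-class] objects (batched variant; aromatic
#'   perception is performed in a single OpenBabel pass).
#' @export
standardizeMolecules <- function(mols) {
  if (!length(mols)) return(mols)
  keptCharges <- 0L
  out <- lapply(mols, function(m) {
    a <- m@atoms; b <- m@bonds
    a$isotope <- 0L
    a$radical <- 0L
    # drop explicit (terminal) hydrogens
    isH <- a$elem %in% c("H", "D", "T")
    if (any(isH)) {
      degH <- tabulate(c(b$a1, b$a2), nbins = nrow(a))
      drop <- which(isH & degH <= 1L)
      if (length(drop)) {
        keepMask <- !(seq_len(nrow(a)) %in% drop)
        remap <- cumsum(keepMask)
        keepB <- !(b$a1 %in% drop) & !(b$a2 %in% drop)
        b <- b[keepB, , drop = FALSE]
        b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
        a <- a[keepMask, , drop = FALSE]
        rownames(a) <- NULL; rownames(b) <- NULL
      }
    }
    # neutralize charges where a standard valence results
    if (any(a$charge != 0L)) {
      ord <- ifelse(b$order == 4L, 1.5, b$order)
      bondsum <- numeric(nrow(a))
      for (k in seq_len(nrow(b))) {
        bondsum[b$a1[k]] <- bondsum[b$a1[k]] + ord[k]
        bondsum[b$a2[k]] <- bondsum[b$a2[k]] + ord[k]
      }
      stdv <- .STD_VALENCE[a$elem]
      adjPos <- logical(nrow(a))
      pos <- which(a$charge > 0L)
      if (length(pos)) {
        touch <- b$a1 %in% pos | b$a2 %in% pos
        adjPos[c(b$a1[touch], b$a2[touch])] <- TRUE
        adjPos[pos] <- FALSE
      }
      neutNeg <- a$charge < 0L & !is.na(stdv) & !adjPos & bondsum <= stdv
      neutPos <- a$charge > 0L & !is.na(stdv) &
        (stdv + a$charge - bondsum) > 0
      a$charge[neutNeg | neutPos] <- 0L
      keptCharges <<- keptCharges + sum(a$charge != 0L)
    }
    m@atoms <- a; m@bonds <- b
    m
  })
  if (keptCharges > 0)
    message(keptCharges, " formal charge(s) could not be neutralized and were kept")
  # aromatic perception, one OpenBabel pass over the whole batch
  out <- .perceiveAromaticity(out)
  for (i in seq_along(out)) out[[i]]@standardized <- TRUE
  out
}

# Mark aromatic atoms/bonds using OpenBabel's perception, read back from
# mol2 (whose atom types and bond orders carry explicit "ar" marks and whose
# record layout preserves atom order).
.perceiveAromaticity <- function(mols) {
  nz <- which(vapply(mols, function(m) nrow(m@atoms) > 0, TRUE))
  if (!length(nz)) return(mols)
  sdf <- paste0(vapply(nz, function(i) {
    a <- mols[[i]]@atoms; b <- mols[[i]]@bonds
    a$parity <- rep(0L, nrow(a))  # stereo is irrelevant to aromaticity and
    b$wedge <- rep(0L, nrow(b))   # upsets the mol2 writer on partial centers
    .molfileText(a, b, paste0("SMREC", i))
  }, ""), collapse = "\n")
  m2 <- .obConvert("SDF", "MOL2", sdf)
  recs <- strsplit(m2, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  recs <- recs[nzchar(trimws(recs))]
  if (length(recs) != length(nz)) {
    warning("aromatic perception skipped (conversion mismatch)")
    return(mols)
  }
  for (k in seq_along(recs)) {
    i <- nz[k]
    lines <- strsplit(recs[[k]], "\n", fixed = TRUE)[[1]]
    aStart <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)
    bStart <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)
    if (!length(aStart) || !length(bStart)) next
    na <- nrow(mols[[i]]@atoms)
    atLines <- lines[(aStart + 1L):(aStart + na)]
    types <- vapply(strsplit(trimws(atLines), "\\s+"), `[`, "", 6L)
    mols[[i]]@atoms$aromatic <- grepl("\\.ar$", types)
    nb <- nrow(mols[[i]]@bonds)
    if (nb > 0) {
      bLines <- lines[(bStart + 1L):(bStart + nb)]
      fl <- strsplit(trimws(bLines), "\\s+")
      b1 <- vapply(fl, function(x) as.integer(x[2]), 0L)
      b2 <- vapply(fl, function(x) as.integer(x[3]), 0L)
      bar <- vapply(fl, function(x) x[4] == "ar", TRUE)
      keyIn <- paste(pmin(mols[[i]]@bonds$a1, mols[[i]]@bonds$a2),
                     pmax(mols[[i]]@bonds$a1, mols[[i]]@bonds$a2))
      keyM2 <- paste(pmin(b1, b2), pmax(b1, b2))
      mols[[i]]@bonds$aromatic <- bar[match(keyIn, keyM2)] %in% TRUE
    }
  }
  mols
}
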