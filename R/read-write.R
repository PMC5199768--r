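#' Read molecules from SMILES or SDF files
#'
#' Reads a molecule file in SMILES (one record per line, optional
#' whitespace-separated name) or SDF/Molfile V2000 format, transparently
#' decompressing gzip. Unparseable records never abort the stream: they are
#' skipped and counted.
#'
#' @param path path to the input file (plain or gzip-compressed).
#' @param format `"auto"` (default; detected from extension then content),
#'   `"smiles"` or `"sdf"`.
#' @return a list with elements `molecules` (list of [Molecule-class], in
#'   file order) and `skipped` (number of unparseable records).
#' @examples
#' tf <- tempfile(fileext = ".smi")
#' writeLines(c("c1ccccc1 benzene", "CCO ethanol"), tf)
#' lib <- readMolecules(tf)
#' length(lib$molecules)  # 2
#' lib$skipped            # 0
#' @export
readMolecules <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  lines <- readLines(gzfile(path), warn = FALSE)
  if (format == "auto") format <- .sniffFormat(path, lines)
  if (format == "sdf") {
    text <- paste(lines, collapse = "\n")
    res <- .parseSdfText(text)
  } else {
    res <- .parseSmilesLines(lines)
  }
  if (res$skipped > 0)
    message(res$skipped, " unparseable record(s) skipped")
  res
}

.sniffFormat <- function(path, lines) {
  base <- sub("\\.gz$", "", basename(path), ignore.case = TRUE)
  ext <- tolower(tools::file_ext(base))
  if (ext %in% c("smi", "smiles", "ism", "can")) return("smiles")
  if (ext %in% c("sdf", "sd", "mol", "mdl")) return("sdf")
  if (any(grepl("V2000|V3000", utils::head(lines, 10)))) return("sdf")
  "smiles"
}

# SMILES lines -> Molecules via OpenBabel. Conversion is batched; OpenBabel
# aborts a batch at the first bad record, so the batch is resumed after each
# failure, which both counts the skips and keeps alignment (verified through
# injected record titles).
.parseSmilesLines <- function(lines) {
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  if (!length(lines)) return(list(molecules = list(), skipped = 0L))
  smiles <- sub("[ \t].*$", "", lines)
  names <- ifelse(grepl("[ \t]", lines),
                  trimws(sub("^[^ \t]+[ \t]+", "", lines)), NA_character_)
  n <- length(smiles)
  sdfParts <- character(0); sdfIdx <- integer(0)
  idx <- 1L
  skipped <- 0L
  while (idx <= n) {
    span <- idx:n
    payload <- paste0(paste(smiles[span], paste0("SMREC", span)), "\n",
                      collapse = "")
    out <- .obConvert("SMI", "SDF", payload)
    got <- if (nzchar(out)) {
      titles <- regmatches(out, gregexpr("SMREC[0-9]+", out))[[1]]
      as.integer(sub("SMREC", "", unique(titles)))
    } else integer(0)
    if (length(got)) {
      stopifnot(identical(got, span[seq_along(got)]))
      sdfParts <- c(sdfParts, out)
      sdfIdx <- c(sdfIdx, got)
    }
    nxt <- idx + length(got)
    if (nxt <= n) skipped <- skipped + 1L  # record nxt failed to parse
    idx <- nxt + 1L
  }
  if (!length(sdfIdx)) return(list(molecules = list(), skipped = skipped))
  parsed <- .parseSdfText(paste(sdfParts, collapse = ""), ids = sdfIdx)
  skipped <- skipped + parsed$skipped
  mols <- parsed$molecules
  for (i in seq_along(mols)) {
    j <- as.integer(mols[[i]]@id)
    mols[[i]]@name <- names[j]
  }
  list(molecules = mols, skipped = skipped)
}

# Parse a character vector of SMILES strings (all expected valid).
.parseSmilesVector <- function(smiles, names = NULL) {
  res <- .parseSmilesLines(smiles)
  if (res$skipped > 0)
    stop(res$skipped, " SMILES failed to parse")
  if (!is.null(names))
    for (i in seq_along(res$molecules))
      res$molecules[[i]]@name <- names[as.integer(res$molecules[[i]]@id)]
  res$molecules
}

#' Write molecules to SMILES or SDF files
#'
#' The inverse of [readMolecules()]: writes a list of molecules as an SDF
#' file or as canonical-SMILES lines (with names where present). A
#' `.gz` suffix on `path` triggers gzip compression.
#'
#' @param mols list of [Molecule-class] objects.
#' @param path output path.
#' @param format `"smiles"` or `"sdf"`; default from the file extension.
#' @return invisibly, the number of records written.
#' @export
writeMolecules <- function(mols, path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") format <- .sniffFormat(path, character(0))
  con <- if (grepl("\\.gz$", path, ignore.case = TRUE)) gzfile(path, "w")
         else file(path, "w")
  on.exit(close(con))
  if (format == "sdf") {
    txt <- vapply(mols, function(m)
      .molfileText(m@atoms, m@bonds,
                   if (is.na(m@name)) m@id else m@name), "")
    writeLines(txt, con)
  } else {
    sdfAll <- paste0(vapply(seq_along(mols), function(i)
      .molfileText(mols[[i]]@atoms, mols[[i]]@bonds, paste0("SMREC", i)), ""),
      collapse = "\n")
    smi <- .canonicalSmiles(sdfAll, length(mols))
    nm <- vapply(mols, function(m) if (is.na(m@name)) "" else m@name, "")
    writeLines(trimws(paste(smi, nm)), con)
  }
  invisible(length(mols))
}
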