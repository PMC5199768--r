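# Shared molecule inputs for the tests. The four drugs are the worked
# examples of the hierarchy (DrugBank DB01050, DB01015, DB00829, DB00741).

DRUG_SMILES <- c(
  ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  sulfamethoxazole = "Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1",
  diazepam = "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc12",
  hydrocortisone = paste0("C[C@]12C[C@H](O)[C@H]3[C@@H](CCC4=CC(=O)CC[C@]43C)",
                          "[C@@H]1CC[C@@]2(O)C(=O)CO"))

parseSmi <- function(smiles, names = NULL) {
  scaffoldmap:::.parseSmilesVector(smiles, names)
}

parseOne <- function(smiles) parseSmi(smiles)[[1]]

writeSmiFile <- function(lines, ext = ".smi") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}
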