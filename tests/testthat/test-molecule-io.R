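# Peptide assembly, standardization and dataset reading.

# molecular formula of a SMILES via the chemistry backend (test oracle)
formulaOf <- function(smiles) UmamiQSAR:::.molFormula(smiles)

parseFormula <- function(f) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  counts <- integer(0)
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    n <- sub("^[A-Za-z]+", "", t)
    counts[el] <- sum(counts[el], if (nzchar(n)) as.integer(n) else 1L,
                      na.rm = TRUE)
  }
  counts
}

test_that("peptide assembly gives the right molecules", {
  canonical <- function(s) standardizeMolecule(s)$canonical_smiles
  expect_identical(canonical(peptideToSmiles("G")), canonical("NCC(=O)O"))
  expect_identical(formulaOf(peptideToSmiles("G")), "C2H5NO2")
  expect_identical(formulaOf(peptideToSmiles("GG")), "C4H8N2O3")
  expect_error(peptideToSmiles("GX"), "'X' at position 2")
  expect_error(peptideToSmiles(""), "empty")
})

test_that("peptide formulas equal summed residue formulas minus water", {
  # formula oracle: sum single-residue formulas, subtract (n-1) x H2O
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  resFormula <- lapply(aa, function(a) parseFormula(formulaOf(
    peptideToSmiles(a))))
  names(resFormula) <- aa
  set.seed(42)
  for (rep in 1:25) {
    len <- sample(2:8, 1)
    seqc <- sample(aa, len, replace = TRUE)
    expected <- Reduce(function(acc, a) {
      for (el in names(resFormula[[a]]))
        acc[el] <- sum(acc[el], resFormula[[a]][el], na.rm = TRUE)
      acc
    }, seqc, integer(0))
    expected["H"] <- expected["H"] - 2L * (len - 1L)
    expected["O"] <- expected["O"] - (len - 1L)
    got <- parseFormula(formulaOf(peptideToSmiles(
      paste(seqc, collapse = ""))))
    expect_equal(got[sort(names(got))],
                 expected[sort(names(expected))][names(got[sort(names(got))])],
                 info = paste(seqc, collapse = ""))
  }
})

test_that("standardization canonicalizes, strips salts and flags issues", {
  r <- standardizeMolecule("C1=CC=CC=C1")
  expect_identical(r$canonical_smiles, "c1ccccc1")
  expect_identical(r$issue_level, "none")
  expect_false(r$excluded)

  salt <- standardizeMolecule("[Na+].CC(=O)[O-]")
  parent <- standardizeMolecule("CC(=O)O")
  expect_identical(salt$canonical_smiles, parent$canonical_smiles)
  expect_identical(salt$issue_level, "low")

  bad <- standardizeMolecule("C(C)(C)(C)(C)C")
  expect_identical(bad$issue_level, "high")
  expect_true(bad$excluded)
  expect_match(bad$message, "valence")

  garbage <- standardizeMolecule("notasmiles!!")
  expect_true(garbage$excluded)
  expect_identical(garbage$issue_level, "high")
})

test_that("standardization is idempotent and drops stereochemistry", {
  inputs <- c("N[C@@H](C)C(=O)O", "C/C=C/C(=O)O",
              vapply(fixturePeptides(10, seed = 3)$input,
                     peptideToSmiles, character(1)))
  for (s in inputs) {
    once <- standardizeMolecule(s)
    expect_false(once$excluded)
    twice <- standardizeMolecule(once$canonical_smiles)
    expect_identical(twice$canonical_smiles, once$canonical_smiles)
    expect_false(grepl("@|/|\\\\", once$canonical_smiles))
  }
})

test_that("InChI input converts and standardizes like SMILES", {
  r <- standardizeMolecule("InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)",
                           notation = "inchi")
  expect_identical(r$canonical_smiles,
                   standardizeMolecule("CC(=O)O")$canonical_smiles)
  bad <- standardizeMolecule("InChI=nonsense", notation = "inchi")
  expect_true(bad$excluded)
})

test_that("dataset CSV reading validates schema and counts classes", {
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    id = c("a", "b", "c", "d"),
    input = c("CCO", "CCC", "EE", "KK"),
    notation = c("smiles", "smiles", "fasta_peptide", "fasta_peptide"),
    label = c(0, 0, 1, 1)), tmp, row.names = FALSE)
  ms <- readLabeledDataset(tmp, format = "csv")
  expect_s4_class(ms, "MoleculeSet")
  expect_identical(sum(molLabels(ms) == 1L), 2L)
  expect_identical(sum(molLabels(ms) == 0L), 2L)

  # duplicate canonical SMILES warns with both ids
  write.csv(data.frame(id = c("x", "y"), input = c("OCC", "CCO"),
                       notation = "smiles", label = c(0, 1)),
            tmp, row.names = FALSE)
  expect_warning(readLabeledDataset(tmp), "duplicate.*x.*y")

  # label outside {0,1} is rejected naming the row
  write.csv(data.frame(id = "z", input = "CCO", notation = "smiles",
                       label = 2), tmp, row.names = FALSE)
  expect_error(readLabeledDataset(tmp), "label.*row 1")

  # missing label column
  write.csv(data.frame(id = "z", input = "CCO", notation = "smiles"),
            tmp, row.names = FALSE)
  expect_error(readLabeledDataset(tmp), "missing column.*label")

  # empty file
  writeLines("id,input,notation,label", tmp)
  expect_error(readLabeledDataset(tmp), "empty")
})

test_that("smi and FASTA inputs round-trip through the readers", {
  tmp <- tempfile(fileext = ".smi")
  writeLines(c("CCO mol_a", "c1ccccc1 mol_b"), tmp)
  ms <- readLabeledDataset(tmp, format = "smi", labels = c(0L, 1L))
  expect_identical(molRecords(ms)$id, c("mol_a", "mol_b"))
  expect_identical(molLabels(ms), c(0L, 1L))

  fa <- tempfile(fileext = ".fasta")
  writePeptideFasta(fixturePeptides(6, seed = 9), fa)
  ms2 <- readLabeledDataset(fa, format = "fasta_pair")
  expect_identical(nrow(molRecords(ms2)), 6L)
  expect_true(all(molLabels(ms2) %in% c(0L, 1L)))
})
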