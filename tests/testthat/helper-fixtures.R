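# Shared fixtures built in code at test time.

# Small labeled peptide set (deterministic).
fixturePeptides <- function(n = 40, seed = 101) {
  makePeptideSet(n, lengthRange = c(2L, 6L), seed = seed)
}

# Canonical SMILES of a few named molecules used across tests.
fixtureSmiles <- function() {
  c(benzene = "c1ccccc1",
    hexane = "CCCCCC",
    glycine = "NCC(=O)O",
    ethanol = "CCO",
    acetic = "CC(=O)O",
    pyridine = "c1ccncc1")
}

# A trained desk-scale bundle, cached per session to keep the suite fast.
fixtureBundle <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    peps <- fixturePeptides(60, seed = 77)
    ms <- suppressWarnings(makeMoleculeSet(peps))
    cfg <- optimizerConfig(population = 8L, generations = 4L,
                           nFolds = 5L, nRuns = 1L, seed = 19L)
    cached <<- suppressWarnings(trainUmamiModel(ms, config = cfg))
    cached
  }
})

# Fixed-probability model for ensemble arithmetic checks.
fixedModel <- function(p, features = c("x1", "x2")) {
  new("UmamiModel", features = features, classifier = "fixed",
      fit = function(X) rep(p, nrow(X)), calibration = c(0, 1),
      seed = 1L, tag = sprintf("fixed_%g", p))
}
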