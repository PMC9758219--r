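# Parsing, conversion and standardization of molecular inputs.

# Side-chain SMILES fragments attached to the alpha carbon. Glycine has no
# side chain; proline is assembled specially because its side chain closes
# a ring onto the backbone nitrogen. Stereocentres are deliberately not
# emitted: the pipeline uses 2D descriptors only, and stereo-free SMILES
# keep descriptor values reproducible across toolkit versions.
.SIDE_CHAINS <- c(
  A = "C",              R = "CCCNC(=N)N",  N = "CC(N)=O",
  D = "CC(=O)O",        C = "CS",          E = "CCC(=O)O",
  Q = "CCC(N)=O",       G = "",            H = "Cc1c[nH]cn1",
  I = "C(C)CC",         L = "CC(C)C",      K = "CCCCN",
  M = "CCSC",           F = "Cc1ccccc1",   P = "",
  S = "CO",             T = "C(C)O",       V = "C(C)C",
  W = "Cc1c[nH]c2ccccc12", Y = "Cc1ccc(O)cc1"
)

#' Linear peptide SMILES from a one-letter amino-acid sequence
#'
#' Assembles the SMILES of the linear peptide with a free N-terminal amine
#' and free C-terminal carboxylic acid, residues joined by amide bonds in
#' sequence order. All 20 standard residues are supported; proline
#' contributes its pyrrolidine ring fused to the backbone nitrogen.
#'
#' @param sequence character scalar of one-letter codes (case-insensitive).
#' @return A SMILES string (not canonicalized; pass through
#'   \code{\link{standardizeMolecule}} for the canonical form).
#' @examples
#' peptideToSmiles("G")   # glycine
#' peptideToSmiles("ED")  # Glu-Asp dipeptide
#' @export
peptideToSmiles <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty peptide sequence")
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- which(!letters1 %in% names(.SIDE_CHAINS))
  if (length(bad)) {
    stop(sprintf("unknown residue letter '%s' at position %d",
                 letters1[bad[1]], bad[1]))
  }
  frag <- vapply(letters1, function(a) {
    if (a == "P") return("N1CCCC1C(=O)")
    if (a == "G") return("NCC(=O)")
    paste0("NC(", .SIDE_CHAINS[[a]], ")C(=O)")
  }, character(1))
  paste0(paste(frag, collapse = ""), "O")
}

.ISSUE_LEVELS <- c("none", "low", "high")

#' Standardize a molecular input to canonical parent SMILES
#'
#' Parses the input in its declared notation (SMILES, one-letter peptide
#' sequence, or InChI), strips counter-ions/fragments to the largest
#' parent, neutralizes charges, removes stereochemical marks (2D
#' descriptors only are computed downstream) and canonicalizes. A structure
#' check assigns an issue level: \code{"high"} (valence violation or
#' unparseable input; the record is excluded), \code{"low"} (multiple
#' fragments stripped, isotopic labels, or residual net charge) or
#' \code{"none"}.
#'
#' @param input character scalar: SMILES, peptide sequence or InChI.
#' @param notation one of \code{"smiles"}, \code{"fasta_peptide"},
#'   \code{"inchi"}.
#' @param id identifier stored on the record.
#' @return A one-row data.frame with columns \code{id}, \code{source_text},
#'   \code{notation}, \code{canonical_smiles}, \code{issue_level},
#'   \code{excluded}, \code{message}.
#' @examples
#' standardizeMolecule("C1=CC=CC=C1")             # benzene -> c1ccccc1
#' standardizeMolecule("[Na+].CC(=O)[O-]")        # sodium acetate -> parent
#' @export
standardizeMolecule <- function(input, notation = c("smiles",
                                "fasta_peptide", "inchi"), id = "query") {
  notation <- match.arg(notation)
  rec <- function(smi, level, excl, msg = "") {
    data.frame(id = id, source_text = input, notation = notation,
               canonical_smiles = smi, issue_level = level,
               excluded = excl, message = msg,
               stringsAsFactors = FALSE)
  }
  fail <- function(msg) rec("", "high", TRUE, msg)
  if (!is.character(input) || length(input) != 1L || !nzchar(input))
    return(fail("empty input"))

  smi <- switch(notation,
    smiles = input,
    fasta_peptide = tryCatch(peptideToSmiles(input),
                             error = function(e) ""),
    inchi = .inchiToSmiles(input)
  )
  if (!nzchar(smi))
    return(fail(sprintf("could not interpret input as %s", notation)))

  can0 <- .canonicalSmiles(smi)
  if (!nzchar(can0)) return(fail("unparseable structure"))

  issues <- character(0)
  multiFrag <- grepl(".", can0, fixed = TRUE)
  if (multiFrag) {
    can0 <- .largestFragment(can0)
    issues <- c(issues, "multiple fragments: kept largest")
  }
  if (.hasIsotope(can0)) issues <- c(issues, "isotopic labels present")

  can1 <- .neutralizeSmiles(can0)
  if (!nzchar(can1)) can1 <- can0
  can1 <- .canonicalSmiles(.stripStereo(can1))
  if (!nzchar(can1)) return(fail("canonicalization failed"))

  g <- .parseOne(can1)
  if (is.null(g)) return(fail("structure no longer parses"))
  val <- .implicitH(g)
  if (any(val$violation)) {
    w <- which(val$violation)[1]
    return(rec(can1, "high", TRUE,
               sprintf("valence violation at %s atom %d", g$elem[w], w)))
  }
  if (any(g$charge != 0L))
    issues <- c(issues, "residual formal charge after neutralization")

  level <- if (length(issues)) "low" else "none"
  rec(can1, level, FALSE, paste(issues, collapse = "; "))
}

#' Read a labeled molecular dataset
#'
#' Reads one of three plain-text formats into a standardized
#' \linkS4class{MoleculeSet}:
#' \describe{
#'   \item{csv}{columns \code{id}, \code{input}, \code{notation},
#'     \code{label}, optional \code{split}.}
#'   \item{smi}{one molecule per line, \code{"SMILES id"}; labels must be
#'     supplied via the optional \code{labels} argument.}
#'   \item{fasta_pair}{FASTA of peptide sequences, label parsed from a
#'     \code{label=<0|1>} token on the header line.}
#' }
#' Duplicate canonical SMILES within a split are reported as a warning,
#' never removed.
#'
#' @param path file path.
#' @param format one of \code{"csv"}, \code{"smi"}, \code{"fasta_pair"}.
#' @param labels optional integer labels for the \code{smi} format.
#' @return A \linkS4class{MoleculeSet}.
#' @export
readLabeledDataset <- function(path, format = c("csv", "smi",
                               "fasta_pair"), labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- switch(format,
    csv = .readDatasetCsv(path),
    smi = .readSmi(path, labels),
    fasta_pair = .readFastaPair(path)
  )
  if (nrow(df) == 0L) stop("empty dataset: ", path)
  makeMoleculeSet(df)
}

.readDatasetCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "input", "notation", "label")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("dataset CSV is missing column(s): ", paste(miss, collapse = ", "))
  badlab <- which(!is.na(df$label) & !df$label %in% c(0, 1))
  if (length(badlab))
    stop(sprintf("label outside {0,1} at row %d (id '%s')",
                 badlab[1], df$id[badlab[1]]))
  if (is.null(df$split)) df$split <- rep("unassigned", nrow(df))
  df
}

.readSmi <- function(path, labels) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  df <- data.frame(
    id = vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("mol", i),
      character(1)),
    input = vapply(parts, `[[`, character(1), 1),
    notation = "smiles",
    label = if (is.null(labels)) NA_integer_ else as.integer(labels),
    split = "unassigned",
    stringsAsFactors = FALSE
  )
  df
}

.readFastaPair <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers found in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  ids <- character(length(hdr)); seqs <- character(length(hdr))
  labs <- integer(length(hdr))
  for (i in seq_along(hdr)) {
    h <- sub("^>", "", lines[hdr[i]])
    ids[i] <- strsplit(h, "[[:space:]]+")[[1]][1]
    m <- regmatches(h, regexpr("label=[01]", h))
    labs[i] <- if (length(m)) as.integer(sub("label=", "", m)) else
      NA_integer_
    body <- lines[seq(hdr[i] + 1L, ends[i])]
    seqs[i] <- gsub("[[:space:]]", "", paste(body, collapse = ""))
  }
  data.frame(id = ids, input = seqs, notation = "fasta_peptide",
             label = labs, split = "unassigned", stringsAsFactors = FALSE)
}

#' Build a standardized MoleculeSet from a raw input table
#'
#' Standardizes every row of a data.frame with columns \code{id},
#' \code{input}, \code{notation}, \code{label} (and optional \code{split})
#' and assembles the \linkS4class{MoleculeSet}. Duplicate canonical SMILES
#' within a split are reported (ids listed) but kept.
#'
#' @param df input data.frame as above.
#' @return A \linkS4class{MoleculeSet}.
#' @export
makeMoleculeSet <- function(df) {
  recs <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    standardizeMolecule(df$input[i], notation = df$notation[i],
                        id = as.character(df$id[i]))
  }))
  split <- if (is.null(df$split)) rep("unassigned", nrow(df)) else
    as.character(df$split)
  ms <- new("MoleculeSet", records = recs,
            labels = as.integer(df$label), split = split)
  .reportDuplicates(ms)
  ms
}

.reportDuplicates <- function(ms) {
  r <- ms@records
  for (sp in unique(ms@split)) {
    idx <- which(ms@split == sp & !r$excluded)
    cs <- r$canonical_smiles[idx]
    dup <- cs[duplicated(cs)]
    if (length(dup)) {
      for (d in unique(dup)) {
        ids <- r$id[idx][cs == d]
        warning(sprintf(
          "duplicate canonical SMILES in split '%s': %s (ids: %s)",
          sp, d, paste(ids, collapse = ", ")), call. = FALSE)
      }
    }
  }
  invisible(NULL)
}

#' Write a MoleculeSet back to the dataset CSV format
#'
#' @param ms a \linkS4class{MoleculeSet}.
#' @param path output file.
#' @export
writeLabeledDataset <- function(ms, path) {
  stopifnot(is(ms, "MoleculeSet"))
  df <- data.frame(id = ms@records$id, input = ms@records$source_text,
                   notation = ms@records$notation, label = ms@labels,
                   split = ms@split, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
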