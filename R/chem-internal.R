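# Internal chemistry layer: OpenBabel-backed SMILES handling and
# hydrogen-suppressed molecular graphs used by the descriptor engine,
# standardizer and fingerprint code.

# Standard atomic masses and Pauling electronegativities for the elements
# that occur in organic/peptide chemistry; anything else falls back to NA
# and the affected descriptor cell becomes missing.
.ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.086, P = 30.974, S = 32.06,
  Cl = 35.453, K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904
)

.PAULING_EN <- c(
  H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
  Na = 0.93, Mg = 1.31, Si = 1.90, P = 2.19, S = 2.58,
  Cl = 3.16, K = 0.82, Ca = 1.00, Br = 2.96, I = 2.66
)

# Allowed valences per neutral element (lowest standard valence states);
# charge shifts the allowance for N/O the usual way.
.VALENCE <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5),
  S = c(2, 4, 6), Cl = 1, Br = 1, I = 1, Na = 1, K = 1, Mg = 2, Ca = 2
)

#' @importFrom ChemmineOB convertFormat
.obConvert <- function(from, to, text, options = NULL) {
  out <- tryCatch(
    suppressWarnings(
      if (is.null(options)) ChemmineOB::convertFormat(from, to, text)
      else ChemmineOB::convertFormat(from, to, text, options = options)),
    error = function(e) ""
  )
  out
}

# Canonical SMILES for a vector of SMILES strings; "" where OpenBabel
# cannot parse. Input ids are positional.
.canonicalSmiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  out <- character(length(smiles))
  for (i in seq_along(smiles)) {
    res <- .obConvert("SMI", "CAN", paste(smiles[i], "m"))
    out[i] <- if (nzchar(res)) sub("\t.*$", "", strsplit(res, "\n")[[1]][1]) else ""
  }
  out
}

.neutralizeSmiles <- function(smiles) {
  res <- .obConvert("SMI", "CAN", paste(smiles, "m"),
                    options = data.frame(names = "neutralize", args = ""))
  if (nzchar(res)) sub("\t.*$", "", strsplit(res, "\n")[[1]][1]) else ""
}

.inchiToSmiles <- function(inchi) {
  res <- .obConvert("INCHI", "CAN", inchi)
  if (nzchar(res)) sub("\t.*$", "", strsplit(res, "\n")[[1]][1]) else ""
}

# Drop stereochemical decorations from a SMILES string. '@' only occurs in
# atom brackets (tetrahedral marks), '/' and '\' are directional single
# bonds; deleting them leaves plain single bonds, re-canonicalized after.
.stripStereo <- function(smiles) {
  s <- gsub("@", "", smiles, fixed = TRUE)
  s <- gsub("/", "", s, fixed = TRUE)
  gsub("\\", "", s, fixed = TRUE)
}

# Parse a batch of SMILES into hydrogen-suppressed graphs via an SDF
# round-trip. Returns a list (one element per molecule, NULL on parse
# failure) of lists: elem, charge (per heavy atom), bonds (a1, a2, order),
# nAromatic (aromatic heavy-atom count from the canonical SMILES).
#' @importFrom ChemmineR smiles2sdf atomblock bondblock validSDF
.parseMolecules <- function(smiles, ids = NULL) {
  n <- length(smiles)
  if (is.null(ids)) ids <- paste0("M", seq_len(n))
  out <- vector("list", n)
  names(out) <- ids
  for (i in seq_len(n)) {
    g <- tryCatch(.parseOne(smiles[i]), error = function(e) NULL)
    out[[i]] <- g
  }
  out
}

.parseOne <- function(smi) {
  if (!nzchar(smi)) return(NULL)
  single <- .parseSingleAtom(smi)
  if (!is.null(single)) return(single)
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(c(m = smi))),
                  error = function(e) NULL)
  if (is.null(sdf) || !ChemmineR::validSDF(sdf)[1]) return(NULL)
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elem <- sub("_.*$", "", rownames(ab))
  nA <- length(elem)
  if (nA == 0L) return(NULL)
  # formal charges live in atom-block column 5 of ChemmineR's parsed SDF
  # as MDL codes in some writers; OpenBabel emits M  CHG lines which
  # ChemmineR folds into the atom pair list. Recover them via bonds().
  binfo <- ChemmineR::bonds(mol)
  charge <- binfo$charge[seq_len(nA)]
  if (is.null(bb) || nrow(bb) == 0L) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  list(elem = elem, charge = as.integer(charge), bonds = bonds,
       nAromatic = .countAromaticAtoms(smi), smiles = smi)
}

# ChemmineR's SDF container cannot represent single-heavy-atom molecules
# (bond-block-less SDFs fail its validity check), so one-atom SMILES such
# as "O", "C" or "[NH4+]" are parsed directly.
.parseSingleAtom <- function(smi) {
  m <- regmatches(smi, regexec(
    "^\\[?([0-9]*)([A-Z][a-z]?)(H[0-9]*)?([+-][0-9]*)?\\]?$", smi))[[1]]
  if (length(m) == 0L) return(NULL)
  elem <- m[3]
  if (!elem %in% names(.VALENCE) && !elem %in% names(.ATOMIC_MASS))
    return(NULL)
  chs <- m[5]
  charge <- if (!nzchar(chs)) 0L else {
    sign <- if (substr(chs, 1, 1) == "+") 1L else -1L
    mag <- if (nchar(chs) > 1) as.integer(substr(chs, 2, nchar(chs))) else 1L
    sign * mag
  }
  list(elem = elem, charge = charge,
       bonds = data.frame(a1 = integer(0), a2 = integer(0),
                          order = integer(0)),
       nAromatic = 0L, smiles = smi)
}

# Count aromatic heavy atoms in a SMILES string: lowercase organic-subset
# tokens outside brackets plus lowercase element heads inside brackets.
.countAromaticAtoms <- function(smi) {
  n <- 0L
  inBracket <- FALSE
  chars <- strsplit(smi, "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      inBracket <- TRUE
      # element symbol = first alpha run after optional isotope digits
      j <- i + 1L
      while (j <= length(chars) && grepl("[0-9]", chars[j])) j <- j + 1L
      if (j <= length(chars) && chars[j] %in% c("c", "n", "o", "p", "s"))
        n <- n + 1L
      while (i <= length(chars) && chars[i] != "]") i <- i + 1L
      inBracket <- FALSE
    } else if (!inBracket && ch %in% c("c", "n", "o", "p", "s")) {
      # 's' could be start of nothing else in organic subset; 'c' 'n' 'o'
      # unambiguous outside brackets
      n <- n + 1L
    }
    i <- i + 1L
  }
  n
}

# Per-atom bond-order sum (aromatic bonds arrive kekulized from OpenBabel).
.bondOrderSum <- function(g) {
  bos <- numeric(length(g$elem))
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      bos[g$bonds$a1[k]] <- bos[g$bonds$a1[k]] + g$bonds$order[k]
      bos[g$bonds$a2[k]] <- bos[g$bonds$a2[k]] + g$bonds$order[k]
    }
  }
  bos
}

# Implicit hydrogen count per heavy atom, and a valence-violation flag.
.implicitH <- function(g) {
  bos <- .bondOrderSum(g)
  nA <- length(g$elem)
  hs <- numeric(nA)
  bad <- logical(nA)
  for (i in seq_len(nA)) {
    el <- g$elem[i]
    allowed <- .VALENCE[[el]]
    if (is.null(allowed)) { hs[i] <- 0; next }  # metals etc: no implicit H
    ch <- g$charge[i]
    # charge adjustment for the common organic cases
    if (el == "N" || el == "P") allowed <- allowed + ch
    if (el == "O" || el == "S") allowed <- allowed + ch
    if (el == "C") allowed <- allowed - abs(ch)
    v <- allowed[allowed >= bos[i]]
    if (length(v) == 0L) { bad[i] <- TRUE; hs[i] <- 0 } else {
      hs[i] <- min(v) - bos[i]
    }
  }
  list(h = hs, violation = bad)
}

.hasIsotope <- function(smi) {
  grepl("\\[[0-9]+[A-Za-z]", smi)
}

# Degree (heavy-neighbour count) per atom.
.degree <- function(g) {
  deg <- integer(length(g$elem))
  if (nrow(g$bonds)) {
    t1 <- tabulate(g$bonds$a1, nbins = length(g$elem))
    t2 <- tabulate(g$bonds$a2, nbins = length(g$elem))
    deg <- t1 + t2
  }
  deg
}

#' @importFrom igraph graph_from_data_frame distances components bridges E
.igraphOf <- function(g) {
  nA <- length(g$elem)
  igraph::graph_from_data_frame(
    d = if (nrow(g$bonds)) g$bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(0), a2 = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nA))
  )
}

# Largest connected fragment of a SMILES written as dot-separated parts;
# ties broken by first occurrence.
.largestFragment <- function(smiles) {
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(parts) <= 1L) return(smiles)
  sizes <- vapply(parts, function(p) {
    g <- tryCatch(.parseOne(p), error = function(e) NULL)
    if (is.null(g)) -1L else length(g$elem)
  }, integer(1))
  parts[which.max(sizes)]
}

# Molecular formula via OpenBabel (oracle-grade; used in tests and counts).
#' @importFrom ChemmineR propOB
.molFormula <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(c(m = smiles)))
  ChemmineR::propOB(sdf)$formula[1]
}
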