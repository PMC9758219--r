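# 2D molecular-descriptor engine. All descriptors are computed on the
# hydrogen-suppressed molecular graph; physicochemical properties (logP,
# MR, TPSA, H-bond counts, MW) come from the OpenBabel backend. Any
# descriptor that cannot be evaluated for a molecule yields a missing
# cell, never an error.

#' Heavy-atom graph summary of a molecule
#'
#' Counts on the hydrogen-suppressed molecular graph: heavy atoms (A),
#' bonds between heavy atoms (B) and heteroatoms (H; heavy atoms that are
#' not carbon).
#'
#' @param smiles a SMILES string.
#' @return list with elements \code{A}, \code{B}, \code{H}.
#' @examples
#' graphSummary("c1ccccc1")  # A=6, B=6, H=0
#' graphSummary("NCC(=O)O")  # glycine: A=5, B=4, H=3
#' @export
graphSummary <- function(smiles) {
  g <- .parseOne(smiles)
  if (is.null(g)) stop("unparseable SMILES: ", smiles)
  list(A = length(g$elem), B = nrow(g$bonds),
       H = sum(g$elem != "C" & g$elem != "H"))
}

#' Fragment-complexity descriptor
#'
#' Closed-form complexity of the heavy-atom graph:
#' \deqn{\mathrm{fragCpx} = |B^2 - A^2 + A| + H/100}
#' with A heavy atoms, B heavy-atom bonds and H heteroatoms.
#'
#' @param summary a list with \code{A}, \code{B}, \code{H} as returned by
#'   \code{\link{graphSummary}}.
#' @return numeric scalar.
#' @examples
#' fragCpx(list(A = 6, B = 6, H = 0))  # benzene: 6
#' fragCpx(list(A = 1, B = 0, H = 1))  # water: 0.01
#' @export
fragCpx <- function(summary) {
  stopifnot(all(c("A", "B", "H") %in% names(summary)))
  with(summary, abs(B^2 - A^2 + A) + H / 100)
}

# ---- descriptor catalogue -------------------------------------------------

# Each entry maps a graph (plus cached igraph/distance objects) to one
# numeric value. Autocorrelation descriptors follow the Moreau-Broto
# family: ATSd(w) = sum over ordered pairs at topological distance d of
# w_i * w_j (d = 0 uses w_i^2); centred variants (ATSC) replace w by
# w - mean(w); averaged centred variants (AATSC) divide by the number of
# contributing pairs.

.descriptorNames <- function() {
  c("nHeavy", "nBonds", "nC", "nN", "nO", "nS", "nHal", "nHetero",
    "fHetero", "nRings", "nAromAtoms", "fAromAtoms", "nImplicitH",
    "meanAtomMass", "nRotB", "nCOOH", "nPrimAmine", "nAmide", "nOH",
    "nSH",
    "MW", "logP", "MR", "TPSA", "HBA1", "HBA2", "HBD", "nF",
    "Wiener", "MeanDist", "Diameter", "Radius", "Harary",
    "Zagreb1", "Zagreb2", "Platt", "Chi0", "Chi1", "BalabanJ",
    "EccConn", "Kappa1", "Kappa2", "Kappa3",
    paste0("ATSC", 0:3, "m"), paste0("AATSC", 0:3, "m"),
    paste0("ATSC", 0:3, "e"), paste0("AATSC", 0:3, "e"),
    "fragCpx")
}

#' Compute the 2D descriptor matrix for a set of molecules
#'
#' One row per molecule over the package's configured 2D descriptor set:
#' constitutional counts and functional-group counts, OpenBabel
#' physicochemical properties, topological indices (Wiener, Zagreb,
#' Randic-type connectivity, Balaban J, Kier shape, eccentricity-based),
#' mass- and electronegativity-weighted Moreau-Broto autocorrelations, and
#' the native fragment-complexity descriptor. Descriptor failures become
#' missing cells.
#'
#' @param smiles character vector of (standardized) SMILES.
#' @param ids molecule identifiers; defaults to names of \code{smiles} or
#'   positional ids.
#' @return A \linkS4class{DescriptorTable}.
#' @export
computeDescriptors <- function(smiles, ids = NULL) {
  if (length(smiles) == 0L) stop("no molecules supplied")
  if (is.null(ids)) {
    ids <- names(smiles)
    if (is.null(ids)) ids <- paste0("M", seq_along(smiles))
  }
  ids <- make.unique(as.character(ids))
  feats <- .descriptorNames()
  vals <- matrix(NA_real_, nrow = length(smiles), ncol = length(feats),
                 dimnames = list(ids, feats))

  # batch the OpenBabel property call
  prop <- .propTable(smiles, ids)

  for (i in seq_along(smiles)) {
    g <- tryCatch(.parseOne(smiles[i]), error = function(e) NULL)
    if (is.null(g)) stop("molecule no longer parses: ", smiles[i])
    row <- .descriptorRow(g, prop[i, , drop = FALSE])
    vals[i, names(row)] <- row
  }
  .DescriptorTable(vals)
}

.propTable <- function(smiles, ids) {
  out <- matrix(NA_real_, nrow = length(smiles), ncol = 8,
                dimnames = list(ids, c("MW", "logP", "MR", "TPSA",
                                       "HBA1", "HBA2", "HBD", "nF")))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids))),
    error = function(e) NULL)
  if (is.null(sdf)) return(out)
  ok <- ChemmineR::validSDF(sdf)
  p <- tryCatch(suppressWarnings(ChemmineR::propOB(sdf[ok])),
                error = function(e) NULL)
  if (is.null(p)) return(out)
  idx <- which(ok)
  for (j in seq_along(idx)) {
    out[idx[j], ] <- suppressWarnings(as.numeric(
      c(p$MW[j], p$logP[j], p$MR[j], p$TPSA[j],
        p$HBA1[j], p$HBA2[j], p$HBD[j], p$nF[j])))
  }
  out
}

.descriptorRow <- function(g, prop) {
  nA <- length(g$elem)
  deg <- .degree(g)
  ih <- .implicitH(g)
  ig <- .igraphOf(g)
  D <- igraph::distances(ig)
  conn <- all(is.finite(D))
  masses <- .ATOMIC_MASS[g$elem]
  ens <- .PAULING_EN[g$elem]

  out <- c(
    nHeavy = nA,
    nBonds = nrow(g$bonds),
    nC = sum(g$elem == "C"),
    nN = sum(g$elem == "N"),
    nO = sum(g$elem == "O"),
    nS = sum(g$elem == "S"),
    nHal = sum(g$elem %in% c("F", "Cl", "Br", "I")),
    nHetero = sum(g$elem != "C"),
    fHetero = sum(g$elem != "C") / nA,
    nRings = nrow(g$bonds) - nA + igraph::components(ig)$no,
    nAromAtoms = g$nAromatic,
    fAromAtoms = g$nAromatic / nA,
    nImplicitH = sum(ih$h),
    meanAtomMass = mean(masses),
    nRotB = .countRotB(g, deg, ig),
    .functionalGroups(g, deg, ih$h),
    MW = prop[1, "MW"], logP = prop[1, "logP"], MR = prop[1, "MR"],
    TPSA = prop[1, "TPSA"], HBA1 = prop[1, "HBA1"],
    HBA2 = prop[1, "HBA2"], HBD = prop[1, "HBD"], nF = prop[1, "nF"]
  )

  out <- c(out, .topological(g, deg, D, conn))
  out <- c(out, .autocorr(D, masses, "m"), .autocorr(D, ens, "e"))
  out <- c(out, fragCpx = fragCpx(list(A = nA, B = nrow(g$bonds),
                                       H = sum(g$elem != "C"))))
  out
}

.functionalGroups <- function(g, deg, hs) {
  b <- g$bonds
  nbr <- function(i) {
    c(b$a2[b$a1 == i], b$a1[b$a2 == i])
  }
  bondOrder <- function(i, j) {
    k <- which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))
    if (length(k)) b$order[k[1]] else 0L
  }
  nCOOH <- 0L; nPrimAmine <- 0L; nAmide <- 0L; nOH <- 0L; nSH <- 0L
  for (i in seq_along(g$elem)) {
    el <- g$elem[i]
    if (el == "C") {
      nb <- nbr(i)
      os <- nb[g$elem[nb] == "O"]
      hasCarbonyl <- any(vapply(os, function(o) bondOrder(i, o) == 2L,
                                logical(1)))
      hasHydroxy <- any(vapply(os, function(o)
        bondOrder(i, o) == 1L && deg[o] == 1L && hs[o] >= 1, logical(1)))
      if (hasCarbonyl && hasHydroxy) nCOOH <- nCOOH + 1L
      if (hasCarbonyl && any(g$elem[nb] == "N")) nAmide <- nAmide + 1L
    } else if (el == "N") {
      if (deg[i] == 1L && hs[i] >= 2) nPrimAmine <- nPrimAmine + 1L
    } else if (el == "O") {
      if (deg[i] == 1L && hs[i] >= 1) nOH <- nOH + 1L
    } else if (el == "S") {
      if (deg[i] == 1L && hs[i] >= 1) nSH <- nSH + 1L
    }
  }
  c(nCOOH = nCOOH, nPrimAmine = nPrimAmine, nAmide = nAmide,
    nOH = nOH, nSH = nSH)
}

# Rotatable bonds: acyclic single bonds whose both ends have heavy degree
# greater than 1 (terminal bonds rotate trivially and are not counted).
.countRotB <- function(g, deg, ig) {
  if (nrow(g$bonds) == 0L) return(0L)
  bridgeIdx <- igraph::bridges(ig)
  isBridge <- rep(FALSE, nrow(g$bonds))
  if (length(bridgeIdx)) isBridge[as.integer(bridgeIdx)] <- TRUE
  sum(g$bonds$order == 1L & isBridge &
      deg[g$bonds$a1] > 1L & deg[g$bonds$a2] > 1L)
}

.topological <- function(g, deg, D, conn) {
  nA <- length(g$elem)
  B <- nrow(g$bonds)
  up <- D[upper.tri(D)]
  zag1 <- sum(deg^2)
  zag2 <- if (B) sum(deg[g$bonds$a1] * deg[g$bonds$a2]) else 0
  chi0 <- sum(ifelse(deg > 0, 1 / sqrt(deg), 0))
  chi1 <- if (B) sum(1 / sqrt(deg[g$bonds$a1] * deg[g$bonds$a2])) else 0
  platt <- if (B) sum(deg[g$bonds$a1] + deg[g$bonds$a2] - 2) else 0

  if (conn && nA > 1) {
    wiener <- sum(up)
    meanDist <- mean(up)
    ecc <- apply(D, 1, max)
    diam <- max(ecc); rad <- min(ecc)
    harary <- sum(1 / up[up > 0])
    eccConn <- sum(deg * ecc)
    mu <- B - nA + 1
    si <- rowSums(D)
    balaban <- if (B) B / (mu + 1) *
      sum(1 / sqrt(si[g$bonds$a1] * si[g$bonds$a2])) else NA_real_
  } else {
    wiener <- meanDist <- diam <- rad <- harary <- eccConn <-
      balaban <- if (nA == 1) 0 else NA_real_
    if (nA == 1) balaban <- NA_real_
  }

  # Kier shape indices from path counts P1 (bonds), P2, P3
  p1 <- B
  p2 <- sum(choose(deg, 2))
  p3 <- if (B) sum((deg[g$bonds$a1] - 1) * (deg[g$bonds$a2] - 1)) else 0
  kap1 <- if (p1 > 0) nA * (nA - 1)^2 / p1^2 else NA_real_
  kap2 <- if (p2 > 0) (nA - 1) * (nA - 2)^2 / p2^2 else NA_real_
  kap3 <- if (p3 > 0) {
    if (nA %% 2 == 1) (nA - 1) * (nA - 3)^2 / p3^2 else
      (nA - 3) * (nA - 2)^2 / p3^2
  } else NA_real_

  c(Wiener = wiener, MeanDist = meanDist, Diameter = diam, Radius = rad,
    Harary = harary, Zagreb1 = zag1, Zagreb2 = zag2, Platt = platt,
    Chi0 = chi0, Chi1 = chi1, BalabanJ = balaban, EccConn = eccConn,
    Kappa1 = kap1, Kappa2 = kap2, Kappa3 = kap3)
}

.autocorr <- function(D, w, suffix) {
  lags <- 0:3
  atsc <- aatsc <- rep(NA_real_, length(lags))
  if (!any(is.na(w)) && all(is.finite(D))) {
    wc <- w - mean(w)
    for (li in seq_along(lags)) {
      d <- lags[li]
      if (d == 0) {
        atsc[li] <- sum(wc^2)
        aatsc[li] <- atsc[li] / length(wc)
      } else {
        pairs <- which(D == d, arr.ind = TRUE)
        pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
        if (nrow(pairs)) {
          atsc[li] <- sum(wc[pairs[, 1]] * wc[pairs[, 2]])
          aatsc[li] <- atsc[li] / nrow(pairs)
        } else {
          atsc[li] <- 0; aatsc[li] <- NA_real_
        }
      }
    }
  }
  stats::setNames(c(atsc, aatsc),
                  c(paste0("ATSC", lags, suffix),
                    paste0("AATSC", lags, suffix)))
}

#' Write / read a DescriptorTable as CSV
#'
#' First column \code{molecule_id}, then one column per descriptor; empty
#' cells encode missing values. The round-trip is lossless up to numeric
#' printing precision.
#'
#' @param dt a \linkS4class{DescriptorTable}.
#' @param path file path.
#' @export
writeDescriptorCsv <- function(dt, path) {
  stopifnot(is(dt, "DescriptorTable"))
  df <- data.frame(molecule_id = rownames(dt@values), dt@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeDescriptorCsv
#' @export
readDescriptorCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  stopifnot(names(df)[1] == "molecule_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$molecule_id
  .DescriptorTable(m)
}
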