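# Applicability domain: Morgan-type circular fingerprints (1024 bits,
# radius 2), Tanimoto similarity, and the average-of-top-5 rule with the
# 0.4 threshold. A query whose average similarity to its 5 most similar
# training compounds falls strictly below the threshold is outside the
# domain.

#' Morgan-type circular fingerprint
#'
#' Deterministic circular (extended-connectivity) fingerprint of the
#' requested radius folded to \code{nbits} bits.
#'
#' @param smiles character vector of SMILES.
#' @param nbits fingerprint width, default 1024.
#' @param radius circular radius, default 2.
#' @return logical matrix, one row per molecule, \code{nbits} columns.
#' @export
morganFp <- function(smiles, nbits = 1024L, radius = 2L) {
  stopifnot(length(smiles) >= 1L)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(
      stats::setNames(smiles, paste0("q", seq_along(smiles))))),
    error = function(e) NULL)
  if (is.null(sdf)) stop("unparseable SMILES input")
  ok <- ChemmineR::validSDF(sdf)
  if (!all(ok)) {
    bad <- which(!ok)
    # single-atom molecules are valid chemistry but unsupported by the
    # SDF container; give them an empty fingerprint
    singles <- vapply(smiles[bad], function(s)
      !is.null(.parseSingleAtom(s)), logical(1))
    if (any(!singles))
      stop("unparseable SMILES: ",
           paste(smiles[bad[!singles]], collapse = ", "))
  }
  wide <- matrix(0L, length(smiles), 4096L)
  if (any(ok)) {
    fp <- ChemmineR::fingerprintOB(sdf[ok], paste0("ECFP", 2L * radius))
    wide[which(ok), ] <- fp@fpma
  }
  # fold the native 4096-bit vector down by OR over congruent positions
  fold <- wide[, 1:nbits, drop = FALSE]
  reps <- 4096L %/% nbits
  if (reps > 1L) {
    for (r in seq_len(reps - 1L)) {
      fold <- fold | wide[, (r * nbits + 1L):((r + 1L) * nbits),
                          drop = FALSE]
    }
  }
  out <- matrix(as.logical(fold), length(smiles), nbits)
  rownames(out) <- names(smiles)
  out
}

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{c / (a + b - c)} over the on-bit counts; defined as 0 when both
#' fingerprints are empty.
#'
#' @param fpA,fpB logical vectors of equal length.
#' @return numeric in [0, 1].
#' @export
tanimoto <- function(fpA, fpB) {
  if (length(fpA) != length(fpB)) stop("fingerprint length mismatch")
  a <- sum(fpA); b <- sum(fpB); c <- sum(fpA & fpB)
  if (a + b - c == 0) return(0)
  c / (a + b - c)
}

#' Fit the applicability domain on training molecules
#'
#' @param smiles training SMILES.
#' @param ids molecule identifiers.
#' @param kTop similar compounds averaged, default 5.
#' @param threshold average-similarity threshold, default 0.4.
#' @param nbits,radius fingerprint parameters.
#' @return An \linkS4class{ADModel}.
#' @export
fitAD <- function(smiles, ids = NULL, kTop = 5L, threshold = 0.4,
                  nbits = 1024L, radius = 2L) {
  if (is.null(ids)) ids <- names(smiles)
  if (is.null(ids)) ids <- paste0("M", seq_along(smiles))
  fps <- morganFp(smiles, nbits = nbits, radius = radius)
  new("ADModel", fps = fps, ids = as.character(ids),
      kTop = as.integer(kTop), threshold = threshold,
      nbits = as.integer(nbits), radius = as.integer(radius))
}

#' Average top-k Tanimoto similarity to the training set
#'
#' Mean of the \code{kTop} largest Tanimoto similarities between the
#' query fingerprint and the training fingerprints. With
#' \code{excludeSelf} one perfect-identity match is removed first (used
#' when scoring training compounds against their own set). When fewer
#' than \code{kTop} comparators remain, all are used with a warning.
#'
#' @param queryFp logical fingerprint vector.
#' @param ad an \linkS4class{ADModel}.
#' @param excludeSelf drop one exact-identity match, default FALSE.
#' @return numeric average similarity.
#' @export
avgTopkSimilarity <- function(queryFp, ad, excludeSelf = FALSE) {
  stopifnot(is(ad, "ADModel"))
  sims <- apply(ad@fps, 1, tanimoto, fpB = queryFp)
  if (excludeSelf) {
    selfIdx <- which(sims >= 1 - 1e-12 &
                       apply(ad@fps, 1, function(f)
                         identical(as.logical(f), as.logical(queryFp))))
    if (length(selfIdx)) sims <- sims[-selfIdx[1]]
  }
  k <- ad@kTop
  if (length(sims) < k) {
    warning(sprintf("only %d comparator(s) available; using all",
                    length(sims)), call. = FALSE)
    k <- length(sims)
  }
  mean(sort(sims, decreasing = TRUE)[seq_len(k)])
}

#' Applicability-domain check for a query molecule
#'
#' @param querySmiles a SMILES string.
#' @param ad an \linkS4class{ADModel}.
#' @return list with \code{inDomain} (average similarity at or above the
#'   threshold) and \code{score}.
#' @export
adCheck <- function(querySmiles, ad) {
  fp <- morganFp(querySmiles, nbits = ad@nbits, radius = ad@radius)[1, ]
  score <- avgTopkSimilarity(fp, ad, excludeSelf = FALSE)
  list(inDomain = score >= ad@threshold, score = score)
}

#' Similarity-score distributions and threshold suggestion
#'
#' Average top-k similarity scores of the training set (self-excluded)
#' and a test set (not self-excluded), plus a suggested threshold: the
#' minimum of the pooled scores rounded down to the nearest 0.05.
#'
#' @param ad an \linkS4class{ADModel}.
#' @param trainSmiles,testSmiles SMILES vectors.
#' @return list: \code{train}, \code{test} (score vectors),
#'   \code{suggestedThreshold}.
#' @export
scoreDistributions <- function(ad, trainSmiles, testSmiles) {
  if (!length(trainSmiles) || !length(testSmiles))
    stop("empty input set")
  trFp <- morganFp(trainSmiles, nbits = ad@nbits, radius = ad@radius)
  teFp <- morganFp(testSmiles, nbits = ad@nbits, radius = ad@radius)
  tr <- apply(trFp, 1, avgTopkSimilarity, ad = ad, excludeSelf = TRUE)
  te <- apply(teFp, 1, avgTopkSimilarity, ad = ad, excludeSelf = FALSE)
  lo <- min(c(tr, te))
  list(train = tr, test = te,
       suggestedThreshold = floor(lo / 0.05) * 0.05)
}

#' Write / read an AD bundle as plain text
#'
#' Hex-encoded fingerprint rows with ids and the threshold, round-tripped
#' losslessly.
#'
#' @param ad an \linkS4class{ADModel}.
#' @param path file path.
#' @export
writeADModel <- function(ad, path) {
  stopifnot(is(ad, "ADModel"))
  hex <- apply(ad@fps, 1, .bitsToHex)
  lines <- c(
    sprintf("# nbits=%d radius=%d kTop=%d threshold=%g",
            ad@nbits, ad@radius, ad@kTop, ad@threshold),
    paste(ad@ids, hex, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeADModel
#' @export
readADModel <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  gv <- function(key) as.numeric(sub(sprintf(".*%s=([0-9.]+).*", key),
                                     "\\1", hdr))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- vapply(body, `[[`, character(1), 1)
  nbits <- as.integer(gv("nbits"))
  fps <- t(vapply(body, function(b) .hexToBits(b[[2]], nbits),
                  logical(nbits)))
  new("ADModel", fps = fps, ids = ids, kTop = as.integer(gv("kTop")),
      threshold = gv("threshold"), nbits = nbits,
      radius = as.integer(gv("radius")))
}

.bitsToHex <- function(bits) {
  stopifnot(length(bits) %% 4 == 0)
  nib <- vapply(seq_len(length(bits) / 4), function(i) {
    b <- bits[(4 * i - 3):(4 * i)]
    sum(b * c(8, 4, 2, 1))
  }, numeric(1))
  paste(sprintf("%x", as.integer(nib)), collapse = "")
}

.hexToBits <- function(hex, nbits) {
  nib <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  bits <- unlist(lapply(nib, function(v)
    as.logical(bitwAnd(v, c(8L, 4L, 2L, 1L)))))
  bits[seq_len(nbits)]
}
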