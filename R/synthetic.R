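# Deterministic generators for test inputs: planted-signal descriptor
# matrices (minority positive class, correlated informative block, sparse
# signal among Gaussian noise) and rule-labeled random peptide sets whose
# class follows an acidic-residue rule that 2D descriptors can see.

#' Planted-signal descriptor matrix
#'
#' Gaussian feature matrix with an informative block: the first
#' \code{nInformative} features are mean-shifted by \code{effectSize}
#' standard deviations in the positive class and share pairwise
#' correlation \code{rho} within the block; the remaining features are
#' independent noise. Missing values are injected completely at random.
#'
#' @param nPos,nNeg class sizes (default 50/50).
#' @param nFeatures total features, default 100.
#' @param nInformative informative features, default 5.
#' @param effectSize mean shift in sd units, default 2.
#' @param rho within-block correlation, default 0.3.
#' @param missingFrac MCAR missing fraction, default 0.
#' @param seed integer seed.
#' @return list: \code{X} (matrix with NAs), \code{y} (0/1),
#'   \code{informative} (feature names).
#' @export
makePlantedDataset <- function(nPos = 50L, nNeg = 50L, nFeatures = 100L,
                               nInformative = 5L, effectSize = 2,
                               rho = 0.3, missingFrac = 0, seed = 1L) {
  stopifnot(nInformative <= nFeatures, nPos > 0, nNeg > 0,
            rho >= 0, rho < 1, missingFrac >= 0, missingFrac < 1)
  n <- nPos + nNeg
  feats <- sprintf("f%03d", seq_len(nFeatures))
  inform <- feats[seq_len(nInformative)]
  .withSeed(seed, {
    X <- matrix(stats::rnorm(n * nFeatures), n, nFeatures,
                dimnames = list(sprintf("s%03d", seq_len(n)), feats))
    if (nInformative > 1L && rho > 0) {
      # compound-symmetry block via a shared latent factor
      z <- stats::rnorm(n)
      B <- sqrt(rho) * z %*% t(rep(1, nInformative)) +
        sqrt(1 - rho) * X[, seq_len(nInformative)]
      X[, seq_len(nInformative)] <- B
    }
    y <- c(rep(1L, nPos), rep(0L, nNeg))
    X[y == 1L, seq_len(nInformative)] <-
      X[y == 1L, seq_len(nInformative), drop = FALSE] + effectSize
    if (missingFrac > 0) {
      mask <- matrix(stats::runif(n * nFeatures) < missingFrac,
                     n, nFeatures)
      # never blank out a full row
      for (i in which(rowSums(!mask) == 0L)) mask[i, 1] <- FALSE
      X[mask] <- NA_real_
    }
    list(X = X, y = y, informative = inform)
  })
}

#' Rule-labeled random peptide set
#'
#' Uniformly random peptide sequences over the 20 standard residues with
#' lengths uniform in \code{lengthRange}; a peptide is labeled umami (1)
#' iff it contains at least \code{minAcidic} acidic residues (D or E),
#' echoing the association between umami taste and glutamate/aspartate
#' content. Because uniform sampling yields few positives, the minority
#' class is topped up by rejection sampling (uniform conditional on the
#' class) until it reaches \code{minClassFrac} of the set, emulating the
#' roughly one-third minority fraction of curated umami datasets.
#'
#' @param n number of peptides (at least 4).
#' @param lengthRange integer length-2, default \code{c(2, 8)}.
#' @param seed integer seed.
#' @param minAcidic acidic-residue count defining the positive class,
#'   default 2.
#' @param minClassFrac minimum minority-class fraction, default 0.2.
#' @return data.frame with columns \code{id}, \code{input} (sequence),
#'   \code{notation} (\code{"fasta_peptide"}), \code{label}.
#' @export
makePeptideSet <- function(n, lengthRange = c(2L, 8L), seed = 1L,
                           minAcidic = 2L, minClassFrac = 0.2) {
  stopifnot(n >= 4L, lengthRange[1] >= 1L,
            lengthRange[2] >= lengthRange[1])
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  labelOf <- function(s) {
    as.integer(sum(strsplit(s, "")[[1]] %in% c("D", "E")) >= minAcidic)
  }
  rseq <- function() {
    len <- sample(seq(lengthRange[1], lengthRange[2]), 1L)
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }
  .withSeed(seed, {
    seqs <- replicate(n, rseq())
    labs <- vapply(seqs, labelOf, integer(1))
    needMinority <- function() {
      tab <- c(neg = sum(labs == 0L), pos = sum(labs == 1L))
      minorLab <- if (tab["pos"] <= tab["neg"]) 1L else 0L
      need <- ceiling(minClassFrac * n) - min(tab)
      list(lab = minorLab, need = need)
    }
    nm <- needMinority()
    guard <- 0L
    while (nm$need > 0L && guard < 1e5) {
      cand <- rseq()
      guard <- guard + 1L
      if (labelOf(cand) == nm$lab) {
        # replace a majority sample
        at <- which(labs != nm$lab)[1]
        seqs[at] <- cand
        labs[at] <- nm$lab
        nm <- needMinority()
      }
    }
    if (min(sum(labs == 0L), sum(labs == 1L)) == 0L)
      stop("could not realize both classes at this n")
    data.frame(id = sprintf("pep%04d", seq_len(n)), input = unname(seqs),
               notation = "fasta_peptide", label = unname(labs),
               stringsAsFactors = FALSE)
  })
}

#' Write a peptide set as a labeled FASTA file
#'
#' Headers carry \code{label=<0|1>} tokens readable by
#' \code{\link{readLabeledDataset}}.
#'
#' @param peptides data.frame from \code{\link{makePeptideSet}}.
#' @param path output file.
#' @export
writePeptideFasta <- function(peptides, path) {
  lines <- as.vector(rbind(
    sprintf(">%s label=%d", peptides$id, peptides$label),
    peptides$input))
  writeLines(lines, path)
  invisible(path)
}
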