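## Sequence-level relatedness of the proteins binding one fragment.

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under BLOSUM62 with affine gap penalties
#' (default opening 10, extension 0.5; a gap of length L costs
#' open + L * extend). Identity is the fraction of identical aligned pairs
#' over aligned columns (gaps included in the denominator). The letter X is
#' tolerated and scores 0 against everything.
#'
#' @param s1,s2 amino-acid sequences (character strings).
#' @param gap_open,gap_extend affine gap penalties.
#' @return A list of class \code{"alignment_result"}:
#'   \code{aligned_length} (columns), \code{identity_fraction},
#'   \code{score}.
#' @examples
#' smith_waterman("AAAA", "AAAA")$score  # 16
#' @export
smith_waterman <- function(s1, s2, gap_open = 10, gap_extend = 0.5) {
  if (nchar(s1) == 0L || nchar(s2) == 0L) {
    res <- list(aligned_length = 0L, identity_fraction = 0, score = 0)
    class(res) <- "alignment_result"
    return(res)
  }
  mat <- blosum62_x0()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  len <- nchar(ap)
  if (len == 0L || Biostrings::score(pa) <= 0) {
    res <- list(aligned_length = 0L, identity_fraction = 0, score = 0)
    class(res) <- "alignment_result"
    return(res)
  }
  pc <- strsplit(ap, "")[[1]]; sc <- strsplit(as_, "")[[1]]
  ident <- sum(pc == sc & pc != "-")
  res <- list(aligned_length = len,
              identity_fraction = ident / len,
              score = Biostrings::score(pa))
  class(res) <- "alignment_result"
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment: %d columns, %.1f%% identity, score %.1f>\n",
              x$aligned_length, 100 * x$identity_fraction, x$score))
  invisible(x)
}

## BLOSUM62 with the X row/column zeroed (X tolerated, scored 0)
blosum62_x0 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      m["X", ] <- 0L; m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

#' Sequence of the chain that carries a binding site
#'
#' Selects the protein chain containing more than half of the amino acids of
#' the fragment binding site; when no chain exceeds half, the plurality chain
#' is taken and the result is flagged. The returned sequence is the full
#' one-letter sequence of that chain in the complex.
#'
#' @param complex a \code{fragverse_complex}.
#' @param site a nonempty \code{protein_site}.
#' @return list(sequence, chain, flagged).
#' @export
site_chain_sequence <- function(complex, site) {
  stopifnot(!site$empty)
  sres <- unique(site$residues[, c("chain", "resno")])
  counts <- table(sres$chain)
  best <- names(counts)[which.max(counts)]
  flagged <- max(counts) <= sum(counts) / 2
  prot <- complex$protein
  chain_res <- unique(prot[prot$chain == best & !prot$is_h,
                           c("resno", "resname")])
  chain_res <- chain_res[order(chain_res$resno), ]
  seq1 <- paste(vapply(chain_res$resname, function(rn) {
    a <- suppressWarnings(bio3d::aa321(rn))
    if (is.na(a) || nchar(a) != 1L) "X" else a
  }, character(1)), collapse = "")
  list(sequence = seq1, chain = best, flagged = flagged)
}

#' Cluster proteins by pairwise sequence identity
#'
#' DBSCAN (min_samples = 2) on distance 1 - identity; pairs whose alignment
#' is shorter than \code{min_alignment_len} columns are forced to distance 1.
#' eps = 0.10 groups the same protein or close homologs (>= 90\% identity);
#' eps = 0.75 groups homologs at >= 25\% identity. Noise points are returned
#' as their own singleton clusters, so labels always partition the input.
#'
#' @param identities symmetric matrix of pairwise identity fractions
#'   (diagonal 1).
#' @param aligned_lengths symmetric matrix of alignment lengths (columns).
#' @param eps DBSCAN eps on 1 - identity.
#' @param min_alignment_len minimum alignment length to trust an identity.
#' @return Integer cluster labels.
#' @export
cluster_by_identity <- function(identities, aligned_lengths = NULL,
                                eps = 0.10, min_alignment_len = 100L) {
  d <- 1 - as.matrix(identities)
  if (!is.null(aligned_lengths))
    d[as.matrix(aligned_lengths) < min_alignment_len] <- 1
  diag(d) <- 0
  d[d < 0] <- 0
  d <- (d + t(d)) / 2
  labels <- dbscan_precomputed(d, eps, 2L)
  nz <- max(labels, 0L)
  for (i in which(labels == 0L)) {
    nz <- nz + 1L
    labels[i] <- nz
  }
  labels
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings for the package's sequence exports.
#'
#' @param path file path.
#' @param sequences named character vector of sequences (for writing).
#' @return \code{read_fasta}: a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
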