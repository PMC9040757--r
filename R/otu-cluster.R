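#' Greedy centroid clustering of ASV sequences into OTUs
#'
#' Classic abundance-sorted greedy clustering: sequences are processed in
#' decreasing total abundance (ties broken by lexicographic id); each
#' sequence joins the first existing centroid whose global pairwise
#' identity reaches the threshold, otherwise it founds a new OTU. Identity
#' is matches / alignment length under Needleman-Wunsch global alignment
#' (match +1, mismatch -1, gap -2 per position by default).
#'
#' @param seqs named character vector of nucleotide sequences over
#'   A/C/G/T/N, or a `Biostrings::DNAStringSet`.
#' @param identity_threshold proportion in \[0, 1\]; default 0.97.
#' @param abundances optional named numeric vector of per-sequence total
#'   abundance; missing entries default to 1.
#' @param match,mismatch,gap alignment scores (gap is the per-position
#'   linear gap penalty, given as a positive cost).
#' @return named character vector mapping each input id to its OTU id
#'   (`OTU_1`, `OTU_2`, ... in founding order).
#' @export
cluster_otus <- function(seqs, identity_threshold = 0.97,
                         abundances = NULL,
                         match = 1, mismatch = -1, gap = 2) {
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (length(seqs) == 0) stop("empty sequence set")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  if (any(!nzchar(seqs))) stop("empty sequence(s) present")
  ab <- stats::setNames(rep(1, length(seqs)), names(seqs))
  if (!is.null(abundances)) {
    hit <- intersect(names(abundances), names(ab))
    ab[hit] <- abundances[hit]
  }
  ord <- order(-ab, names(seqs))
  ids <- names(seqs)[ord]
  sset <- Biostrings::DNAStringSet(seqs[ord])

  centroids <- integer(0)        # indices into sset, in founding order
  assignment <- integer(length(ids))
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (k in seq_along(centroids)) {
      pid <- global_identity(sset[[i]], sset[[centroids[k]]],
                             sub_mat, gap)
      if (pid >= identity_threshold) {
        assignment[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, i)
      assignment[i] <- length(centroids)
    }
  }
  stats::setNames(paste0("OTU_", assignment), ids)[names(seqs)]
}

# fraction of identical columns in the global alignment of two sequences
global_identity <- function(a, b, sub_mat, gap) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = sub_mat,
    gapOpening = 0, gapExtension = gap)
  aligned_len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / aligned_len
}
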