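#' Rarefy a count table to even depth
#'
#' Subsamples each sample's counts without replacement to a fixed depth
#' (multivariate hypergeometric draw). Samples whose total is below the
#' depth are dropped and their identifiers reported.
#'
#' @param x a `community_table` of counts.
#' @param depth positive integer target depth.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a `community_table` of counts whose rows all sum to `depth`,
#'   with attribute `dropped` listing removed sample ids.
#' @export
rarefy <- function(x, depth, seed = 1L) {
  stopifnot(inherits(x, "community_table"))
  if (is_relative(x)) stop("rarefy() needs a count table")
  if (length(depth) != 1 || depth <= 0 || depth != round(depth))
    stop("'depth' must be a positive integer")
  totals <- rowSums(x)
  keep <- totals >= depth
  dropped <- rownames(x)[!keep]
  if (!any(keep)) stop("no sample reaches depth ", depth)
  m <- unclass(x)[keep, , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (i in seq_len(nrow(m))) {
    out[i, ] <- rarefy_row(m[i, ], depth)
  }
  res <- retag(out, x)
  attr(res, "dropped") <- dropped
  res
}

# one multivariate-hypergeometric draw: depth items without replacement
# from the count multiset
rarefy_row <- function(counts, depth) {
  tot <- sum(counts)
  if (tot == depth) return(counts)
  pool <- rep.int(seq_along(counts), counts)
  tabulate(pool[sample.int(length(pool), depth)], nbins = length(counts))
}

#' Convert counts to relative abundances
#'
#' @param x a `community_table` of counts (or proportions, returned as-is)
#'   with strictly positive row sums.
#' @return a `community_table` with `is_relative = TRUE`; each row sums
#'   to 1.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "community_table"))
  if (is_relative(x)) return(x)
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("all-zero sample(s): ",
         paste(rownames(x)[rs == 0], collapse = ", "))
  retag(unclass(x) / rs, x, is_relative = TRUE)
}

#' Aggregate taxa at a taxonomic rank
#'
#' Sums columns sharing the same label at the requested rank. Taxa not
#' resolving at that rank fall into the `"unassigned"` bucket, which is
#' kept as its own column (never merged into `"Others"`).
#'
#' @param x a `community_table` at ASV or OTU level.
#' @param taxonomy data.frame as returned by [read_taxonomy()].
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return a `community_table` at the aggregated level; row sums are
#'   preserved exactly.
#' @export
aggregate_taxa <- function(x, taxonomy, rank = "phylum") {
  stopifnot(inherits(x, "community_table"))
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  if (!rank %in% ranks)
    stop("unknown rank '", rank, "'; expected one of ",
         paste(ranks, collapse = ", "))
  lab <- taxonomy[[rank]][match(colnames(x), taxonomy$taxon_id)]
  lab[is.na(lab) | !nzchar(lab)] <- "unassigned"
  groups <- unique(lab)
  m <- unclass(x)
  out <- vapply(groups, function(g)
    rowSums(m[, lab == g, drop = FALSE]), numeric(nrow(m)))
  if (nrow(m) == 1) out <- matrix(out, nrow = 1,
                                  dimnames = list(rownames(m), groups))
  retag(out, x, level = if (rank == "phylum") "phylum" else "custom")
}

#' Group rare phyla into an "Others" column
#'
#' Phyla whose mean relative abundance across all samples falls below the
#' threshold are summed into a single `"Others"` column. The default,
#' 0.001, groups phyla below 0.1% mean RA.
#'
#' @param x a relative `community_table` at phylum level.
#' @param threshold mean-RA proportion below which a phylum is grouped.
#' @return a `community_table`; row sums are preserved.
#' @export
group_rare_taxa <- function(x, threshold = 0.001) {
  stopifnot(inherits(x, "community_table"))
  if (!is_relative(x)) stop("group_rare_taxa() needs a relative table")
  rare <- colMeans(x) < threshold
  if (!any(rare)) return(x)
  m <- unclass(x)
  out <- cbind(m[, !rare, drop = FALSE],
               Others = rowSums(m[, rare, drop = FALSE]))
  retag(out, x)
}

# seed handling: set the RNG locally, restore global state on exit
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
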