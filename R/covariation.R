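#' Metabolite intensity matrix
#'
#' Light wrapper tagging a samples-by-compounds matrix with its
#' transform state (`raw`, `log`, or `log-range`).
#'
#' @param values numeric matrix, samples in rows, compounds in columns,
#'   with dimnames.
#' @param state transform state flag.
#' @return a `metabolite_matrix`.
#' @export
metabolite_matrix <- function(values, state = c("raw", "log",
                                                "log-range")) {
  state <- match.arg(state)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("metabolite matrix needs sample and compound names")
  if (state == "raw" && any(values < 0))
    stop("negative raw intensity")
  structure(values, state = state,
            class = c("metabolite_matrix", "matrix", "array"))
}

#' Log-transform and range-normalize metabolite intensities
#'
#' Per value: log10(x + eps), where eps is half the smallest positive
#' intensity of that compound and is added to zero values only; then
#' per-compound range scaling (v - min) / (max - min) into \[0, 1\].
#' Constant compounds map to 0 and are flagged. Idempotent: an already
#' log-range matrix is returned unchanged.
#'
#' @param m a raw `metabolite_matrix`.
#' @return a `metabolite_matrix` in state `log-range`; attribute
#'   `constant_compounds` lists degenerate columns.
#' @export
preprocess_metabolites <- function(m) {
  stopifnot(inherits(m, "metabolite_matrix"))
  if (attr(m, "state") == "log-range") return(m)
  if (attr(m, "state") != "raw") stop("expected a raw matrix")
  v <- unclass(m)
  if (any(v < 0)) stop("negative intensity")
  constant <- character(0)
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    pos <- col[col > 0]
    eps <- if (length(pos) > 0) min(pos) / 2 else 1
    col[col == 0] <- eps
    col <- log10(col)
    rng <- range(col)
    if (diff(rng) == 0) {
      col[] <- 0
      constant <- c(constant, colnames(v)[j])
    } else {
      col <- (col - rng[1]) / diff(rng)
    }
    v[, j] <- col
  }
  out <- metabolite_matrix(v, state = "log-range")
  attr(out, "constant_compounds") <- constant
  out
}

#' Rank taxa by random-forest importance for metabolite profiles
#'
#' For each compound, a random-forest regression of the compound on all
#' taxon relative abundances is fitted; per-taxon importance is the
#' permutation increase in out-of-bag MSE. A taxon's score is its
#' maximum importance across compounds (`combine = "max"`; mean
#' available), and the top `k` taxa by score are returned. Taxa are
#' prevalence-filtered before fitting.
#'
#' @param x a relative `community_table` restricted to the samples of
#'   interest (typically root samples).
#' @param m a log-range `metabolite_matrix` sharing samples with `x`.
#' @param k number of taxa to return (25 by convention).
#' @param n_trees number of trees per forest.
#' @param min_prevalence taxa below this prevalence are excluded.
#' @param combine `"max"` or `"mean"` across compounds.
#' @param seed integer seed.
#' @return data.frame `taxon`, `score`, `best_compound`, sorted by
#'   decreasing score, at most `k` rows (all taxa, with a warning, when
#'   fewer than `k` survive the filter).
#' @export
rank_predictive_taxa <- function(x, m, k = 25, n_trees = 500,
                                 min_prevalence = 0.1,
                                 combine = c("max", "mean"), seed = 1L) {
  combine <- match.arg(combine)
  shared <- intersect(rownames(x), rownames(m))
  if (length(shared) < 10) stop("need >= 10 shared samples")
  xm <- unclass(x)[shared, , drop = FALSE]
  keep <- colMeans(xm > 0) >= min_prevalence
  xm <- xm[, keep, drop = FALSE]
  ym <- unclass(m)[shared, , drop = FALSE]
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  imp <- matrix(0, ncol(xm), ncol(ym),
                dimnames = list(colnames(xm), colnames(ym)))
  for (j in seq_len(ncol(ym))) {
    if (stats::sd(ym[, j]) == 0) next
    rf <- randomForest::randomForest(x = xm, y = ym[, j],
                                     ntree = n_trees,
                                     importance = TRUE)
    imp[, j] <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  }
  score <- if (combine == "max") apply(imp, 1, max)
           else rowMeans(imp)
  best <- colnames(ym)[apply(imp, 1, which.max)]
  out <- data.frame(taxon = rownames(imp), score = score,
                    best_compound = best, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$taxon), ]
  if (nrow(out) < k)
    warning("only ", nrow(out), " taxa available after filtering (k = ",
            k, ")")
  utils::head(out, k)
}

#' Taxa-metabolite Spearman correlation network
#'
#' Spearman rho and its two-sided p for every (selected taxon, compound)
#' pair; edges are kept when |rho| > `r_min` AND p < `alpha` (raw,
#' unadjusted p-values). Pairs involving a constant vector are skipped
#' with a warning.
#'
#' @param x a relative `community_table`.
#' @param m a `metabolite_matrix`.
#' @param taxa character vector of selected taxon ids.
#' @param r_min correlation-magnitude threshold.
#' @param alpha significance threshold on the raw p-value.
#' @return a `covariation_network`: list with `edges` (taxon, compound,
#'   rho, p_value) and `thresholds`.
#' @export
correlation_network <- function(x, m, taxa, r_min = 0.5, alpha = 0.05) {
  shared <- intersect(rownames(x), rownames(m))
  if (length(shared) < 5) stop("need >= 5 shared samples")
  taxa <- intersect(taxa, colnames(x))
  xm <- unclass(x)[shared, taxa, drop = FALSE]
  ym <- unclass(m)[shared, , drop = FALSE]
  edges <- list()
  skipped <- 0L
  for (t in colnames(xm)) {
    tx <- xm[, t]
    if (stats::sd(tx) == 0) { skipped <- skipped + ncol(ym); next }
    for (cmpd in colnames(ym)) {
      cy <- ym[, cmpd]
      if (stats::sd(cy) == 0) { skipped <- skipped + 1L; next }
      ct <- suppressWarnings(
        stats::cor.test(tx, cy, method = "spearman",
                        alternative = "two.sided", exact = FALSE))
      if (abs(ct$estimate) > r_min && ct$p.value < alpha) {
        edges[[length(edges) + 1]] <-
          data.frame(taxon = t, compound = cmpd,
                     rho = unname(ct$estimate),
                     p_value = ct$p.value,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped > 0)
    warning(skipped, " constant pair(s) skipped")
  edges <- if (length(edges) > 0) do.call(rbind, edges)
           else data.frame(taxon = character(0), compound = character(0),
                           rho = numeric(0), p_value = numeric(0))
  structure(list(edges = edges,
                 thresholds = list(r_min = r_min, alpha = alpha)),
            class = "covariation_network")
}

#' Vegetative-to-reproductive abundance ratio per node
#'
#' Node annotation for the covariation network: mean relative abundance
#' (taxa) or intensity (compounds) over vegetative root samples divided
#' by the mean over reproductive root samples. A 0/0 ratio is flagged
#' `NA` (undefined).
#'
#' @param values a relative `community_table` or `metabolite_matrix`.
#' @param metadata metadata data.frame.
#' @param ids column ids (taxa or compounds) to annotate.
#' @param compartment compartment whose samples are used (default
#'   `"root"`).
#' @return named numeric vector of ratios (`NA` where undefined).
#' @export
stage_ra_ratio <- function(values, metadata, ids,
                           compartment = "root") {
  md <- metadata[match(rownames(values), metadata$sample_id), ,
                 drop = FALSE]
  veg <- rownames(values)[md$compartment == compartment &
                            md$stage == "vegetative"]
  rep_ <- rownames(values)[md$compartment == compartment &
                             md$stage == "reproductive"]
  if (length(veg) == 0 || length(rep_) == 0)
    stop("a growth stage is absent among ", compartment, " samples")
  ids <- intersect(ids, colnames(values))
  v <- unclass(values)
  mv <- colMeans(v[veg, ids, drop = FALSE])
  mr <- colMeans(v[rep_, ids, drop = FALSE])
  out <- mv / mr
  out[mv == 0 & mr == 0] <- NA_real_
  out
}

#' Export a covariation network as node and edge tables
#'
#' Writes tab-separated `<prefix>_nodes.tsv` and `<prefix>_edges.tsv`,
#' plus a GraphML file `<prefix>.graphml`.
#'
#' @param net a `covariation_network`.
#' @param node_ratios named vector from [stage_ra_ratio()] (optional).
#' @param prefix output path prefix.
#' @export
write_covariation_network <- function(net, prefix, node_ratios = NULL) {
  edges <- net$edges
  nodes <- data.frame(
    id = c(unique(edges$taxon), unique(edges$compound)),
    type = c(rep("taxon", length(unique(edges$taxon))),
             rep("compound", length(unique(edges$compound)))),
    stringsAsFactors = FALSE)
  nodes$stage_ratio <- if (is.null(node_ratios)) NA_real_
                       else unname(node_ratios[nodes$id])
  utils::write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gml <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
           '<key id="rho" for="edge" attr.name="rho" attr.type="double"/>',
           '<graph edgedefault="undirected">',
           sprintf('<node id="%s"/>', nodes$id),
           sprintf('<edge source="%s" target="%s"><data key="rho">%.6f</data></edge>',
                   edges$taxon, edges$compound, edges$rho),
           '</graph>', '</graphml>')
  writeLines(gml, paste0(prefix, ".graphml"))
  invisible(prefix)
}
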