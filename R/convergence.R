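#' Reference community profile
#'
#' The composition of a reference community (e.g. "unplanted soil before
#' sowing" or "reproductive root") as the arithmetic mean of its
#' samples' relative-abundance rows (median available as option).
#'
#' @param x a relative `community_table`.
#' @param sample_set non-empty character vector of sample ids.
#' @param fun `"mean"` (default) or `"median"`; a median profile is
#'   re-normalized to sum to 1.
#' @return named numeric composition vector over the table's taxa.
#' @export
reference_profile <- function(x, sample_set, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  if (!is_relative(x)) stop("reference_profile() needs a relative table")
  if (length(sample_set) == 0) stop("empty sample set")
  miss <- setdiff(sample_set, rownames(x))
  if (length(miss) > 0) stop("unknown samples: ", miss[1])
  m <- unclass(x)[sample_set, , drop = FALSE]
  prof <- if (fun == "mean") colMeans(m)
          else apply(m, 2, stats::median)
  if (fun == "median") prof <- prof / sum(prof)
  prof
}

#' Per-sample distances to initial and final reference communities
#'
#' For every sample, the Bray-Curtis dissimilarity to the initial
#' reference (unplanted soil) and to the final reference (reproductive
#' root), plus the Euclidean norm of that 2-vector used for 1-D distance
#' distributions.
#'
#' @param x a relative `community_table`.
#' @param ref_init,ref_final composition vectors over the same taxa as
#'   `x` (see [reference_profile()]).
#' @return a `convergence_coordinates` data.frame: `sample_id`,
#'   `d_init`, `d_final`, `norm`; attributes `level` and `kingdom`.
#' @export
convergence_coordinates <- function(x, ref_init, ref_final) {
  if (!is_relative(x)) stop("needs a relative table")
  for (ref in list(ref_init, ref_final)) {
    if (length(ref) != ncol(x) ||
        !identical(names(ref), colnames(x)))
      stop("reference profile does not match the table's taxa")
  }
  m <- unclass(x)
  bc_to <- function(ref) {
    apply(m, 1, function(row)
      sum(abs(row - ref)) / (sum(row) + sum(ref)))
  }
  out <- data.frame(sample_id = rownames(x),
                    d_init = bc_to(ref_init),
                    d_final = bc_to(ref_final),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$norm <- sqrt(out$d_init^2 + out$d_final^2)
  structure(out, level = table_level(x), kingdom = table_kingdom(x),
            class = c("convergence_coordinates", "data.frame"))
}

#' Separation of two groups in the convergence plane
#'
#' The statistic is the Euclidean distance between the two group
#' centroids in the (d_init, d_final) plane; its significance comes from
#' permuting group labels.
#'
#' @param coords a `convergence_coordinates` data.frame.
#' @param metadata metadata data.frame (matched by `sample_id`).
#' @param group_a,group_b logical predicates given as named lists of
#'   metadata column = value pairs (e.g.
#'   `list(compartment = "soil", stage = "vegetative")`), or directly as
#'   character vectors of sample ids.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list with `delta` (centroid distance), `p_value`, and the two
#'   group sizes.
#' @export
group_separation <- function(coords, metadata, group_a, group_b,
                             n_perm = 999, seed = 1L) {
  ids_a <- resolve_group(coords, metadata, group_a)
  ids_b <- resolve_group(coords, metadata, group_b)
  if (length(ids_a) == 0 || length(ids_b) == 0)
    stop("empty group")
  xy <- as.matrix(coords[match(c(ids_a, ids_b), coords$sample_id),
                         c("d_init", "d_final")])
  na <- length(ids_a)
  n <- nrow(xy)
  centroid_delta <- function(idx_a) {
    ca <- colMeans(xy[idx_a, , drop = FALSE])
    cb <- colMeans(xy[-idx_a, , drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }
  obs <- centroid_delta(seq_len(na))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  exceed <- 0
  for (b in seq_len(n_perm)) {
    if (centroid_delta(sample.int(n, na)) >= obs - 1e-12)
      exceed <- exceed + 1
  }
  list(delta = obs, p_value = (1 + exceed) / (1 + n_perm),
       n_a = na, n_b = n - na)
}

resolve_group <- function(coords, metadata, group) {
  if (is.character(group)) return(intersect(group, coords$sample_id))
  md <- metadata[match(coords$sample_id, metadata$sample_id), ,
                 drop = FALSE]
  sel <- rep(TRUE, nrow(md))
  for (col in names(group)) sel <- sel & md[[col]] %in% group[[col]]
  coords$sample_id[sel]
}

#' Convergence contrast at ASV versus phylum level
#'
#' Runs the full convergence analysis — reference profiles, per-sample
#' coordinates, and group separation — on the same sample set at two
#' taxonomic levels, so that phylum-level convergence can be compared
#' with the ASV-level signal.
#'
#' @param x_asv,x_phylum relative `community_table`s over identical
#'   sample sets (typically ASV-level and its phylum aggregation).
#' @param metadata metadata data.frame.
#' @param init_samples,final_samples sample ids defining the initial and
#'   final reference communities.
#' @inheritParams group_separation
#' @return list with per-level `coordinates` and `separation`
#'   (elements `asv` and `phylum`), and a `summary` data.frame
#'   (level, delta, p_value).
#' @export
level_contrast <- function(x_asv, x_phylum, metadata,
                           init_samples, final_samples,
                           group_a, group_b, n_perm = 999, seed = 1L) {
  if (!setequal(rownames(x_asv), rownames(x_phylum)))
    stop("the two tables cover different sample sets")
  run_level <- function(tab) {
    ref_i <- reference_profile(tab, init_samples)
    ref_f <- reference_profile(tab, final_samples)
    co <- convergence_coordinates(tab, ref_i, ref_f)
    sep <- group_separation(co, metadata, group_a, group_b,
                            n_perm = n_perm, seed = seed)
    list(coordinates = co, separation = sep)
  }
  asv <- run_level(x_asv)
  phy <- run_level(x_phylum)
  list(asv = asv, phylum = phy,
       summary = data.frame(
         level = c("ASV", "phylum"),
         delta = c(asv$separation$delta, phy$separation$delta),
         p_value = c(asv$separation$p_value, phy$separation$p_value),
         stringsAsFactors = FALSE))
}
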