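#' Per-taxon prevalence over a sample set
#'
#' Fraction of the given samples in which each taxon has nonzero
#' abundance.
#'
#' @param x a `community_table`.
#' @param sample_set character vector of sample ids.
#' @return named numeric vector in \[0, 1\], one entry per taxon.
#' @export
prevalence <- function(x, sample_set) {
  if (length(sample_set) == 0) stop("empty sample set")
  miss <- setdiff(sample_set, rownames(x))
  if (length(miss) > 0)
    stop("samples not in table: ", paste(utils::head(miss, 5),
                                         collapse = ", "))
  m <- unclass(x)[sample_set, , drop = FALSE]
  colMeans(m > 0)
}

#' Stable taxa of a compartment
#'
#' A taxon is stable when it is found in more than a fraction `theta`
#' (default 0.8, i.e. "more than 80% of samples") of the compartment's
#' samples at BOTH the vegetative and the reproductive stage. The
#' inequality is strict by default; set `strict = FALSE` for ">=".
#' Prevalence is pooled across managements and genotypes within each
#' compartment-by-stage set.
#'
#' @param x a `community_table` (detection = nonzero value; apply to the
#'   rarefied table for the depth-standardized definition).
#' @param metadata metadata data.frame covering the table's samples.
#' @param compartment compartment to evaluate (`"soil"`,
#'   `"rhizosphere"`, `"root"`).
#' @param theta prevalence threshold.
#' @param strict logical; strict ">" (default) or ">=".
#' @return character vector of stable taxon ids; attributes
#'   `prevalence_vegetative` and `prevalence_reproductive` carry the
#'   underlying per-taxon prevalences.
#' @export
stable_taxa <- function(x, metadata, compartment, theta = 0.8,
                        strict = TRUE) {
  md <- match_metadata(x, metadata)
  sel <- md$compartment == compartment
  veg <- rownames(x)[sel & md$stage == "vegetative"]
  rep_ <- rownames(x)[sel & md$stage == "reproductive"]
  if (length(veg) == 0 || length(rep_) == 0)
    stop("compartment '", compartment,
         "' lacks samples at one of the stages")
  pv <- prevalence(x, veg)
  pr <- prevalence(x, rep_)
  ok <- if (strict) pv > theta & pr > theta else pv >= theta & pr >= theta
  out <- colnames(x)[ok]
  attr(out, "prevalence_vegetative") <- pv
  attr(out, "prevalence_reproductive") <- pr
  out
}

#' Aggregated relative abundance of a taxon set
#'
#' Mean over the chosen samples of the per-sample sum of the set's
#' relative abundances, in percent.
#'
#' @param x a relative `community_table`.
#' @param taxon_set character vector of taxon ids (may be empty: 0%).
#' @param sample_set character vector of sample ids.
#' @return scalar percent in \[0, 100\].
#' @export
aggregated_ra <- function(x, taxon_set, sample_set) {
  if (!is_relative(x)) stop("aggregated_ra() needs a relative table")
  if (length(sample_set) == 0) stop("empty sample set")
  miss <- setdiff(sample_set, rownames(x))
  if (length(miss) > 0) stop("unknown samples: ", miss[1])
  taxon_set <- intersect(taxon_set, colnames(x))
  m <- unclass(x)[sample_set, taxon_set, drop = FALSE]
  100 * mean(rowSums(m))
}

#' Stable-to-dynamic ratio
#'
#' Ratio of aggregated relative abundances between the stable and the
#' dynamic (complement) community members:
#' ratio = stable_aRA / (100 - stable_aRA). E.g. a stable aRA of 39.35%
#' leaves 60.65% dynamic and gives a ratio of 0.65.
#'
#' @param stable_ara stable aggregated RA in percent, strictly between
#'   0 and 100.
#' @return list with `ratio` (full precision), `ratio_2dp` (rounded to
#'   two decimals) and `dynamic_ara`.
#' @export
stable_dynamic_ratio <- function(stable_ara) {
  if (stable_ara <= 0 || stable_ara >= 100)
    stop("ratio undefined for stable aRA of ", stable_ara, "%")
  r <- stable_ara / (100 - stable_ara)
  list(ratio = r, ratio_2dp = round(r, 2),
       dynamic_ara = 100 - stable_ara)
}

#' Venn-region counts for named taxon sets
#'
#' Counts every region of the inclusion-exclusion partition of two or
#' more named sets (the numbers a Venn diagram displays).
#'
#' @param sets named list of character vectors.
#' @return data.frame with one row per non-empty membership pattern:
#'   `region` (set names joined by `&`), `count`.
#' @export
compartment_overlap <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)))
    stop("need >= 2 named sets")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL,
                                                              names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  counts <- apply(patterns, 1, function(p) {
    sum(apply(member, 1, function(row) all(row == p)))
  })
  region <- apply(patterns, 1, function(p)
    paste(names(sets)[as.logical(p)], collapse = "&"))
  data.frame(region = region, count = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full stable/dynamic partition for one compartment
#'
#' Convenience wrapper producing the per-compartment partition: stable
#' and dynamic taxon sets, per-stage stable aggregated RAs and
#' stable-to-dynamic ratios.
#'
#' @inheritParams stable_taxa
#' @param x_rel relative `community_table` used for aRA (defaults to
#'   `to_relative(x)`).
#' @return a `stability_partition` list.
#' @export
stability_partition <- function(x, metadata, compartment, theta = 0.8,
                                strict = TRUE, x_rel = to_relative(x)) {
  st <- stable_taxa(x, metadata, compartment, theta, strict)
  md <- match_metadata(x, metadata)
  observed <- colnames(x)[colSums(unclass(x)[
    md$compartment == compartment, , drop = FALSE]) > 0]
  dyn <- setdiff(observed, st)
  per_stage <- lapply(c(vegetative = "vegetative",
                        reproductive = "reproductive"), function(s) {
    ss <- rownames(x)[md$compartment == compartment & md$stage == s]
    ara <- aggregated_ra(x_rel, as.character(st), ss)
    ratio <- if (ara > 0 && ara < 100) stable_dynamic_ratio(ara)
             else list(ratio = NA_real_, ratio_2dp = NA_real_,
                       dynamic_ara = 100 - ara)
    list(stable_ara = ara, dynamic_ara = ratio$dynamic_ara,
         ratio = ratio$ratio, ratio_2dp = ratio$ratio_2dp)
  })
  structure(list(compartment = compartment,
                 kingdom = table_kingdom(x),
                 theta = theta,
                 stable = as.character(st),
                 dynamic = dyn,
                 stages = per_stage),
            class = "stability_partition")
}

#' @export
print.stability_partition <- function(x, ...) {
  cat(sprintf("<stability_partition> %s %s: %d stable / %d dynamic taxa (theta = %g)\n",
              x$kingdom, x$compartment, length(x$stable),
              length(x$dynamic), x$theta))
  for (s in names(x$stages))
    cat(sprintf("  %s: stable aRA %.2f%%, ratio %.2f\n", s,
                x$stages[[s]]$stable_ara, x$stages[[s]]$ratio))
  invisible(x)
}

#' @rdname stability_partition
#' @param partition a `stability_partition`.
#' @param path output path for the JSON serialization.
#' @export
write_stability_partition <- function(partition, path) {
  jsonlite::write_json(unclass(partition), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
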