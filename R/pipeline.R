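#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults follow
#' the field-survey conventions: rarefaction depths of 1,000 (bacteria),
#' 10,000 (fungi) and 2,000 (oomycetes); Shannon averaged over 999
#' rarefactions; stability threshold 0.8; network thresholds
#' |rho| > 0.5 at raw p < 0.05 over the top 25 random-forest taxa; 999
#' permutations for every permutation test.
#'
#' @param counts named list (by kingdom) of count-table paths, or of
#'   `community_table` objects.
#' @param metadata path to the metadata TSV, or a metadata data.frame.
#' @param taxonomy named list (by kingdom) of taxonomy paths or
#'   data.frames.
#' @param metabolites optional path to a samples-by-compounds TSV, or a
#'   `metabolite_matrix` (raw intensities).
#' @param rarefaction_depth named per-kingdom depths.
#' @param n_rarefactions rarefactions averaged for the Shannon index.
#' @param theta stable-taxon prevalence threshold.
#' @param r_min,alpha,k covariation-network thresholds.
#' @param n_perm permutations for PERMANOVA and separation tests.
#' @param permanova_terms factors partitioned by PERMANOVA, in order.
#' @param rare_phylum_threshold mean-RA cutoff for the "Others" bucket.
#' @param seed master seed; per-stage seeds are derived from it as
#'   `seed + stage offset` (rarefaction +1, alpha +2, beta +3,
#'   convergence +4, covariation +5), so any stage can be reproduced in
#'   isolation.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(counts, metadata, taxonomy,
                            metabolites = NULL,
                            rarefaction_depth = c(bacteria = 1000,
                                                  fungi = 10000,
                                                  oomycetes = 2000),
                            n_rarefactions = 999,
                            theta = 0.8, r_min = 0.5, alpha = 0.05,
                            k = 25, n_perm = 999,
                            permanova_terms = c("management",
                                                "compartment", "stage"),
                            rare_phylum_threshold = 0.001,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (any(rarefaction_depth <= 0)) stop("depths must be positive")
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, manifest_env, expr) {
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  manifest_env$stages <- c(manifest_env$stages, name)
  res
}

#' Run the full analysis pipeline
#'
#' Per kingdom: rarefaction, alpha diversity (repeated-rarefaction
#' Shannon with Wilcoxon+FDR letters by compartment), beta diversity
#' (Bray-Curtis, PCoA, PERMANOVA), the phylum pipeline (aggregation,
#' rare-phylum grouping, phylum-level Bray-Curtis), the stable/dynamic
#' partition per compartment, the ASV-versus-phylum convergence
#' contrast, and — when metabolites are supplied — the taxa-metabolite
#' covariation network on root samples. Every intermediate artifact is
#' written under `out_dir`, along with a JSON run manifest recording
#' stages, seeds and the package version.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisible list of in-memory results per kingdom plus the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env()
  env$stages <- character(0)

  metadata <- run_stage("read_metadata", env, {
    if (is.character(config$metadata))
      read_sample_metadata(config$metadata)
    else validate_sample_metadata(config$metadata)
  })

  results <- list()
  for (kg in names(config$counts)) {
    kdir <- file.path(out_dir, kg)
    dir.create(kdir, showWarnings = FALSE)
    res <- list()

    tab <- run_stage(paste0("read_counts_", kg), env, {
      x <- config$counts[[kg]]
      if (is.character(x)) read_community_table(x, kingdom = kg) else x
    })
    taxo <- run_stage(paste0("read_taxonomy_", kg), env, {
      x <- config$taxonomy[[kg]]
      if (is.character(x)) read_taxonomy(x) else x
    })

    depth <- config$rarefaction_depth[[kg]]
    rar <- run_stage(paste0("rarefy_", kg), env, {
      r <- rarefy(tab, depth, seed = config$seed + 1L)
      write_community_table(r, file.path(kdir, "rarefied_counts.tsv"))
      r
    })
    res$rarefied <- rar
    res$dropped <- attr(rar, "dropped")
    md <- metadata[metadata$sample_id %in% rownames(rar), , drop = FALSE]

    res$alpha <- run_stage(paste0("alpha_", kg), env, {
      sh <- rarefied_shannon(tab, depth,
                             n_rarefactions = config$n_rarefactions,
                             seed = config$seed + 2L)
      sh <- sh[names(sh) %in% rownames(rar)]
      grp <- md$compartment[match(names(sh), md$sample_id)]
      wf <- if (length(unique(grp)) >= 2 && all(table(grp) >= 2))
        wilcoxon_fdr(as.numeric(sh), grp, alpha = config$alpha)
      else NULL
      utils::write.table(
        data.frame(sample_id = names(sh), shannon = as.numeric(sh)),
        file.path(kdir, "alpha_shannon.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      list(shannon = sh, compartment_test = wf)
    })

    res$beta <- run_stage(paste0("beta_", kg), env, {
      bc <- bray_curtis(rar)
      write_distance_matrix(bc, file.path(kdir, "bray_curtis.tsv"))
      ord <- pcoa(bc, n_axes = 4)
      utils::write.table(
        data.frame(sample_id = rownames(ord$coordinates),
                   ord$coordinates),
        file.path(kdir, "pcoa_coordinates.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      terms <- config$permanova_terms[
        vapply(config$permanova_terms, function(t)
          length(unique(term_factor(t, md[match(rownames(bc),
                                                md$sample_id), ]))) >= 2,
          logical(1))]
      pmv <- if (length(terms) > 0)
        permanova(bc, md, terms, n_perm = config$n_perm,
                  seed = config$seed + 3L)
      else NULL
      if (!is.null(pmv))
        utils::write.table(pmv, file.path(kdir, "permanova.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      list(bc = bc, pcoa = ord, permanova = pmv)
    })

    res$phylum <- run_stage(paste0("phylum_", kg), env, {
      rel <- to_relative(rar)
      phy <- aggregate_taxa(rel, taxo, "phylum")
      phy_g <- group_rare_taxa(phy, config$rare_phylum_threshold)
      write_community_table(phy_g,
                            file.path(kdir, "phylum_relative.tsv"))
      list(relative = rel, phylum = phy,
           phylum_grouped = phy_g,
           bc = bray_curtis(phy))
    })

    res$stability <- run_stage(paste0("stability_", kg), env, {
      out <- list()
      for (cm in unique(md$compartment)) {
        has <- all(c("vegetative", "reproductive") %in%
                     md$stage[md$compartment == cm])
        if (!has) next
        part <- stability_partition(rar, md, cm, theta = config$theta,
                                    x_rel = res$phylum$relative)
        write_stability_partition(
          part, file.path(kdir, paste0("stability_", cm, ".json")))
        out[[cm]] <- part
      }
      if (length(out) >= 2)
        out$overlap <- compartment_overlap(
          lapply(out, function(p) p$stable))
      out
    })

    res$convergence <- run_stage(paste0("convergence_", kg), env, {
      init_s <- md$sample_id[md$compartment == "soil" &
                               md$stage == "unplanted"]
      final_s <- md$sample_id[md$compartment == "root" &
                                md$stage == "reproductive"]
      soil_v <- md$sample_id[md$compartment == "soil" &
                               md$stage == "vegetative"]
      soil_r <- md$sample_id[md$compartment == "soil" &
                               md$stage == "reproductive"]
      if (length(init_s) == 0 || length(final_s) == 0 ||
          length(soil_v) == 0 || length(soil_r) == 0) {
        NULL
      } else {
        lc <- level_contrast(res$phylum$relative,
                             to_relative(res$phylum$phylum),
                             md, init_s, final_s,
                             group_a = soil_v, group_b = soil_r,
                             n_perm = config$n_perm,
                             seed = config$seed + 4L)
        jsonlite::write_json(lc$summary,
                             file.path(kdir, "convergence.json"),
                             auto_unbox = TRUE, digits = NA)
        lc
      }
    })

    if (!is.null(config$metabolites)) {
      res$covariation <- run_stage(paste0("covariation_", kg), env, {
        mm <- if (is.character(config$metabolites))
          read_metabolite_matrix(config$metabolites)
        else config$metabolites
        root_s <- md$sample_id[md$compartment == "root"]
        rel_root <- res$phylum$relative[
          rownames(res$phylum$relative) %in% root_s, , drop = FALSE]
        rel_root <- retag(unclass(rel_root), res$phylum$relative)
        mlr <- preprocess_metabolites(mm)
        ranked <- rank_predictive_taxa(rel_root, mlr, k = config$k,
                                       seed = config$seed + 5L)
        net <- correlation_network(rel_root, mlr, ranked$taxon,
                                   r_min = config$r_min,
                                   alpha = config$alpha)
        ratios <- c(stage_ra_ratio(res$phylum$relative, md,
                                   ranked$taxon),
                    stage_ra_ratio(mlr, md, colnames(mlr)))
        write_covariation_network(net, file.path(kdir, "network"),
                                  node_ratios = ratios)
        list(ranked = ranked, network = net, stage_ratios = ratios)
      })
    }
    results[[kg]] <- res
  }

  manifest <- list(
    package = "rhizodyn",
    version = as.character(utils::packageVersion("rhizodyn")),
    seed = config$seed,
    stage_seeds = stats::setNames(config$seed + 1:5,
                                  c("rarefaction", "alpha", "beta",
                                    "convergence", "covariation")),
    n_rarefactions = config$n_rarefactions,
    theta = config$theta, n_perm = config$n_perm,
    stages = env$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Read a metabolite intensity matrix
#'
#' Tab-separated, samples in rows, first column `sample_id`.
#'
#' @param path file path.
#' @return a raw `metabolite_matrix`.
#' @export
read_metabolite_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE)
  metabolite_matrix(as.matrix(df), state = "raw")
}

#' Generate the demonstration dataset
#'
#' Writes a small two-kingdom synthetic experiment (about 240 samples,
#' 200 taxa per kingdom, with metabolites linked to root bacteria) plus
#' its ground-truth ledger, in the formats the pipeline reads.
#'
#' @param dir output directory.
#' @param seed master seed.
#' @return invisible named vector of written file paths.
#' @export
make_demo <- function(dir, seed = 1L) {
  cfg <- sim_config(kingdoms = c("bacteria", "fungi"),
                    managements = c("NK", "CONMIN"),
                    genotypes = c("B73", "F2"),
                    n_reps = 6, seed = seed)
  ex <- generate_experiment(cfg)
  rel <- to_relative(ex$tables$bacteria)
  met <- generate_metabolites(ex$metadata, rel, ex$truth, cfg)
  ex$truth <- met$truth
  write_experiment(ex, dir, metabolites = met$metabolites)
}
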