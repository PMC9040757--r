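#' Configuration for the field-experiment simulator
#'
#' Encodes the sampling design of a two-field maize experiment — three
#' compartments (bulk soil, rhizosphere, root), three sampling times
#' (unplanted soil before sowing, vegetative, reproductive), four soil
#' managements across two fields, five genotypes — together with the
#' generating model's parameters: a planted stable core per compartment,
#' a stage-specific dynamic shell, phylum-level convergence of soil and
#' rhizosphere communities toward the reproductive-root composition, and
#' Dirichlet-multinomial count noise.
#'
#' @param kingdoms kingdoms to simulate.
#' @param n_taxa,n_phyla taxa and phyla per kingdom.
#' @param compartments subset of soil/rhizosphere/root (root must be
#'   included: it defines the final reference community).
#' @param managements subset of NK/NPK/CONMIN/BIODYN; NK and NPK sit in
#'   field DEMO (one plot each), CONMIN and BIODYN in DOK (three plots
#'   each), mirroring the long-term field layout.
#' @param genotypes host genotypes planted in every plot.
#' @param n_reps plants per genotype, plot and stage (6 in the field
#'   design).
#' @param n_soil_reps bulk-soil samples per plot and planted stage.
#' @param n_unplanted unplanted-soil samples per plot.
#' @param stable_core_size,core_mean_ra number of planted stable-core
#'   taxa per compartment and their combined expected relative
#'   abundance.
#' @param kappa_vegetative,kappa_reproductive phylum-level convergence
#'   strength of soil/rhizosphere communities toward the
#'   reproductive-root composition (0 = none; unplanted soil always 0).
#' @param alpha0 Dirichlet concentration (larger = less compositional
#'   overdispersion).
#' @param rarefaction_depth named per-kingdom depth (defaults 1,000
#'   bacteria / 10,000 fungi / 2,000 oomycetes).
#' @param depth_factor,depth_sdlog sequencing depths are log-normal
#'   around `depth_factor` times the kingdom's rarefaction depth, so a
#'   known small fraction of samples falls below depth and is dropped at
#'   rarefaction.
#' @param occupancy probability a taxon is native to a compartment
#'   (independent across compartments, so compartments overlap only
#'   partially at ASV level).
#' @param off_stage_factor weight multiplier for a dynamic shell taxon
#'   at its non-preferred stage (rhizosphere/root only; bulk-soil stage
#'   structure comes solely from the convergence mixing).
#' @param base_sdlog log-normal sd of baseline taxon weights.
#' @param plot_sd,management_sd,genotype_sd log-normal sds of the
#'   plot-, management- and genotype-level taxon-weight jitters.
#' @param n_compounds,n_linked_taxa,beta,noise_sd metabolite model:
#'   number of compounds, number of root-core taxa carrying a linear
#'   taxon-lipid link of strength `beta` (applied to the standardized
#'   taxon RA inside an exponential link), and Gaussian noise sd.
#' @param stage_effect_mean,stage_effect_sd mean and sd of the
#'   per-compound reproductive-stage main effect (set both to 0 for
#'   stage-free null metabolites).
#' @param seed master seed; all outputs are deterministic given it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(kingdoms = "bacteria",
                       n_taxa = 200, n_phyla = 12,
                       compartments = c("soil", "rhizosphere", "root"),
                       managements = c("NK", "NPK", "CONMIN", "BIODYN"),
                       genotypes = c("B73", "PH207", "DK105", "F2",
                                     "pht1;6"),
                       n_reps = 6, n_soil_reps = 3, n_unplanted = 6,
                       stable_core_size = 20, core_mean_ra = 0.4,
                       kappa_vegetative = 0.25,
                       kappa_reproductive = 0.5,
                       alpha0 = 500,
                       rarefaction_depth = c(bacteria = 1000,
                                             fungi = 10000,
                                             oomycetes = 2000),
                       depth_factor = 3, depth_sdlog = 0.3,
                       occupancy = 0.5, off_stage_factor = 0.01,
                       base_sdlog = 1.2,
                       plot_sd = 0.2, management_sd = 0.3,
                       genotype_sd = 0.1,
                       n_compounds = 30, n_linked_taxa = 5,
                       beta = 5, noise_sd = 0.1,
                       stage_effect_mean = 1, stage_effect_sd = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (!"root" %in% cfg$compartments)
    stop("'root' must be among the compartments")
  if (cfg$stable_core_size > cfg$n_taxa)
    stop("stable_core_size exceeds n_taxa")
  if (cfg$kappa_vegetative < 0 || cfg$kappa_vegetative > 1 ||
      cfg$kappa_reproductive < 0 || cfg$kappa_reproductive > 1)
    stop("kappa must lie in [0, 1]")
  if (cfg$alpha0 <= 0) stop("alpha0 must be positive")
  if (cfg$core_mean_ra <= 0 || cfg$core_mean_ra >= 1)
    stop("core_mean_ra must lie in (0, 1)")
  if (any(!cfg$kingdoms %in% names(cfg$rarefaction_depth)))
    stop("every kingdom needs a rarefaction depth")
  structure(cfg, class = "sim_config")
}

# field/plot layout for a set of managements (DEMO: 1 plot, DOK: 3)
management_layout <- function(managements) {
  do.call(rbind, lapply(managements, function(m) {
    fld <- if (m %in% c("NK", "NPK")) "DEMO" else "DOK"
    np <- if (fld == "DEMO") 1 else 3
    data.frame(management = m, field = fld,
               plot = paste0(m, "-", seq_len(np)),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a multi-kingdom field experiment with known ground truth
#'
#' Builds per-condition expected compositions (stable core at both
#' stages, stage-specific dynamic shell in rhizosphere and root,
#' phylum-level convergence of soil/rhizosphere toward the
#' reproductive-root profile) and draws Dirichlet-multinomial counts at
#' log-normal sequencing depths.
#'
#' @param config a [sim_config()].
#' @return list with `tables` (one count `community_table` per
#'   kingdom), `metadata`, `taxonomy` (one data.frame per kingdom), and
#'   `truth` (planted cores, expected compositions, convergence
#'   strengths; metabolite links are added by
#'   [generate_metabolites()]).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))

  metadata <- build_metadata(config)
  tables <- list()
  taxonomy <- list()
  truth <- list(kappa = c(unplanted = 0,
                          vegetative = config$kappa_vegetative,
                          reproductive = config$kappa_reproductive),
                core = list(), expected_composition = list(),
                links = NULL)
  for (kg in config$kingdoms) {
    sim <- simulate_kingdom(kg, metadata, config)
    tables[[kg]] <- sim$table
    taxonomy[[kg]] <- sim$taxonomy
    truth$core[[kg]] <- sim$core
    truth$expected_composition[[kg]] <- sim$expected
  }
  list(tables = tables, metadata = metadata, taxonomy = taxonomy,
       truth = truth)
}

build_metadata <- function(config) {
  lay <- management_layout(config$managements)
  rows <- list()
  add <- function(df) rows[[length(rows) + 1]] <<- df
  for (i in seq_len(nrow(lay))) {
    m <- lay$management[i]; fld <- lay$field[i]; pl <- lay$plot[i]
    if ("soil" %in% config$compartments) {
      if (config$n_unplanted > 0)
        add(data.frame(field = fld, management = m, plot = pl,
                       genotype = "none", compartment = "soil",
                       stage = "unplanted",
                       rep = seq_len(config$n_unplanted),
                       stringsAsFactors = FALSE))
      for (s in c("vegetative", "reproductive"))
        if (config$n_soil_reps > 0)
          add(data.frame(field = fld, management = m, plot = pl,
                         genotype = "none", compartment = "soil",
                         stage = s, rep = seq_len(config$n_soil_reps),
                         stringsAsFactors = FALSE))
    }
    for (comp in intersect(config$compartments,
                           c("rhizosphere", "root")))
      for (s in c("vegetative", "reproductive"))
        for (g in config$genotypes)
          add(data.frame(field = fld, management = m, plot = pl,
                         genotype = g, compartment = comp, stage = s,
                         rep = seq_len(config$n_reps),
                         stringsAsFactors = FALSE))
  }
  md <- do.call(rbind, rows)
  stage_code <- c(unplanted = "Un", vegetative = "V", reproductive = "R")
  comp_code <- c(soil = "S", rhizosphere = "Rh", root = "Rt")
  md$sample_id <- sprintf("%s.%s.%s.%s.r%02d",
                          gsub("[^A-Za-z0-9]", "", md$plot),
                          comp_code[md$compartment],
                          stage_code[md$stage],
                          gsub("[^A-Za-z0-9]", "", md$genotype),
                          md$rep)
  md$rep <- NULL
  validate_sample_metadata(
    md[c("sample_id", "field", "management", "plot", "genotype",
         "compartment", "stage")])
}

simulate_kingdom <- function(kingdom, metadata, config) {
  n <- config$n_taxa
  pfx <- substr(kingdom, 1, 1)
  taxa <- sprintf("%sASV_%03d", pfx, seq_len(n))
  phyla <- sprintf("%s_Phylum_%02d", kingdom, seq_len(config$n_phyla))
  # few dominant phyla, long tail
  phy_p <- exp(-0.35 * seq_len(config$n_phyla))
  phylum_of <- sample(phyla, n, replace = TRUE,
                      prob = phy_p / sum(phy_p))
  taxonomy <- data.frame(taxon_id = taxa, kingdom = kingdom,
                         phylum = phylum_of, class = "unassigned",
                         order = "unassigned", family = "unassigned",
                         genus = "unassigned",
                         stringsAsFactors = FALSE)

  comps <- config$compartments
  # baseline weights with partial compartment occupancy; every
  # compartment keeps at least stable_core_size + 10 native taxa
  native <- matrix(stats::runif(n * length(comps)) < config$occupancy,
                   n, length(comps), dimnames = list(taxa, comps))
  for (j in seq_along(comps)) {
    need <- config$stable_core_size + 10 - sum(native[, j])
    if (need > 0)
      native[sample(which(!native[, j]), need), j] <- TRUE
  }
  w_base <- matrix(stats::rlnorm(n * length(comps),
                                 sdlog = config$base_sdlog),
                   n, length(comps), dimnames = list(taxa, comps))
  w_base <- w_base * native

  core <- lapply(comps, function(cm)
    sample(taxa[native[, cm]], config$stable_core_size))
  names(core) <- comps

  # per compartment x stage weight vectors, before convergence mixing
  stages_of <- function(cm) if (cm == "soil")
    c("unplanted", "vegetative", "reproductive")
  else c("vegetative", "reproductive")
  # stage preference of the dynamic shell (rhizosphere/root only)
  pref <- sample(c("vegetative", "reproductive"), n, replace = TRUE)
  core_w <- stats::rlnorm(n, sdlog = 0.5)   # relative core weights

  w <- list()
  for (cm in comps) {
    is_core <- taxa %in% core[[cm]]
    for (s in stages_of(cm)) {
      wv <- w_base[, cm]
      wv[is_core] <- 0
      if (cm != "soil") {
        off <- !is_core & wv > 0 & pref != s
        wv[off] <- wv[off] * config$off_stage_factor
      }
      shell_sum <- sum(wv)
      wv[is_core] <- core_w[is_core] / sum(core_w[is_core]) *
        shell_sum * config$core_mean_ra / (1 - config$core_mean_ra)
      w[[paste(cm, s, sep = ".")]] <- wv / sum(wv)
    }
  }

  # phylum-level convergence of soil/rhizosphere toward the
  # reproductive-root profile, broadcast proportionally to member taxa
  pi_final <- w[["root.reproductive"]]
  kappa <- c(unplanted = 0, vegetative = config$kappa_vegetative,
             reproductive = config$kappa_reproductive)
  for (cm in intersect(comps, c("soil", "rhizosphere"))) {
    for (s in stages_of(cm)) {
      k <- kappa[[s]]
      if (k == 0) next
      w[[paste(cm, s, sep = ".")]] <-
        mix_phylum(w[[paste(cm, s, sep = ".")]], pi_final,
                   phylum_of, k)
    }
  }

  # condition-level jitters (constant across stages, so stage
  # contrasts are driven only by the model's stage structure)
  lay <- management_layout(config$managements)
  mg_j <- vapply(config$managements, function(m)
    exp(stats::rnorm(n, sd = config$management_sd)), numeric(n))
  pl_j <- vapply(lay$plot, function(p)
    exp(stats::rnorm(n, sd = config$plot_sd)), numeric(n))
  gt_j <- vapply(config$genotypes, function(g)
    exp(stats::rnorm(n, sd = config$genotype_sd)), numeric(n))
  colnames(mg_j) <- config$managements
  colnames(pl_j) <- lay$plot
  colnames(gt_j) <- config$genotypes

  depth_mu <- log(config$depth_factor *
                    config$rarefaction_depth[[kingdom]])
  counts <- matrix(0L, nrow(metadata), n,
                   dimnames = list(metadata$sample_id, taxa))
  expected <- w
  for (i in seq_len(nrow(metadata))) {
    md <- metadata[i, ]
    pi_s <- w[[paste(md$compartment, md$stage, sep = ".")]] *
      mg_j[, md$management] * pl_j[, md$plot]
    if (md$genotype != "none") pi_s <- pi_s * gt_j[, md$genotype]
    pi_s <- pi_s / sum(pi_s)
    depth <- max(1L, as.integer(round(
      stats::rlnorm(1, meanlog = depth_mu, sdlog = config$depth_sdlog))))
    counts[i, ] <- rdirichlet_multinom(pi_s * config$alpha0, depth)
  }
  list(table = community_table(counts, kingdom = kingdom,
                               level = "ASV"),
       taxonomy = taxonomy, core = core, expected = expected)
}

# rescale member-taxon weights so phylum totals hit
# (1 - kappa) * current + kappa * target; phyla absent from the source
# composition inherit the target's within-phylum profile (immigration)
mix_phylum <- function(pi_src, pi_tgt, phylum_of, kappa) {
  src_p <- tapply(pi_src, phylum_of, sum)
  tgt_p <- tapply(pi_tgt, phylum_of, sum)
  lev <- union(names(src_p), names(tgt_p))
  src_p <- ifelse(is.na(src_p[lev]), 0, src_p[lev])
  tgt_p <- ifelse(is.na(tgt_p[lev]), 0, tgt_p[lev])
  names(src_p) <- names(tgt_p) <- lev
  new_p <- (1 - kappa) * src_p + kappa * tgt_p
  out <- numeric(length(pi_src))
  for (p in lev) {
    idx <- phylum_of == p
    if (src_p[p] > 0) {
      out[idx] <- pi_src[idx] / src_p[p] * new_p[p]
    } else if (tgt_p[p] > 0) {
      out[idx] <- pi_tgt[idx] / tgt_p[p] * new_p[p]
    }
  }
  out / sum(out)
}

# one Dirichlet-multinomial draw
rdirichlet_multinom <- function(alpha, size) {
  pos <- alpha > 0
  g <- numeric(length(alpha))
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos])
  as.integer(stats::rmultinom(1, size, g / sum(g)))
}

#' Simulate metabolite intensities linked to root taxa
#'
#' Each compound's intensity is
#' `exp(baseline + stage_effect * is_reproductive + beta * z(RA) +
#' Gaussian noise)`, where the `beta` term is present only for the
#' planted linked compounds and `z(RA)` is the linked taxon's relative
#' abundance standardized across the root samples used. Values are
#' strictly positive by construction.
#'
#' @param metadata metadata data.frame.
#' @param x_rel relative `community_table` containing the root samples.
#' @param truth truth list from [generate_experiment()]; realized links
#'   are appended to it.
#' @param config a [sim_config()].
#' @return list with `metabolites` (a raw `metabolite_matrix` over the
#'   vegetative + reproductive root samples) and the updated `truth`.
#' @export
generate_metabolites <- function(metadata, x_rel, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  old <- local_seed(config$seed + 1L)
  on.exit(restore_seed(old))
  md <- match_metadata(x_rel, metadata)
  sel <- md$compartment == "root" &
    md$stage %in% c("vegetative", "reproductive")
  if (!any(sel)) stop("no root samples in the table")
  samples <- rownames(x_rel)[sel]
  is_rep <- md$stage[sel] == "reproductive"
  m <- unclass(x_rel)[samples, , drop = FALSE]

  kg <- table_kingdom(x_rel)
  core_pool <- intersect(truth$core[[kg]]$root, colnames(m))
  n_link <- min(config$n_linked_taxa, length(core_pool),
                config$n_compounds)
  linked_taxa <- if (n_link > 0) sample(core_pool, n_link)
                 else character(0)
  compounds <- sprintf("lipid_%02d", seq_len(config$n_compounds))

  base <- stats::rnorm(config$n_compounds, mean = 3, sd = 0.5)
  stage_eff <- stats::rnorm(config$n_compounds,
                            mean = config$stage_effect_mean,
                            sd = config$stage_effect_sd)
  out <- matrix(0, length(samples), config$n_compounds,
                dimnames = list(samples, compounds))
  for (j in seq_len(config$n_compounds)) {
    eta <- base[j] + stage_eff[j] * is_rep
    if (j <= n_link) {
      ra <- m[, linked_taxa[j]]
      z <- if (stats::sd(ra) > 0) (ra - mean(ra)) / stats::sd(ra)
           else rep(0, length(ra))
      eta <- eta + config$beta * z
    }
    noise <- if (config$noise_sd > 0)
      stats::rnorm(length(samples), sd = config$noise_sd) else 0
    out[, j] <- exp(eta + noise)
  }
  truth$links <- data.frame(
    taxon = linked_taxa,
    compound = compounds[seq_len(n_link)],
    beta = rep(config$beta, n_link),
    stringsAsFactors = FALSE)
  list(metabolites = metabolite_matrix(out, state = "raw"),
       truth = truth)
}

#' Write a simulated experiment to disk
#'
#' Emits the same formats the readers consume: per-kingdom count tables
#' (taxa-in-rows TSV), metadata and taxonomy TSVs, optional metabolite
#' TSV, and the truth ledger as JSON.
#'
#' @param experiment result of [generate_experiment()].
#' @param dir output directory (created if missing).
#' @param metabolites optional `metabolite_matrix`.
#' @return invisible named vector of written paths.
#' @export
write_experiment <- function(experiment, dir, metabolites = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (kg in names(experiment$tables)) {
    p <- file.path(dir, paste0(kg, "_counts.tsv"))
    write_community_table(experiment$tables[[kg]], p)
    paths[paste0("counts_", kg)] <- p
    pt <- file.path(dir, paste0(kg, "_taxonomy.tsv"))
    utils::write.table(experiment$taxonomy[[kg]], pt, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[paste0("taxonomy_", kg)] <- pt
  }
  pm <- file.path(dir, "metadata.tsv")
  utils::write.table(experiment$metadata, pm, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["metadata"] <- pm
  if (!is.null(metabolites)) {
    px <- file.path(dir, "metabolites.tsv")
    df <- data.frame(sample_id = rownames(metabolites),
                     unclass(metabolites), check.names = FALSE)
    utils::write.table(df, px, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["metabolites"] <- px
  }
  pj <- file.path(dir, "truth.json")
  jsonlite::write_json(experiment$truth, pj, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths["truth"] <- pj
  invisible(paths)
}
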