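small_cfg <- function(...) {
  args <- utils::modifyList(
    list(kingdoms = "bacteria", managements = "NK",
         genotypes = "B73", n_reps = 6, n_soil_reps = 6,
         n_unplanted = 6, n_taxa = 120),
    list(...))
  do.call(sim_config, args)
}

test_that("the generator is deterministic and conserves drawn depths", {
  cfg <- small_cfg(seed = 42)
  ex1 <- generate_experiment(cfg)
  ex2 <- generate_experiment(cfg)
  expect_identical(unclass(ex1$tables$bacteria),
                   unclass(ex2$tables$bacteria))
  expect_identical(ex1$metadata, ex2$metadata)
  # different seed, same schema, different counts
  ex3 <- generate_experiment(small_cfg(seed = 43))
  expect_identical(dim(ex1$tables$bacteria), dim(ex3$tables$bacteria))
  expect_false(identical(unclass(ex1$tables$bacteria),
                         unclass(ex3$tables$bacteria)))
  # integer totals: every row is a complete multinomial draw
  expect_true(all(rowSums(ex1$tables$bacteria) >= 1))
  expect_true(all(unclass(ex1$tables$bacteria) ==
                    round(unclass(ex1$tables$bacteria))))
})

test_that("metadata mirrors the factorial field design", {
  cfg <- sim_config(kingdoms = "bacteria",
                    managements = c("NK", "CONMIN"),
                    genotypes = c("B73", "F2"), n_reps = 2,
                    n_soil_reps = 2, n_unplanted = 3, n_taxa = 50,
                    seed = 1)
  ex <- generate_experiment(cfg)
  md <- ex$metadata
  expect_setequal(unique(md$field), c("DEMO", "DOK"))
  expect_equal(length(unique(md$plot[md$management == "CONMIN"])), 3L)
  expect_equal(length(unique(md$plot[md$management == "NK"])), 1L)
  expect_true(all(md$genotype[md$compartment == "soil"] == "none"))
  expect_setequal(unique(md$stage[md$compartment == "root"]),
                  c("vegetative", "reproductive"))
  expect_equal(anyDuplicated(md$sample_id), 0L)
})

test_that("with kappa = 0 soil composition is stage-invariant in expectation", {
  reps <- 6
  diffs <- pdiff <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- small_cfg(kappa_vegetative = 0, kappa_reproductive = 0,
                     n_soil_reps = 25, seed = 500 + i)
    ex <- generate_experiment(cfg)
    md <- ex$metadata
    rel <- to_relative(ex$tables$bacteria)
    v <- colMeans(unclass(rel)[md$compartment == "soil" &
                                 md$stage == "vegetative", ])
    r <- colMeans(unclass(rel)[md$compartment == "soil" &
                                 md$stage == "reproductive", ])
    # per-taxon two-sided t test on the dominant taxon
    top <- which.max(v + r)
    mv <- unclass(rel)[md$compartment == "soil" &
                         md$stage == "vegetative", top]
    mr <- unclass(rel)[md$compartment == "soil" &
                         md$stage == "reproductive", top]
    pdiff[i] <- t.test(mv, mr)$p.value
  }
  # no-effect null: rejections at alpha = 0.05 should be rare
  expect_lte(sum(pdiff < 0.05), 2)
})

test_that("planted core taxa reach near-total prevalence at both stages", {
  cfg <- small_cfg(seed = 77)
  ex <- generate_experiment(cfg)
  md <- ex$metadata
  core <- ex$truth$core$bacteria$root
  for (s in c("vegetative", "reproductive")) {
    pv <- prevalence(ex$tables$bacteria,
                     md$sample_id[md$compartment == "root" &
                                    md$stage == s])
    expect_true(all(pv[core] > 0.9))
  }
})

test_that("stage explains more distance variance than plot when built to", {
  ok <- logical(5)
  for (i in 1:5) {
    cfg <- sim_config(kingdoms = "bacteria", compartments = "root",
                      managements = "CONMIN", genotypes = "B73",
                      n_reps = 8, n_taxa = 120, seed = 600 + i)
    ex <- generate_experiment(cfg)
    r <- rarefy(ex$tables$bacteria, 1000, seed = 1)
    md <- ex$metadata[ex$metadata$sample_id %in% rownames(r), ]
    pv <- permanova(bray_curtis(r), md, c("stage", "plot"),
                    n_perm = 19, seed = i)
    ok[i] <- pv$r2[1] > pv$r2[2]
  }
  expect_gte(sum(ok), 4)
})

test_that("metabolites follow the planted link and stage structure", {
  cfg <- small_cfg(compartments = "root", n_reps = 24,
                   n_compounds = 8, n_linked_taxa = 2, seed = 91)
  ex <- generate_experiment(cfg)
  rel <- to_relative(ex$tables$bacteria)
  gm <- generate_metabolites(ex$metadata, rel, ex$truth, cfg)
  expect_true(all(unclass(gm$metabolites) > 0))
  expect_equal(nrow(gm$truth$links), 2L)
  # deterministic given the config seed
  gm2 <- generate_metabolites(ex$metadata, rel, ex$truth, cfg)
  expect_identical(unclass(gm$metabolites), unclass(gm2$metabolites))
  # beta = 0, noise = 0: intensity depends on stage only
  cfg0 <- small_cfg(compartments = "root", n_reps = 6,
                    n_compounds = 4, n_linked_taxa = 0, beta = 0,
                    noise_sd = 0, seed = 92)
  ex0 <- generate_experiment(cfg0)
  gm0 <- generate_metabolites(ex0$metadata,
                              to_relative(ex0$tables$bacteria),
                              ex0$truth, cfg0)
  md0 <- ex0$metadata[match(rownames(gm0$metabolites),
                            ex0$metadata$sample_id), ]
  for (s in c("vegetative", "reproductive")) {
    block <- unclass(gm0$metabolites)[md0$stage == s, , drop = FALSE]
    expect_true(all(apply(block, 2, stats::sd) == 0))
  }
})

test_that("written experiments are readable by the core readers", {
  cfg <- small_cfg(n_reps = 2, n_soil_reps = 2, n_unplanted = 2,
                   n_taxa = 40, seed = 10)
  ex <- generate_experiment(cfg)
  dir <- withr::local_tempdir()
  paths <- write_experiment(ex, dir)
  back <- read_community_table(paths[["counts_bacteria"]])
  expect_equal(unclass(back)[rownames(ex$tables$bacteria), ],
               unclass(ex$tables$bacteria), ignore_attr = TRUE)
  md <- read_sample_metadata(paths[["metadata"]])
  expect_setequal(md$sample_id, ex$metadata$sample_id)
  tx <- read_taxonomy(paths[["taxonomy_bacteria"]])
  expect_setequal(tx$taxon_id, colnames(back))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_true(length(truth$core$bacteria$root) ==
                cfg$stable_core_size)
})
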