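make_md <- function(n, ...) {
  basic_metadata(paste0("s", seq_len(n)), rep("root", n),
                 rep(c("vegetative", "reproductive"), length.out = n),
                 ...)
}

test_that("permanova matches vegan's sequential partition", {
  skip_if_not_installed("vegan")
  set.seed(12)
  m <- matrix(rpois(24 * 40, 8), 24, 40,
              dimnames = list(paste0("s", 1:24), paste0("t", 1:40)))
  md <- basic_metadata(paste0("s", 1:24),
                       rep("root", 24),
                       rep(c("vegetative", "reproductive"), 12),
                       management = rep(c("NK", "NPK", "CONMIN"),
                                        each = 8))
  d <- bray_curtis(community_table(m + 0, "bacteria", "ASV"))
  got <- permanova(d, md, c("management", "stage"), n_perm = 99,
                   seed = 1)
  ref <- vegan::adonis2(vegan::vegdist(m, "bray") ~ management + stage,
                        data = md, permutations = 99, by = "terms")
  expect_equal(got$sum_sq[1:2], ref$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(got$r2[1:2], ref$R2[1:2], tolerance = 1e-10)
  expect_equal(got$pseudo_f[1:2], ref$F[1:2], tolerance = 1e-10)
  # partition identity: R2 sums to 1
  expect_equal(sum(got$r2[got$term != "Total"]), 1, tolerance = 1e-9)
})

test_that("sequential SS totals are conserved across term orders", {
  set.seed(13)
  m <- matrix(rpois(18 * 30, 6), 18, 30,
              dimnames = list(paste0("s", 1:18), paste0("t", 1:30)))
  md <- basic_metadata(paste0("s", 1:18), rep("root", 18),
                       rep(c("vegetative", "reproductive"), 9),
                       management = rep(c("NK", "NPK"), each = 9))
  d <- bray_curtis(community_table(m + 0, "bacteria", "ASV"))
  a <- permanova(d, md, c("management", "stage"), n_perm = 9, seed = 1)
  b <- permanova(d, md, c("stage", "management"), n_perm = 9, seed = 1)
  expect_equal(sum(a$sum_sq[1:3]), a$sum_sq[4], tolerance = 1e-9)
  expect_equal(sum(a$sum_sq[1:3]), sum(b$sum_sq[1:3]),
               tolerance = 1e-9)
})

test_that("perfect group separation yields R2 near 1 and minimal p", {
  pts <- rbind(matrix(0, 6, 2), matrix(5, 6, 2))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:12), paste0("s", 1:12))
  md <- make_md(12)
  md$stage <- rep(c("vegetative", "reproductive"), each = 6)
  got <- permanova(distance_matrix(d, "euclidean"), md, "stage",
                   n_perm = 99, seed = 2)
  expect_gt(got$r2[1], 0.99)
  # only permutations reproducing the two-block partition tie the
  # observed F, so p sits at (or within a tie or two of) its floor
  expect_lte(got$p_value[1], 0.04)
  expect_error(permanova(distance_matrix(d, "euclidean"), md,
                         "compartment"), "single level")
})

test_that("permutation p matches exhaustive enumeration at n = 6", {
  set.seed(21)
  xy <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(xy))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  md <- make_md(6)
  md$stage <- rep(c("vegetative", "reproductive"), each = 3)
  p_exact <- exact_permanova_p(d, md$stage)
  got <- permanova(distance_matrix(d, "euclidean"), md, "stage",
                   n_perm = 999, seed = 3)
  # +1-corrected permutation estimate vs exact tail probability
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(got$p_value[1] - p_exact), 3 * se + 2 / 1000)
})

test_that("constrained_pcoa satisfies the projection identities", {
  set.seed(30)
  xy <- matrix(rnorm(40), 20, 2)
  d <- as.matrix(dist(xy))
  dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
  md <- make_md(20)
  dm <- distance_matrix(d, "euclidean")
  cp <- constrained_pcoa(dm, md, "stage", n_axes = 1, n_perm = 49,
                         seed = 1)
  # constrained-axis eigenvalues account exactly for the fitted
  # variance, and fitted + residual = total (Pythagoras of projection)
  g <- rhizodyn:::gower_center(d)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  ss_tot <- sum(ev[ev > 1e-10])
  expect_equal(sum(cp$eigenvalues),
               cp$constrained_proportion * ss_tot, tolerance = 1e-9)
  expect_lte(cp$constrained_proportion, 1)

  skip_if_not_installed("vegan")
  ref <- vegan::capscale(dist(xy) ~ stage, data = md)
  expect_equal(cp$constrained_proportion,
               ref$CCA$tot.chi / ref$tot.chi, tolerance = 1e-9)
})

test_that("a constraint indexing duplicated points captures all variance", {
  pts <- rbind(matrix(0, 5, 2), matrix(3, 5, 2), matrix(c(0, 9), 5, 2,
                                                        byrow = TRUE))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:15), paste0("s", 1:15))
  md <- basic_metadata(paste0("s", 1:15), rep("root", 15),
                       rep(c("vegetative", "reproductive",
                             "vegetative"), each = 5),
                       management = rep(c("NK", "NPK", "CONMIN"),
                                        each = 5))
  cp <- constrained_pcoa(distance_matrix(d, "euclidean"), md,
                         "management", n_axes = 2, n_perm = 49,
                         seed = 1)
  expect_gte(cp$constrained_proportion, 0.999)
  expect_equal(cp$permutation_p, 1 / 50)
})

test_that("constrained proportion under a null factor matches its expectation", {
  set.seed(77)
  props <- replicate(60, {
    xy <- matrix(rnorm(80), 40, 2)
    d <- as.matrix(dist(xy))
    dimnames(d) <- list(paste0("s", 1:40), paste0("s", 1:40))
    md <- basic_metadata(paste0("s", 1:40), rep("root", 40),
                         sample(rep(c("vegetative", "reproductive"),
                                    20)))
    cp <- constrained_pcoa(distance_matrix(d, "euclidean"), md,
                           "stage", n_axes = 1, n_perm = 1, seed = 1)
    cp$constrained_proportion
  })
  # E[R2] = rank / (n - 1) = 1/39 for an unrelated 2-level factor
  expect_lt(abs(mean(props) - 1 / 39), 0.01)
})

test_that("wilcoxon_fdr letters separate exactly the distinguishable groups", {
  set.seed(41)
  vals <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1), rnorm(10, 20, 0.1))
  grp <- rep(c("g1", "g2", "g3"), each = 10)
  res <- wilcoxon_fdr(vals, grp)
  expect_true(all(res$pairs$q_value < 1e-3))
  expect_equal(length(unique(res$letters)), 3L)
  # identical distributions: one shared letter
  res2 <- wilcoxon_fdr(rep(c(1, 2, 3, 4), 3),
                       rep(c("a", "b", "c"), each = 4))
  expect_equal(length(unique(res2$letters)), 1L)
  # BH monotonicity
  ord <- order(res$pairs$p_value)
  expect_true(all(diff(res$pairs$q_value[ord]) >= -1e-15))
})

test_that("rank-sum p at n=3 vs 3 with full separation is exactly 0.1", {
  res <- wilcoxon_fdr(c(1, 2, 3, 4, 5, 6),
                      rep(c("lo", "hi"), each = 3))
  expect_equal(res$pairs$p_value, 0.1)
})
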