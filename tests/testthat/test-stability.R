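stab_fixture <- function() {
  # 6 vegetative + 6 reproductive root samples, 4 taxa with known
  # detection patterns
  m <- matrix(0, 12, 4,
              dimnames = list(paste0("s", 1:12),
                              c("always", "five_of_six", "veg_only",
                                "absent")))
  m[, "always"] <- 5
  m[c(1:5, 7:12), "five_of_six"] <- 3      # 5/6 veg, 6/6 rep
  m[c(1:6, 7:9), "veg_only"] <- 2          # all veg, 3/6 rep
  ct <- community_table(m, "bacteria", "ASV")
  md <- basic_metadata(rownames(m), rep("root", 12),
                       rep(c("vegetative", "reproductive"), each = 6))
  list(ct = ct, md = md)
}

test_that("prevalence counts nonzero detections", {
  f <- stab_fixture()
  pv <- prevalence(f$ct, paste0("s", 1:6))
  expect_equal(unname(pv["always"]), 1)
  expect_equal(unname(pv["absent"]), 0)
  expect_equal(unname(pv["five_of_six"]), 5 / 6, tolerance = 1e-9)
  expect_error(prevalence(f$ct, character(0)), "empty")
})

test_that("stable_taxa applies a strict threshold at both stages", {
  f <- stab_fixture()
  st <- stable_taxa(f$ct, f$md, "root", theta = 0.8)
  expect_setequal(as.character(st), c("always", "five_of_six"))
  # prevalence exactly at theta is NOT stable under the strict rule
  st2 <- stable_taxa(f$ct, f$md, "root", theta = 5 / 6)
  expect_setequal(as.character(st2), "always")
  st3 <- stable_taxa(f$ct, f$md, "root", theta = 5 / 6,
                     strict = FALSE)
  expect_setequal(as.character(st3), c("always", "five_of_six"))
  expect_error(stable_taxa(f$ct, f$md, "soil"), "lacks samples")
})

test_that("raising theta never adds a stable taxon", {
  f <- stab_fixture()
  thetas <- seq(0.1, 0.95, by = 0.05)
  sets <- lapply(thetas, function(t)
    as.character(stable_taxa(f$ct, f$md, "root", theta = t)))
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("aggregated_ra averages per-sample set sums, in percent", {
  m <- rbind(s1 = c(0.3, 0.2, 0.5), s2 = c(0.5, 0.1, 0.4))
  colnames(m) <- c("t1", "t2", "t3")
  ct <- community_table(m, "bacteria", "ASV", is_relative = TRUE)
  expect_equal(aggregated_ra(ct, "t1", c("s1", "s2")), 40)
  expect_equal(aggregated_ra(ct, colnames(m), c("s1", "s2")), 100)
  expect_equal(aggregated_ra(ct, character(0), "s1"), 0)
  expect_error(aggregated_ra(ct, "t1", character(0)), "empty")
})

test_that("stable and dynamic aRAs always complement to 100", {
  set.seed(19)
  for (i in 1:10) {
    m <- matrix(rexp(5 * 20), 5, 20,
                dimnames = list(paste0("s", 1:5), paste0("t", 1:20)))
    ct <- rel_table(m)
    stable <- sample(colnames(m), sample(1:19, 1))
    dynamic <- setdiff(colnames(m), stable)
    expect_equal(aggregated_ra(ct, stable, rownames(m)) +
                   aggregated_ra(ct, dynamic, rownames(m)),
                 100, tolerance = 1e-9)
  }
})

test_that("stable-to-dynamic ratio reproduces the worked examples", {
  expect_equal(stable_dynamic_ratio(39.35)$ratio_2dp, 0.65)
  expect_equal(stable_dynamic_ratio(39.35)$dynamic_ara, 60.65)
  expect_equal(stable_dynamic_ratio(80.49)$ratio_2dp, 4.13)
  expect_equal(stable_dynamic_ratio(50)$ratio_2dp, 1.00)
  expect_error(stable_dynamic_ratio(0), "undefined")
  expect_error(stable_dynamic_ratio(100), "undefined")
})

test_that("the ratio is symmetric under swapping stable and dynamic", {
  for (x in seq(5, 95, by = 5)) {
    expect_equal(stable_dynamic_ratio(x)$ratio *
                   stable_dynamic_ratio(100 - x)$ratio, 1,
                 tolerance = 1e-12)
  }
})

test_that("compartment_overlap enumerates every Venn region", {
  # identical sets
  r1 <- compartment_overlap(list(A = letters[1:5], B = letters[1:5]))
  expect_equal(r1$count[r1$region == "A&B"], 5L)
  expect_equal(sum(r1$count), 5L)
  # disjoint sets
  r2 <- compartment_overlap(list(A = c("1", "2", "3"),
                                 B = c("4", "5", "6", "7")))
  expect_equal(r2$count[r2$region == "A"], 3L)
  expect_equal(r2$count[r2$region == "B"], 4L)
  expect_equal(r2$count[r2$region == "A&B"], 0L)
  # three-set case verified against brute-force membership
  sets <- list(A = c("1", "2", "3"), B = c("2", "3", "4"), C = "3")
  r3 <- compartment_overlap(sets)
  universe <- unique(unlist(sets))
  for (i in seq_len(nrow(r3))) {
    inset <- strsplit(r3$region[i], "&", fixed = TRUE)[[1]]
    outset <- setdiff(names(sets), inset)
    want <- sum(vapply(universe, function(el) {
      all(vapply(inset, function(s) el %in% sets[[s]], logical(1))) &&
        !any(vapply(outset, function(s) el %in% sets[[s]],
                    logical(1)))
    }, logical(1)))
    expect_equal(r3$count[i], want)
  }
  expect_equal(r3$count[r3$region == "A"], 1L)
  expect_equal(r3$count[r3$region == "A&B"], 1L)
  expect_equal(r3$count[r3$region == "A&B&C"], 1L)
})

test_that("stability_partition assembles sets, aRAs and ratios coherently", {
  f <- stab_fixture()
  part <- stability_partition(f$ct, f$md, "root", theta = 0.8)
  expect_setequal(part$stable, c("always", "five_of_six"))
  expect_setequal(part$dynamic, "veg_only")
  for (s in c("vegetative", "reproductive")) {
    st <- part$stages[[s]]
    expect_equal(st$stable_ara + st$dynamic_ara, 100,
                 tolerance = 1e-9)
    expect_equal(st$ratio, st$stable_ara / st$dynamic_ara,
                 tolerance = 1e-9)
  }
  p <- withr::local_tempfile(fileext = ".json")
  write_stability_partition(part, p)
  back <- jsonlite::read_json(p)
  expect_equal(unlist(back$stable), part$stable)
})
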