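# shared fixtures and independent oracles, built in code

tiny_counts <- function(values = c(3, 0, 1, 2),
                        samples = c("s1", "s2"),
                        taxa = c("t1", "t2")) {
  m <- matrix(values, length(samples), length(taxa), byrow = TRUE,
              dimnames = list(samples, taxa))
  community_table(m, kingdom = "bacteria", level = "ASV")
}

rel_table <- function(m, kingdom = "bacteria", level = "ASV") {
  community_table(m / rowSums(m), kingdom = kingdom, level = level,
                  is_relative = TRUE)
}

basic_metadata <- function(sample_id, compartment, stage,
                           management = "NK", genotype = "B73",
                           plot = "NK-1", field = "DEMO") {
  df <- data.frame(sample_id = sample_id, field = field,
                   management = management, plot = plot,
                   genotype = ifelse(compartment == "soil" &
                                       stage == "unplanted",
                                     "none", genotype),
                   compartment = compartment, stage = stage,
                   stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

# independent Needleman-Wunsch oracle: global alignment score and
# identity (matches / alignment columns); linear gap penalty
nw_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  sc <- matrix(0, n + 1, m + 1)
  sc[, 1] <- gap * (0:n); sc[1, ] <- gap * (0:m)
  for (i in 1:n) for (j in 1:m) {
    d <- sc[i, j] + if (a[i] == b[j]) match else mismatch
    sc[i + 1, j + 1] <- max(d, sc[i, j + 1] + gap, sc[i + 1, j] + gap)
  }
  # traceback preferring diagonal moves
  i <- n; j <- m; matches <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        sc[i + 1, j + 1] == sc[i, j] +
        (if (a[i] == b[j]) match else mismatch)) {
      matches <- matches + (a[i] == b[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && sc[i + 1, j + 1] == sc[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    len <- len + 1L
  }
  list(score = sc[n + 1, m + 1], identity = matches / len)
}

# brute-force PERMANOVA p over all assignments of group labels (one
# two-level factor); independent of the package's permutation machinery
exact_permanova_p <- function(d, labels) {
  n <- nrow(d)
  idx_a <- which(labels == labels[1])
  f_stat <- function(sel) {
    grp <- rep("b", n); grp[sel] <- "a"
    ss_within <- 0
    for (g in c("a", "b")) {
      ii <- which(grp == g)
      ss_within <- ss_within +
        sum(d[ii, ii]^2) / (2 * length(ii))
    }
    ss_total <- sum(d^2) / (2 * n)
    ss_b <- ss_total - ss_within
    (ss_b / 1) / (ss_within / (n - 2))
  }
  obs <- f_stat(idx_a)
  sels <- utils::combn(n, length(idx_a))
  fs <- apply(sels, 2, f_stat)
  mean(fs >= obs - 1e-12)
}
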