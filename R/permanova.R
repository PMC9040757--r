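#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Sequential (Type I) partition of a dissimilarity matrix by a list of
#' experimental factors, with significance from free permutation of
#' sample labels. Terms are fitted in the given order; interaction terms
#' can be written as `"a:b"` and are built as factor crosses.
#'
#' @param d a `distance_matrix`.
#' @param metadata per-sample metadata data.frame containing every term;
#'   rows are matched to `rownames(d)` by the `sample_id` column.
#' @param terms character vector of metadata column names (optionally
#'   `"a:b"` interactions), fitted sequentially.
#' @param n_perm number of permutations (999 default).
#' @param seed integer seed.
#' @return a `permanova` object: data.frame with one row per term plus
#'   `Residual` and `Total` rows, columns `term`, `df`, `sum_sq`, `r2`,
#'   `pseudo_f`, `p_value`.
#' @export
permanova <- function(d, metadata, terms, n_perm = 999, seed = 1L) {
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  n <- nrow(d)
  md <- metadata[match(rownames(d), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("samples missing from metadata")
  fac <- lapply(terms, term_factor, metadata = md)
  names(fac) <- terms
  for (t in terms)
    if (nlevels(fac[[t]]) < 2)
      stop("term '", t, "' has a single level")

  g <- gower_center(unclass(d))
  ss_total <- sum(diag(g))
  hats <- sequential_hats(fac, n)
  obs <- partition_ss(hats, g, ss_total)

  old <- local_seed(seed)
  on.exit(restore_seed(old))
  exceed <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    gp <- g[perm, perm]
    st <- partition_ss(hats, gp, ss_total)
    exceed <- exceed + (st$f >= obs$f - 1e-12)
  }
  p <- (1 + exceed) / (1 + n_perm)

  res <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(obs$df, obs$df_res, n - 1),
    sum_sq = c(obs$ss, obs$ss_res, ss_total),
    r2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    pseudo_f = c(obs$f, NA, NA),
    p_value = c(p, NA, NA),
    stringsAsFactors = FALSE)
  class(res) <- c("permanova", "data.frame")
  res
}

# a term name, possibly "a:b", into a factor over metadata rows
term_factor <- function(term, metadata) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  miss <- setdiff(parts, names(metadata))
  if (length(miss) > 0)
    stop("metadata has no column(s): ", paste(miss, collapse = ", "))
  f <- interaction(metadata[parts], drop = TRUE, sep = ":")
  factor(f)
}

# nested hat matrices for intercept + term 1..k, with per-term df
sequential_hats <- function(fac, n) {
  x <- matrix(1, n, 1)
  hats <- vector("list", length(fac))
  dfs <- integer(length(fac))
  rank_prev <- 1L
  h_prev <- matrix(1 / n, n, n)
  for (k in seq_along(fac)) {
    x <- cbind(x, stats::model.matrix(~ f - 1,
                                      data.frame(f = fac[[k]])))
    q <- qr(x)
    h <- tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
    hats[[k]] <- list(h = h, h_prev = h_prev,
                      df = q$rank - rank_prev)
    dfs[k] <- q$rank - rank_prev
    rank_prev <- q$rank
    h_prev <- h
  }
  list(hats = hats, dfs = dfs, rank_full = rank_prev)
}

# sequential SS and pseudo-F for a (possibly permuted) Gower matrix
partition_ss <- function(hats, g, ss_total) {
  m <- length(hats$hats)
  ss <- numeric(m)
  for (k in seq_len(m)) {
    hk <- hats$hats[[k]]
    ss[k] <- sum(hk$h * g) - sum(hk$h_prev * g)
  }
  # perfectly separated duplicated points give SS_res = 0 up to
  # rounding; clamp so the pseudo-F degenerates to +Inf, not -Inf
  ss_res <- max(sum(diag(g)) - sum(hats$hats[[m]]$h * g), 0)
  df_res <- nrow(g) - hats$rank_full
  f <- (ss / hats$dfs) / (ss_res / df_res)
  list(ss = ss, df = hats$dfs, ss_res = ss_res, df_res = df_res, f = f)
}

#' Constrained principal-coordinate analysis (CPCoA / db-RDA)
#'
#' PCoA scores on all positive axes are regressed on the constraint
#' design matrix; the eigendecomposition of the fitted values gives the
#' constrained axes. The constrained-variance proportion is
#' SS(fitted) / SS(total positive-axis inertia); its significance comes
#' from permuting sample rows.
#'
#' @inheritParams permanova
#' @param constraint_terms metadata columns defining the constraint.
#' @param n_axes number of constrained axes to return.
#' @return an `ordination` with extra elements `constrained_proportion`
#'   and `permutation_p`.
#' @export
constrained_pcoa <- function(d, metadata, constraint_terms, n_axes = 2,
                             n_perm = 999, seed = 1L) {
  n <- nrow(d)
  md <- metadata[match(rownames(d), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("samples missing from metadata")
  g <- gower_center(unclass(d))
  e <- eigen(g, symmetric = TRUE)
  pos <- which(e$values > max(e$values[1], 0) * 1e-10 & e$values > 0)
  y <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  ss_tot <- sum(e$values[pos])

  f <- interaction(md[unlist(strsplit(constraint_terms, ":",
                                      fixed = TRUE))],
                   drop = TRUE, sep = ":")
  z <- stats::model.matrix(~ f - 1, data.frame(f = factor(f)))
  z <- scale(z, center = TRUE, scale = FALSE)
  qz <- qr(z)
  if (qz$rank >= n - 1)
    stop("constraint is saturated (rank >= n - 1)")
  qmat <- qr.Q(qz)[, seq_len(qz$rank), drop = FALSE]

  fitted <- qmat %*% crossprod(qmat, y)
  ss_fit <- sum(fitted^2)
  prop <- ss_fit / ss_tot

  sv <- svd(fitted)
  k <- min(n_axes, qz$rank)
  coords <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k)
  coords <- fix_axis_signs(coords)
  dimnames(coords) <- list(rownames(d), paste0("CPCo", seq_len(k)))

  old <- local_seed(seed)
  on.exit(restore_seed(old))
  exceed <- 0
  for (b in seq_len(n_perm)) {
    yp <- y[sample.int(n), , drop = FALSE]
    ssb <- sum((qmat %*% crossprod(qmat, yp))^2)
    if (ssb >= ss_fit - 1e-12) exceed <- exceed + 1
  }
  structure(list(coordinates = coords,
                 eigenvalues = sv$d^2,
                 proportion_explained = sv$d[seq_len(k)]^2 / ss_tot,
                 constrained_proportion = prop,
                 permutation_p = (1 + exceed) / (1 + n_perm)),
            class = "ordination")
}

#' Pairwise Wilcoxon rank-sum tests with FDR correction and letters
#'
#' Two-sided rank-sum tests for every group pair, Benjamini-Hochberg
#' q-values across all pairs, and a compact-letter display in which
#' groups sharing a letter are not significantly different at `alpha`.
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) of the same length; letter order
#'   follows the factor's level order.
#' @param alpha significance level applied to q-values.
#' @return list with `pairs` (data.frame: group_a, group_b, statistic,
#'   p_value, q_value) and `letters` (named character vector per group).
#' @export
wilcoxon_fdr <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2) stop("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2)) stop("every group needs >= 2 observations")
  cmb <- utils::combn(lev, 2)
  res <- apply(cmb, 2, function(pr) {
    xa <- values[groups == pr[1]]
    xb <- values[groups == pr[2]]
    if (length(unique(c(xa, xb))) == 1) {
      c(statistic = length(xa) * length(xb) / 2, p_value = 1)
    } else {
      w <- suppressWarnings(stats::wilcox.test(xa, xb,
                                               alternative = "two.sided"))
      c(statistic = unname(w$statistic), p_value = w$p.value)
    }
  })
  pairs <- data.frame(group_a = cmb[1, ], group_b = cmb[2, ],
                      statistic = res["statistic", ],
                      p_value = res["p_value", ],
                      stringsAsFactors = FALSE)
  pairs$q_value <- stats::p.adjust(pairs$p_value, method = "BH")
  letters_out <- compact_letters(lev, pairs, alpha)
  list(pairs = pairs, letters = letters_out)
}

# insert-and-absorb compact letter display: start from one class holding
# all groups, split on each significant pair, absorb subset classes
compact_letters <- function(lev, pairs, alpha) {
  classes <- list(lev)
  sig <- pairs[pairs$q_value < alpha, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    a <- sig$group_a[r]; b <- sig$group_b[r]
    new_classes <- list()
    for (cl in classes) {
      if (a %in% cl && b %in% cl) {
        new_classes <- c(new_classes, list(setdiff(cl, a)),
                         list(setdiff(cl, b)))
      } else {
        new_classes <- c(new_classes, list(cl))
      }
    }
    # absorb: drop classes contained in another class
    keep <- rep(TRUE, length(new_classes))
    for (i in seq_along(new_classes)) {
      for (j in seq_along(new_classes)) {
        if (i != j && keep[j] &&
            all(new_classes[[i]] %in% new_classes[[j]]) &&
            (length(new_classes[[i]]) < length(new_classes[[j]]) ||
             i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    classes <- new_classes[keep]
  }
  out <- stats::setNames(rep("", length(lev)), lev)
  for (k in seq_along(classes)) {
    lab <- letters[(k - 1) %% 26 + 1]
    for (gname in classes[[k]]) out[gname] <- paste0(out[gname], lab)
  }
  out
}
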