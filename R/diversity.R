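#' Shannon diversity index
#'
#' H = -sum p_i log p_i over taxa with nonzero counts, natural log by
#' default (the common ecology convention).
#'
#' @param counts non-negative numeric vector with positive sum.
#' @param base logarithm base; default `exp(1)`.
#' @return non-negative scalar.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("negative counts")
  tot <- sum(counts)
  if (tot == 0) stop("all-zero vector")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Alpha diversity as the mean Shannon index over repeated rarefactions
#'
#' For each sample, the Shannon index is averaged over `n_rarefactions`
#' independent rarefactions to `depth`. Samples below depth are dropped
#' and reported via the `dropped` attribute.
#'
#' @param x a `community_table` of counts.
#' @param depth rarefaction depth.
#' @param n_rarefactions number of independent rarefactions (999 by
#'   convention for amplicon surveys).
#' @param seed integer seed.
#' @param base logarithm base for the Shannon index.
#' @return named numeric vector of per-sample mean Shannon values.
#' @export
rarefied_shannon <- function(x, depth, n_rarefactions = 999, seed = 1L,
                             base = exp(1)) {
  stopifnot(inherits(x, "community_table"))
  if (is_relative(x)) stop("rarefied_shannon() needs a count table")
  if (depth <= 0) stop("'depth' must be positive")
  totals <- rowSums(x)
  keep <- totals >= depth
  dropped <- rownames(x)[!keep]
  m <- unclass(x)[keep, , drop = FALSE]
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  res <- vapply(seq_len(nrow(m)), function(i) {
    row <- m[i, ]
    if (sum(row) == depth)        # no sampling variability
      return(shannon(row, base = base))
    pool <- rep.int(seq_along(row), row)   # built once per sample
    mean(vapply(seq_len(n_rarefactions), function(j) {
      sub <- tabulate(pool[sample.int(length(pool), depth)],
                      nbins = length(row))
      shannon(sub, base = base)
    }, numeric(1)))
  }, numeric(1))
  names(res) <- rownames(m)
  attr(res, "dropped") <- dropped
  res
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed between all
#' sample pairs. Intended for equal-sum rows: rarefied counts or relative
#' abundances.
#'
#' @param x a `community_table`.
#' @return a `distance_matrix`: full symmetric matrix with zero diagonal,
#'   sample ids as dimnames, and a `metric` attribute.
#' @export
bray_curtis <- function(x) {
  m <- unclass(x)
  rs <- rowSums(m)
  if (sum(rs == 0) >= 2) stop("more than one all-zero sample")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        sum(abs(xi - m[j, ])) / (rs[i] + rs[j])
    }
  }
  distance_matrix(d, metric = "bray-curtis")
}

#' @rdname bray_curtis
#' @param d symmetric numeric matrix with zero diagonal and dimnames.
#' @param metric label recorded on the object.
#' @export
distance_matrix <- function(d, metric = "unknown") {
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("nonzero diagonal")
  if (is.null(rownames(d))) stop("distance matrix needs sample ids")
  structure(d, metric = metric,
            class = c("distance_matrix", "matrix", "array"))
}

#' @rdname bray_curtis
#' @param path file path for the tab-separated square matrix.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), unclass(d),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname bray_curtis
#' @export
read_distance_matrix <- function(path, metric = "unknown") {
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  colnames(m) <- rownames(m)
  distance_matrix(m, metric = metric)
}

#' Principal-coordinate analysis (classical metric scaling)
#'
#' Gower double-centering of -D^2/2 followed by eigendecomposition.
#' Axes with positive eigenvalues are retained up to `n_axes`; the
#' proportion explained uses only positive eigenvalues in its
#' denominator. Negative eigenvalues are reported but excluded. Each
#' axis's sign is fixed so its largest-magnitude coordinate is positive.
#'
#' @param d a `distance_matrix`.
#' @param n_axes maximum number of axes to return.
#' @return an object of class `ordination`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, sorted), and
#'   `proportion_explained` for retained axes.
#' @export
pcoa <- function(d, n_axes = 2) {
  if (n_axes < 1) stop("'n_axes' must be >= 1")
  n <- nrow(d)
  if (n < 3) stop("need at least 3 samples")
  g <- gower_center(unclass(d))
  e <- eigen(g, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(ev[1], 0) * 1e-10 & ev > 0)
  k <- min(n_axes, length(pos))
  coords <- if (k > 0) {
    co <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(ev[pos[seq_len(k)]]), k)
    co <- fix_axis_signs(co)
    dimnames(co) <- list(rownames(d), paste0("PCo", seq_len(k)))
    co
  } else {
    matrix(0, n, 0, dimnames = list(rownames(d), NULL))
  }
  prop <- if (k > 0) ev[pos[seq_len(k)]] / sum(ev[pos]) else numeric(0)
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion_explained = prop),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d samples, %d axes", nrow(x$coordinates),
              ncol(x$coordinates)))
  if (length(x$proportion_explained) > 0)
    cat(sprintf(" (%s explained)",
                paste0(round(100 * x$proportion_explained, 1), "%",
                       collapse = ", ")))
  if (!is.null(x$constrained_proportion))
    cat(sprintf("; constrained %.1f%% (p = %.4g)",
                100 * x$constrained_proportion, x$permutation_p))
  cat("\n")
  invisible(x)
}

# Gower-centered matrix G = -(1/2) J D^2 J with J = I - 11'/n
gower_center <- function(d) {
  a <- -0.5 * d^2
  rm_ <- rowMeans(a)
  a - outer(rm_, rep(1, ncol(a))) - outer(rep(1, nrow(a)), colMeans(a)) +
    mean(a)
}

fix_axis_signs <- function(co) {
  for (j in seq_len(ncol(co))) {
    i <- which.max(abs(co[, j]))
    if (co[i, j] < 0) co[, j] <- -co[, j]
  }
  co
}
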