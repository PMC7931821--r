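#' Per-sample sparsity
#'
#' Proportion of zero entries in each sample after thresholding:
#' abundances below `threshold` count as zero (the simulator's
#' truncation rule uses 1e-4).
#'
#' @param table an [abundance_table()].
#' @param threshold abundances strictly below this count as zero
#'   (default 0: only exact zeros).
#' @return numeric vector, one value per sample.
#' @export
sparsity <- function(table, threshold = 0) {
  v <- table$values
  rowMeans(v < threshold | v == 0)
}

#' Shannon diversity index
#'
#' Per-sample entropy `-sum p_j log(p_j)` (natural log) with
#' `0 log 0 := 0`; each row is renormalized over its nonzero entries
#' before the entropy is taken.
#'
#' @param table an [abundance_table()].
#' @return numeric vector of entropies; all-zero rows yield 0 with a
#'   warning.
#' @export
shannon <- function(table) {
  v <- table$values
  rs <- rowSums(v)
  if (any(rs == 0)) warning("all-zero sample(s): Shannon index set to 0")
  apply(v, 1L, function(r) {
    s <- sum(r)
    if (s == 0) return(0)
    p <- r[r > 0] / s
    -sum(p * log(p))
  })
}

#' Unweighted UniFrac distance matrix
#'
#' For each pair of samples, the fraction of branch length observed in
#' either sample that is unique to exactly one of them: branches are
#' classified by whether any descendant leaf is present (abundance
#' above the presence threshold) in each sample.  Taxonomy-derived
#' trees carry no branch lengths and unit lengths are used.
#'
#' @param table an [abundance_table()] whose columns map to leaves of
#'   `tree`.
#' @param tree a [taxonomy_tree()].
#' @param threshold presence cutoff (default 1e-4, the truncation
#'   threshold, for consistency between real and simulated tables).
#' @return a symmetric distance matrix in `[0, 1]` with zero diagonal;
#'   rows for samples with no present taxa are `NA` (flagged with a
#'   warning).
#' @export
unweighted_unifrac <- function(table, tree, threshold = 1e-4) {
  v <- table$values
  leaves <- tree_leaves(tree)
  if (!all(colnames(v) %in% leaves))
    stop("table columns must map to tree leaves")
  A <- descendant_matrix(tree)[, colnames(v), drop = FALSE]
  has_edge <- !is.na(tree$parent) # the root has no edge above it
  blen <- tree$branch_length
  blen[is.na(blen)] <- 1
  P <- (v > threshold) * 1 # samples x leaves
  ## samples x nodes: does any descendant leaf occur in the sample?
  occ <- tcrossprod(P, A[has_edge, , drop = FALSE]) > 0
  w <- blen[has_edge]
  n <- nrow(v)
  D <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  empty <- rowSums(P) == 0
  if (any(empty))
    warning("sample(s) with no present taxa: UniFrac undefined, set NA")
  for (m in seq_len(n)) {
    if (empty[m]) { D[m, ] <- NA; D[, m] <- NA; D[m, m] <- 0; next }
    for (k in seq_len(n)) {
      if (k <= m || empty[k]) next
      both <- occ[m, ] | occ[k, ]
      uniq <- xor(occ[m, ], occ[k, ])
      D[m, k] <- D[k, m] <- sum(w[uniq]) / sum(w[both])
    }
  }
  D
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Seeded wrapper around [vegan::metaMDS()] producing a
#' rank-preserving low-dimensional embedding and its Kruskal stress.
#'
#' @param d symmetric, zero-diagonal, nonnegative distance matrix (or
#'   `dist`).
#' @param dims embedding dimension (default 2).
#' @param seed seed for the random restarts.
#' @param trymax maximum random restarts (default 20).
#' @return list with `points` (n x dims coordinates) and `stress`.
#' @export
nmds <- function(d, dims = 2, seed = 1, trymax = 20) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8))
      stop("distance matrix must be symmetric")
    if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
    if (any(d < 0)) stop("distances must be nonnegative")
    d <- stats::as.dist(d)
  }
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = dims, trymax = trymax, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  list(points = fit$points, stress = fit$stress)
}

#' Drop taxa with an excessive number of zeros
#'
#' @param table an [abundance_table()].
#' @param max_zero_fraction taxa whose fraction of zero entries exceeds
#'   this are dropped (default 0.9, the ">90 percent zeros" rule).
#' @param threshold abundances below this count as zero (default 0).
#' @return the filtered [abundance_table()].
#' @export
filter_taxa <- function(table, max_zero_fraction = 0.9, threshold = 0) {
  stopifnot(max_zero_fraction > 0, max_zero_fraction <= 1)
  v <- table$values
  zf <- colMeans(v < threshold | v == 0)
  keep <- zf <= max_zero_fraction
  if (!any(keep))
    stop(sprintf("no taxa retained (%d of %d exceed zero fraction %.2f)",
                 sum(!keep), length(keep), max_zero_fraction))
  abundance_table(v[, keep, drop = FALSE], rank_level = table$rank_level,
                  normalized = NA, normalization = table$normalization)
}

#' Keep the most abundant fraction of taxa
#'
#' Taxa are ranked by mean relative abundance across samples; the top
#' `ceiling(fraction * p)` are kept, with ties broken by taxon id.
#'
#' @param table an [abundance_table()].
#' @param fraction fraction of taxa to keep (default 0.1).
#' @return the reduced [abundance_table()].
#' @export
top_abundant <- function(table, fraction = 0.1) {
  stopifnot(fraction > 0, fraction <= 1)
  v <- table$values
  k <- ceiling(fraction * ncol(v))
  ord <- order(-colMeans(v), colnames(v))
  keep <- sort(ord[seq_len(k)])
  abundance_table(v[, keep, drop = FALSE], rank_level = table$rank_level,
                  normalized = NA, normalization = table$normalization)
}

#' Compare taxa-taxa Spearman correlation structure
#'
#' Computes the pairwise Spearman correlation matrix of a taxon subset
#' in the real and the simulated table, pairs the strict upper
#' triangles, and summarizes agreement by the squared Pearson
#' correlation (R^2) of the paired coefficients and the mean squared
#' difference (MSE).  Pairs involving a constant (zero-variance) taxon
#' in either table are excluded and counted.
#'
#' @param real,sim [abundance_table()]s sharing the taxon subset.
#' @param taxa taxon ids to use (default: all taxa common to both).
#' @return list with `pairs` (data frame: taxon_m, taxon_k, real, sim),
#'   `r_squared`, `mse`, `n_dropped`.
#' @export
spearman_structure <- function(real, sim, taxa = NULL) {
  if (is.null(taxa)) taxa <- intersect(colnames(real$values),
                                       colnames(sim$values))
  if (length(taxa) < 2) stop("need at least two shared taxa")
  miss <- setdiff(taxa, intersect(colnames(real$values), colnames(sim$values)))
  if (length(miss)) stop("taxa absent from a table: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  cr <- suppressWarnings(stats::cor(real$values[, taxa], method = "spearman"))
  cs <- suppressWarnings(stats::cor(sim$values[, taxa], method = "spearman"))
  ut <- upper.tri(cr)
  idx <- which(ut, arr.ind = TRUE)
  pairs <- data.frame(taxon_m = taxa[idx[, 1]], taxon_k = taxa[idx[, 2]],
                      real = cr[ut], sim = cs[ut])
  ok <- stats::complete.cases(pairs$real, pairs$sim)
  n_dropped <- sum(!ok)
  pr <- pairs$real[ok]; ps <- pairs$sim[ok]
  r2 <- if (length(pr) < 2 || stats::sd(pr) == 0 || stats::sd(ps) == 0)
    NA_real_ else stats::cor(pr, ps)^2
  list(pairs = pairs, r_squared = r2, mse = mean((ps - pr)^2),
       n_dropped = n_dropped)
}

#' Centered log-ratio transform
#'
#' `clr(x)_m = log(x_m / g(x))` with `g(x)` the geometric mean of the
#' sample, applied per row; components of each transformed row sum to
#' zero.  Zeros are replaced by half the smallest positive value in
#' the row before the transform (multiplicative-replacement flavor);
#' set `zero_replace = "none"` to require strictly positive input.
#'
#' @param x composition vector or samples x taxa matrix.
#' @param zero_replace `"half-min"` (default) or `"none"`.
#' @return transformed vector/matrix of the same shape.
#' @export
clr <- function(x, zero_replace = c("half-min", "none")) {
  zero_replace <- match.arg(zero_replace)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, 1L) else as.matrix(x)
  if (any(m < 0)) stop("clr requires nonnegative input")
  if (zero_replace == "half-min") {
    for (i in seq_len(nrow(m))) {
      z <- m[i, ] == 0
      if (any(z)) {
        pos <- m[i, !z]
        if (!length(pos)) stop("all-zero composition in clr")
        m[i, z] <- min(pos) / 2
      }
    }
  } else if (any(m == 0)) stop("nonpositive entries in clr input")
  out <- log(m) - rowMeans(log(m))
  if (vec) drop(out) else { dimnames(out) <- dimnames(x); out }
}

#' Lovell proportionality statistic phi
#'
#' `phi(x_m, x_k) = var(x_m - x_k) / var(x_m)` on log-scale (clr)
#' values: zero iff the two taxa are exactly proportional across
#' samples.  Inputs are expected to be clr-transformed (see [clr()]);
#' the statistic is asymmetric in its arguments.
#'
#' @param x_m,x_k numeric vectors across samples (clr scale).
#' @return the scalar statistic (`NA` with a warning when
#'   `var(x_m)` is zero).
#' @export
proportionality_phi <- function(x_m, x_k) {
  stopifnot(length(x_m) == length(x_k), length(x_m) >= 3)
  v <- stats::var(x_m)
  if (v == 0) { warning("zero variance in reference taxon"); return(NA_real_) }
  stats::var(x_m - x_k) / v
}

## all ordered upper-triangle phi values for a clr matrix restricted to taxa
phi_pairs <- function(clr_mat, taxa) {
  k <- length(taxa)
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  vapply(seq_len(nrow(idx)), function(r)
    suppressWarnings(proportionality_phi(clr_mat[, taxa[idx[r, 1]]],
                                         clr_mat[, taxa[idx[r, 2]]])),
    numeric(1))
}
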