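#' Expand a species-level table over a taxonomy tree
#'
#' The first half of the weighted phylogeny transformation: each tree
#' node receives the sum of the relative abundances of its descendant
#' leaves (leaves carry their own abundance), then every column is
#' multiplied by its node weight.  Node columns follow the tree's
#' canonical root-first order, restricted to the selected ranks.
#'
#' @param table an [abundance_table()] whose columns all map to leaves
#'   of `tree`.
#' @param tree a [taxonomy_tree()].
#' @param weights optional nonnegative per-node multipliers, named by
#'   node id (default: unit weight everywhere).  Passing the tree's
#'   branch lengths turns the transform into branch-length weighting.
#' @param include_kingdom keep kingdom-rank nodes (and the root /
#'   rank-free internal nodes)?  Default `FALSE`: only phylum through
#'   species enter the expansion, plus all leaves.  For trees without
#'   rank annotation all non-root nodes are kept.
#' @return An object of class `expanded_matrix`: list with `values`
#'   (samples x nodes), `node_ids`, `sample_ids`, `weights`.
#' @export
expand_abundance <- function(table, tree, weights = NULL,
                             include_kingdom = FALSE) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(tree, "taxonomy_tree"))
  leaves <- tree_leaves(tree)
  unmapped <- setdiff(colnames(table$values), leaves)
  if (length(unmapped))
    stop("taxa not mapped to tree leaves: ",
         paste(utils::head(unmapped, 5), collapse = ", "),
         if (length(unmapped) > 5) sprintf(" (and %d more)",
                                           length(unmapped) - 5))
  A <- descendant_matrix(tree)[, colnames(table$values), drop = FALSE]
  keep <- .expansion_nodes(tree, include_kingdom)
  A <- A[keep, , drop = FALSE]
  w <- rep(1, nrow(A))
  names(w) <- rownames(A)
  if (!is.null(weights)) {
    if (any(weights < 0, na.rm = TRUE)) stop("negative node weights")
    hit <- intersect(names(weights), names(w))
    w[hit] <- weights[hit]
  }
  vals <- table$values %*% t(A * w)
  structure(list(values = vals, node_ids = rownames(A),
                 sample_ids = rownames(table$values), weights = w),
            class = "expanded_matrix")
}

.expansion_nodes <- function(tree, include_kingdom = FALSE) {
  root <- which(is.na(tree$parent))
  keep <- rep(TRUE, length(tree$id))
  if (!include_kingdom) {
    keep[root] <- tree$is_leaf[root] # root kept only in the 1-node tree
    keep[!is.na(tree$rank) & tree$rank == "kingdom" & !tree$is_leaf] <- FALSE
  }
  which(keep)
}

#' Log amplification of small relative abundances
#'
#' Elementwise map `y = log((1 + 1000 x) / (1 + x))` (natural log).
#' Strictly increasing on `[0, Inf)`, `y(0) = 0`, bounded by
#' `log(1000)`; the slope at the origin is 999, so abundances near the
#' truncation scale are amplified into the critic's working range.
#'
#' @param x numeric vector or matrix of nonnegative abundances.
#' @return transformed values of the same shape.
#' @export
amplify <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("amplify() requires nonnegative input")
  log1p(1000 * x) - log1p(x)
}

## derivative of amplify, used by the generator's backward pass
.amplify_grad <- function(x) 1000 / (1 + 1000 * x) - 1 / (1 + x)

#' Critic input: phylogeny expansion followed by log amplification
#'
#' The full transformation applied identically to real and generated
#' batches before they are scored by the critic.
#'
#' @inheritParams expand_abundance
#' @return an `expanded_matrix` with amplified values.
#' @export
critic_input <- function(table, tree, weights = NULL,
                         include_kingdom = FALSE) {
  ex <- expand_abundance(table, tree, weights, include_kingdom)
  ex$values <- amplify(ex$values)
  ex
}
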