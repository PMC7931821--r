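#' Construct a taxonomy tree
#'
#' A rooted multilevel tree linking species-level leaves to internal
#' rank nodes.  Nodes are stored root-first (every parent precedes its
#' children) in a deterministic order, which also fixes the column
#' order of [expand_abundance()].
#'
#' @param id character vector of unique node identifiers.  For trees
#'   derived from lineage strings the identifier of a node is its full
#'   rank prefix, so homonymous names at the same rank under different
#'   parents remain distinct.
#' @param parent integer vector: index of each node's parent
#'   (`NA` for the single root).
#' @param label display name of each node (defaults to `id`).
#' @param rank taxonomic rank of each node or `NA`.
#' @param branch_length nonnegative length of the edge above each node
#'   (`NA` when the tree carries no lengths; unit lengths are assumed
#'   downstream).
#' @return An object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(id, parent, label = id, rank = NA_character_,
                          branch_length = NA_real_) {
  n <- length(id)
  stopifnot(length(parent) == n)
  if (anyDuplicated(id)) stop("duplicate node ids")
  rank <- rep_len(rank, n)
  label <- rep_len(label, n)
  branch_length <- rep_len(as.numeric(branch_length), n)
  if (any(branch_length < 0, na.rm = TRUE)) stop("negative branch length")
  roots <- which(is.na(parent))
  if (length(roots) != 1L) stop("tree must have exactly one root")
  ## check acyclic / reachability by walking up from every node
  for (i in seq_len(n)) {
    seen <- 0L; j <- i
    while (!is.na(parent[j])) {
      j <- parent[j]; seen <- seen + 1L
      if (seen > n) stop("cycle detected in tree")
    }
    if (j != roots) stop("node ", id[i], " not connected to the root")
  }
  is_leaf <- !(seq_len(n) %in% parent)
  tr <- structure(
    list(id = id, parent = as.integer(parent), label = label, rank = rank,
         branch_length = branch_length, is_leaf = is_leaf),
    class = "taxonomy_tree")
  .tree_reorder(tr)
}

## canonical order: breadth-first from the root, siblings sorted by id
.tree_reorder <- function(tr) {
  n <- length(tr$id)
  root <- which(is.na(tr$parent))
  ord <- integer(0)
  frontier <- root
  while (length(frontier)) {
    frontier <- frontier[order(tr$id[frontier])]
    ord <- c(ord, frontier)
    frontier <- which(tr$parent %in% frontier)
  }
  stopifnot(length(ord) == n)
  remap <- match(seq_len(n), ord)
  structure(
    list(id = tr$id[ord],
         parent = ifelse(is.na(tr$parent[ord]), NA_integer_,
                         remap[tr$parent[ord]]),
         label = tr$label[ord], rank = tr$rank[ord],
         branch_length = tr$branch_length[ord],
         is_leaf = tr$is_leaf[ord]),
    class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d nodes, %d leaves%s\n",
              length(x$id), sum(x$is_leaf),
              if (all(is.na(x$branch_length[-1]))) " (no branch lengths)" else ""))
  invisible(x)
}

#' Leaf identifiers of a taxonomy tree
#' @param tree a [taxonomy_tree()].
#' @export
tree_leaves <- function(tree) tree$id[tree$is_leaf]

#' Build the taxonomy tree implied by a set of lineage strings
#'
#' Internal nodes are every distinct rank prefix of every lineage;
#' leaves are the full lineages.  Node identity is the full prefix, so
#' identical names at the same rank under different parents yield
#' distinct nodes.  When the lineages name more than one top-level
#' taxon, a synthetic root node `"root"` is added above them; branch
#' lengths are absent (unit lengths assumed downstream).
#'
#' @param taxon_ids character vector of lineage strings.
#' @param sep lineage field separator.
#' @return a [taxonomy_tree()] whose leaf set equals `unique(taxon_ids)`.
#' @export
lineage_to_tree <- function(taxon_ids, sep = "|") {
  taxon_ids <- unique(taxon_ids)
  parsed <- parse_lineage(taxon_ids, sep) # validates the dialect
  prefixes <- lapply(taxon_ids, .lineage_prefixes, sep = sep)
  ids <- unique(unlist(prefixes))
  parent_id <- vapply(ids, function(p) {
    fields <- strsplit(p, sep, fixed = TRUE)[[1]]
    if (length(fields) == 1L) NA_character_
    else paste(fields[-length(fields)], collapse = sep)
  }, character(1))
  tops <- ids[is.na(parent_id)]
  if (length(tops) > 1L) {
    ids <- c("root", ids)
    parent_id <- c(NA_character_, ifelse(is.na(parent_id), "root", parent_id))
  }
  depth <- lengths(strsplit(ids, sep, fixed = TRUE))
  rank <- ifelse(ids == "root", NA_character_,
                 names(.rank_prefixes)[match(substr(
                   vapply(strsplit(ids, sep, fixed = TRUE),
                          function(f) f[length(f)], character(1)),
                   1L, 3L), .rank_prefixes)])
  label <- vapply(strsplit(ids, sep, fixed = TRUE),
                  function(f) f[length(f)], character(1))
  taxonomy_tree(id = ids, parent = match(parent_id, ids), label = label,
                rank = rank)
}

#' Read a rooted tree from a Newick file
#'
#' @param path Newick file.
#' @return a [taxonomy_tree()]; tip labels become leaf ids, unlabeled
#'   internal nodes receive synthetic ids.
#' @export
read_newick <- function(path) {
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("Newick parse error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(phy)) stop("Newick parse error in '", path, "'")
  as_taxonomy_tree(phy)
}

#' Convert an ape \code{phylo} object to a taxonomy tree
#' @param phy an [ape::read.tree()] style `phylo` object.
#' @export
as_taxonomy_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  n <- ntip + nnode
  node_lab <- if (!is.null(phy$node.label) && all(nzchar(phy$node.label)))
    phy$node.label else paste0("node_", seq_len(nnode) + ntip)
  id <- c(phy$tip.label, node_lab)
  if (anyDuplicated(id)) id <- make.unique(id, sep = "#")
  parent <- rep(NA_integer_, n)
  blen <- rep(NA_real_, n)
  for (e in seq_len(nrow(phy$edge))) {
    child <- phy$edge[e, 2]
    parent[child] <- phy$edge[e, 1]
    if (!is.null(phy$edge.length)) blen[child] <- phy$edge.length[e]
  }
  taxonomy_tree(id = id, parent = parent, branch_length = blen)
}

#' Convert a taxonomy tree to an ape \code{phylo} object
#' @param tree a [taxonomy_tree()].
#' @return a `phylo` object (edge lengths included when present).
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  n <- length(tree$id)
  leaves <- which(tree$is_leaf)
  internals <- which(!tree$is_leaf)
  root <- which(is.na(tree$parent))
  internals <- c(root, setdiff(internals, root))
  newid <- integer(n)
  newid[leaves] <- seq_along(leaves)
  newid[internals] <- length(leaves) + seq_along(internals)
  has_edge <- which(!is.na(tree$parent))
  edge <- cbind(newid[tree$parent[has_edge]], newid[has_edge])
  phy <- list(edge = edge, Nnode = length(internals),
              tip.label = tree$id[leaves],
              node.label = tree$id[internals])
  if (!all(is.na(tree$branch_length[has_edge])))
    phy$edge.length <- ifelse(is.na(tree$branch_length[has_edge]), 1,
                              tree$branch_length[has_edge])
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

#' Write a taxonomy tree as Newick
#' @param tree a [taxonomy_tree()].
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(as_phylo(tree), file = path)
  invisible(path)
}

#' Indicator matrix of leaf descendants for every node
#'
#' @param tree a [taxonomy_tree()].
#' @return a nodes x leaves 0/1 matrix `A` with `A[v, l] = 1` iff leaf
#'   `l` is `v` or a descendant of `v`; rows in canonical node order.
#' @export
descendant_matrix <- function(tree) {
  n <- length(tree$id)
  leaves <- which(tree$is_leaf)
  A <- matrix(0, n, length(leaves), dimnames = list(tree$id, tree$id[leaves]))
  for (k in seq_along(leaves)) {
    j <- leaves[k]
    while (!is.na(j)) {
      A[j, k] <- 1
      j <- tree$parent[j]
    }
  }
  A
}
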