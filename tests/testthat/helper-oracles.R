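## Independent oracles and small builders shared across the test files.

## tiny lineage set under one kingdom: two phyla, four species
tiny_lineages <- function() {
  c("k__B|p__P1|g__G1|s__a", "k__B|p__P1|g__G1|s__b",
    "k__B|p__P2|g__G2|s__c", "k__B|p__P2|g__G2|s__d")
}

tiny_table <- function(values = NULL) {
  lin <- tiny_lineages()
  if (is.null(values))
    values <- matrix(c(0.4, 0.3, 0.2, 0.1,
                       0.1, 0.2, 0.3, 0.4), 2, 4, byrow = TRUE)
  colnames(values) <- lin
  abundance_table(values)
}

## brute-force descendant sums: walk every node, enumerate its leaves
oracle_expand <- function(table, tree) {
  leaves <- tree_leaves(tree)
  desc_leaves <- function(i) {
    if (tree$is_leaf[i]) return(tree$id[i])
    kids <- which(tree$parent == i)
    unlist(lapply(kids, desc_leaves))
  }
  sapply(seq_along(tree$id), function(i) {
    d <- intersect(desc_leaves(i), colnames(table$values))
    rowSums(table$values[, d, drop = FALSE])
  })
}

## brute-force unweighted UniFrac on an ape tree: classify every edge
## by whether any descendant tip is present in each sample
oracle_unifrac <- function(phy, pres_a, pres_b) {
  ntip <- length(phy$tip.label)
  tips_below <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  uniq <- 0; obs <- 0
  for (e in seq_len(nrow(phy$edge))) {
    tips <- tips_below(phy$edge[e, 2])
    len <- if (is.null(phy$edge.length)) 1 else phy$edge.length[e]
    in_a <- any(tips %in% pres_a); in_b <- any(tips %in% pres_b)
    if (in_a || in_b) obs <- obs + len
    if (xor(in_a, in_b)) uniq <- uniq + len
  }
  uniq / obs
}

## rank correlation computed from first principles (average ranks)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## finite-difference gradient of a critic network at one input row
oracle_input_grad <- function(net, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    (mbgan:::mlp_forward(net, matrix(xp, 1))$out -
       mbgan:::mlp_forward(net, matrix(xm, 1))$out) / (2 * h)
  }, numeric(1))
}

## build an mlp with explicit weights (list of W, list of b)
manual_mlp <- function(W, b, act = "relu") {
  structure(list(W = W, b = b, act = act,
                 dims = c(nrow(W[[1]]), vapply(W, ncol, 1L))),
            class = "mlp")
}

## random abundance table over the tiny taxonomy
random_tiny_table <- function(n = 6, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rexp(n * 4), n, 4)
  v <- v / rowSums(v)
  colnames(v) <- tiny_lineages()
  abundance_table(v)
}
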