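#' Specification of a synthetic compositional fixture
#'
#' Ground-truth generator used throughout the test suite: a
#' logistic-normal composition with a known latent covariance (so
#' taxa-taxa correlation structure is controllable) followed by
#' per-taxon independent zero-masking (so sparsity is controllable),
#' attached to a balanced multilevel taxonomy.  Not a model of any
#' particular cohort; a testbed with known structure emulating
#' zero-inflated, correlated relative-abundance data.
#'
#' @param n_samples number of samples.
#' @param n_species number of species-level taxa.
#' @param correlation latent covariance description: a list with
#'   `structure = "block"` (fields `n_blocks`, `rho`), `structure =
#'   "ar1"` (field `rho`), or `structure = "none"`; alternatively a
#'   full covariance matrix.
#' @param zero_inflation per-taxon probability of masking an entry to
#'   zero (scalar recycled, or vector of length `n_species`).
#' @param branching integer vector of group sizes used to build the
#'   taxonomy bottom-up: species per genus, genera per family, families
#'   per order, and so on up to phylum; a single kingdom roots the tree.
#' @param seed integer seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_samples = 300, n_species = 30,
                         correlation = list(structure = "block",
                                            n_blocks = 2, rho = 0.6),
                         zero_inflation = 0.6,
                         branching = c(3, 2, 2, 2, 2),
                         seed = 1) {
  zero_inflation <- rep_len(zero_inflation, n_species)
  stopifnot(n_samples >= 1, n_species >= 2,
            all(zero_inflation >= 0 & zero_inflation <= 1))
  sigma <- .fixture_sigma(correlation, n_species)
  structure(list(n_samples = n_samples, n_species = n_species,
                 correlation = correlation, sigma = sigma,
                 zero_inflation = zero_inflation,
                 branching = branching, seed = seed),
            class = "fixture_spec")
}

.fixture_sigma <- function(correlation, p) {
  if (is.matrix(correlation)) {
    stopifnot(nrow(correlation) == p, isSymmetric(correlation))
    return(correlation)
  }
  s <- switch(correlation$structure,
    none = diag(p),
    block = {
      nb <- correlation$n_blocks
      sizes <- rep(p %/% nb, nb); sizes[seq_len(p %% nb)] <- sizes[seq_len(p %% nb)] + 1L
      blk <- rep(seq_len(nb), sizes)
      m <- outer(blk, blk, "==") * correlation$rho
      diag(m) <- 1
      m
    },
    ar1 = correlation$rho^abs(outer(seq_len(p), seq_len(p), "-")),
    stop("unknown correlation structure"))
  ev <- min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) stop("fixture covariance not positive semi-definite")
  s
}

#' Balanced rank-prefixed taxonomy for a set of species
#'
#' Groups species bottom-up with the given group sizes, producing
#' lineage strings through kingdom, phylum, class, order, family and
#' genus (a single kingdom roots everything).
#'
#' @param n_species number of species.
#' @param branching group sizes, finest first (see [fixture_spec()]).
#' @return character vector of lineage strings, one per species.
#' @export
make_taxonomy <- function(n_species, branching = c(3, 2, 2, 2, 2)) {
  ranks <- c("genus", "family", "order", "class", "phylum")
  stopifnot(length(branching) <= length(ranks), all(branching >= 1))
  groups <- list(seq_len(n_species)) # ids at current level per species
  ids <- seq_len(n_species) - 1L
  lineage_parts <- list(sprintf("s__sp%03d", seq_len(n_species)))
  for (k in seq_along(branching)) {
    ids <- ids %/% branching[k]
    lineage_parts[[k + 1L]] <- sprintf("%s__%s%d",
      substr(ranks[k], 1, 1), toupper(substr(ranks[k], 1, 1)), ids + 1L)
  }
  lineage_parts[[length(branching) + 2L]] <- rep("k__Bacteria", n_species)
  do.call(paste, c(rev(lineage_parts), sep = "|"))
}

#' Draw a synthetic fixture
#'
#' Latent draws `Y ~ N(0, sigma)` are mapped through a row-wise softmax
#' to closed compositions, entries are independently zero-masked with
#' the per-taxon probabilities, and surviving entries are renormalized.
#' Rows masked entirely to zero are redrawn (at most 100 attempts per
#' row).  The `truth` element records everything needed for recovery
#' tests: the covariance, the pre-mask compositions and the mask.
#'
#' @param spec a [fixture_spec()].
#' @return list with `table` (an [abundance_table()]), `tree` (a
#'   [taxonomy_tree()]) and `truth`.
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; p <- spec$n_species
  taxa <- make_taxonomy(p, spec$branching)
  R <- chol(spec$sigma + diag(1e-10, p))
  draw_rows <- function(k) {
    Y <- matrix(stats::rnorm(k * p), k, p) %*% R
    S <- softmax_rows(Y)
    keep <- matrix(stats::rbinom(k * p, 1L,
                                 rep(1 - spec$zero_inflation, each = k)), k, p)
    list(pre = S, masked = S * keep)
  }
  d <- draw_rows(n)
  vals <- d$masked; pre <- d$pre
  for (i in seq_len(n)) {
    tries <- 0L
    while (sum(vals[i, ]) == 0) {
      tries <- tries + 1L
      if (tries > 100L) stop("all-zero sample persisted after 100 redraws")
      r <- draw_rows(1L)
      vals[i, ] <- r$masked; pre[i, ] <- r$pre
    }
  }
  vals <- vals / rowSums(vals)
  colnames(vals) <- taxa
  rownames(vals) <- sprintf("fix_%04d", seq_len(n))
  tab <- abundance_table(vals, rank_level = "species")
  list(table = tab, tree = lineage_to_tree(taxa),
       truth = list(sigma = spec$sigma, pre_mask = pre,
                    zero_inflation = spec$zero_inflation, spec = spec))
}

#' Reference statistics from a large re-simulation of a fixture
#'
#' Re-simulates the fixture at `factor` times its sample size (with a
#' seed derived from the fixture's) and returns reference
#' distributions used by recovery tests: per-sample sparsity and
#' Shannon vectors with medians, and the pairwise Spearman matrix of
#' the species columns.
#'
#' @param fixture result of [make_fixture()] (or a [fixture_spec()]).
#' @param factor re-simulation size multiplier (default 10).
#' @return list with `sparsity`, `shannon`, `spearman`, and medians.
#' @export
truth_statistics <- function(fixture, factor = 10) {
  spec <- if (inherits(fixture, "fixture_spec")) fixture else fixture$truth$spec
  big <- spec
  big$n_samples <- spec$n_samples * factor
  big$seed <- spec$seed + 104729L # distinct stream, still deterministic
  class(big) <- "fixture_spec"
  fx <- make_fixture(big)
  v <- fx$table$values
  sp <- rowMeans(v == 0)
  sh <- shannon(fx$table)
  list(sparsity = sp, shannon = sh,
       spearman = stats::cor(v, method = "spearman"),
       sparsity_median = stats::median(sp),
       shannon_median = stats::median(sh))
}
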