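#' Assemble a real-versus-simulated fidelity report
#'
#' Runs the full evaluation suite for one real table against any
#' number of simulated tables: per-sample sparsity summaries, Shannon
#' diversity with two-sample Wilcoxon rank-sum tests, stratified
#' abundance comparisons (taxa with <10% zeros and with 10-20% zeros
#' in the real data, abundances pooled within each stratum, one
#' rank-sum p-value per stratum), unweighted UniFrac with a joint nMDS
#' ordination (when a tree is supplied), and taxa-taxa structure
#' (Spearman pairs and clr-based Lovell proportionality, both with
#' R^2/MSE) on the taxa that survive the >90%-zeros filter restricted
#' to the top 10% most abundant species of the real table.
#'
#' @param real an [abundance_table()].
#' @param sims named list of simulated [abundance_table()]s.
#' @param tree optional [taxonomy_tree()]; without it the UniFrac/nMDS
#'   section is skipped with a notice.
#' @param truncation_threshold presence/zero cutoff shared by all
#'   metrics (default 1e-4).
#' @param max_zero_fraction taxa filter for the structure metrics
#'   (default 0.9).
#' @param top_fraction fraction of most abundant taxa used by the
#'   structure metrics (default 0.1).
#' @param nmds_seed seed for the ordination restarts.
#' @param max_unifrac_samples cap on the number of samples per dataset
#'   entering the UniFrac/nMDS section (subsampled deterministically;
#'   default 100).
#' @return a `fidelity_report` list; see Details.
#' @details Sections: `sparsity` (vectors + min/median/max),
#'   `shannon` (vectors + `p_value` per simulator), `strata`
#'   (per-stratum pooled rank-sum p-values), `beta` (UniFrac matrix,
#'   nMDS points, stress, dataset labels) or a skip notice,
#'   `structure` (per simulator: Spearman pairs, R^2, MSE) and
#'   `proportionality` (same for phi), plus `metadata` (retained taxa,
#'   thresholds, policies).
#' @export
compare_fidelity <- function(real, sims, tree = NULL,
                             truncation_threshold = 1e-4,
                             max_zero_fraction = 0.9,
                             top_fraction = 0.1,
                             nmds_seed = 1,
                             max_unifrac_samples = 100) {
  stopifnot(inherits(real, "abundance_table"), is.list(sims),
            length(sims) >= 1, !is.null(names(sims)),
            all(nzchar(names(sims))))
  for (s in sims) stopifnot(inherits(s, "abundance_table"))

  rep <- list()
  rep$sparsity <- c(
    list(real = .sparsity_summary(real, truncation_threshold)),
    lapply(sims, .sparsity_summary, threshold = truncation_threshold))

  sh_real <- shannon(real)
  rep$shannon <- c(
    list(real = list(values = sh_real)),
    lapply(sims, function(s) {
      v <- shannon(s)
      list(values = v,
           p_value = .ranksum_p(sh_real, v))
    }))

  rep$strata <- .strata_section(real, sims)

  if (!is.null(tree)) {
    rep$beta <- .beta_section(real, sims, tree, truncation_threshold,
                              nmds_seed, max_unifrac_samples)
  } else {
    rep$beta <- list(skipped = "no tree supplied; UniFrac/nMDS omitted")
  }

  retained <- .structure_taxa(real, max_zero_fraction, top_fraction)
  rep$structure <- lapply(sims, function(s)
    spearman_structure(real, s, intersect(retained, colnames(s$values))))
  rep$proportionality <- lapply(sims, function(s)
    .phi_section(real, s, intersect(retained, colnames(s$values))))

  rep$metadata <- list(
    n_real = nrow(real$values),
    n_sim = vapply(sims, function(s) nrow(s$values), numeric(1)),
    truncation_threshold = truncation_threshold,
    max_zero_fraction = max_zero_fraction,
    top_fraction = top_fraction,
    retained_taxa = retained,
    clr_zero_policy = "half minimum positive value per sample",
    branch_length_policy = "unit lengths when the tree carries none")
  structure(rep, class = "fidelity_report")
}

.sparsity_summary <- function(table, threshold) {
  v <- sparsity(table, threshold)
  list(values = v, min = min(v), median = stats::median(v), max = max(v))
}

## rank-sum p-value; identical inputs give exactly 1
.ranksum_p <- function(a, b) {
  suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                      correct = FALSE)$p.value)
}

.strata_section <- function(real, sims) {
  zf <- colMeans(real$values == 0)
  strata <- list(zeros_lt_10pct = zf < 0.1,
                 zeros_10_20pct = zf >= 0.1 & zf <= 0.2)
  lapply(strata, function(keep) {
    taxa <- colnames(real$values)[keep]
    if (!length(taxa)) return(list(n_taxa = 0L))
    ps <- lapply(sims, function(s) {
      common <- intersect(taxa, colnames(s$values))
      if (!length(common)) return(NA_real_)
      .ranksum_p(as.vector(real$values[, common]),
                 as.vector(s$values[, common]))
    })
    list(n_taxa = length(taxa), taxa = taxa, p_values = ps)
  })
}

.beta_section <- function(real, sims, tree, threshold, nmds_seed, cap) {
  take <- function(tab) {
    n <- nrow(tab$values)
    idx <- if (n > cap) round(seq(1, n, length.out = cap)) else seq_len(n)
    tab$values[idx, , drop = FALSE]
  }
  mats <- c(list(real = take(real)), lapply(sims, take))
  labels <- rep(names(mats), vapply(mats, nrow, numeric(1)))
  all_taxa <- colnames(real$values)
  stacked <- do.call(rbind, lapply(mats, function(m) {
    out <- matrix(0, nrow(m), length(all_taxa),
                  dimnames = list(NULL, all_taxa))
    common <- intersect(colnames(m), all_taxa)
    out[, common] <- m[, common]
    out
  }))
  rownames(stacked) <- sprintf("%s_%04d", labels, seq_along(labels))
  tab <- abundance_table(stacked, rank_level = real$rank_level,
                         normalized = NA)
  D <- unweighted_unifrac(tab, tree, threshold)
  ok <- !apply(D, 1L, anyNA)
  ord <- nmds(D[ok, ok, drop = FALSE], dims = 2, seed = nmds_seed)
  list(unifrac = D, labels = labels, points = ord$points,
       stress = ord$stress, n_dropped = sum(!ok))
}

.structure_taxa <- function(real, max_zero_fraction, top_fraction) {
  filtered <- filter_taxa(real, max_zero_fraction)
  kept <- top_abundant(real, top_fraction)
  taxa <- intersect(colnames(filtered$values), colnames(kept$values))
  if (length(taxa) < 2)
    stop("fewer than 2 taxa retained for structure metrics")
  taxa
}

.phi_section <- function(real, sim, taxa) {
  cr <- clr(real$values)
  cs <- clr(sim$values)
  pr <- phi_pairs(cr, taxa)
  ps <- phi_pairs(cs, taxa)
  ok <- is.finite(pr) & is.finite(ps)
  r2 <- if (sum(ok) >= 3 && stats::sd(pr[ok]) > 0 && stats::sd(ps[ok]) > 0)
    stats::cor(pr[ok], ps[ok])^2 else NA_real_
  list(real = pr, sim = ps, r_squared = r2,
       mse = mean((ps[ok] - pr[ok])^2), n_dropped = sum(!ok))
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report>\n")
  for (nm in names(x$sparsity))
    cat(sprintf("  sparsity %-10s min/median/max %.3f / %.3f / %.3f\n", nm,
                x$sparsity[[nm]]$min, x$sparsity[[nm]]$median,
                x$sparsity[[nm]]$max))
  for (nm in setdiff(names(x$shannon), "real"))
    cat(sprintf("  shannon  %-10s median %.3f (real %.3f), rank-sum p = %.3g\n",
                nm, stats::median(x$shannon[[nm]]$values),
                stats::median(x$shannon$real$values),
                x$shannon[[nm]]$p_value))
  for (nm in names(x$structure))
    cat(sprintf("  spearman %-10s R^2 %.3f MSE %.4f | phi R^2 %.3f MSE %.4f\n",
                nm, x$structure[[nm]]$r_squared, x$structure[[nm]]$mse,
                x$proportionality[[nm]]$r_squared,
                x$proportionality[[nm]]$mse))
  if (!is.null(x$beta$stress))
    cat(sprintf("  nMDS stress %.4f over %d samples\n", x$beta$stress,
                length(x$beta$labels) - x$beta$n_dropped))
  invisible(x)
}

#' Write a fidelity report to disk
#'
#' The report is written as a single JSON file; the UniFrac matrix and
#' the nMDS coordinates additionally as TSV files next to it.
#'
#' @param report a `fidelity_report`.
#' @param path output JSON path; companion TSVs take the same stem.
#' @return `path`, invisibly.
#' @export
write_fidelity_report <- function(report, path) {
  out <- unclass(report)
  if (!is.null(out$beta$unifrac)) {
    stem <- sub("\\.json$", "", path)
    utils::write.table(out$beta$unifrac, paste0(stem, "_unifrac.tsv"),
                       sep = "\t", quote = FALSE)
    pts <- data.frame(label = out$beta$labels, out$beta$points)
    utils::write.table(pts, paste0(stem, "_nmds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$beta$unifrac <- NULL # matrices live in the TSVs
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Plot a fidelity report
#'
#' Four base-graphics panels mirroring the evaluation suite: Shannon
#' box plots, sparsity box plots, the nMDS ordination colored by
#' dataset, and the real-vs-simulated Spearman scatter.
#'
#' @param x a `fidelity_report`.
#' @param ... unused.
#' @export
plot.fidelity_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  sh <- lapply(x$shannon, `[[`, "values")
  graphics::boxplot(sh, main = "Shannon index", ylab = "entropy (nats)")
  sp <- lapply(x$sparsity, `[[`, "values")
  graphics::boxplot(sp, main = "Sparsity", ylab = "fraction of zeros")
  if (!is.null(x$beta$points)) {
    grp <- factor(x$beta$labels)
    graphics::plot(x$beta$points, col = as.integer(grp), pch = 16,
                   cex = 0.6, main = sprintf("nMDS (stress %.3f)",
                                             x$beta$stress),
                   xlab = "nMDS1", ylab = "nMDS2")
    graphics::legend("topright", legend = levels(grp), pch = 16,
                     col = seq_along(levels(grp)), cex = 0.7)
  } else graphics::plot.new()
  nm <- names(x$structure)[1]
  pr <- x$structure[[nm]]$pairs
  graphics::plot(pr$real, pr$sim, pch = 16, cex = 0.5,
                 xlab = "Spearman (real)", ylab = sprintf("Spearman (%s)", nm),
                 main = sprintf("R^2 = %.3f", x$structure[[nm]]$r_squared))
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
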