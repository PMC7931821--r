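#' Fit a zero-inflated negative binomial to a count vector
#'
#' Maximum-likelihood fit of the mixture
#' `pi * I(y = 0) + (1 - pi) * NB(mu, size)` by BFGS on the
#' (logit, log, log) scale.  When the optimizer fails to converge the
#' fit falls back to a method-of-moments approximation (excess-zero
#' estimate of `pi`, then moment matching of `mu` and `size` on the
#' inflated moments) with a warning.
#'
#' @param y nonnegative integer counts.
#' @return list with `pi` (zero-inflation probability), `size`
#'   (dispersion), `mu` (NB mean), `loglik`, `method`
#'   (`"mle"` or `"moments"`), `converged`.
#' @export
fit_zinb <- function(y) {
  stopifnot(all(y >= 0), all(y == round(y)))
  n <- length(y)
  zf <- mean(y == 0)
  m1 <- mean(y); v1 <- stats::var(y)
  ## moment-based starting values
  pi0 <- max(min(zf / 2, 0.9), 1e-3)
  mu0 <- max(m1 / (1 - pi0), 1e-3)
  size0 <- if (v1 > m1) max(m1^2 / (v1 - m1), 0.05) else 10
  nll <- function(par) {
    pi <- stats::plogis(par[1]); size <- exp(par[2]); mu <- exp(par[3])
    ll <- ifelse(y == 0,
                 log(pi + (1 - pi) * stats::dnbinom(0, size = size, mu = mu)),
                 log1p(-pi) + stats::dnbinom(y, size = size, mu = mu,
                                             log = TRUE))
    -sum(ll)
  }
  fit <- tryCatch(
    stats::optim(c(stats::qlogis(pi0), log(size0), log(mu0)), nll,
                 method = "BFGS", control = list(maxit = 500)),
    error = function(e) NULL)
  if (!is.null(fit) && is.finite(fit$value)) {
    par <- fit$par
    return(list(pi = stats::plogis(par[1]), size = exp(par[2]),
                mu = exp(par[3]), loglik = -fit$value,
                method = "mle", converged = fit$convergence == 0))
  }
  warning("ziNB likelihood fit failed; falling back to method of moments")
  pihat <- {
    p0_nb <- stats::dnbinom(0, size = size0, mu = mu0)
    max(0, min((zf - p0_nb) / (1 - p0_nb), 0.95))
  }
  muhat <- if (pihat < 1) m1 / (1 - pihat) else m1
  vpos <- v1
  sizehat <- if (vpos > muhat) max(muhat^2 / (vpos - muhat), 0.05) else 10
  list(pi = pihat, size = sizehat, mu = muhat, loglik = NA_real_,
       method = "moments", converged = FALSE)
}

#' Quantile function of the zero-inflated negative binomial
#'
#' Mixture inversion: `q(u) = 0` for `u <= pi`, otherwise the NB
#' quantile at `(u - pi) / (1 - pi)`.
#'
#' @param u probabilities in `[0, 1]`.
#' @param pi zero-inflation probability.
#' @param size,mu NB dispersion and mean.
#' @return integer counts.
#' @export
qzinb <- function(u, pi, size, mu) {
  stopifnot(all(u >= 0 & u <= 1))
  out <- numeric(length(u))
  pos <- u > pi
  out[pos] <- stats::qnbinom((u[pos] - pi) / (1 - pi), size = size, mu = mu)
  out
}

#' Fit the NorTA (Normal-to-Anything) simulator to a count table
#'
#' Estimation half of the copula baseline: taxa observed as zero in
#' every sample are removed, the taxa-taxa correlation matrix of the
#' counts is estimated (Pearson by default, matching a correlation
#' matrix "calculated from the real data"; Spearman available), and a
#' zero-inflated negative binomial marginal is fitted to every
#' retained taxon.  Indefinite empirical correlation matrices are
#' repaired by clipping negative eigenvalues and rescaling to unit
#' diagonal.
#'
#' @param counts samples x taxa matrix of nonnegative integer counts
#'   (an [abundance_table()] holding counts is also accepted).
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return a `norta_spec`: `correlation` (repaired), `marginals`
#'   (list of [fit_zinb()] results), `taxon_ids`, `cor_method`,
#'   `n_samples`.
#' @export
fit_norta <- function(counts, cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  m <- if (inherits(counts, "abundance_table")) counts$values else
    as.matrix(counts)
  if (any(m < 0) || any(m != round(m)))
    stop("fit_norta expects nonnegative integer counts")
  keep <- colSums(m) > 0
  if (sum(keep) < 2) stop("fewer than 2 taxa with nonzero counts")
  m <- m[, keep, drop = FALSE]
  R <- stats::cor(m, method = cor_method)
  R <- .repair_correlation(R)
  marg <- lapply(seq_len(ncol(m)), function(j) fit_zinb(m[, j]))
  names(marg) <- colnames(m)
  structure(list(correlation = R, marginals = marg,
                 taxon_ids = colnames(m), cor_method = cor_method,
                 n_samples = nrow(m)),
            class = "norta_spec")
}

## clip negative eigenvalues at a small floor, rescale to unit diagonal
.repair_correlation <- function(R) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 1e-10) {
    v <- pmax(e$values, 1e-10)
    R <- e$vectors %*% (v * t(e$vectors))
    D <- 1 / sqrt(diag(R))
    R <- R * tcrossprod(D)
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 0)
    stop("correlation matrix not repairable to positive semi-definite")
  R
}

#' Simulate from a fitted NorTA specification
#'
#' Sampling half of the copula baseline: draw multivariate normal
#' rows with the target correlation, map each coordinate through the
#' standard normal CDF to uniforms, apply the fitted ziNB quantile per
#' taxon to obtain counts, and compositionalize by dividing each row
#' by its total.  Rows whose total count is zero are emitted as
#' all-zero compositions with a warning.
#'
#' @param spec a `norta_spec` from [fit_norta()].
#' @param n_samples rows to simulate.
#' @param seed integer seed.
#' @return list with `counts` (matrix) and `table`
#'   (an [abundance_table()] of relative abundances).
#' @export
norta_simulate <- function(spec, n_samples, seed = 1) {
  stopifnot(inherits(spec, "norta_spec"), n_samples >= 1)
  set.seed(seed)
  p <- length(spec$taxon_ids)
  L <- chol(spec$correlation + diag(1e-10, p))
  Z <- matrix(stats::rnorm(n_samples * p), n_samples, p) %*% L
  U <- stats::pnorm(Z)
  counts <- matrix(0, n_samples, p,
                   dimnames = list(sprintf("norta_%04d", seq_len(n_samples)),
                                   spec$taxon_ids))
  for (j in seq_len(p)) {
    mj <- spec$marginals[[j]]
    counts[, j] <- qzinb(U[, j], mj$pi, mj$size, mj$mu)
  }
  tot <- rowSums(counts)
  if (any(tot == 0))
    warning(sum(tot == 0), " sample(s) with zero total count left all-zero")
  rel <- counts
  nz <- tot > 0
  rel[nz, ] <- rel[nz, , drop = FALSE] / tot[nz]
  list(counts = counts,
       table = abundance_table(rel, normalized = all(nz),
                               normalization = "counts"))
}

#' Convert relative abundances to pseudo-counts
#'
#' NorTA operates on counts; when only relative abundances are
#' available they are multiplied by a nominal library size and
#' rounded.
#'
#' @param table an [abundance_table()].
#' @param library_size counts per sample (default 1e6).
#' @return samples x taxa integer matrix.
#' @export
as_pseudocounts <- function(table, library_size = 1e6) {
  round(table$values * library_size)
}
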