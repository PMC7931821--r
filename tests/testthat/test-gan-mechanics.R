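test_that("gradient penalty hits its analytic fixed points", {
  d <- 7
  lin <- manual_mlp(list(matrix(1 / sqrt(d), d, 1)), list(0))
  X <- matrix(rnorm(5 * d), 5, d)
  expect_equal(gradient_penalty(lin, X, X + 1), 0, tolerance = 1e-12)
  const <- manual_mlp(list(matrix(0, d, 1)), list(2))
  expect_equal(gradient_penalty(const, X, X + 1), 1, tolerance = 1e-12)
})

test_that("gradient penalty agrees with finite-difference gradient norms", {
  set.seed(21)
  for (rep in 1:3) {
    net <- mlp_init(c(5, 6, 4, 1))
    Xr <- matrix(rnorm(4 * 5), 4, 5)
    Xf <- matrix(rnorm(4 * 5), 4, 5)
    eps <- runif(4)
    pen <- gradient_penalty(net, Xr, Xf, eps = eps)
    Xhat <- eps * Xr + (1 - eps) * Xf
    norms <- vapply(seq_len(4), function(i)
      sqrt(sum(oracle_input_grad(net, Xhat[i, ])^2)), numeric(1))
    expect_equal(pen, mean((norms - 1)^2), tolerance = 1e-3)
  }
})

test_that("gradient-penalty parameter gradients match finite differences", {
  set.seed(4)
  net <- mlp_init(c(4, 5, 1), act = "lrelu")
  X <- matrix(rnorm(6 * 4), 6, 4)
  gp <- mbgan:::gp_penalty_grads(net, X)
  h <- 1e-6
  for (l in 1:2) {
    k <- sample(length(net$W[[l]]), 5)
    for (idx in k) {
      np <- net; np$W[[l]][idx] <- np$W[[l]][idx] + h
      nm <- net; nm$W[[l]][idx] <- nm$W[[l]][idx] - h
      fd <- (mbgan:::gp_penalty_grads(np, X, want_grads = FALSE)$penalty -
             mbgan:::gp_penalty_grads(nm, X, want_grads = FALSE)$penalty) / (2 * h)
      expect_equal(gp$dW[[l]][idx], fd, tolerance = 1e-5)
    }
  }
})

test_that("critic scores are dot products for a linear critic", {
  d <- 6
  w <- rnorm(d)
  model <- list(critic = manual_mlp(list(matrix(w, d, 1)), list(0.5)),
                node_ids = paste0("n", 1:d))
  X <- matrix(rnorm(8 * d), 8, d)
  expect_equal(critic_score(model, X), drop(X %*% w) + 0.5,
               tolerance = 1e-12)
  ## permuting samples permutes scores identically
  perm <- sample(8)
  expect_equal(critic_score(model, X[perm, ]),
               critic_score(model, X)[perm])
  ## zero-weight critic scores everything 0
  z <- list(critic = manual_mlp(list(matrix(0, d, 1)), list(0)),
            node_ids = paste0("n", 1:d))
  expect_equal(critic_score(z, X), rep(0, 8))
  expect_error(critic_score(model, X[, 1:3]), "does not match")
})

test_that("one training iteration records 5 critic updates and 1 generator update", {
  tab <- random_tiny_table(n = 40, seed = 2)
  tr <- lineage_to_tree(tiny_lineages())
  cfg <- gan_config_small(max_iterations = 1, seed = 5, noise_dim = 8,
                          generator_hidden = c(8, 8), critic_hidden = c(8, 8),
                          batch_size = 8, init_marginals = FALSE,
                          checkpoint_every = 0)
  m <- mbgan_train(tab, tr, cfg)
  expect_equal(nrow(m$history$critic), 5L)
  expect_equal(m$history$critic$step, 1:5)
  expect_equal(nrow(m$history$generator), 1L)
  expect_true(all(is.finite(m$history$critic$w_loss)))
  expect_true(all(is.finite(m$history$critic$gp)))
  expect_length(m$history$weight_mse, 1L)
})

test_that("training is deterministic under a fixed seed", {
  tab <- random_tiny_table(n = 40, seed = 2)
  tr <- lineage_to_tree(tiny_lineages())
  cfg <- gan_config_small(max_iterations = 20, seed = 123, noise_dim = 8,
                          generator_hidden = c(8, 8), critic_hidden = c(8, 8),
                          batch_size = 8, init_marginals = FALSE,
                          checkpoint_every = 0)
  m1 <- mbgan_train(tab, tr, cfg)
  m2 <- mbgan_train(tab, tr, cfg)
  expect_identical(m1$history$critic$w_loss, m2$history$critic$w_loss)
  expect_identical(m1$history$generator$loss, m2$history$generator$loss)
  expect_identical(m1$generator$W, m2$generator$W)
})

test_that("generated rows close to 1 before truncation and truncate after", {
  tab <- random_tiny_table(n = 40, seed = 2)
  tr <- lineage_to_tree(tiny_lineages())
  cfg <- gan_config_small(max_iterations = 2, seed = 5, noise_dim = 8,
                          generator_hidden = c(8, 8), critic_hidden = c(8, 8),
                          batch_size = 8, init_marginals = FALSE,
                          checkpoint_every = 0)
  m <- mbgan_train(tab, tr, cfg)
  z <- matrix(rnorm(10 * 8), 10, 8)
  raw <- gan_generate(m, z, truncate = FALSE)
  expect_true(all(abs(rowSums(raw$values) - 1) < 1e-6))
  expect_true(all(raw$values >= 0))
  ## same noise twice -> identical tables
  expect_identical(gan_generate(m, z)$values, gan_generate(m, z)$values)
  expect_error(gan_generate(m, z[, 1:3]), "noise_dim")

  sim <- gan_simulate(m, 200, seed = 31)
  expect_equal(nrow(sim$values), 200L)
  thr <- m$config$truncation_threshold
  expect_true(!any(sim$values > 0 & sim$values < thr))
  expect_identical(sim$values, gan_simulate(m, 200, seed = 31)$values)
  expect_error(gan_simulate(m, 0), "positive")
})

test_that("truncation sets sub-threshold entries to zero without re-closing", {
  model <- list(generator = manual_mlp(
                  list(matrix(0, 2, 4)),
                  list(log(c(0.99985 + 5e-5, 5e-5, 4e-5, 2e-5)))),
                taxon_ids = tiny_lineages(), rank_level = "species",
                config = list(noise_dim = 2, truncation_threshold = 1e-4,
                              softmax_gain = 1))
  class(model) <- "gan_model"
  out <- gan_generate(model, matrix(0, 1, 2))
  expect_equal(sum(out$values == 0), 3L)
  expect_false(out$normalized)
  expect_lt(sum(out$values), 1)
})

test_that("convergence statistics follow the windowed mean-MSE rule", {
  mk_hist <- function(wmse) {
    n <- length(wmse)
    list(generator = data.frame(iteration = seq_len(n),
                                loss = rnorm(n), critic_w = rnorm(n)),
         weight_mse = wmse)
  }
  ## constant weight change: difference of windowed means is 0
  cs <- convergence_stats(mk_hist(rep(0.5, 250)), window = 100)
  expect_true(cs$converged)
  expect_equal(cs$converged_at, 200L) # after two windows
  ## frozen weights
  cs0 <- convergence_stats(mk_hist(rep(0, 200)), window = 100)
  expect_true(cs0$converged)
  expect_equal(cs0$converged_at, 200L)
  ## short history is not assessable
  csna <- convergence_stats(mk_hist(rep(0, 150)), window = 100)
  expect_false(csna$assessable)
  expect_false(csna$converged)
  ## hand-computed windowed means on a known series
  wmse <- c(rep(1, 100), rep(3, 100), rep(3, 100))
  h <- mk_hist(wmse)
  csh <- convergence_stats(h, window = 100, tol = 1e-8)
  expect_equal(csh$converged_at, 300L) # windows 2 and 3 agree (3 vs 3)
  expect_equal(csh$combined_wasserstein,
               h$generator$loss + h$generator$critic_w)
})

test_that("checkpoints save and reload losslessly", {
  tab <- random_tiny_table(n = 40, seed = 2)
  tr <- lineage_to_tree(tiny_lineages())
  cfg <- gan_config_small(max_iterations = 2, seed = 5, noise_dim = 8,
                          generator_hidden = c(8, 8), critic_hidden = c(8, 8),
                          batch_size = 8, init_marginals = FALSE,
                          checkpoint_every = 0)
  m <- mbgan_train(tab, tr, cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_gan_model(m, f)
  m2 <- load_gan_model(f)
  z <- matrix(rnorm(4 * 8), 4, 8)
  expect_identical(gan_generate(m, z)$values, gan_generate(m2, z)$values)
})
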