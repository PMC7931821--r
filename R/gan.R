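#' Configuration for MB-GAN training
#'
#' Defaults follow the WGAN-GP training schedule used for full-size
#' microbiome tables: the Wasserstein and gradient-penalty losses are
#' weighted 1:10, RMSprop with learning rate 5e-5, batches of 32, five
#' critic steps per generator step, and truncation of simulated
#' abundances below 1e-4.  For small problems (tens of taxa, a few
#' thousand iterations) a proportionally larger learning rate is
#' appropriate; see [gan_config_small()].
#'
#' @param noise_dim width of the Gaussian noise input z ~ N(0, 1).
#' @param generator_hidden,critic_hidden hidden-layer widths.
#' @param gp_weight gradient-penalty multiplier lambda (default 10).
#' @param learning_rate RMSprop learning rate (default 5e-5).
#' @param batch_size minibatch size (default 32).
#' @param critic_steps critic updates per generator update (default 5).
#' @param max_iterations number of generator iterations (default 1e5).
#' @param truncation_threshold simulated abundances below this are set
#'   to zero (default 1e-4); truncated rows are not renormalized.
#' @param seed integer seed governing weight init, batch sampling,
#'   noise and the interpolation draws of the gradient penalty.
#' @param critic_lr_mult multiplier on the critic's learning rate
#'   relative to the generator's (two-timescale rule; default 1).
#' @param lr_decay_to final learning-rate fraction of an exponential
#'   decay schedule over the run (1 = constant, default).
#' @param rmsprop_rho,rmsprop_eps RMSprop decay and stabilizer.
#' @param generator_momentum momentum applied to the generator's
#'   RMSprop updates (default 0, the critic never uses momentum).
#' @param activation hidden activation of both networks: `"lrelu"`
#'   (leaky ReLU, slope 0.2; default) or `"relu"`.
#' @param standardize_critic_input center and scale each node of the
#'   amplified critic input by its training-data mean and standard
#'   deviation (floored at 0.05) before scoring.  Applied identically
#'   to real and generated batches; improves the conditioning of the
#'   critic and the strength of its gradients on rarely occupied
#'   nodes (default TRUE).
#' @param softmax_gain inverse temperature of the generator's softmax
#'   head: compositions are `softmax(gain * logits)`.  Values above 1
#'   sharpen the output towards the bimodal zero/abundant pattern of
#'   highly sparse tables (default 1).
#' @param init_output_bias initialize the generator's output-layer
#'   bias to the log of the mean training composition, so training
#'   starts from the right overall abundance scale (default TRUE;
#'   ignored when `init_marginals` is on).
#' @param init_drop_depth logit drop of a fully active dropout unit
#'   under `init_marginals` (default 30; deeper drops make the initial
#'   masks harder at the cost of leaky-ReLU noise on active entries).
#' @param init_marginals marginal-informed initialization: the first
#'   hidden layer is wired as one noise-thresholded dropout unit per
#'   taxon calibrated to that taxon's observed zero rate, intermediate
#'   layers pass these units through, and the output layer reproduces
#'   the observed mean log-abundance of the occupied entries.  The
#'   initial generator thus already matches per-taxon occupancy and
#'   abundance scale (with independent masks); adversarial training
#'   refines the joint structure.  Requires `noise_dim` and all hidden
#'   widths to be at least the number of taxa (default FALSE).
#' @param include_kingdom,weights passed to [critic_input()].
#' @param sample_with_replacement allow training sets smaller than the
#'   batch size by sampling batches with replacement.
#' @param checkpoint_every cadence (iterations) at which candidate
#'   generators are scored for model selection by the energy distance
#'   between a generated batch and a real batch in transformed space;
#'   the best-scoring snapshot is kept.  0 disables selection and the
#'   final weights are used.
#' @param convergence_window window (iterations) for the convergence
#'   statistics, see [convergence_stats()].
#' @return a `gan_config` list.
#' @export
gan_config <- function(noise_dim = 100,
                       generator_hidden = c(256, 512),
                       critic_hidden = c(512, 256),
                       gp_weight = 10,
                       learning_rate = 5e-5,
                       batch_size = 32,
                       critic_steps = 5,
                       max_iterations = 100000,
                       truncation_threshold = 1e-4,
                       seed = 1,
                       critic_lr_mult = 1,
                       lr_decay_to = 1,
                       rmsprop_rho = 0.9,
                       rmsprop_eps = 1e-8,
                       generator_momentum = 0,
                       activation = c("lrelu", "relu"),
                       standardize_critic_input = TRUE,
                       softmax_gain = 1,
                       init_output_bias = TRUE,
                       init_marginals = FALSE,
                       init_drop_depth = 30,
                       include_kingdom = FALSE,
                       weights = NULL,
                       sample_with_replacement = FALSE,
                       checkpoint_every = 0,
                       convergence_window = 1000) {
  activation <- match.arg(activation)
  stopifnot(gp_weight > 0, batch_size >= 2, critic_steps >= 1,
            noise_dim >= 1, learning_rate > 0, truncation_threshold >= 0,
            softmax_gain > 0)
  structure(as.list(environment()), class = "gan_config")
}

## Marginal-informed generator initialization (see gan_config).  The
## structured entries sit on top of a damped He init so the remaining
## units keep gradient diversity.
.init_generator_marginals <- function(gen, x, config) {
  p <- ncol(x)
  L <- length(gen$W)
  if (nrow(gen$W[[1L]]) < p || any(vapply(gen$W[-L], ncol, 1L) < p))
    stop("init_marginals requires noise_dim and hidden widths >= n_taxa")
  pi_hat <- pmin(pmax(colMeans(x == 0), 0.01), 0.95)
  ## mean log abundance of the occupied entries per taxon
  mu_hat <- vapply(seq_len(p), function(j) {
    v <- x[x[, j] > 0, j]
    if (!length(v)) log(1e-6) else mean(log(v))
  }, numeric(1))
  g <- config$softmax_gain
  drop_depth <- config$init_drop_depth / g # masked entries fall below 1e-4
  for (l in seq_len(L)) gen$W[[l]] <- gen$W[[l]] * 0.3
  ## layer 1: u_j = act(z_j - t_j), active (masking) with prob pi_hat
  diag(gen$W[[1L]][seq_len(p), seq_len(p)]) <- 1
  gen$b[[1L]][seq_len(p)] <- -stats::qnorm(1 - pi_hat)
  ## middle layers: pass the p mask units through unchanged
  if (L > 2L) for (l in 2L:(L - 1L)) {
    diag(gen$W[[l]][seq_len(p), seq_len(p)]) <-
      diag(gen$W[[l]][seq_len(p), seq_len(p)]) * 0 + 1
  }
  ## output layer: logit_j = mu_hat_j/g - drop_depth * mask_j
  diag(gen$W[[L]][seq_len(p), seq_len(p)]) <- -drop_depth
  gen$b[[L]] <- (mu_hat - mean(mu_hat)) / g
  gen
}

#' Small-problem preset of [gan_config()]
#'
#' For fixtures with tens of taxa trained for a few thousand
#' iterations the full-size schedule (5e-5 over 100,000 iterations) is
#' far from its operating point; this preset scales the learning rate
#' up and the architecture down while keeping the loss weighting and
#' 5:1 schedule.
#'
#' @param max_iterations generator iterations (default 4000).
#' @param seed integer seed.
#' @param ... overrides passed to [gan_config()].
#' @export
gan_config_small <- function(max_iterations = 5000, seed = 1, ...) {
  args <- list(noise_dim = 32, generator_hidden = c(64, 128),
               critic_hidden = c(128, 64), learning_rate = 1e-2,
               lr_decay_to = 0.1, softmax_gain = 3,
               init_marginals = TRUE, init_drop_depth = 30,
               max_iterations = max_iterations, seed = seed,
               checkpoint_every = 250)
  override <- list(...)
  args[names(override)] <- override
  do.call(gan_config, args)
}

## squared-Euclidean-based energy distance between two point sets
.energy_distance <- function(X, Y) {
  cross <- sqrt(pmax(outer(rowSums(X^2), rowSums(Y^2), "+") -
                       2 * tcrossprod(X, Y), 0))
  dxx <- stats::dist(X); dyy <- stats::dist(Y)
  2 * mean(cross) - 2 * mean(dxx) * (nrow(X) - 1) / nrow(X) / 2 -
    2 * mean(dyy) * (nrow(Y) - 1) / nrow(Y) / 2
}

#' Train MB-GAN on a relative-abundance table
#'
#' Alternating WGAN-GP optimization: each iteration runs
#' `critic_steps` critic updates (loss `mean f(fake) - mean f(real) +
#' gp_weight * GP`, minimized) followed by one generator update (loss
#' `-mean f(fake)`, minimized).  Both real and generated batches pass
#' through the phylogeny transformation ([critic_input()]) before the
#' critic scores them.  The generator ends in a softmax head so every
#' generated row is a closed composition.
#'
#' @param real an [abundance_table()] of training samples (species level).
#' @param tree a [taxonomy_tree()] whose leaves cover the table's taxa.
#' @param config a [gan_config()].
#' @param verbose print progress every 500 iterations.
#' @return a `gan_model`: generator and critic networks, the config,
#'   node/taxon orders, full training history (per-critic-step
#'   Wasserstein and penalty losses, per-iteration generator loss and
#'   parameter-change MSE), the convergence iteration (or `NA`), and
#'   the selected checkpoint.
#' @export
mbgan_train <- function(real, tree, config = gan_config(), verbose = FALSE) {
  stopifnot(inherits(real, "abundance_table"),
            inherits(tree, "taxonomy_tree"),
            inherits(config, "gan_config"))
  n <- nrow(real$values)
  p <- ncol(real$values)
  if (n < config$batch_size && !config$sample_with_replacement)
    stop("training set smaller than batch_size; set sample_with_replacement")
  set.seed(config$seed)

  ## fixed transformation: generated compositions S map to critic input
  ## amplify(S %*% M) with M = t(weighted descendant indicator)
  ex_real <- critic_input(real, tree, config$weights, config$include_kingdom)
  node_ids <- ex_real$node_ids
  A <- descendant_matrix(tree)[node_ids, colnames(real$values), drop = FALSE]
  M <- t(A * ex_real$weights[node_ids]) # p x d
  Xreal <- ex_real$values               # n x d
  d <- ncol(Xreal)
  if (isTRUE(config$standardize_critic_input)) {
    in_center <- colMeans(Xreal)
    in_scale <- pmax(apply(Xreal, 2L, stats::sd), 0.05)
  } else {
    in_center <- numeric(d)
    in_scale <- rep(1, d)
  }
  Xreal <- sweep(sweep(Xreal, 2L, in_center), 2L, in_scale, "/")

  gen <- mlp_init(c(config$noise_dim, config$generator_hidden, p),
                  act = config$activation)
  cri <- mlp_init(c(d, config$critic_hidden, 1L), act = config$activation)
  if (isTRUE(config$init_marginals)) {
    gen <- .init_generator_marginals(gen, real$values, config)
  } else if (isTRUE(config$init_output_bias)) {
    mu <- colMeans(real$values)
    lb <- log(mu + 1e-8) / config$softmax_gain
    gen$b[[length(gen$b)]] <- lb - mean(lb)
  }
  st_g <- rmsprop_state(gen)
  st_c <- rmsprop_state(cri)

  iters <- config$max_iterations
  B <- config$batch_size
  gen_loss <- numeric(iters)
  crit_w <- numeric(iters) # last critic step's Wasserstein loss per iteration
  weight_mse <- numeric(iters)
  prev_par <- params_flatten(gen, cri)
  ci <- 0L
  nrec <- iters * config$critic_steps
  hc_it <- integer(nrec); hc_st <- integer(nrec)
  hc_w <- numeric(nrec); hc_gp <- numeric(nrec)

  best <- list(gen = gen, iteration = 0L, value = Inf)
  converged_at <- NA_integer_

  gain <- config$softmax_gain
  gen_forward <- function(z) {
    fw <- mlp_forward(gen, z, cache = TRUE)
    S <- softmax_rows(gain * fw$out)
    Xr <- S %*% M
    X <- sweep(sweep(amplify(Xr), 2L, in_center), 2L, in_scale, "/")
    list(fw = fw, S = S, Xraw = Xr, X = X)
  }

  for (it in seq_len(iters)) {
    lr_it <- config$learning_rate *
      config$lr_decay_to^((it - 1) / max(iters - 1, 1))
    for (cs in seq_len(config$critic_steps)) {
      idx <- sample.int(n, B, replace = config$sample_with_replacement || B > n)
      Xr <- Xreal[idx, , drop = FALSE]
      z <- matrix(stats::rnorm(B * config$noise_dim), B, config$noise_dim)
      Xf <- gen_forward(z)$X
      ## Wasserstein part: d/dw [ mean f(fake) - mean f(real) ]
      fw_f <- mlp_forward(cri, Xf, cache = TRUE)
      fw_r <- mlp_forward(cri, Xr, cache = TRUE)
      g_f <- mlp_backward(cri, fw_f, matrix(1 / B, B, 1L))
      g_r <- mlp_backward(cri, fw_r, matrix(-1 / B, B, 1L))
      w_loss <- mean(fw_f$out) - mean(fw_r$out)
      if (!is.finite(w_loss))
        stop("non-finite critic loss at iteration ", it)
      ## gradient penalty at per-sample interpolates
      epsv <- stats::runif(B)
      Xhat <- epsv * Xr + (1 - epsv) * Xf
      gp <- gp_penalty_grads(cri, Xhat)
      grads <- add_grads(add_grads(g_f, g_r), gp, w = config$gp_weight)
      up <- rmsprop_step(cri, grads, st_c, lr_it * config$critic_lr_mult,
                         config$rmsprop_rho, config$rmsprop_eps)
      cri <- up$net; st_c <- up$state
      ci <- ci + 1L
      hc_it[ci] <- it; hc_st[ci] <- cs; hc_w[ci] <- w_loss; hc_gp[ci] <- gp$penalty
    }
    ## generator step: minimize -mean f(fake)
    z <- matrix(stats::rnorm(B * config$noise_dim), B, config$noise_dim)
    gf <- gen_forward(z)
    fw_c <- mlp_forward(cri, gf$X, cache = TRUE)
    gl <- -mean(fw_c$out)
    if (!is.finite(gl)) stop("non-finite generator loss at iteration ", it)
    bk_c <- mlp_backward(cri, fw_c, matrix(-1 / B, B, 1L))
    dXraw <- sweep(bk_c$dX, 2L, in_scale, "/") * .amplify_grad(gf$Xraw)
    dS <- tcrossprod(dXraw, M)
    dO <- gain * softmax_backward(gf$S, dS)
    bk_g <- mlp_backward(gen, gf$fw, dO)
    up <- rmsprop_step(gen, bk_g, st_g, lr_it,
                       config$rmsprop_rho, config$rmsprop_eps,
                       config$generator_momentum)
    gen <- up$net; st_g <- up$state

    gen_loss[it] <- gl
    crit_w[it] <- hc_w[ci]
    cur_par <- params_flatten(gen, cri)
    weight_mse[it] <- mean((cur_par - prev_par)^2)
    prev_par <- cur_par

    ## model selection by generated-vs-real energy distance
    if (config$checkpoint_every > 0 && it %% config$checkpoint_every == 0) {
      zs <- matrix(stats::rnorm(128L * config$noise_dim), 128L,
                   config$noise_dim)
      Xs <- gen_forward(zs)$X
      ridx <- sample.int(n, min(n, 256L))
      ed <- .energy_distance(Xs, Xreal[ridx, , drop = FALSE])
      if (ed < best$value) best <- list(gen = gen, iteration = it, value = ed)
    }
    if (verbose && it %% 500 == 0)
      message(sprintf("iter %d  critic W %.4f  gen %.4f  gp %.4f  wMSE %.3g",
                      it, crit_w[it], gl, hc_gp[ci], weight_mse[it]))
  }

  history <- list(
    critic = data.frame(iteration = hc_it, step = hc_st, w_loss = hc_w,
                        gp = hc_gp, total = hc_w + config$gp_weight * hc_gp),
    generator = data.frame(iteration = seq_len(iters), loss = gen_loss,
                           critic_w = crit_w),
    weight_mse = weight_mse)
  cs <- convergence_stats(history, window = config$convergence_window)
  selected <- if (is.finite(best$value)) best else
    list(gen = gen, iteration = iters, value = NA_real_)
  structure(
    list(generator = selected$gen, critic = cri, final_generator = gen,
         config = config, node_ids = node_ids,
         input_center = in_center, input_scale = in_scale,
         taxon_ids = colnames(real$values), rank_level = real$rank_level,
         M = M, history = history, converged_at = cs$converged_at,
         selection = selected[c("iteration", "value")]),
    class = "gan_model")
}

#' @export
print.gan_model <- function(x, ...) {
  cat(sprintf(paste0("<gan_model> %d taxa, %d critic-input nodes, ",
                     "%d iterations trained\n"),
              length(x$taxon_ids), length(x$node_ids),
              nrow(x$history$generator)))
  cat(sprintf("  selected checkpoint: iteration %d; converged at: %s\n",
              x$selection$iteration,
              if (is.na(x$converged_at)) "not reached" else x$converged_at))
  invisible(x)
}

#' Generate compositions from a (trained) model and explicit noise
#'
#' Each output row is a species-level composition: nonnegative with
#' row sum 1 before truncation.  Entries below the truncation
#' threshold are then set to zero and the row is *not* renormalized;
#' the broken closure is recorded in the returned table.
#'
#' @param model a `gan_model` from [mbgan_train()].
#' @param z noise matrix (batch x noise_dim) of standard-normal draws.
#' @param truncate apply the truncation threshold (default TRUE).
#' @return an [abundance_table()].
#' @export
gan_generate <- function(model, z, truncate = TRUE) {
  stopifnot(inherits(model, "gan_model"))
  if (ncol(z) != model$config$noise_dim)
    stop("noise width ", ncol(z), " does not match noise_dim ",
         model$config$noise_dim)
  gain <- if (is.null(model$config$softmax_gain)) 1 else model$config$softmax_gain
  S <- softmax_rows(gain * mlp_forward(model$generator, z)$out)
  colnames(S) <- model$taxon_ids
  rownames(S) <- paste0("sim_", seq_len(nrow(S)))
  truncated <- FALSE
  if (truncate) {
    thr <- model$config$truncation_threshold
    truncated <- any(S > 0 & S < thr)
    S[S < thr] <- 0
  }
  abundance_table(S, rank_level = model$rank_level,
                  normalized = !truncated, normalization = "none")
}

#' Simulate samples from a trained model
#'
#' @param model a `gan_model`.
#' @param n_samples number of samples to draw.
#' @param seed seed for the noise draws.
#' @param truncate apply the truncation threshold.
#' @return an [abundance_table()] with `n_samples` rows.
#' @export
gan_simulate <- function(model, n_samples, seed = 1, truncate = TRUE) {
  if (n_samples <= 0) stop("n_samples must be positive")
  set.seed(seed)
  z <- matrix(stats::rnorm(n_samples * model$config$noise_dim),
              n_samples, model$config$noise_dim)
  gan_generate(model, z, truncate = truncate)
}

#' Score a batch of transformed samples with the critic
#'
#' @param model a `gan_model` (or any list with a `critic` network and
#'   `node_ids`).
#' @param batch an `expanded_matrix` from [critic_input()], or a plain
#'   matrix whose columns follow the model's node order.
#' @return one unconstrained real score per sample.
#' @export
critic_score <- function(model, batch) {
  X <- if (inherits(batch, "expanded_matrix")) batch$values else as.matrix(batch)
  if (ncol(X) != length(model$node_ids))
    stop("batch width ", ncol(X), " does not match the ",
         length(model$node_ids), " critic-input nodes")
  if (!is.null(model$input_center))
    X <- sweep(sweep(X, 2L, model$input_center), 2L, model$input_scale, "/")
  drop(mlp_forward(model$critic, X)$out)
}

#' Gradient penalty of the critic at real/fake interpolates
#'
#' Draws one epsilon ~ Uniform(0, 1) per sample, forms the interpolates
#' `eps * real + (1 - eps) * fake` in critic-input space, and returns
#' the mean of `(||grad_x f(x)|| - 1)^2`.
#'
#' @param model a `gan_model`, or a bare critic network (`mlp`).
#' @param real_batch,fake_batch matrices (or `expanded_matrix`) of equal
#'   shape in critic-input space.
#' @param eps optional explicit interpolation weights (length = batch).
#' @return the scalar penalty.
#' @export
gradient_penalty <- function(model, real_batch, fake_batch, eps = NULL) {
  net <- if (inherits(model, "mlp")) model else model$critic
  Xr <- if (inherits(real_batch, "expanded_matrix")) real_batch$values else as.matrix(real_batch)
  Xf <- if (inherits(fake_batch, "expanded_matrix")) fake_batch$values else as.matrix(fake_batch)
  stopifnot(all(dim(Xr) == dim(Xf)))
  if (is.null(eps)) eps <- stats::runif(nrow(Xr))
  Xhat <- eps * Xr + (1 - eps) * Xf
  out <- gp_penalty_grads(net, Xhat, want_grads = FALSE)
  if (!is.finite(out$penalty)) stop("non-finite gradient penalty")
  out$penalty
}

#' Convergence statistics of a training history
#'
#' Two monitors: (1) the combined Wasserstein statistic, the sum of
#' generator and critic Wasserstein losses per iteration, and (2) the
#' mean over parameters of the squared change between consecutive
#' iterations.  Training is flagged converged at the first iteration
#' where the difference of the windowed means of monitor (2) across
#' two consecutive windows falls below `tol`.
#'
#' @param history a `gan_model` or its `history` component.
#' @param window window length in iterations (default 1000).
#' @param tol convergence tolerance on the windowed-mean difference
#'   (default 1e-8).
#' @return list with `combined_wasserstein` (per-iteration series),
#'   `weight_mse` (per-iteration series), `converged` flag,
#'   `converged_at` iteration (`NA` when not reached) and
#'   `assessable` (FALSE when the history is shorter than two windows).
#' @export
convergence_stats <- function(history, window = 1000, tol = 1e-8) {
  h <- if (inherits(history, "gan_model")) history$history else history
  it <- length(h$weight_mse)
  combined <- h$generator$loss + h$generator$critic_w
  if (it < 2 * window)
    return(list(combined_wasserstein = combined, weight_mse = h$weight_mse,
                converged = FALSE, converged_at = NA_integer_,
                assessable = FALSE))
  cm <- cumsum(h$weight_mse)
  wmean <- (cm[window:it] - c(0, cm[seq_len(it - window)])) / window
  ## wmean[k] = mean over iterations (k .. k+window-1), k = 1 .. it-window+1
  nw <- length(wmean) - window
  converged_at <- NA_integer_
  if (nw >= 1) {
    dif <- abs(wmean[window + seq_len(nw)] - wmean[seq_len(nw)])
    hit <- which(dif < tol)
    if (length(hit)) converged_at <- hit[1] + 2L * window - 1L
  }
  list(combined_wasserstein = combined, weight_mse = h$weight_mse,
       converged = !is.na(converged_at), converged_at = converged_at,
       assessable = TRUE)
}

#' Save / load a trained model
#'
#' The checkpoint is a self-describing list (config, generator and
#' critic parameters, node/taxon order, history) written with
#' [saveRDS()].
#'
#' @param model a `gan_model`.
#' @param path checkpoint file.
#' @export
save_gan_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_gan_model
#' @export
load_gan_model <- function(path) {
  structure(readRDS(path), class = "gan_model")
}
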