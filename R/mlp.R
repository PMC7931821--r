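## Dense feed-forward networks with explicit forward/backward passes.
## This is the package's training engine for the Wasserstein critic and
## the generator: plain matrices and BLAS, no external framework.
##
## A network is a list(W = list of d_in x d_out matrices,
##                     b = list of length-d_out vectors,
##                     act = "relu")
## with a linear output layer.  All hidden activations are ReLU, which
## makes the second derivative of the activation zero almost
## everywhere; the gradient-penalty double-backward below relies on
## this to be exact.

#' Initialize a dense network
#'
#' He-initialized weights, zero biases, ReLU hidden layers, linear
#' output.  Used for both the generator (whose softmax head is applied
#' by the caller) and the critic (scalar output).
#'
#' @param dims integer vector of layer widths, input first, output last.
#' @param act hidden activation: `"relu"` or `"lrelu"` (leaky ReLU,
#'   negative slope 0.2, the usual choice for Wasserstein critics).
#' @return a network object (list of weight matrices and bias vectors).
#' @export
mlp_init <- function(dims, act = c("relu", "lrelu")) {
  act <- match.arg(act)
  stopifnot(length(dims) >= 2)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  structure(list(W = W, b = b, act = act, dims = dims), class = "mlp")
}

.act_slope <- function(net) if (identical(net$act, "lrelu")) 0.2 else 0

## derivative mask of the hidden activation at pre-activation z
.act_dmask <- function(net, z) {
  a <- .act_slope(net)
  (z > 0) + a * (z <= 0)
}

## forward pass; cache pre-activations for backprop
mlp_forward <- function(net, X, cache = FALSE) {
  L <- length(net$W)
  slope <- .act_slope(net)
  Z <- if (cache) vector("list", L) else NULL
  A <- if (cache) vector("list", L + 1L) else NULL
  a <- X
  if (cache) A[[1L]] <- a
  for (l in seq_len(L)) {
    z <- a %*% net$W[[l]]
    z <- sweep(z, 2L, net$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) + slope * pmin(z, 0) else z
    if (cache) { Z[[l]] <- z; A[[l + 1L]] <- a }
  }
  if (cache) list(out = a, Z = Z, A = A) else list(out = a)
}

## backward pass: gradient of sum(dOut * out) w.r.t. parameters and input
mlp_backward <- function(net, fw, dOut) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  d <- dOut
  for (l in rev(seq_len(L))) {
    if (l < L) d <- d * .act_dmask(net, fw$Z[[l]])
    dW[[l]] <- crossprod(fw$A[[l]], d)
    db[[l]] <- colSums(d)
    d <- tcrossprod(d, net$W[[l]])
  }
  list(dW = dW, db = db, dX = d)
}

## gradient of the scalar-output network w.r.t. its input, per sample,
## returning also the per-layer backward signals s_l needed by the
## gradient-penalty double-backward.  s_L = 1; s_{l-1} = (s_l W_l') o relu'(z_{l-1}).
mlp_input_grad <- function(net, fw) {
  L <- length(net$W)
  stopifnot(ncol(fw$out) == 1L)
  s <- vector("list", L)
  s[[L]] <- matrix(1, nrow(fw$out), 1L)
  g <- s[[L]]
  for (l in rev(seq_len(L))) {
    g <- tcrossprod(g, net$W[[l]])
    if (l > 1L) {
      g <- g * .act_dmask(net, fw$Z[[l - 1L]])
      s[[l - 1L]] <- g
    }
  }
  list(G = g, s = s)
}

## Gradient penalty and its parameter gradients at interpolates Xhat.
## penalty = mean_i (||grad_x f(x_i)|| - 1)^2.
## With ReLU activations the activation pattern carries no parameter
## gradient (relu'' = 0 a.e.), so the input-gradient chain
##   G = s_L W_L' -> o relu' -> ... -> W_1'
## is linear in each W_l given the pattern, and the exact parameter
## gradient of the penalty is obtained by reverse-mode over that chain.
## (Holds for leaky ReLU too: its second derivative is also 0 a.e.)
## Biases do not enter the chain and receive no penalty gradient.
gp_penalty_grads <- function(net, Xhat, want_grads = TRUE) {
  B <- nrow(Xhat)
  fw <- mlp_forward(net, Xhat, cache = TRUE)
  ig <- mlp_input_grad(net, fw)
  nrm <- sqrt(rowSums(ig$G^2))
  penalty <- mean((nrm - 1)^2)
  if (!want_grads)
    return(list(penalty = penalty, grad_norms = nrm))
  L <- length(net$W)
  ## dP/dG, guarding the non-differentiable point ||G|| = 0
  safe <- pmax(nrm, 1e-12)
  U <- ig$G * (2 * (nrm - 1) / (safe * B))
  dW <- vector("list", L)
  ## reverse the backward chain: U_l = dP/dG_l where G_l is the signal
  ## entering layer l's transpose-multiply; at layer l the chain does
  ## G_{l-1} = s_l W_l', then s_{l-1} = G_{l-1} o relu'(z_{l-1}).
  Ucur <- U # dP/dG_0 (input space)
  for (l in seq_len(L)) {
    dW[[l]] <- crossprod(Ucur, ig$s[[l]])  # t(U_{l-1}) %*% s_l : d_{l-1} x d_l
    if (l < L) Ucur <- (Ucur %*% net$W[[l]]) * .act_dmask(net, fw$Z[[l]])
  }
  db <- lapply(net$b, function(bb) numeric(length(bb)))
  list(penalty = penalty, grad_norms = nrm, dW = dW, db = db)
}

## ---- RMSprop ---------------------------------------------------------

rmsprop_state <- function(net) {
  z <- lapply(net$W, function(m) m * 0)
  zb <- lapply(net$b, function(v) v * 0)
  list(W = z, b = zb, mW = z, mb = zb)
}

rmsprop_step <- function(net, grads, state, lr, rho = 0.9, eps = 1e-8,
                         momentum = 0) {
  for (l in seq_along(net$W)) {
    state$W[[l]] <- rho * state$W[[l]] + (1 - rho) * grads$dW[[l]]^2
    state$mW[[l]] <- momentum * state$mW[[l]] +
      grads$dW[[l]] / (sqrt(state$W[[l]]) + eps)
    net$W[[l]] <- net$W[[l]] - lr * state$mW[[l]]
    state$b[[l]] <- rho * state$b[[l]] + (1 - rho) * grads$db[[l]]^2
    state$mb[[l]] <- momentum * state$mb[[l]] +
      grads$db[[l]] / (sqrt(state$b[[l]]) + eps)
    net$b[[l]] <- net$b[[l]] - lr * state$mb[[l]]
  }
  list(net = net, state = state)
}

## flatten all parameters of one or more networks into a single vector
params_flatten <- function(...) {
  nets <- list(...)
  unlist(lapply(nets, function(n) c(unlist(n$W), unlist(n$b))), use.names = FALSE)
}

## row-wise softmax
softmax_rows <- function(X) {
  m <- apply(X, 1L, max)
  E <- exp(X - m)
  E / rowSums(E)
}

## backward through row-wise softmax: given S = softmax(O) and dL/dS,
## dL/dO = S o (dS - rowSums(dS o S))
softmax_backward <- function(S, dS) {
  S * (dS - rowSums(dS * S))
}

add_grads <- function(g1, g2, w = 1) {
  list(dW = Map(function(a, b) a + w * b, g1$dW, g2$dW),
       db = Map(function(a, b) a + w * b, g1$db, g2$db))
}
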