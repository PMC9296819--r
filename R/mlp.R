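#' Multilayer perceptron primitives
#'
#' The decoder is a fully connected network `input -> 128 -> 64 -> 2` with
#' ReLU hidden activations and a softmax cross-entropy loss. These primitives
#' are deliberately exposed: the meta-gradient contract of
#' [meta_gradient_step()] is checked against finite differences built from
#' them alone.
#'
#' @param input_size Number of input features.
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param n_classes Number of output classes (2 for binary decoding).
#' @param seed Integer seed for the initialization.
#' @return An object of class `mlp_model`: list with `W` (list of weight
#'   matrices, `d_in x d_out`) and `b` (list of bias vectors). Weights are
#'   drawn uniformly on `+/- 1/sqrt(d_in)` (fan-in scaling), biases are zero.
#' @export
mlp_init <- function(input_size, hidden_sizes = c(128L, 64L), n_classes = 2L,
                     seed = 1L) {
  sizes <- c(as.integer(input_size), as.integer(hidden_sizes),
             as.integer(n_classes))
  stopifnot(all(sizes >= 1L))
  L <- length(sizes) - 1L
  withr::with_seed(as.integer(seed), {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      r <- 1 / sqrt(sizes[l])
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -r, r),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
  })
  structure(list(W = W, b = b, sizes = sizes), class = "mlp_model")
}

# Forward pass keeping intermediate activations for backprop.
# Returns list(A = list(A0=X, A1, ..), Z = list(preactivations), scores).
mlp_forward <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$sizes[1L])
    stop(sprintf("feature width %d does not match model input size %d",
                 ncol(X), model$sizes[1L]))
  L <- length(model$W)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% model$W[[l]], 2L, model$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) pmax(Z[[l]], 0) else Z[[l]]
  }
  list(A = A, Z = Z, scores = A[[L + 1L]])
}

# Row-wise log-softmax (numerically stable) and per-sample cross entropy.
softmax_probs <- function(scores) {
  m <- apply(scores, 1L, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

per_sample_ce <- function(scores, y) {
  m <- apply(scores, 1L, max)
  lse <- m + log(rowSums(exp(scores - m)))
  lse - scores[cbind(seq_len(nrow(scores)), y + 1L)]
}

# Per-sample output deltas of the *unweighted* per-sample cross entropy
# (d CE_i / d scores_i = p_i - onehot_i), plus backpropagated hidden deltas.
mlp_deltas <- function(model, fw, y) {
  L <- length(model$W)
  n <- nrow(fw$scores)
  P <- softmax_probs(fw$scores)
  dZ <- vector("list", L)
  D <- P
  D[cbind(seq_len(n), y + 1L)] <- D[cbind(seq_len(n), y + 1L)] - 1
  dZ[[L]] <- D
  for (l in rev(seq_len(L - 1L)))
    dZ[[l]] <- (dZ[[l + 1L]] %*% t(model$W[[l + 1L]])) * (fw$Z[[l]] > 0)
  dZ
}

# Parameter gradients of sum_i w_i * CE_i given per-sample deltas.
mlp_param_grads <- function(model, fw, dZ, w) {
  L <- length(model$W)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in seq_len(L)) {
    Dw <- dZ[[l]] * w
    gW[[l]] <- crossprod(fw$A[[l]], Dw)
    gb[[l]] <- colSums(Dw)
  }
  list(W = gW, b = gb)
}

#' Loss and gradient of a weighted cross-entropy objective
#'
#' Computes `sum_i w_i * CE(y_i, model(x_i))` and its gradient with respect to
#' every parameter. With `weights = rep(1/n, n)` this is the mean loss used
#' for validation; with a one-hot weight vector it isolates one sample's
#' gradient.
#'
#' @param model An [mlp_init()] model.
#' @param X Feature matrix (rows are samples).
#' @param y Integer 0-based class labels.
#' @param weights Per-sample loss weights (default all ones).
#' @return List with `loss` (scalar), `ce` (per-sample cross entropies) and
#'   `grads` (list of `W`/`b` gradients shaped like the model).
#' @export
mlp_loss_grad <- function(model, X, y, weights = NULL) {
  X <- as.matrix(X); y <- as.integer(y)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  stopifnot(length(y) == nrow(X), length(weights) == nrow(X))
  fw <- mlp_forward(model, X)
  ce <- per_sample_ce(fw$scores, y)
  dZ <- mlp_deltas(model, fw, y)
  g <- mlp_param_grads(model, fw, dZ, weights)
  if (!all(vapply(g$W, function(m) all(is.finite(m)), logical(1))))
    stop("non-finite gradient encountered")
  list(loss = sum(weights * ce), ce = ce, grads = g)
}

#' One plain gradient-descent step
#'
#' Returns the model with parameters `theta - step_size * grads`; this is the
#' inner update through which the meta-gradient differentiates.
#'
#' @param model An [mlp_init()] model.
#' @param grads Gradient list as returned in `mlp_loss_grad()$grads`.
#' @param step_size Positive step size.
#' @return The updated `mlp_model`.
#' @export
mlp_step <- function(model, grads, step_size) {
  for (l in seq_along(model$W)) {
    model$W[[l]] <- model$W[[l]] - step_size * grads$W[[l]]
    model$b[[l]] <- model$b[[l]] - step_size * grads$b[[l]]
  }
  model
}

#' Class scores and predicted labels
#'
#' @param model An [mlp_init()] model (or a fitted object's `$model`).
#' @param features Feature matrix with one row per sample.
#' @return List with `scores` (n x n_classes) and `labels` (0-based predicted
#'   class; the larger score wins, ties break toward class 0).
#' @export
forward_predict <- function(model, features) {
  fw <- mlp_forward(model, as.matrix(features))
  labels <- as.integer(fw$scores[, 2L] > fw$scores[, 1L])
  list(scores = fw$scores, labels = labels)
}

#' Epsilon-weighted training loss
#'
#' The perturbed objective `sum_i eps_i * CE_i` whose gradient at `eps = 0`
#' defines the meta-gradient: zero at `eps = 0`, and a single-sample cross
#' entropy when `eps` selects one sample.
#'
#' @inheritParams mlp_loss_grad
#' @param eps Per-sample perturbation weights (length = batch size).
#' @return Scalar loss value.
#' @export
epsilon_weighted_loss <- function(model, X, y, eps) {
  X <- as.matrix(X)
  stopifnot(length(eps) == nrow(X))
  fw <- mlp_forward(model, X)
  v <- sum(eps * per_sample_ce(fw$scores, as.integer(y)))
  if (!is.finite(v)) stop("non-finite loss")
  v
}

# ---- Adam optimizer ------------------------------------------------------

adam_init <- function(model) {
  zeros <- function(p) lapply(p, function(x) x * 0)
  list(mW = zeros(model$W), vW = zeros(model$W),
       mb = zeros(model$b), vb = zeros(model$b), t = 0L)
}

adam_update <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (l in seq_along(model$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    model$W[[l]] <- model$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    model$b[[l]] <- model$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(model = model, state = state)
}
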