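# Independent oracles and small fixtures shared across test files.

# Central finite differences of the mean validation loss with respect to the
# per-sample perturbation eps_i, taken through an explicit one-step inner
# update built from the inner-step primitives; independent of the
# meta_gradient_step implementation path. The validation loss is only
# piecewise smooth in eps (hidden ReLUs), so each component carries a
# `smooth` flag: FALSE when a hidden preactivation of the validation batch
# changes sign inside the difference interval, where the derivative does not
# exist and the comparison is meaningless.
fd_meta_gradient <- function(model, X, y, Xv, yv, alpha, h = 1e-4) {
  m <- nrow(Xv)
  inner <- function(i, ei) {
    eps <- rep(0, nrow(X)); eps[i] <- ei
    mlp_step(model, mlp_loss_grad(model, X, y, weights = eps)$grads, alpha)
  }
  res <- vapply(seq_len(nrow(X)), function(i) {
    tp <- inner(i, h); tm <- inner(i, -h)
    zp <- metadecode:::mlp_forward(tp, Xv)$Z
    zm <- metadecode:::mlp_forward(tm, Xv)$Z
    L <- length(zp)
    smooth <- all(mapply(function(a, b) all((a > 0) == (b > 0)),
                         zp[-L], zm[-L]))
    fd <- -(epsilon_weighted_loss(tp, Xv, yv, rep(1 / m, m)) -
              epsilon_weighted_loss(tm, Xv, yv, rep(1 / m, m))) / (2 * h)
    c(fd, smooth)
  }, numeric(2))
  list(fd = res[1, ], smooth = res[2, ] > 0)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# assignments of the pooled (untied) values to the two groups.
wilcox_exact_enum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# Linearly separable 2-D two-class task with optional label flips.
toy_task <- function(n, flip = 0, seed = 1) {
  withr::with_seed(seed, {
    y <- rep_len(c(0L, 1L), n)
    X <- matrix(rnorm(2 * n, sd = 0.6), n, 2) + 1.6 * cbind(y, y) - 0.8
    noisy <- y
    mask <- NULL
    if (flip > 0) {
      k <- round(flip * n)
      idx <- sample.int(n, k)
      noisy[idx] <- 1L - noisy[idx]
      mask <- noisy != y
    }
  })
  labeled_dataset(X, noisy, clean_labels = y, mislabel_mask = mask)
}

# Small, fast simulator settings for structural tests.
small_sim <- function(...) {
  simulator_params(n_group_a = 10L, n_group_b = 10L, trial_duration = 200,
                   activity_normalizer = 60, ...)
}

fast_config <- function(steps = 300L, ...) {
  trainer_config(hidden_sizes = c(16L, 8L), steps = steps,
                 patience = max(1L, steps), ...)
}
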