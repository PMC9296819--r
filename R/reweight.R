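#' Trainer configuration
#'
#' Settings shared by the reweighted and plain trainers. The reweighting
#' update takes one inner gradient-descent step of size `alpha` on the
#' epsilon-perturbed batch loss and differentiates the validation loss through
#' it; the outer update is Adam. The training batch size always equals the
#' validation sample size (`m`), so each step's validation "mini-batch" is the
#' full validation set.
#'
#' @param hidden_sizes Hidden-layer widths (default `c(128, 64)`).
#' @param learning_rate Outer Adam learning rate.
#' @param alpha Inner gradient-descent step size; defaults to
#'   `learning_rate`.
#' @param eta Meta learning rate of the raw weights. It is cancelled exactly
#'   by the weight normalization, so it only scales the reported `mu`; kept
#'   for documentation and fixed at 1.
#' @param steps Total optimisation-step budget `T`. Counting in steps rather
#'   than passes keeps the amount of optimisation comparable across training
#'   and validation sizes (the batch size equals the validation size, so a
#'   pass contains fewer steps when either grows); the default corresponds to
#'   about 100 passes over a 600-sample training set at batch size 20.
#'   Training can end earlier via `patience`.
#' @param batch_size Training mini-batch size `n`. For reweighted training
#'   this must equal (and defaults to) the validation size `m`; for plain
#'   training it defaults to `min(20, n_samples)`.
#' @param patience Early-stopping allowance in optimisation steps: training
#'   stops once this many consecutive steps pass without the epoch-mean
#'   weighted (or plain) loss improving by at least `min_delta`. The default
#'   corresponds to 50 passes of the reference 600-sample, batch-20 study.
#' @param min_delta Minimal loss improvement counted as progress.
#' @param weight_aggregation How a per-sample aggregate weight is summarised
#'   from the trace: mean over the final epoch's steps (`"final_epoch"`,
#'   default) or the last recorded step per sample (`"last_step"`).
#' @param model_selection Which parameters the reweighted fit returns:
#'   `"best_val"` (default) restores the checkpoint with the lowest
#'   epoch-mean validation loss — the validation set already steers every
#'   update, so it also picks the reported model — or `"final"` for the
#'   parameters at the last step. Plain (baseline) training always returns
#'   the final parameters.
#' @param seed Integer seed covering initialization and batch order.
#' @return An object of class `trainer_config`.
#' @export
trainer_config <- function(hidden_sizes = c(128L, 64L), learning_rate = 1e-3,
                           alpha = NULL, eta = 1, steps = 3000L,
                           batch_size = NULL,
                           patience = 1500L, min_delta = 1e-3,
                           weight_aggregation = c("final_epoch", "last_step"),
                           model_selection = c("best_val", "final"),
                           seed = 1L) {
  if (is.null(alpha)) alpha <- learning_rate
  stopifnot(learning_rate > 0, alpha >= 0, steps >= 0, patience >= 1)
  structure(
    list(hidden_sizes = as.integer(hidden_sizes),
         learning_rate = learning_rate, alpha = alpha, eta = eta,
         steps = as.integer(steps),
         batch_size = if (!is.null(batch_size)) as.integer(batch_size),
         patience = as.integer(patience), min_delta = min_delta,
         weight_aggregation = match.arg(weight_aggregation),
         model_selection = match.arg(model_selection),
         seed = as.integer(seed)),
    class = "trainer_config"
  )
}

as_xy <- function(data) {
  if (inherits(data, "labeled_dataset"))
    list(X = data$features, y = data$labels)
  else if (is.list(data) && !is.null(data$features))
    list(X = as.matrix(data$features), y = as.integer(data$labels))
  else if (is.list(data) && !is.null(data$X))
    list(X = as.matrix(data$X), y = as.integer(data$y))
  else stop("expected a labeled_dataset or a list(features, labels)")
}

#' Rectify and normalize raw meta-gradient weights
#'
#' Negative raw weights are clipped to zero and the rest are scaled to sum to
#' one. When every raw weight is non-positive the zero denominator is guarded
#' (a one is added to it), so the degenerate all-zero weight vector is
#' returned instead of a division failure. Scaling `mu` by any positive
#' constant (e.g. the meta learning rate) leaves the result unchanged.
#'
#' @param mu Numeric vector of raw per-sample weights.
#' @return List with `rectified` (`max(mu, 0)`) and `normalized` (sums to 1,
#'   or all zeros).
#' @export
#' @examples
#' rectify_and_normalize(c(1, 3))$normalized    # 0.25 0.75
#' rectify_and_normalize(c(-1, -2))$normalized  # 0 0
rectify_and_normalize <- function(mu) {
  stopifnot(all(is.finite(mu)))
  rectified <- pmax(mu, 0)
  s <- sum(rectified)
  list(rectified = rectified,
       normalized = rectified / (s + as.numeric(s == 0)))
}

#' One meta-gradient reweighting step
#'
#' Computes the raw weight `mu_i` of every sample in the training batch: the
#' negative derivative of the mean validation loss, taken after a single
#' inner gradient-descent step of size `alpha` on the epsilon-perturbed batch
#' loss, with respect to that sample's perturbation at `eps = 0`. Because the
#' inner step is linear in `eps`, this equals the inner product of the
#' sample's loss gradient with the validation loss gradient, scaled by
#' `alpha` (and the meta rate `eta`, fixed at 1): samples whose gradients
#' point the way the clean validation set wants get positive weight.
#'
#' @param model Current [mlp_init()] model.
#' @param train_batch,val_batch [labeled_dataset()]s or
#'   `list(features, labels)`.
#' @param config A [trainer_config()] (supplies `alpha` and `eta`).
#' @param sample_ids Optional ids of the batch rows in the full training set.
#' @param step Optional step index for bookkeeping.
#' @return An object of class `weight_record`: list with `step`,
#'   `sample_ids`, `mu`, `rectified` and `normalized` (see
#'   [rectify_and_normalize()]).
#' @export
meta_gradient_step <- function(model, train_batch, val_batch, config,
                               sample_ids = NULL, step = NA_integer_) {
  tr <- as_xy(train_batch); va <- as_xy(val_batch)
  if (nrow(tr$X) == 0L || nrow(va$X) == 0L) stop("empty batch")
  m <- nrow(va$X)
  gv <- mlp_loss_grad(model, va$X, va$y, weights = rep(1 / m, m))$grads
  fw <- mlp_forward(model, tr$X)
  dZ <- mlp_deltas(model, fw, tr$y)
  mu <- numeric(nrow(tr$X))
  for (l in seq_along(model$W)) {
    mu <- mu + rowSums((dZ[[l]] %*% t(gv$W[[l]])) * fw$A[[l]]) +
      drop(dZ[[l]] %*% gv$b[[l]])
  }
  mu <- config$eta * config$alpha * mu
  if (!all(is.finite(mu)))
    stop(sprintf("non-finite meta-gradient at step %s", step))
  w <- rectify_and_normalize(mu)
  structure(list(step = step,
                 sample_ids = if (is.null(sample_ids)) seq_along(mu)
                              else sample_ids,
                 mu = mu, rectified = w$rectified,
                 normalized = w$normalized),
            class = "weight_record")
}

# Epoch-shuffled batch index partition.
epoch_batches <- function(n, batch_size) {
  ord <- sample.int(n, n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Train a decoder with meta-learned sample weights
#'
#' The central fitting function. Each step draws a training mini-batch (the
#' epochs are shuffled partitions, so every sample appears once per epoch),
#' computes per-sample weights by a meta-gradient through a one-step inner
#' update against the clean validation set ([meta_gradient_step()]),
#' rectifies and normalizes them, and applies one Adam update on the
#' weighted cross entropy. Training stops after `config$steps` optimisation
#' steps or earlier, when the epoch-mean weighted loss stops improving for
#' `config$patience` consecutive epochs.
#'
#' @param train Noisy training data: a [labeled_dataset()].
#' @param val Small, (near-)clean validation data: a [labeled_dataset()].
#'   The batch size is set to its sample size.
#' @param config A [trainer_config()].
#' @return An object of class `reweight_fit`: list with `model`, `trace`
#'   (data.frame `step`, `epoch`, `sample_id`, `mu`, `omega`),
#'   `aggregate_weights` (per training sample), `loss` (per-step weighted
#'   training and validation loss), `mislabel_mask` (copied from `train` if
#'   present), `n_epochs_run`, `config` and the training data dimensions.
#'   Methods: [predict.reweight_fit()], `print`, `summary`, `coef`, `plot`,
#'   `residuals`.
#' @export
train_reweighted <- function(train, val, config = trainer_config()) {
  tr <- as_xy(train); va <- as_xy(val)
  n <- nrow(tr$X); m <- nrow(va$X)
  stopifnot(n >= 1L, m >= 1L)
  if (!is.null(config$batch_size) && config$batch_size != m)
    stop("the training batch size must equal the validation sample size")
  batch <- min(m, n)

  model <- mlp_init(ncol(tr$X), config$hidden_sizes, 2L,
                    seed = config$seed)
  opt <- adam_init(model)
  trace <- list(); losses <- list()
  step <- 0L; best <- Inf; stall <- 0L; epochs_run <- 0L
  best_val <- Inf; best_model <- model
  withr::with_seed(config$seed + 1L, {
    ep <- 0L
    while (step < config$steps) {
      ep <- ep + 1L
      batches <- epoch_batches(n, batch)
      ep_loss <- 0; ep_val <- 0; nb <- 0L
      for (bi in seq_along(batches)) {
        if (step >= config$steps) break
        ids <- batches[[bi]]
        step <- step + 1L
        wr <- meta_gradient_step(
          model, list(features = tr$X[ids, , drop = FALSE], labels = tr$y[ids]),
          va, config, sample_ids = ids, step = step)
        bl <- mlp_loss_grad(model, tr$X[ids, , drop = FALSE], tr$y[ids],
                            weights = wr$normalized)
        upd <- adam_update(model, bl$grads, opt, config$learning_rate)
        model <- upd$model; opt <- upd$state
        val_loss <- mean(per_sample_ce(mlp_forward(model, va$X)$scores, va$y))
        trace[[step]] <- data.frame(step = step, epoch = ep,
                                    sample_id = ids, mu = wr$mu,
                                    omega = wr$normalized)
        losses[[step]] <- data.frame(step = step, epoch = ep,
                                     weighted_loss = bl$loss,
                                     val_loss = val_loss)
        ep_loss <- ep_loss + bl$loss
        ep_val <- ep_val + val_loss
        nb <- nb + 1L
      }
      epochs_run <- ep
      if (nb == 0L) break
      ep_loss <- ep_loss / nb
      ep_val <- ep_val / nb
      if (!is.finite(ep_loss))
        stop(sprintf("training diverged at epoch %d (non-finite loss)", ep))
      if (ep_val < best_val) {
        best_val <- ep_val; best_model <- model
      }
      if (ep_loss < best - config$min_delta) {
        best <- ep_loss; stall <- 0L
      } else {
        stall <- stall + nb
        if (stall >= config$patience) break
      }
    }
  })
  if (config$model_selection == "best_val" && is.finite(best_val))
    model <- best_model
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), epoch = integer(), sample_id = integer(),
               mu = numeric(), omega = numeric())
  losses <- if (length(losses)) do.call(rbind, losses) else
    data.frame(step = integer(), epoch = integer(), weighted_loss = numeric(),
               val_loss = numeric())
  structure(
    list(model = model, trace = trace,
         aggregate_weights = aggregate_trace_weights(
           trace, n, epochs_run, config$weight_aggregation),
         loss = losses,
         mislabel_mask = if (inherits(train, "labeled_dataset"))
           train$mislabel_mask,
         n_train = n, n_val = m, n_epochs_run = epochs_run,
         config = config, call = match.call()),
    class = "reweight_fit"
  )
}

# Per-sample aggregate weight: mean omega over the final epoch (default) or
# the last step at which the sample appeared.
aggregate_trace_weights <- function(trace, n, final_epoch, how) {
  if (!nrow(trace)) return(NULL)
  agg <- numeric(n)
  if (how == "final_epoch") {
    # use the last epoch in which every sample appeared (the step cap can
    # truncate the final pass)
    if (sum(trace$epoch == final_epoch) < n && final_epoch > 1L)
      final_epoch <- final_epoch - 1L
    tr <- trace[trace$epoch == final_epoch, ]
    s <- tapply(tr$omega, tr$sample_id, mean)
  } else {
    tr <- trace[order(trace$step), ]
    s <- tapply(tr$omega, tr$sample_id, function(x) x[length(x)])
  }
  agg[as.integer(names(s))] <- as.numeric(s)
  agg
}

#' Plain mini-batch training (baselines)
#'
#' Standard cross-entropy training of the same architecture with Adam and no
#' sample reweighting. Baseline 1 trains on the merged training + validation
#' data ([mix_datasets()]); baseline 2 trains on the validation data alone.
#'
#' @param data A [labeled_dataset()].
#' @param config A [trainer_config()]; `batch_size` defaults to
#'   `min(20, n_samples)`.
#' @return An object of class `mlp_fit`: list with `model`, `loss` (per-step
#'   training loss), `n_epochs_run` and `config`. Methods: `predict`,
#'   `print`.
#' @export
train_plain <- function(data, config = trainer_config()) {
  d <- as_xy(data)
  n <- nrow(d$X)
  stopifnot(n >= 1L)
  batch <- min(if (is.null(config$batch_size)) 20L else config$batch_size, n)
  model <- mlp_init(ncol(d$X), config$hidden_sizes, 2L, seed = config$seed)
  opt <- adam_init(model)
  losses <- list(); step <- 0L; best <- Inf; stall <- 0L; epochs_run <- 0L
  withr::with_seed(config$seed + 1L, {
    ep <- 0L
    while (step < config$steps) {
      ep <- ep + 1L
      batches <- epoch_batches(n, batch)
      ep_loss <- 0; nb <- 0L
      for (ids in batches) {
        if (step >= config$steps) break
        step <- step + 1L
        bl <- mlp_loss_grad(model, d$X[ids, , drop = FALSE], d$y[ids],
                            weights = rep(1 / length(ids), length(ids)))
        upd <- adam_update(model, bl$grads, opt, config$learning_rate)
        model <- upd$model; opt <- upd$state
        losses[[step]] <- data.frame(step = step, epoch = ep, loss = bl$loss)
        ep_loss <- ep_loss + bl$loss
        nb <- nb + 1L
      }
      epochs_run <- ep
      if (nb == 0L) break
      ep_loss <- ep_loss / nb
      if (!is.finite(ep_loss))
        stop(sprintf("training diverged at epoch %d (non-finite loss)", ep))
      if (ep_loss < best - config$min_delta) {
        best <- ep_loss; stall <- 0L
      } else {
        stall <- stall + nb
        if (stall >= config$patience) break
      }
    }
  })
  structure(list(model = model,
                 loss = if (length(losses)) do.call(rbind, losses) else
                   data.frame(step = integer(), epoch = integer(),
                              loss = numeric()),
                 n_epochs_run = epochs_run, config = config,
                 call = match.call()),
            class = "mlp_fit")
}

# ---- S3 methods ----------------------------------------------------------

predict_features <- function(newdata) {
  if (inherits(newdata, "labeled_dataset")) newdata$features
  else if (inherits(newdata, "trial_matrix")) newdata$trajectories
  else as.matrix(newdata)
}

#' Predict from a reweighted (or plain) fit
#'
#' @param object A `reweight_fit` or `mlp_fit`.
#' @param newdata Feature matrix, [labeled_dataset()] or `trial_matrix`.
#' @param type `"class"` for 0/1 labels, `"scores"` for the class-score
#'   matrix, `"prob"` for softmax class probabilities.
#' @param ... Unused.
#' @return Labels, scores or probabilities.
#' @export
predict.reweight_fit <- function(object, newdata,
                                 type = c("class", "scores", "prob"), ...) {
  type <- match.arg(type)
  out <- forward_predict(object$model, predict_features(newdata))
  switch(type, class = out$labels, scores = out$scores,
         prob = softmax_probs(out$scores))
}

#' @rdname predict.reweight_fit
#' @export
predict.mlp_fit <- predict.reweight_fit

#' @export
print.reweight_fit <- function(x, ...) {
  cat(sprintf(
    "Sample-reweighted MLP decoder (%s)\n",
    paste(x$model$sizes, collapse = "-")))
  cat(sprintf("  %d training / %d validation samples, %d epoch(s) run\n",
              x$n_train, x$n_val, x$n_epochs_run))
  if (nrow(x$loss))
    cat(sprintf("  final weighted loss %.4f, validation loss %.4f\n",
                x$loss$weighted_loss[nrow(x$loss)],
                x$loss$val_loss[nrow(x$loss)]))
  invisible(x)
}

#' @export
summary.reweight_fit <- function(object, ...) {
  out <- list(fit = object,
              weight_summary = if (!is.null(object$aggregate_weights))
                summary(object$aggregate_weights),
              separation = if (!is.null(object$aggregate_weights) &&
                               !is.null(object$mislabel_mask) &&
                               any(object$mislabel_mask) &&
                               !all(object$mislabel_mask))
                weight_separation(object$aggregate_weights,
                                  object$mislabel_mask))
  class(out) <- "summary.reweight_fit"
  out
}

#' @export
print.summary.reweight_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$weight_summary)) {
    cat("Aggregate sample weights:\n")
    print(x$weight_summary)
  }
  if (!is.null(x$separation)) print(x$separation)
  invisible(x)
}

#' @export
coef.reweight_fit <- function(object, ...) object$model[c("W", "b")]

#' @export
coef.mlp_fit <- coef.reweight_fit

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf("Plain MLP decoder (%s), %d epoch(s) run\n",
              paste(x$model$sizes, collapse = "-"), x$n_epochs_run))
  invisible(x)
}

#' Diagnostic plots for a reweighted fit
#'
#' `type = "loss"` draws the weighted training and validation loss curves;
#' `type = "weights"` draws boxplots of the aggregate sample weights split by
#' mislabel status (requires the training data to have carried a mislabel
#' mask).
#'
#' @param x A `reweight_fit`.
#' @param type `"loss"` or `"weights"`.
#' @param ... Passed to the underlying base-graphics call.
#' @return Invisibly, `x`.
#' @export
plot.reweight_fit <- function(x, type = c("loss", "weights"), ...) {
  type <- match.arg(type)
  if (type == "loss") {
    graphics::plot(x$loss$step, x$loss$weighted_loss, type = "l",
                   xlab = "step", ylab = "loss",
                   ylim = range(c(x$loss$weighted_loss, x$loss$val_loss)),
                   ...)
    graphics::lines(x$loss$step, x$loss$val_loss, lty = 2)
    graphics::legend("topright", c("weighted training", "validation"),
                     lty = c(1, 2), bty = "n")
  } else {
    if (is.null(x$mislabel_mask) || is.null(x$aggregate_weights))
      stop("weight plot needs aggregate weights and a mislabel mask")
    graphics::boxplot(
      split(x$aggregate_weights,
            factor(x$mislabel_mask, c(FALSE, TRUE),
                   c("correct", "mislabeled"))),
      ylab = "aggregate sample weight", ...)
  }
  invisible(x)
}

#' @export
residuals.reweight_fit <- function(object, newdata, ...) {
  if (missing(newdata))
    stop("supply the data to compute residuals on (labels required)")
  d <- as_xy(newdata)
  p <- predict(object, d$X, type = "prob")[, 2L]
  d$y - p
}
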