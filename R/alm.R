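#' Trial-trajectory matrix
#'
#' Container for trial-based decoding data in the style of two-photon
#' calcium-imaging sessions: each row is one trial's ensemble-activity
#' trajectory over a fixed number of time points, with a binary trial-type
#' label and a session identifier.
#'
#' @param trajectories Numeric matrix, trials x timepoints.
#' @param labels 0/1 trial-type labels.
#' @param session Per-trial session identifiers.
#' @param meta Free-form provenance list.
#' @return An object of class `trial_matrix`.
#' @export
trial_matrix <- function(trajectories, labels, session, meta = list()) {
  trajectories <- as.matrix(trajectories)
  storage.mode(trajectories) <- "double"
  if (anyNA(trajectories)) stop("trajectories contain missing values")
  n <- nrow(trajectories)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels must have one entry per trial")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (length(session) != n) stop("session must have one entry per trial")
  structure(list(trajectories = trajectories, labels = labels,
                 session = as.character(session), meta = meta),
            class = "trial_matrix")
}

#' @export
print.trial_matrix <- function(x, ...) {
  cat(sprintf("Trial matrix: %d trials x %d timepoints, %d session(s)\n",
              nrow(x$trajectories), ncol(x$trajectories),
              length(unique(x$session))))
  invisible(x)
}

#' Synthetic trial-trajectory fixture
#'
#' Synthesizes a multi-session trial-trajectory dataset emulating the shape
#' of a single-subject calcium-imaging study: a configurable number of
#' sessions with 48-67 trials each, 91 time points per trial, and two
#' class-conditional smooth temporal templates that differ mainly in a late
#' "response-epoch" window. Trials are the session gain times the class
#' template plus AR(1) noise; labels are balanced within each session. This
#' is a synthetic stand-in: it reproduces the trials-by-timepoints geometry
#' and a learnable late-epoch class signal, not the statistics of real
#' recordings.
#'
#' @param n_sessions Number of sessions (default 18).
#' @param trials_range Inclusive range of per-session trial counts.
#' @param timepoints Time points per trial (default 91).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param noise_sd Marginal SD of the AR(1) trial noise.
#' @param ar_coef AR(1) coefficient of the noise.
#' @param session_gain_sd SD of the multiplicative per-session gain (mean 1).
#' @param class_separation Amplitude of the late-window template difference.
#' @return A [trial_matrix()].
#' @export
generate_alm_like_fixture <- function(n_sessions = 18L,
                                      trials_range = c(48L, 67L),
                                      timepoints = 91L, seed = 1L,
                                      noise_sd = 0.35, ar_coef = 0.7,
                                      session_gain_sd = 0.08,
                                      class_separation = 1.2) {
  stopifnot(n_sessions >= 1L, timepoints >= 2L,
            trials_range[1] >= 2L, trials_range[2] >= trials_range[1],
            abs(ar_coef) < 1)
  tgrid <- seq(0, 1, length.out = timepoints)
  base <- 0.5 * exp(-((tgrid - 0.35) / 0.2)^2)
  resp <- pmax(0, (tgrid - 0.65) / 0.35)^1.5
  templ <- rbind(base - 0.5 * class_separation * resp,
                 base + 0.5 * class_separation * resp)
  innov_sd <- noise_sd * sqrt(1 - ar_coef^2)
  withr::with_seed(as.integer(seed), {
    traj <- list(); labels <- integer(0); session <- character(0)
    for (s in seq_len(n_sessions)) {
      nt <- sample(seq.int(trials_range[1], trials_range[2]), 1L)
      gain <- max(0.2, 1 + stats::rnorm(1L, 0, session_gain_sd))
      y <- rep_len(c(0L, 1L), nt)
      noise <- matrix(0, nt, timepoints)
      if (noise_sd > 0) {
        e <- matrix(stats::rnorm(nt * timepoints, 0, innov_sd), nt)
        noise[, 1L] <- stats::rnorm(nt, 0, noise_sd)  # stationary start
        for (k in 2L:timepoints)
          noise[, k] <- ar_coef * noise[, k - 1L] + e[, k]
      }
      traj[[s]] <- gain * templ[y + 1L, , drop = FALSE] + noise
      labels <- c(labels, y)
      session <- c(session, rep(sprintf("session-%02d", s), nt))
    }
  })
  trial_matrix(do.call(rbind, traj), labels, session,
               meta = list(seed = as.integer(seed), noise_sd = noise_sd,
                           ar_coef = ar_coef,
                           session_gain_sd = session_gain_sd,
                           class_separation = class_separation,
                           source = "synthetic_alm_like_fixture"))
}

#' Read / write trial matrices
#'
#' Delimited-text layout: one row per trial with columns `t0..t<k-1>`,
#' `label`, `session`. The `rds` format is the binary array container
#' (R native serialization, bit-exact round trip).
#'
#' @param path File path.
#' @param format `"csv"` or `"rds"`.
#' @param tm A [trial_matrix()] (for writing).
#' @return `load_trial_matrix` returns a [trial_matrix()];
#'   `write_trial_matrix` returns `path` invisibly.
#' @export
load_trial_matrix <- function(path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    x <- readRDS(path)
    return(trial_matrix(x$trajectories, x$labels, x$session,
                        meta = if (is.null(x$meta)) list() else x$meta))
  }
  df <- utils::read.csv(path)
  tcols <- grep("^t[0-9]+$", names(df), value = TRUE)
  tcols <- tcols[order(as.integer(sub("^t", "", tcols)))]
  if (!length(tcols)) stop("no timepoint columns t0.. found")
  if (is.null(df$label)) stop("missing label column")
  if (anyNA(df[tcols])) stop("ragged or missing trajectory values")
  trial_matrix(as.matrix(df[tcols]), df$label,
               if (is.null(df$session)) rep("session-01", nrow(df))
               else df$session)
}

#' @rdname load_trial_matrix
#' @export
write_trial_matrix <- function(tm, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(unclass(tm), path)
    return(invisible(path))
  }
  df <- as.data.frame(tm$trajectories)
  names(df) <- paste0("t", seq_len(ncol(tm$trajectories)) - 1L)
  df$label <- tm$labels
  df$session <- tm$session
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Zero-mean normalization of trial trajectories
#'
#' Subtracts per-timepoint means. The means are computed on
#' `statistics_from` (typically the training split) and applied to `tm`, so
#' validation and test splits are shifted by the training statistics.
#'
#' @param tm A [trial_matrix()] to normalize.
#' @param statistics_from Optional [trial_matrix()] supplying the means;
#'   defaults to `tm` itself.
#' @return The normalized [trial_matrix()]; the means used are stored in
#'   `meta$feature_means`.
#' @export
zero_mean_normalize <- function(tm, statistics_from = NULL) {
  src <- if (is.null(statistics_from)) tm else statistics_from
  if (ncol(src$trajectories) != ncol(tm$trajectories))
    stop("timepoint counts differ between data and statistics source")
  mu <- colMeans(src$trajectories)
  tm$trajectories <- sweep(tm$trajectories, 2L, mu)
  tm$meta$feature_means <- mu
  tm
}

#' Convert a trial matrix to a labeled dataset
#'
#' @param tm A [trial_matrix()].
#' @return A [labeled_dataset()] whose features are the trajectories.
#' @export
as_labeled_dataset <- function(tm) {
  stopifnot(inherits(tm, "trial_matrix"))
  labeled_dataset(tm$trajectories, tm$labels, clean_labels = tm$labels,
                  meta = c(tm$meta, list(session = tm$session)))
}

#' Trial-trajectory decoding experiment with annotator-style label noise
#'
#' Splits the sessions into training, one clean validation session and two
#' clean test sessions, zero-mean normalizes everything with training-split
#' statistics, makes one copy of the training data per portion parameter
#' with shuffled labels, and compares the methods per noise level.
#'
#' @param plan An [experiment_plan()] (supplies portions, methods, trainer).
#' @param data A [trial_matrix()]; defaults expect several sessions.
#' @param val_session,test_sessions Session ids for the validation / test
#'   splits; by default the first session is validation and the next two are
#'   test (in sorted id order).
#' @return data.frame with one row per (portion, method): `portion`,
#'   `noise_level`, `method`, `f1`, `balanced_accuracy`, weight statistics
#'   for the reweighting rows, `status`.
#' @export
run_alm_like_experiment <- function(plan, data, val_session = NULL,
                                    test_sessions = NULL) {
  stopifnot(inherits(data, "trial_matrix"))
  ids <- sort(unique(data$session))
  if (length(ids) < 4L)
    stop("need at least 4 sessions (1 validation, 2 test, >=1 training)")
  if (is.null(val_session)) val_session <- ids[1L]
  if (is.null(test_sessions)) test_sessions <- setdiff(ids, val_session)[1:2]
  train_ids <- setdiff(ids, c(val_session, test_sessions))
  take <- function(keep) {
    k <- data$session %in% keep
    trial_matrix(data$trajectories[k, , drop = FALSE], data$labels[k],
                 data$session[k], meta = data$meta)
  }
  tr <- take(train_ids)
  va <- zero_mean_normalize(take(val_session), statistics_from = tr)
  te <- zero_mean_normalize(take(test_sessions), statistics_from = tr)
  tr <- zero_mean_normalize(tr)
  train0 <- as_labeled_dataset(tr)
  val <- shuffle_labels(as_labeled_dataset(va), 0, seed = plan$seed)
  test <- as_labeled_dataset(te)

  rows <- list()
  for (i in seq_along(plan$portions)) {
    noisy <- shuffle_labels(train0, plan$portions[i],
                            seed = plan$seed + 700L + i)
    cfg <- plan$trainer
    cfg$seed <- plan$trainer$seed + 10L * i
    for (method in plan$methods) {
      r <- fit_and_score(method, noisy, val, test, cfg)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(portion = plan$portions[i],
                         noise_level = realized_noise_level(noisy)), r)
    }
  }
  do.call(rbind, rows)
}
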