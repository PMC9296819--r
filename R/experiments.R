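#' Plan for the simulation experiments
#'
#' Bundles the study conditions: the portion parameters of the five
#' annotators, the validation-size grid, the resampling count, the methods to
#' compare, dataset sizes, simulator and trainer settings, and the master
#' seed from which every dataset seed is derived.
#'
#' @param portions Portion parameters of the training sets (annotators).
#' @param val_sizes Validation sample sizes for the size sweep.
#' @param n_resamples Validation resamples per size.
#' @param methods Subset of `"reweight"`, `"baseline1"` (train + validation
#'   merged, no reweighting), `"baseline2"` (validation only).
#' @param n_train,n_val_pool,n_test Dataset sizes.
#' @param val_size Validation subset size used by the noise sweep and the
#'   mixed experiment.
#' @param val_portion Shuffle portion applied to the validation pool (near
#'   clean; 0.10 for the simulated study).
#' @param mixtures List of integer vectors indexing `portions`; each defines
#'   one pooled training mixture. Default: the full pool of all levels.
#' @param sim_params A [simulator_params()] object.
#' @param trainer A [trainer_config()] object.
#' @param calibrate Whether to calibrate the simulator to
#'   `target_positive_fraction` before generating data.
#' @param target_positive_fraction,n_pilot Calibration target and pilot size.
#' @param seed Master seed for dataset generation.
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(portions = c(1, 0.8, 0.6, 0.4, 0.2),
                            val_sizes = c(20L, 40L, 60L, 80L, 100L),
                            n_resamples = 5L,
                            methods = c("reweight", "baseline1", "baseline2"),
                            n_train = 600L, n_val_pool = 600L, n_test = 600L,
                            val_size = 20L, val_portion = 0.10,
                            mixtures = NULL,
                            sim_params = simulator_params(),
                            trainer = trainer_config(),
                            calibrate = TRUE,
                            target_positive_fraction = 0.23,
                            n_pilot = 5000L,
                            seed = 1L) {
  stopifnot(all(portions >= 0 & portions <= 1), all(val_sizes >= 1L),
            n_resamples >= 1L,
            all(methods %in% c("reweight", "baseline1", "baseline2")))
  if (is.null(mixtures)) mixtures <- list(seq_along(portions))
  structure(list(portions = portions, val_sizes = as.integer(val_sizes),
                 n_resamples = as.integer(n_resamples), methods = methods,
                 n_train = as.integer(n_train),
                 n_val_pool = as.integer(n_val_pool),
                 n_test = as.integer(n_test),
                 val_size = as.integer(val_size), val_portion = val_portion,
                 mixtures = mixtures, sim_params = sim_params,
                 trainer = trainer, calibrate = calibrate,
                 target_positive_fraction = target_positive_fraction,
                 n_pilot = as.integer(n_pilot), seed = as.integer(seed)),
            class = "experiment_plan")
}

#' Generate the shared study datasets for a plan
#'
#' Calibrates the simulator (optionally), then generates one clean-labelled
#' training set per portion parameter and corrupts it, a near-clean
#' validation pool, and a clean test set, all with seeds derived from the
#' plan seed. Runners accept the result through their `study` argument so
#' several runs (e.g. different trainer seeds) can share the same datasets,
#' as when fixed annotated datasets are reanalysed under different training
#' randomisations.
#'
#' @param plan An [experiment_plan()].
#' @return List with `params` (calibrated simulator), `train_sets` (list of
#'   noisy [labeled_dataset()]s), `noise_levels`, `val_pool`, `test`.
#' @export
build_study_data <- function(plan) {
  params <- if (isTRUE(plan$calibrate))
    calibrate_simulator(plan$sim_params, plan$target_positive_fraction,
                        n_pilot = plan$n_pilot, seed = plan$seed)
  else plan$sim_params
  train_sets <- lapply(seq_along(plan$portions), function(i) {
    clean <- generate_dataset(params, plan$n_train,
                              seed = plan$seed + 100L + i)
    shuffle_labels(clean, plan$portions[i], seed = plan$seed + 200L + i)
  })
  val_pool <- shuffle_labels(
    generate_dataset(params, plan$n_val_pool, seed = plan$seed + 300L),
    plan$val_portion, seed = plan$seed + 301L)
  test <- generate_dataset(params, plan$n_test, seed = plan$seed + 400L)
  list(params = params, train_sets = train_sets,
       noise_levels = vapply(train_sets, realized_noise_level, numeric(1)),
       val_pool = val_pool, test = test)
}

#' Standardize features with training-split statistics
#'
#' Per-feature means and SDs are computed on the training split and applied
#' to every split, so validation and test data are shifted and scaled by the
#' training statistics. This is the documented preprocessing for the
#' firing-rate features (which span 0-130 Hz); the experiment runners apply
#' it automatically.
#'
#' @param train Training [labeled_dataset()] supplying the statistics.
#' @param ... Further datasets to transform with the same statistics.
#' @return List of transformed datasets, the training set first.
#' @export
standardize_features <- function(train, ...) {
  mu <- colMeans(train$features)
  sd <- pmax(apply(train$features, 2L, stats::sd), 1e-8)
  shift <- function(d) {
    d$features <- sweep(sweep(d$features, 2L, mu), 2L, sd, "/")
    d
  }
  c(list(shift(train)), lapply(list(...), shift))
}

# Fit one method and evaluate it on the test set; returns a one-row
# data.frame, with the error message in `status` if the cell fails.
fit_and_score <- function(method, train, val, test, config) {
  row <- data.frame(method = method, f1 = NA_real_,
                    balanced_accuracy = NA_real_,
                    mean_weight_correct = NA_real_,
                    mean_weight_mislabeled = NA_real_,
                    zero_weight_fraction_mislabeled = NA_real_,
                    wilcoxon_p = NA_real_, status = "ok",
                    stringsAsFactors = FALSE)
  tryCatch({
    if (method == "reweight") {
      fit <- train_reweighted(train, val, config)
      if (!is.null(train$mislabel_mask) && any(train$mislabel_mask) &&
          !all(train$mislabel_mask)) {
        ws <- weight_separation(fit$aggregate_weights, train$mislabel_mask)
        row$mean_weight_correct <- ws$mean_weight_correct
        row$mean_weight_mislabeled <- ws$mean_weight_mislabeled
        row$zero_weight_fraction_mislabeled <-
          ws$zero_weight_fraction_mislabeled
        row$wilcoxon_p <- ws$p_value
      }
    } else if (method == "baseline1") {
      fit <- train_plain(mix_datasets(list(train, val)), config)
    } else if (method == "baseline2") {
      fit <- train_plain(val, config)
    } else stop("unknown method: ", method)
    rep <- evaluate_model(fit, test)
    row$f1 <- rep$f1
    row$balanced_accuracy <- rep$balanced_accuracy
    row
  }, error = function(e) {
    row$status <- paste("failed:", conditionMessage(e))
    row
  })
}

# Class-balanced draw from the validation pool: half the samples from each
# (noisy) label class, mirroring the balanced validation session of the
# trial-trajectory study. A simple random draw of 20 from a ~3:1 pool often
# contains too few minority-class samples to guide minority-class learning.
draw_val_subset <- function(plan, study, size, seed) {
  pool <- study$val_pool
  i1 <- which(pool$labels == 1L); i0 <- which(pool$labels == 0L)
  k1 <- min(size %/% 2L, length(i1))
  idx <- withr::with_seed(seed, c(sample(i0, size - k1), sample(i1, k1)))
  subset_dataset(pool, idx)
}

#' Noise sweep: decoding quality versus training label noise
#'
#' For every portion parameter, trains each requested method on the
#' corresponding noisy training set, guided by a small validation subset
#' drawn from the near-clean pool, and evaluates F1 and balanced accuracy on
#' the clean test set. For the reweighting method the weight-separation
#' statistics between correctly labeled and mislabeled training samples are
#' attached.
#'
#' @param plan An [experiment_plan()].
#' @param study Optional precomputed [build_study_data()] result.
#' @return data.frame with one row per (portion, method): columns `method`,
#'   `portion`, `noise_level`, `f1`, `balanced_accuracy`, weight statistics
#'   (reweight rows only) and `status` ("ok" or a failure record).
#' @export
run_noise_sweep <- function(plan, study = NULL) {
  if (is.null(study)) study <- build_study_data(plan)
  val <- draw_val_subset(plan, study, plan$val_size,
                         plan$trainer$seed + 500L)
  rows <- list()
  for (i in seq_along(plan$portions)) {
    cent <- standardize_features(study$train_sets[[i]], val, study$test)
    cfg <- plan$trainer
    cfg$seed <- plan$trainer$seed + 10L * i
    for (method in plan$methods) {
      r <- fit_and_score(method, cent[[1L]], cent[[2L]], cent[[3L]], cfg)
      r <- cbind(data.frame(portion = plan$portions[i],
                            noise_level = study$noise_levels[i]), r)
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

#' Validation-size sweep at the highest noise level
#'
#' Trains the reweighting method on the highest-noise training set with
#' validation sets of increasing size, each resampled `n_resamples` times
#' without replacement from the validation pool, and reports mean and SD of
#' the test metrics per size.
#'
#' @inheritParams run_noise_sweep
#' @return data.frame with columns `val_size`, `mean_f1`, `sd_f1`,
#'   `mean_balanced_accuracy`, `sd_balanced_accuracy`, `n_ok`.
#' @export
run_validation_size_sweep <- function(plan, study = NULL) {
  if (is.null(study)) study <- build_study_data(plan)
  i_max <- which.max(plan$portions)
  train <- study$train_sets[[i_max]]
  rows <- lapply(plan$val_sizes, function(size) {
    f1 <- ba <- numeric(0)
    for (r in seq_len(plan$n_resamples)) {
      val <- draw_val_subset(plan, study, size,
                             plan$seed + 600L + 1000L * size + r)
      cent <- standardize_features(train, val, study$test)
      cfg <- plan$trainer
      cfg$seed <- plan$trainer$seed + r
      res <- fit_and_score("reweight", cent[[1L]], cent[[2L]], cent[[3L]],
                           cfg)
      if (res$status == "ok") {
        f1 <- c(f1, res$f1); ba <- c(ba, res$balanced_accuracy)
      }
    }
    data.frame(val_size = size, mean_f1 = mean(f1), sd_f1 = stats::sd(f1),
               mean_balanced_accuracy = mean(ba),
               sd_balanced_accuracy = stats::sd(ba), n_ok = length(f1))
  })
  do.call(rbind, rows)
}

#' Mixed-annotator pooling experiment
#'
#' Pools training sets of different noise levels ([mix_datasets()]) and
#' trains the reweighting method on each configured mixture with the small
#' validation subset, reporting test metrics per mixture.
#'
#' @inheritParams run_noise_sweep
#' @return data.frame with columns `mixture` (portions pooled), `n_train`,
#'   `noise_level` (realised, equal to the size-weighted component mean),
#'   `f1`, `balanced_accuracy`, `status`.
#' @export
run_mixed_experiment <- function(plan, study = NULL) {
  if (is.null(study)) study <- build_study_data(plan)
  val <- draw_val_subset(plan, study, plan$val_size,
                         plan$trainer$seed + 500L)
  rows <- lapply(seq_along(plan$mixtures), function(k) {
    idx <- plan$mixtures[[k]]
    pooled <- mix_datasets(study$train_sets[idx])
    cent <- standardize_features(pooled, val, study$test)
    cfg <- plan$trainer
    cfg$seed <- plan$trainer$seed + 100L * k
    res <- fit_and_score("reweight", cent[[1L]], cent[[2L]], cent[[3L]], cfg)
    data.frame(mixture = paste(plan$portions[idx], collapse = "+"),
               n_train = n_samples(pooled),
               noise_level = realized_noise_level(pooled),
               f1 = res$f1, balanced_accuracy = res$balanced_accuracy,
               status = res$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an experiment report table
#'
#' Writes a runner's result both as delimited text and as JSON.
#'
#' @param table A data.frame returned by a runner.
#' @param path Base path; `.csv` and `.json` are appended.
#' @return Invisibly, the two paths written.
#' @export
write_report <- function(table, path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  utils::write.csv(table, csv, row.names = FALSE)
  jsonlite::write_json(table, js, dataframe = "rows", digits = NA,
                       na = "null")
  invisible(c(csv, js))
}
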