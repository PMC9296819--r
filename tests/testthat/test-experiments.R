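# Desk-scale experiment plan: small simulator, short training; exercises the
# full runner machinery rather than the full-scale study conditions (those run in
# test-acceptance.R).
mini_plan <- function(seed = 3) {
  experiment_plan(
    portions = c(0.8, 0.2),
    val_sizes = c(12L, 20L),
    n_resamples = 2L,
    n_train = 150L, n_val_pool = 150L, n_test = 150L,
    val_size = 12L,
    mixtures = list(1:2, 2L),
    sim_params = small_sim(),
    trainer = fast_config(steps = 250L),
    calibrate = TRUE, target_positive_fraction = 0.3, n_pilot = 600L,
    seed = seed
  )
}

mini_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_study_data(mini_plan())
    cache
  }
})

test_that("study data carry calibrated labels, masks and a shared geometry", {
  st <- mini_study()
  expect_length(st$train_sets, 2L)
  expect_equal(vapply(st$train_sets, n_samples, integer(1)), c(150L, 150L))
  expect_true(all(st$noise_levels > 0))
  expect_gt(st$noise_levels[1], st$noise_levels[2]) # higher portion, more noise
  expect_true(all(vapply(st$train_sets, function(d)
    ncol(d$features), integer(1)) == 20L))
  expect_null(st$test$mislabel_mask[1]) # test set is clean
})

test_that("the noise sweep returns a complete method-by-condition grid", {
  st <- mini_study()
  res <- run_noise_sweep(mini_plan(), st)
  expect_equal(nrow(res), 2L * 3L)
  expect_setequal(unique(res$method), c("reweight", "baseline1", "baseline2"))
  expect_true(all(res$status == "ok"))
  expect_true(all(res$f1 >= 0 & res$f1 <= 1))
  expect_true(all(res$balanced_accuracy >= 0 & res$balanced_accuracy <= 1))
  rw <- res[res$method == "reweight", ]
  expect_true(all(is.finite(rw$zero_weight_fraction_mislabeled)))
  expect_true(all(rw$wilcoxon_p >= 0 & rw$wilcoxon_p <= 1))
  expect_true(all(is.na(res$wilcoxon_p[res$method != "reweight"])))
})

test_that("the validation-size sweep reports means and SDs per size", {
  st <- mini_study()
  res <- run_validation_size_sweep(mini_plan(), st)
  expect_equal(res$val_size, c(12L, 20L))
  expect_true(all(res$n_ok == 2L))
  expect_true(all(is.finite(res$mean_f1)))
  expect_true(all(is.finite(res$sd_f1)))
})

test_that("mixtures pool rows and their noise is the weighted component mean", {
  st <- mini_study()
  res <- run_mixed_experiment(mini_plan(), st)
  expect_equal(res$n_train, c(300L, 150L))
  lv <- vapply(st$train_sets, realized_noise_level, numeric(1))
  expect_equal(res$noise_level[1], mean(lv), tolerance = 1e-12)
  expect_equal(res$noise_level[2], lv[2], tolerance = 1e-12)
  expect_true(all(res$status == "ok"))
})

test_that("report tables serialize to delimited text and JSON", {
  st <- mini_study()
  res <- run_noise_sweep(mini_plan(), st)
  base <- file.path(withr::local_tempdir(), "report")
  paths <- write_report(res, base)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1])
  expect_equal(nrow(back), nrow(res))
  js <- jsonlite::read_json(paths[2])
  expect_length(js, nrow(res))
})
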