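test_that("the trial-trajectory fixture has the documented geometry", {
  tm <- generate_alm_like_fixture(n_sessions = 18, seed = 4)
  n <- nrow(tm$trajectories)
  expect_true(n >= 18 * 48 && n <= 18 * 67)
  expect_equal(ncol(tm$trajectories), 91L)
  expect_length(unique(tm$session), 18L)
  # labels balanced within each session (odd counts differ by one)
  per <- tapply(tm$labels, tm$session, function(y) abs(sum(y == 0) - sum(y == 1)))
  expect_true(all(per <= 1))
  # deterministic given the seed
  tm2 <- generate_alm_like_fixture(n_sessions = 18, seed = 4)
  expect_identical(tm$trajectories, tm2$trajectories)
})

test_that("with no noise, within-class trials are identical up to session gain", {
  tm <- generate_alm_like_fixture(n_sessions = 3, seed = 1, noise_sd = 0,
                                  session_gain_sd = 0)
  for (cl in 0:1) {
    rows <- tm$trajectories[tm$labels == cl, ]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
  }
})

test_that("zero-mean normalization centers on the statistics source", {
  tm <- generate_alm_like_fixture(n_sessions = 4, seed = 2)
  ids <- unique(tm$session)
  keep <- tm$session %in% ids[1:2]
  train <- trial_matrix(tm$trajectories[keep, ], tm$labels[keep],
                        tm$session[keep])
  test <- trial_matrix(tm$trajectories[!keep, ], tm$labels[!keep],
                       tm$session[!keep])
  ntrain <- zero_mean_normalize(train)
  expect_lt(max(abs(colMeans(ntrain$trajectories))), 1e-10)
  ntest <- zero_mean_normalize(test, statistics_from = train)
  expect_equal(ntest$trajectories,
               sweep(test$trajectories, 2, colMeans(train$trajectories)),
               tolerance = 1e-12)
  # constant column maps to zero
  cm <- trial_matrix(matrix(3, 5, 4), rep(c(0, 1), length.out = 5), rep("s", 5))
  expect_true(all(zero_mean_normalize(cm)$trajectories == 0))
})

test_that("trial matrices round-trip through text and the array container", {
  tm <- generate_alm_like_fixture(n_sessions = 2, seed = 6)
  csv <- withr::local_tempfile(fileext = ".csv")
  rds <- withr::local_tempfile(fileext = ".rds")
  write_trial_matrix(tm, csv, format = "csv")
  back <- load_trial_matrix(csv, format = "csv")
  expect_equal(back$trajectories, unname(tm$trajectories),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$labels, tm$labels)
  expect_identical(back$session, tm$session)
  write_trial_matrix(tm, rds, format = "rds")
  expect_identical(load_trial_matrix(rds, format = "rds")$trajectories,
                   tm$trajectories)
})

test_that("a plain decoder learns the clean fixture (task is learnable)", {
  tm <- generate_alm_like_fixture(n_sessions = 6, seed = 8)
  ids <- sort(unique(tm$session))
  tr_keep <- tm$session %in% ids[1:4]
  train <- as_labeled_dataset(
    zero_mean_normalize(trial_matrix(tm$trajectories[tr_keep, ],
                                     tm$labels[tr_keep],
                                     tm$session[tr_keep])))
  te <- trial_matrix(tm$trajectories[!tr_keep, ], tm$labels[!tr_keep],
                     tm$session[!tr_keep])
  test <- as_labeled_dataset(
    zero_mean_normalize(te, statistics_from =
                          trial_matrix(tm$trajectories[tr_keep, ],
                                       tm$labels[tr_keep],
                                       tm$session[tr_keep])))
  fit <- train_plain(train, fast_config(steps = 400L))
  expect_gt(evaluate_model(fit, test)$f1, 0.9)
})

test_that("the trial-trajectory experiment runs per noise level and method", {
  tm <- generate_alm_like_fixture(n_sessions = 6, seed = 12)
  plan <- experiment_plan(portions = c(0.8, 0),
                          methods = c("reweight", "baseline1"),
                          trainer = fast_config(steps = 250L),
                          sim_params = small_sim(), calibrate = FALSE,
                          seed = 5)
  res <- run_alm_like_experiment(plan, tm)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$status == "ok"))
  # the portion-0 copy is recorded as noise-free
  expect_equal(unique(res$noise_level[res$portion == 0]), 0)
  expect_true(all(res$f1 >= 0 & res$f1 <= 1))
})
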