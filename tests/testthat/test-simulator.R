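test_that("connectivity respects fan-in choices and is reproducible", {
  p <- simulator_params()
  conn <- build_connectivity(p, seed = 7)
  expect_length(conn$edges, 40L)
  deg <- lengths(conn$edges)
  expect_true(all(deg %in% c(2L, 3L)))
  expect_true(all(unlist(conn$edges) >= 1L & unlist(conn$edges) <= 40L))
  expect_false(any(vapply(conn$edges, anyDuplicated, integer(1)) > 0L))

  conn2 <- build_connectivity(p, seed = 7)
  expect_identical(conn$edges, conn2$edges)

  forced <- simulator_params(n_group_a = 1L, n_group_b = 5L,
                             fan_in_choices = 1L)
  cf <- build_connectivity(forced, seed = 1)
  expect_true(all(unlist(cf$edges) == 1L))

  expect_error(simulator_params(fan_in_choices = c(2L, 50L)),
               "fan_in_choices")
  expect_error(simulator_params(fan_in_choices = 0L), "fan_in_choices")
})

test_that("label rule fires exactly when sin(pi * r_b) exceeds threshold", {
  expect_identical(compute_label(0.5), 1L)   # peak of the sine
  expect_identical(compute_label(0), 0L)
  expect_identical(compute_label(0.35), 1L)  # sin(0.35*pi) ~ 0.891
  expect_identical(compute_label(0.1), 0L)   # sin(0.1*pi) ~ 0.309
  expect_equal(compute_label(c(0, 0.5, 0.35)), c(0L, 1L, 1L))
  expect_error(compute_label(0.5, threshold = 1.2), "threshold")
})

test_that("noise-free dynamics are deterministic and silent when unstimulated", {
  p <- small_sim(additive_noise_sd = 0)
  conn <- build_connectivity(p, seed = 3)
  a <- simulate_trial(p, conn, stimulus = 2.0)
  b <- simulate_trial(p, conn, stimulus = 2.0)
  expect_identical(a$features, b$features)

  silent <- simulate_trial(p, conn, stimulus = 0)
  expect_true(all(silent$features == 0))
  expect_identical(silent$r_b, 0)
})

test_that("group-B activity is non-decreasing in the stimulus (noise off)", {
  p <- small_sim(additive_noise_sd = 0)
  conn <- build_connectivity(p, seed = 3)
  grid <- seq(0.5, 3.5, length.out = 9)
  rb <- simulate_trials(p, conn, length(grid), stimulus = grid)$r_b
  expect_true(all(diff(rb) >= 0))
})

test_that("generated datasets have consistent shapes and label provenance", {
  p <- small_sim()
  d1 <- generate_dataset(p, 1, seed = 5)
  expect_equal(dim(d1$features), c(1L, 20L))

  d <- generate_dataset(p, 60, seed = 5)
  expect_equal(dim(d$features), c(60L, 20L))
  expect_true(all(is.finite(d$features)))
  expect_identical(d$labels, d$clean_labels)

  # labels depend on the features only through r_b
  rb <- rowMeans(d$features[, 11:20]) / p$activity_normalizer
  expect_equal(rb, d$meta$r_b)
  expect_identical(compute_label(rb, p$label_threshold), d$clean_labels)

  # bit-reproducible given the seed
  expect_identical(generate_dataset(p, 60, seed = 5)$features, d$features)
})

test_that("non-finite dynamics are reported, not clipped", {
  p <- simulator_params(n_group_a = 10L, n_group_b = 10L, dt = 100,
                        trial_duration = 1000, additive_noise_sd = 0,
                        stimulus_mean = 5, stimulus_sd_across_trials = 0)
  conn <- build_connectivity(p, seed = 1)
  expect_error(simulate_trials(p, conn, 3, stimulus = rep(-1e308, 3)),
               "non-finite")
})

test_that("calibration is a fixed point when already on target", {
  p <- small_sim()
  conn <- build_connectivity(p, seed = p$wiring_seed)
  pilot <- withr::with_seed(6L, simulate_trials(p, conn, 800))
  frac <- mean(compute_label(pilot$r_b, p$label_threshold))
  out <- calibrate_simulator(p, target_positive_fraction = frac,
                             n_pilot = 800L, seed = 5L)
  expect_identical(out, p)
})

test_that("calibration reaches an attainable target and verifies on fresh data", {
  p <- small_sim()
  out <- calibrate_simulator(p, target_positive_fraction = 0.35,
                             n_pilot = 1500L, seed = 2L)
  fresh <- generate_dataset(out, 1500, seed = 77)
  expect_lt(abs(mean(fresh$labels) - 0.35), 0.05)

  expect_error(
    calibrate_simulator(small_sim(stimulus_mean = 0,
                                  stimulus_sd_across_trials = 0),
                        target_positive_fraction = 0.3,
                        n_pilot = 300L, seed = 2L),
    "calibration failed")
})
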