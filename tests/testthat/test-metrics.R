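test_that("F1 follows the hand-computed values and zero conventions", {
  expect_equal(f1_score(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(f1_score(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  expect_equal(f1_score(c(1, 0, 1), c(0, 0, 0)), 0)
  expect_equal(f1_score(c(0, 0, 0), c(1, 1, 0)), 0)
  expect_error(f1_score(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("balanced accuracy is the mean of per-class recalls", {
  expect_equal(balanced_accuracy(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(balanced_accuracy(c(0, 0, 0, 1), c(0, 0, 0, 0)), 0.5)
  expect_equal(balanced_accuracy(c(0, 1), c(1, 0)), 0)
  expect_error(balanced_accuracy(c(1, 1, 1), c(1, 0, 1)), "single class")
})

test_that("metrics are order invariant and reduce to accuracy when balanced", {
  withr::with_seed(1, {
    for (rep in 1:20) {
      n <- 40L
      y <- sample(0:1, n, TRUE)
      if (length(unique(y)) < 2L) next
      p <- sample(0:1, n, TRUE)
      o <- sample.int(n)
      expect_equal(f1_score(y, p), f1_score(y[o], p[o]))
      expect_equal(balanced_accuracy(y, p), balanced_accuracy(y[o], p[o]))
    }
    yb <- rep(c(0L, 1L), 25)
    pb <- sample(0:1, 50, TRUE)
    expect_equal(balanced_accuracy(yb, pb), mean(yb == pb))
  })
})

test_that("metrics match an independent confusion-matrix computation", {
  withr::with_seed(7, {
    for (rep in 1:100) {
      n <- sample(10:60, 1)
      y <- c(0L, 1L, sample(0:1, n - 2, TRUE)) # both classes present
      p <- sample(0:1, n, TRUE)
      tp <- sum(y == 1 & p == 1); fp <- sum(y == 0 & p == 1)
      fn <- sum(y == 1 & p == 0); tn <- sum(y == 0 & p == 0)
      f1_ref <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
      ba_ref <- (tp / (tp + fn) + tn / (tn + fp)) / 2
      expect_equal(f1_score(y, p), f1_ref, tolerance = 1e-12)
      expect_equal(balanced_accuracy(y, p), ba_ref, tolerance = 1e-12)
    }
  })
})

test_that("rank-sum test matches exact enumeration for small untied groups", {
  ws <- weight_separation(c(1, 2, 3, 4, 5, 6),
                          c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(unname(ws$statistic), 0)
  expect_equal(ws$p_value, 0.1)

  withr::with_seed(11, {
    for (rep in 1:20) {
      n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
      x <- rnorm(n1); y <- rnorm(n2) + runif(1, -1, 1)
      got <- weight_separation(c(x, y),
                               c(rep(FALSE, n1), rep(TRUE, n2)))$p_value
      expect_equal(got, wilcox_exact_enum(x, y), tolerance = 1e-12)
    }
  })
})

test_that("degenerate and zero-weight cases are handled explicitly", {
  tied <- weight_separation(rep(0.5, 8), rep(c(FALSE, TRUE), 4))
  expect_equal(tied$p_value, 1)

  ws <- weight_separation(c(0, 0, 0, 0.2, 0.8),
                          c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(ws$zero_weight_fraction_mislabeled, 1)
  expect_equal(ws$mean_weight_correct, 0.5)

  expect_error(weight_separation(1:4, rep(FALSE, 4)), "non-empty")
})

test_that("model evaluation fills both metrics from predictions", {
  test <- toy_task(60, seed = 21)
  # constant class-0 predictor via a zeroed output layer
  model <- mlp_init(2, c(4L), seed = 1)
  L <- length(model$W)
  model$W[[L]][] <- 0; model$b[[L]][] <- 0
  rep0 <- evaluate_model(model, test)
  expect_equal(rep0$f1, 0)
  expect_equal(rep0$balanced_accuracy, 0.5)
  expect_equal(rep0$n_test, 60L)

  wt <- weight_table(c(0.1, 0, 0.3), c(FALSE, TRUE, FALSE))
  expect_equal(names(wt), c("sample_id", "weight", "mislabeled"))
})
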