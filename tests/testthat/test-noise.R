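test_that("shuffling preserves features and class totals, and tracks masks", {
  d <- toy_task(60, seed = 4)
  noisy <- shuffle_labels(d, 0.8, seed = 11)
  expect_identical(noisy$features, d$features)
  expect_identical(sort(noisy$labels), sort(d$labels))
  expect_identical(noisy$clean_labels, d$labels)
  expect_identical(noisy$mislabel_mask, noisy$labels != d$labels)

  # deterministic given the seed
  expect_identical(shuffle_labels(d, 0.8, seed = 11)$labels, noisy$labels)

  # portion 0: nothing changes
  clean <- shuffle_labels(d, 0, seed = 11)
  expect_identical(clean$labels, d$labels)
  expect_identical(realized_noise_level(clean), 0)

  # single-class labels cannot change under a permutation
  same <- labeled_dataset(d$features, rep(1L, 60))
  expect_identical(realized_noise_level(shuffle_labels(same, 1, seed = 2)), 0)

  expect_error(shuffle_labels(d, 1.2, seed = 1), "portion")
})

test_that("realized noise level is the mean of the mislabel mask", {
  mask218 <- c(rep(TRUE, 218), rep(FALSE, 382))
  labels <- ifelse(mask218, 1L, 0L)
  d <- labeled_dataset(matrix(0, 600, 1), labels,
                       clean_labels = rep(0L, 600), mislabel_mask = mask218)
  expect_equal(realized_noise_level(d), 218 / 600, tolerance = 1e-12)
  expect_equal(round(realized_noise_level(d), 4), 0.3633)

  d4 <- labeled_dataset(matrix(0, 4, 1), c(1L, 0L, 1L, 0L),
                        clean_labels = rep(0L, 4),
                        mislabel_mask = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(realized_noise_level(d4), 0.5)

  nomask <- labeled_dataset(matrix(0, 10, 1), rep(c(0L, 1L), 5))
  expect_error(realized_noise_level(nomask), "mislabel_mask")
})

test_that("expected realized noise matches the closed form p * 2 n0 n1 / n^2", {
  cases <- list(c(n0 = 30, n1 = 10, p = 1), c(n0 = 20, n1 = 20, p = 0.5),
                c(n0 = 45, n1 = 15, p = 0.8))
  for (cs in cases) {
    n <- cs["n0"] + cs["n1"]
    d <- labeled_dataset(matrix(0, n, 1),
                         c(rep(0L, cs["n0"]), rep(1L, cs["n1"])))
    mc <- mean(vapply(1:300, function(s)
      realized_noise_level(shuffle_labels(d, cs["p"], seed = s)), numeric(1)))
    expected <- cs["p"] * 2 * cs["n0"] * cs["n1"] / n^2
    expect_lt(abs(mc - expected), 0.03)
  }
})

test_that("pooling datasets concatenates rows and averages noise by size", {
  a <- shuffle_labels(toy_task(60, seed = 1), 0.2, seed = 3)
  b <- shuffle_labels(toy_task(40, seed = 2), 0.9, seed = 4)
  pooled <- mix_datasets(list(a, b))
  expect_equal(n_samples(pooled), 100L)
  expect_equal(realized_noise_level(pooled),
               (60 * realized_noise_level(a) + 40 * realized_noise_level(b))
               / 100)
  expect_identical(pooled$features, rbind(a$features, b$features))

  expect_identical(mix_datasets(list(a)), a)

  wide <- labeled_dataset(matrix(0, 5, 3), rep(0L, 5))
  expect_error(mix_datasets(list(a, wide)), "feature dimensions")
  nomask <- labeled_dataset(a$features, a$labels)
  expect_error(mix_datasets(list(a, nomask)), "all or none")
})
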