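#' Inject label noise by shuffling a portion of the labels
#'
#' Selects `round(portion * n)` samples uniformly without replacement and
#' applies a uniform random permutation to the labels at those positions.
#' Class totals are invariant (a permutation cannot change them), which is
#' what distinguishes annotator-style shuffling noise from independent label
#' flips. Because some shuffled labels land back on their original class, the
#' realised noise level is below the portion parameter; for binary labels its
#' expectation is `portion * 2 * n0 * n1 / n^2`.
#'
#' @param ds A [labeled_dataset()].
#' @param portion Fraction of labels to shuffle, in \[0, 1\] (the portion
#'   parameter). `round()` uses R's round-half-to-even rule.
#' @param seed Integer seed; the corruption is deterministic given the seed.
#' @return A [labeled_dataset()] with the same features, shuffled `labels`,
#'   `clean_labels` set to the input labels, `mislabel_mask` marking every
#'   changed label, and `portion` / `realized_noise` recorded in `meta`.
#' @export
#' @examples
#' d <- labeled_dataset(matrix(rnorm(12), 6, 2), c(0, 0, 0, 0, 1, 1))
#' noisy <- shuffle_labels(d, portion = 1, seed = 1)
#' realized_noise_level(noisy)
shuffle_labels <- function(ds, portion, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (portion < 0 || portion > 1) stop("portion must be in [0, 1]")
  n <- n_samples(ds)
  k <- round(portion * n)
  old <- ds$labels
  new <- old
  if (k >= 2L) {
    withr::with_seed(as.integer(seed), {
      idx <- sample.int(n, k)
      perm <- sample.int(k, k)
    })
    new[idx] <- old[idx][perm]
  }
  meta <- ds$meta
  meta$portion <- portion
  meta$noise_seed <- as.integer(seed)
  meta$realized_noise <- mean(new != old)
  labeled_dataset(ds$features, new, clean_labels = old,
                  mislabel_mask = new != old, meta = meta)
}

#' Realised label-noise level
#'
#' Fraction of samples whose current label differs from the clean label.
#'
#' @param ds A [labeled_dataset()] carrying a `mislabel_mask`.
#' @return A number in \[0, 1\].
#' @export
realized_noise_level <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (is.null(ds$mislabel_mask))
    stop("dataset has no mislabel_mask; apply shuffle_labels() first")
  mean(ds$mislabel_mask)
}

#' Pool datasets of mixed annotation quality
#'
#' Row-concatenates datasets (e.g. training sets produced by different
#' annotators at different noise levels), preserving per-sample mislabel
#' bookkeeping. The realised noise level of the pool is the sample-size
#' weighted mean of the inputs' levels.
#'
#' @param datasets List of [labeled_dataset()] objects with equal feature
#'   dimension; either all or none may carry a `mislabel_mask`.
#' @return A pooled [labeled_dataset()].
#' @export
mix_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "labeled_dataset")))
  if (length(datasets) == 1L) return(datasets[[1L]])
  p <- vapply(datasets, function(d) ncol(d$features), integer(1))
  if (length(unique(p)) != 1L)
    stop("feature dimensions differ across datasets")
  has_mask <- vapply(datasets, function(d) !is.null(d$mislabel_mask),
                     logical(1))
  if (any(has_mask) && !all(has_mask))
    stop("either all or none of the datasets may carry a mislabel_mask")
  has_clean <- vapply(datasets, function(d) !is.null(d$clean_labels),
                      logical(1))
  labeled_dataset(
    do.call(rbind, lapply(datasets, function(d) d$features)),
    unlist(lapply(datasets, function(d) d$labels)),
    clean_labels = if (all(has_clean))
      unlist(lapply(datasets, function(d) d$clean_labels)),
    mislabel_mask = if (all(has_mask))
      unlist(lapply(datasets, function(d) d$mislabel_mask)),
    meta = list(source = "mix_datasets",
                component_sizes = vapply(datasets, n_samples, integer(1)),
                component_noise = if (all(has_mask))
                  vapply(datasets, realized_noise_level, numeric(1)))
  )
}
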