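#' Labeled neural-activity dataset
#'
#' Container for a feature matrix with (possibly noisy) binary labels, used by
#' the simulator, the noise injector and the trainers. Optionally carries the
#' clean labels and a per-sample mislabel mask so that realised noise levels
#' and weight-separation statistics can be computed after noise injection.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Integer/numeric vector of 0/1 labels, one per row.
#' @param clean_labels Optional 0/1 vector of the uncorrupted labels.
#' @param mislabel_mask Optional logical vector; must equal
#'   `labels != clean_labels` elementwise when both are present.
#' @param meta Free-form provenance list (seed, simulator parameters, noise
#'   portion, realised noise level, ...).
#'
#' @return An object of class `labeled_dataset`: a list with elements
#'   `features`, `labels`, `clean_labels`, `mislabel_mask`, `meta`.
#' @export
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20), 10, 2), rep(c(0, 1), 5))
#' nrow(d$features)
labeled_dataset <- function(features, labels, clean_labels = NULL,
                            mislabel_mask = NULL, meta = list()) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  n <- nrow(features)
  if (length(labels) != n)
    stop("`labels` must have one entry per row of `features`")
  if (!all(labels %in% c(0L, 1L)))
    stop("`labels` must be binary (0/1)")
  if (!is.null(clean_labels)) {
    clean_labels <- as.integer(clean_labels)
    if (length(clean_labels) != n)
      stop("`clean_labels` length mismatch")
    if (!all(clean_labels %in% c(0L, 1L)))
      stop("`clean_labels` must be binary (0/1)")
  }
  if (!is.null(mislabel_mask)) {
    mislabel_mask <- as.logical(mislabel_mask)
    if (length(mislabel_mask) != n)
      stop("`mislabel_mask` length mismatch")
    if (!is.null(clean_labels) &&
        !identical(mislabel_mask, labels != clean_labels))
      stop("`mislabel_mask` must equal (labels != clean_labels)")
  }
  structure(
    list(features = features, labels = labels, clean_labels = clean_labels,
         mislabel_mask = mislabel_mask, meta = meta),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  n <- nrow(x$features)
  cat(sprintf("Labeled dataset: %d samples x %d features\n",
              n, ncol(x$features)))
  cat(sprintf("  class counts: 0 -> %d, 1 -> %d\n",
              sum(x$labels == 0L), sum(x$labels == 1L)))
  if (!is.null(x$mislabel_mask))
    cat(sprintf("  realised label noise: %.1f%%\n",
                100 * mean(x$mislabel_mask)))
  invisible(x)
}

#' Number of samples in a labeled dataset
#' @param ds A `labeled_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(ds) nrow(ds$features)

#' Subset a labeled dataset by row index
#'
#' @param ds A `labeled_dataset`.
#' @param idx Integer row indices.
#' @return A `labeled_dataset` restricted to `idx` (masks and clean labels
#'   subset alongside; `meta` is carried over).
#' @export
subset_dataset <- function(ds, idx) {
  labeled_dataset(
    ds$features[idx, , drop = FALSE], ds$labels[idx],
    clean_labels = if (!is.null(ds$clean_labels)) ds$clean_labels[idx],
    mislabel_mask = if (!is.null(ds$mislabel_mask)) ds$mislabel_mask[idx],
    meta = ds$meta
  )
}

#' Write / read a labeled dataset as delimited text
#'
#' The text layout is one row per sample with feature columns `f0..f<p-1>`
#' followed by `label` and, when available, `clean_label` and `mislabeled`.
#'
#' @param ds A `labeled_dataset`.
#' @param path Output (input) file path.
#' @return `write_dataset_csv` returns `path` invisibly; `read_dataset_csv`
#'   returns a `labeled_dataset`.
#' @export
write_dataset_csv <- function(ds, path) {
  p <- ncol(ds$features)
  df <- as.data.frame(ds$features)
  names(df) <- paste0("f", seq_len(p) - 1L)
  df$label <- ds$labels
  if (!is.null(ds$clean_labels)) df$clean_label <- ds$clean_labels
  if (!is.null(ds$mislabel_mask)) df$mislabeled <- as.integer(ds$mislabel_mask)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  if (!length(fcols) || is.null(df$label))
    stop("file does not contain feature columns f0.. and a label column")
  labeled_dataset(
    as.matrix(df[fcols]), df$label,
    clean_labels = df$clean_label,
    mislabel_mask = if (!is.null(df$mislabeled)) df$mislabeled != 0L
  )
}

#' Write / read a labeled dataset in the binary array container
#'
#' Uses R native serialization; stores the same arrays as the delimited-text
#' layout plus the full `meta` provenance record, and round-trips values
#' bit-exactly.
#'
#' @inheritParams write_dataset_csv
#' @return `write_dataset_rds` returns `path` invisibly; `read_dataset_rds`
#'   a `labeled_dataset`.
#' @export
write_dataset_rds <- function(ds, path) {
  saveRDS(unclass(ds), path)
  invisible(path)
}

#' @rdname write_dataset_rds
#' @export
read_dataset_rds <- function(path) {
  x <- readRDS(path)
  labeled_dataset(x$features, x$labels, x$clean_labels, x$mislabel_mask,
                  meta = if (is.null(x$meta)) list() else x$meta)
}
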