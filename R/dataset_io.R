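# Dataset manifests, stratified splitting and the feature store.
#
# A manifest is the bookkeeping unit of the pipeline: one row per image
# (path + class label, optionally a split tag), plus the ordered class
# vocabulary. The five-class vocabulary is kept in alphabetical order
# (colon_aca, colon_bnt, lung_aca, lung_bnt, lung_scc) so confusion
# matrices are comparable across runs.

new_manifest <- function(records, class_names) {
  stopifnot(is.data.frame(records), all(c("path", "label") %in% names(records)))
  structure(list(records = records, class_names = class_names),
            class = "dataset_manifest")
}

#' Load a dataset manifest from delimited text
#'
#' The manifest is a comma-separated file with a header containing at
#' least `path` and `label` columns and optionally a `split` column with
#' values in `train`/`validation`/`test`.
#'
#' @param path path to the CSV manifest.
#' @param expected_classes if non-`NULL`, the number of distinct labels
#'   required; a mismatch is an error.
#' @return a `dataset_manifest`: a list with `records` (data frame) and
#'   `class_names` (sorted label vocabulary).
#' @export
load_manifest <- function(path, expected_classes = NULL) {
  if (!file.exists(path)) stop("manifest file not found: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(rec)))
    stop("manifest must have 'path' and 'label' columns", call. = FALSE)
  if (nrow(rec) == 0L) stop("manifest is empty", call. = FALSE)
  if (anyDuplicated(rec$path))
    stop("manifest contains duplicate image paths", call. = FALSE)
  cls <- sort(unique(rec$label))
  if (!is.null(expected_classes) && length(cls) != expected_classes)
    stop("expected ", expected_classes, " classes, found ", length(cls),
         call. = FALSE)
  if ("split" %in% names(rec) &&
      !all(rec$split %in% c("train", "validation", "test")))
    stop("split column values must be train/validation/test", call. = FALSE)
  new_manifest(rec[, intersect(c("path", "label", "split"), names(rec))], cls)
}

#' Write a dataset manifest to delimited text
#'
#' @param manifest a `dataset_manifest`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  utils::write.csv(manifest$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Two-level stratified train/validation/test split
#'
#' Splits a manifest per class: first `test_fraction` of each class is
#' held out as the test set, then `validation_fraction` of the remainder
#' becomes the validation set; everything else is training data. Counts
#' are exact: `n_test = floor(n * test_fraction)` and
#' `n_val = round((n - n_test) * validation_fraction)` (half away from
#' zero), with the remainder staying in training, so the three splits
#' always partition each class. Rows are shuffled per class with the given seed before
#' slicing, making the assignment a pure function of (manifest order,
#' fractions, seed).
#'
#' @param manifest a `dataset_manifest`.
#' @param test_fraction,validation_fraction fractions in (0, 1).
#' @param seed integer seed controlling the per-class shuffle.
#' @return the manifest with a `split` column added to its records.
#' @export
split_dataset <- function(manifest, test_fraction = 0.2,
                          validation_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  if (test_fraction <= 0 || test_fraction >= 1 ||
      validation_fraction <= 0 || validation_fraction >= 1)
    stop("fractions must lie strictly between 0 and 1", call. = FALSE)
  rec <- manifest$records
  rec$split <- NA_character_
  with_preserved_seed(seed, {
    for (cl in manifest$class_names) {
      idx <- which(rec$label == cl)
      n <- length(idx)
      n_test <- floor(n * test_fraction)
      n_val <- floor((n - n_test) * validation_fraction + 0.5)
      if (n_test < 1L || n_val < 1L || n - n_test - n_val < 1L)
        stop("class '", cl, "' has too few samples (", n,
             ") for one per split", call. = FALSE)
      idx <- idx[sample.int(n)]
      rec$split[idx[seq_len(n_test)]] <- "test"
      rec$split[idx[n_test + seq_len(n_val)]] <- "validation"
      rec$split[idx[(n_test + n_val + 1L):n]] <- "train"
    }
  })
  new_manifest(rec, manifest$class_names)
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("<dataset_manifest> ", nrow(x$records), " records, ",
      length(x$class_names), " classes\n", sep = "")
  if ("split" %in% names(x$records))
    print(table(x$records$label, x$records$split))
  else print(table(x$records$label))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Feature matrices: the currency between pipeline stages.

#' Construct a feature matrix with aligned labels
#'
#' @param values numeric matrix, one row per sample.
#' @param labels character vector of class labels, one per row.
#' @param feature_names optional column names; defaults to existing
#'   colnames or `f1..fd`.
#' @param source_tag provenance string recording which extractor or
#'   fusion strategy produced the matrix.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, feature_names = NULL,
                           source_tag = "") {
  values <- as.matrix(values)
  if (ncol(values) < 1L) stop("feature dimension must be positive", call. = FALSE)
  if (length(labels) != nrow(values))
    stop("labels must align with rows of values", call. = FALSE)
  if (any(!is.finite(values)))
    stop("feature values must be finite", call. = FALSE)
  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(values)))
  if (length(feature_names) != ncol(values))
    stop("feature_names length must equal the feature dimension", call. = FALSE)
  colnames(values) <- feature_names
  structure(list(values = values, labels = as.character(labels),
                 feature_names = feature_names, source_tag = source_tag),
            class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " x ", ncol(x$values),
      if (nzchar(x$source_tag)) paste0("  [", x$source_tag, "]"), "\n", sep = "")
  invisible(x)
}

#' Subset rows of a feature matrix
#'
#' @param x a `feature_matrix`.
#' @param i row index vector.
#' @param ... unused.
#' @export
`[.feature_matrix` <- function(x, i, ...) {
  feature_matrix(x$values[i, , drop = FALSE], x$labels[i],
                 x$feature_names, x$source_tag)
}

#' Save a feature matrix to a binary store
#'
#' Writes the values as little-endian float64 in `path` and a JSON
#' sidecar `<path>.json` describing dimensions, labels, feature names
#' and the source tag, so the store is inspectable and language-neutral.
#'
#' @param fm a `feature_matrix`.
#' @param path destination path for the binary array.
#' @return `path`, invisibly.
#' @export
save_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (any(!is.finite(fm$values)))
    stop("refusing to save non-finite feature values", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(fm$values), con, size = 8L, endian = "little")
  meta <- list(n_samples = nrow(fm$values), dim = ncol(fm$values),
               labels = fm$labels, feature_names = fm$feature_names,
               source_tag = fm$source_tag)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a feature matrix from a binary store
#'
#' @param path path previously passed to [save_features()].
#' @return the restored `feature_matrix`.
#' @export
load_features <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar))
    stop("feature store or its sidecar is missing: ", path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- as.integer(meta$n_samples); d <- as.integer(meta$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = n * d + 1L, size = 8L,
                  endian = "little")
  if (length(vals) != n * d)
    stop("feature store is corrupted: expected ", n * d, " values, found ",
         length(vals), call. = FALSE)
  feature_matrix(matrix(vals, nrow = n, ncol = d), meta$labels,
                 meta$feature_names, meta$source_tag)
}
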