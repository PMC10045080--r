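# PCA dimensionality reduction and the three fusion strategies that
# produce the 455-, 910-, 740- and 699-dimensional feature spaces.

fm_values <- function(x) if (inherits(x, "feature_matrix")) x$values else as.matrix(x)

#' Fit a PCA model
#'
#' Mean-centred principal component analysis (covariance PCA by default;
#' set `scale = TRUE` for correlation PCA), computed via the singular
#' value decomposition (`stats::prcomp`). Components carry a
#' deterministic sign convention: the loading of largest magnitude in
#' each component is made positive, so fitted models are bit-reproducible.
#' Explained variances use the sample (n - 1) divisor.
#'
#' @param train a [feature_matrix()] or numeric matrix of training rows
#'   only (the model is meant to be applied unchanged to validation and
#'   test data).
#' @param n_components number of components,
#'   `<= min(n_samples - 1, dim)`.
#' @param scale standardise features to unit variance before the
#'   decomposition.
#' @return a `pca_model`: list with `mean`, `components`
#'   (`n_components` x dim orthonormal rows), `explained_variance`,
#'   `n_components`, and `scale` (feature scales or `NULL`).
#' @export
pca_fit <- function(train, n_components, scale = FALSE) {
  x <- fm_values(train)
  n <- nrow(x); d <- ncol(x)
  if (n_components > min(n - 1L, d))
    stop("n_components must be <= min(n_samples - 1, dim) = ",
         min(n - 1L, d), call. = FALSE)
  if (n_components < 1L) stop("n_components must be >= 1", call. = FALSE)
  if (all(apply(x, 2, stats::var) == 0))
    stop("zero-variance input: PCA undefined", call. = FALSE)
  pr <- stats::prcomp(x, center = TRUE, scale. = scale, rank. = n_components)
  comp <- t(pr$rotation)                 # n_components x d
  for (k in seq_len(nrow(comp))) {
    jmax <- which.max(abs(comp[k, ]))
    if (comp[k, jmax] < 0) comp[k, ] <- -comp[k, ]
  }
  structure(list(mean = pr$center, components = comp,
                 explained_variance = pr$sdev[seq_len(n_components)]^2,
                 n_components = as.integer(n_components),
                 scale = if (scale) pr$scale else NULL),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", x$n_components, " components over ",
      length(x$mean), " features\n", sep = "")
  invisible(x)
}

#' Project data onto a fitted PCA basis
#'
#' @param model a [pca_fit()] result.
#' @param X a [feature_matrix()] or numeric matrix with the model's
#'   input dimension.
#' @param source_tag provenance tag for the projected matrix.
#' @return a `feature_matrix` (when `X` carries labels) or plain matrix
#'   of scores with `n_components` columns.
#' @export
pca_transform <- function(model, X, source_tag = "pca") {
  stopifnot(inherits(model, "pca_model"))
  x <- fm_values(X)
  if (ncol(x) != length(model$mean))
    stop("dimension mismatch: model expects ", length(model$mean),
         " features, got ", ncol(x), call. = FALSE)
  xc <- sweep(x, 2, model$mean)
  if (!is.null(model$scale)) xc <- sweep(xc, 2, model$scale, "/")
  sc <- xc %*% t(model$components)
  colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
  if (inherits(X, "feature_matrix"))
    feature_matrix(sc, X$labels, source_tag = source_tag)
  else sc
}

#' Reconstruct data from PCA scores
#'
#' @param model a [pca_fit()] result.
#' @param scores score matrix with `n_components` columns.
#' @return matrix in the original feature space.
#' @export
pca_inverse_transform <- function(model, scores) {
  stopifnot(inherits(model, "pca_model"))
  scores <- fm_values(scores)
  x <- scores %*% model$components
  if (!is.null(model$scale)) x <- sweep(x, 2, model$scale, "*")
  sweep(x, 2, model$mean, "+")
}

cap_components <- function(n_components, n_train, d) {
  cap <- min(n_train - 1L, d)
  if (n_components > cap) {
    message("capping n_components at min(n - 1, dim) = ", cap)
    cap
  } else n_components
}

standardize_branch <- function(x, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(x, 2, center), 2, scale, "/")
}

#' Fuse feature branches by one of three strategies
#'
#' * `separate`: PCA-reduce a single branch (455 components at the
#'   reference settings).
#' * `merge_after_pca`: PCA-reduce each branch separately, then
#'   concatenate the scores (455 + 455 = 910).
#' * `merge_before_pca`: concatenate the raw branches, then apply a
#'   single PCA (740).
#' * `cnn_plus_handcrafted`: PCA-reduce the first (deep) branch, keep
#'   the second (handcrafted) branch raw, standardise each branch
#'   per-feature on training statistics so neither scale dominates, and
#'   concatenate (455 + 244 = 699).
#'
#' PCA models are fitted on the rows indexed by `train_idx` only
#' (defaults to all rows); requested component counts are capped at
#' `min(n_train - 1, dim)` with a message, so the reference counts can be
#' used verbatim on small synthetic runs.
#'
#' @param branches list of [feature_matrix()] objects with aligned rows
#'   and identical labels.
#' @param strategy fusion strategy (see above).
#' @param n_components per-branch component counts (recycled);
#'   `merge_before_pca` uses a single count for the pooled matrix.
#' @param train_idx rows used to fit PCA (and standardisation) models.
#' @return a `feature_matrix` whose feature names record branch
#'   provenance.
#' @export
fuse <- function(branches,
                 strategy = c("separate", "merge_after_pca",
                              "merge_before_pca", "cnn_plus_handcrafted"),
                 n_components = NULL, train_idx = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(is.list(branches), length(branches) >= 1L,
            all(vapply(branches, inherits, TRUE, "feature_matrix")))
  ns <- vapply(branches, function(b) nrow(b$values), 1L)
  if (length(unique(ns)) != 1L)
    stop("branch row counts differ: not row-aligned", call. = FALSE)
  labs <- branches[[1]]$labels
  for (b in branches[-1])
    if (!identical(b$labels, labs))
      stop("branch labels differ: not row-aligned", call. = FALSE)
  if (is.null(train_idx)) train_idx <- seq_len(ns[1])
  n_train <- length(train_idx)

  reduce_branch <- function(b, k, tag) {
    k <- cap_components(k, n_train, ncol(b$values))
    mod <- pca_fit(b[train_idx], k)
    out <- pca_transform(mod, b, source_tag = tag)
    out$feature_names <- paste0(tag, "_PC", seq_len(k))
    colnames(out$values) <- out$feature_names
    list(fm = out, model = mod)
  }
  branch_tag <- function(i) {
    tg <- branches[[i]]$source_tag
    if (nzchar(tg)) tg else paste0("branch", i)
  }

  if (strategy == "separate") {
    if (length(branches) != 1L)
      stop("'separate' takes exactly one branch", call. = FALSE)
    k <- if (is.null(n_components)) 455L else n_components[1]
    r <- reduce_branch(branches[[1]], k, branch_tag(1))
    out <- r$fm
    out$source_tag <- "separate"
    return(out)
  }
  if (strategy == "merge_after_pca") {
    if (length(branches) < 2L)
      stop("'merge_after_pca' needs at least two branches", call. = FALSE)
    if (is.null(n_components)) n_components <- 455L
    ks <- rep_len(n_components, length(branches))
    parts <- lapply(seq_along(branches), function(i)
      reduce_branch(branches[[i]], ks[i], branch_tag(i))$fm)
    vals <- do.call(cbind, lapply(parts, function(p) p$values))
    return(feature_matrix(vals, labs, source_tag = "merge_after_pca"))
  }
  if (strategy == "merge_before_pca") {
    if (is.null(n_components)) n_components <- 740L
    pooled <- feature_matrix(
      do.call(cbind, lapply(seq_along(branches), function(i) {
        v <- branches[[i]]$values
        colnames(v) <- paste0(branch_tag(i), "_", colnames(v))
        v
      })), labs, source_tag = "pooled")
    r <- reduce_branch(pooled, n_components[1], "merged")
    out <- r$fm
    out$source_tag <- "merge_before_pca"
    return(out)
  }
  # cnn_plus_handcrafted
  if (length(branches) != 2L)
    stop("'cnn_plus_handcrafted' takes exactly two branches (deep, handcrafted)",
         call. = FALSE)
  if (is.null(n_components)) n_components <- 455L
  deep <- reduce_branch(branches[[1]], n_components[1], branch_tag(1))$fm
  hc <- branches[[2]]
  dtr <- deep$values[train_idx, , drop = FALSE]
  htr <- hc$values[train_idx, , drop = FALSE]
  dv <- standardize_branch(deep$values, colMeans(dtr), apply(dtr, 2, stats::sd))
  hv <- standardize_branch(hc$values, colMeans(htr), apply(htr, 2, stats::sd))
  colnames(hv) <- paste0(branch_tag(2), "_", hc$feature_names)
  feature_matrix(cbind(dv, hv), labs, source_tag = "cnn_plus_handcrafted")
}
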