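# Deep-style feature extraction: the pooling primitives, a backbone
# adapter contract (any function image -> fixed-length vector), and a
# deterministic pseudo-backbone built from seeded random convolution
# kernels so the full pipeline runs without pretrained weights.

#' Configuration for 2-D pooling
#'
#' @param k square window size (>= 1).
#' @param p stride (>= 1).
#' @param mode `"max"` or `"average"`.
#' @return a `pooling_config` list.
#' @export
pooling_config <- function(k = 2L, p = 2L, mode = c("max", "average")) {
  stopifnot(k >= 1L, p >= 1L)
  structure(list(k = as.integer(k), p = as.integer(p),
                 mode = match.arg(mode)), class = "pooling_config")
}

#' 2-D max / average pooling
#'
#' Window maximum or mean over k x k windows at stride p, with no
#' padding (only fully covered windows contribute).
#'
#' @param map numeric matrix.
#' @param cfg a [pooling_config()].
#' @return pooled matrix of size `floor((n - k) / p) + 1` per axis.
#' @export
pool2d <- function(map, cfg = pooling_config()) {
  stopifnot(is.matrix(map), inherits(cfg, "pooling_config"))
  k <- cfg$k; p <- cfg$p
  if (nrow(map) < k || ncol(map) < k)
    stop("pooling window larger than map", call. = FALSE)
  i0 <- seq(1L, nrow(map) - k + 1L, by = p)
  j0 <- seq(1L, ncol(map) - k + 1L, by = p)
  acc <- NULL
  for (m in 0:(k - 1L)) for (n in 0:(k - 1L)) {
    v <- map[i0 + m, j0 + n, drop = FALSE]
    acc <- if (is.null(acc)) v
           else if (cfg$mode == "max") pmax(acc, v) else acc + v
  }
  if (cfg$mode == "average") acc <- acc / k^2
  acc
}

#' Global average pooling
#'
#' Reduces each feature map to its spatial mean, preserving map order.
#'
#' @param maps a list of equally shaped numeric matrices (or a single
#'   matrix).
#' @return numeric vector with one mean per map.
#' @export
global_average_pool <- function(maps) {
  if (is.matrix(maps)) maps <- list(maps)
  stopifnot(length(maps) >= 1L)
  if (any(vapply(maps, length, 1L) == 0L))
    stop("empty feature map", call. = FALSE)
  vapply(maps, mean, numeric(1))
}

# 'same' convolution with reflective padding (3 x 3 kernels).
conv3 <- function(mat, kern) {
  p <- reflect_pad(mat, 1L, 1L, 1L, 1L)
  n <- nrow(mat); m <- ncol(mat)
  acc <- matrix(0, n, m)
  for (a in 0:2) for (b in 0:2) {
    acc <- acc + kern[a + 1L, b + 1L] * p[a + seq_len(n), b + seq_len(m)]
  }
  acc
}

#' Construct a backbone adapter
#'
#' An adapter is the contract every deep-feature source must satisfy: a
#' name, a fixed output dimension, and a deterministic `extract` function
#' mapping an RGB image to a vector of that length. Real pretrained
#' networks can be plugged in through the same contract.
#'
#' @param name adapter label, recorded in feature provenance.
#' @param output_dim fixed feature length.
#' @param extract `function(img)` returning a numeric vector of length
#'   `output_dim`.
#' @return a `backbone_adapter` object.
#' @export
backbone_adapter <- function(name, output_dim, extract) {
  stopifnot(is.function(extract), output_dim >= 1L)
  structure(list(name = name, output_dim = as.integer(output_dim),
                 extract = extract), class = "backbone_adapter")
}

#' Deterministic pseudo convolutional backbone
#'
#' A desk-scale stand-in for a pretrained network: a seeded bank of
#' random 3 x 3 x 3 convolution kernels, rectification (`max(0, x)`), max
#' pooling, a second per-map convolution + rectification + average
#' pooling stage, global average pooling, raw channel colour moments, and
#' finally a seeded random projection to `output_dim`. All parameters are
#' a pure function of the seed, so extraction is bit-reproducible.
#'
#' @param seed integer seed generating the kernel bank and projection.
#' @param output_dim output feature length (default 4096).
#' @param n_kernels number of first-stage kernels.
#' @return a [backbone_adapter()] whose `extract` yields
#'   `output_dim`-long vectors.
#' @export
pseudo_backbone <- function(seed = 7L, output_dim = 4096L, n_kernels = 12L) {
  params <- with_preserved_seed(seed, {
    k1 <- array(stats::rnorm(n_kernels * 27), c(3, 3, 3, n_kernels))
    k2 <- array(stats::rnorm(n_kernels * 9), c(3, 3, n_kernels))
    feat_dim <- n_kernels + 6L
    proj <- matrix(stats::rnorm(feat_dim * output_dim) / sqrt(feat_dim),
                   feat_dim, output_dim)
    list(k1 = k1, k2 = k2, proj = proj)
  })
  extract <- function(img) {
    assert_rgb_image(img, min_side = 8L)
    x <- img / 255
    pool_max <- pooling_config(2L, 2L, "max")
    pool_avg <- pooling_config(2L, 2L, "average")
    maps <- lapply(seq_len(n_kernels), function(q) {
      m <- conv3(x[, , 1], params$k1[, , 1, q]) +
           conv3(x[, , 2], params$k1[, , 2, q]) +
           conv3(x[, , 3], params$k1[, , 3, q])
      pool2d(pmax(m, 0), pool_max)
    })
    maps <- lapply(seq_len(n_kernels), function(q)
      pool2d(pmax(conv3(maps[[q]], params$k2[, , q]), 0), pool_avg))
    gap <- global_average_pool(maps)
    moments <- c(apply(x, 3, mean), apply(x, 3, stats::sd))
    as.vector(c(gap, moments) %*% params$proj)
  }
  backbone_adapter(paste0("pseudo_seed", seed), output_dim, extract)
}

#' Extract pseudo-backbone features from one image
#'
#' Convenience wrapper constructing a [pseudo_backbone()] and applying
#' it; deterministic given `(seed, output_dim)`.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param seed integer seed.
#' @param output_dim feature length (default 4096).
#' @return numeric vector of length `output_dim`.
#' @export
pseudo_backbone_extract <- function(img, seed = 7L, output_dim = 4096L) {
  pseudo_backbone(seed, output_dim)$extract(img)
}

#' Deep feature matrix for a set of images
#'
#' Applies a backbone adapter to each image (in order), producing an
#' `n x output_dim` feature matrix aligned with the labels.
#'
#' @param images list of RGB arrays, or a `dataset_manifest` whose paths
#'   will be read with [read_image()].
#' @param adapter a [backbone_adapter()].
#' @param labels class labels (taken from the manifest when omitted).
#' @return a [feature_matrix()] tagged with the adapter name.
#' @export
deep_feature_matrix <- function(images, adapter, labels = NULL) {
  stopifnot(inherits(adapter, "backbone_adapter"))
  if (inherits(images, "dataset_manifest")) {
    if (is.null(labels)) labels <- images$records$label
    paths <- images$records$path
    images <- lapply(paths, function(p) {
      tryCatch(read_image(p),
               error = function(e) stop("failed to read image '", p, "': ",
                                        conditionMessage(e), call. = FALSE))
    })
  }
  stopifnot(length(labels) == length(images))
  vals <- t(vapply(images, adapter$extract, numeric(adapter$output_dim)))
  feature_matrix(vals, labels,
                 feature_names = paste0(adapter$name, "_", seq_len(adapter$output_dim)),
                 source_tag = adapter$name)
}
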