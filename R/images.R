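#' @keywords internal
"_PACKAGE"

# Shared image utilities. Images are plain numeric arrays: RGB images are
# H x W x 3 arrays and grayscale images H x W matrices, both on the
# 0..255 intensity scale (doubles are allowed mid-pipeline; quantization
# back to integers happens once, at the end of the enhancement chain).

assert_rgb_image <- function(img, min_side = 1L) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  if (dim(img)[1] < min_side || dim(img)[2] < min_side)
    stop("image smaller than required minimum side ", min_side, call. = FALSE)
  if (anyNA(img) || any(!is.finite(img)))
    stop("image contains non-finite intensities", call. = FALSE)
  if (min(img) < 0 || max(img) > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  invisible(img)
}

assert_gray_image <- function(img, min_side = 1L) {
  if (!is.matrix(img))
    stop("expected an H x W grayscale matrix", call. = FALSE)
  if (nrow(img) < min_side || ncol(img) < min_side)
    stop("image smaller than required minimum side ", min_side, call. = FALSE)
  if (anyNA(img) || any(!is.finite(img)))
    stop("image contains non-finite intensities", call. = FALSE)
  invisible(img)
}

#' Convert an RGB image to grayscale luminance
#'
#' Uses the ITU-R BT.601 luma weights 0.2989 R + 0.5870 G + 0.1140 B,
#' the conventional choice for texture analysis on stained tissue images.
#'
#' @param img an H x W x 3 array with intensities in \[0, 255\].
#' @return an H x W numeric matrix on the same intensity scale.
#' @export
rgb_to_gray <- function(img) {
  assert_rgb_image(img)
  0.2989 * img[, , 1] + 0.5870 * img[, , 2] + 0.1140 * img[, , 3]
}

#' Quantize a grayscale image to a small number of levels
#'
#' Equal-width binning of \[0, 255\] into `levels` gray levels, as used to
#' build co-occurrence matrices.
#'
#' @param gray H x W matrix in \[0, 255\].
#' @param levels number of output gray levels.
#' @return integer matrix with values in `0..levels-1`.
#' @export
quantize_gray <- function(gray, levels = 8L) {
  assert_gray_image(gray)
  stopifnot(levels >= 2L)
  q <- floor(gray / 256 * levels)
  q[q > levels - 1L] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}

# Symmetric (reflective, edge-repeating) padding of a matrix.
reflect_pad <- function(mat, top = 0L, bottom = 0L, left = 0L, right = 0L) {
  n <- nrow(mat); m <- ncol(mat)
  if (top > n || bottom > n || left > m || right > m)
    stop("padding exceeds image size", call. = FALSE)
  ri <- c(rev(seq_len(top)), seq_len(n), n - seq_len(bottom) + 1L)
  ci <- c(rev(seq_len(left)), seq_len(m), m - seq_len(right) + 1L)
  mat[ri, ci, drop = FALSE]
}

clip_255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' Quantize an enhanced image back to 8-bit integers
#'
#' @param img RGB array or grayscale matrix with real-valued intensities.
#' @return the same structure rounded to whole numbers and clipped to
#'   \[0, 255\].
#' @export
quantize_image <- function(img) {
  clip_255(round(img))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read an 8-bit image file as an RGB array
#'
#' Reads PNG images, promoting grayscale to three identical channels and
#' dropping any alpha channel.
#'
#' @param path path to a PNG file.
#' @return H x W x 3 array with intensities in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  x <- png::readPNG(path)
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] == 2L) x <- array(rep(x[, , 1], 3L), dim = c(dim(x)[1:2], 3L))
  if (dim(x)[3] >= 4L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' Write an RGB array as an 8-bit PNG file
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_rgb_image(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}
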