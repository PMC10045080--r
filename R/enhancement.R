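# Image enhancement chain: gray-world colour balance, neighbourhood
# averaging, and contrast-limited adaptive histogram equalisation
# (CLAHE), composed in that fixed order. All stages work in doubles;
# quantization back to 8-bit integers happens once, after the full chain.

#' Gray-world colour balance
#'
#' Scales each channel by (global mean / channel mean) so the three
#' channel means coincide, then clips to \[0, 255\]. A channel whose mean
#' is zero (an all-black channel) is left untouched with a warning.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @return colour-balanced image (doubles, same shape).
#' @export
gray_world_balance <- function(img) {
  assert_rgb_image(img)
  ch_means <- apply(img, 3, mean)
  g <- mean(ch_means)
  out <- img
  for (c in 1:3) {
    if (ch_means[c] == 0) {
      warning("channel ", c, " has zero mean; scaling skipped")
      next
    }
    out[, , c] <- img[, , c] * (g / ch_means[c])
  }
  clip_255(out)
}

#' Configuration for the neighbourhood averaging filter
#'
#' The default reproduces a 4 x 4 (16-pixel) window whose centre pixel is
#' excluded from the average, so each pixel is replaced by the mean of
#' its N = 15 configured neighbours. Because an even window has no
#' symmetric centre, the default anchors the window with the centre
#' pixel at its top-left cell (offsets 0..3 in both directions); odd
#' windows are centred conventionally. A standard 3 x 3 / N = 9 mode is
#' available via `average_filter_config(3, 3, include_center = TRUE)`.
#'
#' @param window_height,window_width window dimensions (positive).
#' @param include_center whether the centre pixel takes part in the mean.
#' @param anchor `"auto"` (top-left for even windows, centred for odd),
#'   `"topleft"`, or `"center"` (floor-centred for even sizes).
#' @return an `average_filter_config` list with the offset grid and N.
#' @export
average_filter_config <- function(window_height = 4L, window_width = 4L,
                                  include_center = FALSE,
                                  anchor = c("auto", "topleft", "center")) {
  anchor <- match.arg(anchor)
  stopifnot(window_height >= 1L, window_width >= 1L)
  off <- function(k) {
    use_topleft <- anchor == "topleft" ||
      (anchor == "auto" && k %% 2L == 0L)
    if (use_topleft) 0L:(k - 1L) else seq_len(k) - 1L - (k - 1L) %/% 2L
  }
  dr <- off(window_height); dc <- off(window_width)
  grid <- expand.grid(dr = dr, dc = dc)
  if (!include_center) grid <- grid[!(grid$dr == 0L & grid$dc == 0L), ]
  n <- nrow(grid)
  if (n < 1L) stop("filter must use at least one pixel", call. = FALSE)
  structure(list(window_height = window_height, window_width = window_width,
                 include_center = include_center, offsets = grid, N = n),
            class = "average_filter_config")
}

avg_filter_channel <- function(mat, cfg) {
  g <- cfg$offsets
  top <- max(0L, -min(g$dr)); bottom <- max(0L, max(g$dr))
  left <- max(0L, -min(g$dc)); right <- max(0L, max(g$dc))
  p <- reflect_pad(mat, top, bottom, left, right)
  n <- nrow(mat); m <- ncol(mat)
  acc <- matrix(0, n, m)
  for (k in seq_len(nrow(g))) {
    acc <- acc + p[top + g$dr[k] + seq_len(n), left + g$dc[k] + seq_len(m)]
  }
  acc / cfg$N
}

#' Neighbourhood averaging filter
#'
#' Replaces each pixel by the mean of its N configured neighbours
#' (borders handled by reflective padding); applied per channel for RGB
#' input.
#'
#' @param img RGB array or grayscale matrix in \[0, 255\].
#' @param cfg an [average_filter_config()].
#' @return smoothed image of the same type (doubles).
#' @export
average_filter <- function(img, cfg = average_filter_config()) {
  stopifnot(inherits(cfg, "average_filter_config"))
  gray <- is.matrix(img)
  h <- if (gray) nrow(img) else dim(img)[1]
  w <- if (gray) ncol(img) else dim(img)[2]
  if (h < cfg$window_height || w < cfg$window_width)
    stop("window larger than image", call. = FALSE)
  if (gray) return(avg_filter_channel(img, cfg))
  out <- img
  for (c in 1:3) out[, , c] <- avg_filter_channel(img[, , c], cfg)
  out
}

#' Configuration for CLAHE contrast enhancement
#'
#' @param tiles_y,tiles_x number of tiles along each axis.
#' @param clip_limit histogram clip level as a fraction of the tile pixel
#'   count; larger values allow stronger equalisation.
#' @param n_gray_levels number of intensity levels (256 for 8-bit input).
#' @param channels apply on the luminance channel with chroma preserved
#'   (default) or independently per RGB channel.
#' @return a `clahe_config` list.
#' @export
clahe_config <- function(tiles_y = 8L, tiles_x = 8L, clip_limit = 0.01,
                         n_gray_levels = 256L,
                         channels = c("luminance", "rgb")) {
  stopifnot(tiles_y >= 1L, tiles_x >= 1L, clip_limit > 0, n_gray_levels >= 2L)
  structure(list(tiles_y = tiles_y, tiles_x = tiles_x,
                 clip_limit = clip_limit, n_gray_levels = n_gray_levels,
                 channels = match.arg(channels)),
            class = "clahe_config")
}

# Build the per-tile clipped-equalisation mappings for one intensity
# channel, then apply them with bilinear interpolation between tile
# centres. `chan` is a matrix on the 0..255 scale; the returned matrix
# is on the same scale.
clahe_channel <- function(chan, cfg) {
  L <- cfg$n_gray_levels
  h <- nrow(chan); w <- ncol(chan)
  ty <- min(cfg$tiles_y, h); tx <- min(cfg$tiles_x, w)
  tpos <- chan / 256 * L
  lev <- floor(tpos)
  lev[lev > L - 1L] <- L - 1L
  frac <- tpos - lev   # sub-level residual, carried through the mapping
  # tile index per row/column (near-equal tiles)
  row_tile <- ceiling(seq_len(h) / h * ty)
  col_tile <- ceiling(seq_len(w) / w * tx)
  maps <- matrix(0, ty * tx, L)       # mapping: intensity level -> output level
  centers_y <- numeric(ty); centers_x <- numeric(tx)
  for (i in seq_len(ty)) centers_y[i] <- mean(which(row_tile == i))
  for (j in seq_len(tx)) centers_x[j] <- mean(which(col_tile == j))
  for (i in seq_len(ty)) for (j in seq_len(tx)) {
    vals <- lev[row_tile == i, col_tile == j]
    npix <- length(vals)
    hst <- tabulate(as.vector(vals) + 1L, nbins = L)
    if (sum(hst > 0) <= 1L) {
      # degenerate tile (single intensity): identity mapping
      maps[(i - 1L) * tx + j, ] <- seq_len(L) - 1L
      next
    }
    clip <- cfg$clip_limit * npix
    if (clip < 1) clip <- 1
    excess <- sum(pmax(hst - clip, 0))
    hst <- pmin(hst, clip) + excess / L
    cdf <- cumsum(hst) / sum(hst)
    maps[(i - 1L) * tx + j, ] <- cdf * (L - 1L)
  }
  # bilinear interpolation between the four surrounding tile mappings
  interp_idx <- function(pos, centers) {
    k <- findInterval(pos, centers)
    lo <- pmax(k, 1L); hi <- pmin(k + 1L, length(centers))
    lo <- pmin(lo, length(centers))
    span <- centers[hi] - centers[lo]
    wgt <- ifelse(span > 0, (pos - centers[lo]) / span, 0)
    wgt[pos <= centers[1]] <- 0
    list(lo = lo, hi = hi, w = wgt)
  }
  ry <- interp_idx(seq_len(h), centers_y)
  rx <- interp_idx(seq_len(w), centers_x)
  lo_y <- matrix(ry$lo, h, w); hi_y <- matrix(ry$hi, h, w)
  wy <- matrix(ry$w, h, w)
  lo_x <- matrix(rx$lo, h, w, byrow = TRUE); hi_x <- matrix(rx$hi, h, w, byrow = TRUE)
  wx <- matrix(rx$w, h, w, byrow = TRUE)
  li <- lev + 1L
  tidx <- function(tyi, txi) (tyi - 1L) * tx + txi
  out <- (1 - wy) * (1 - wx) * maps[cbind(as.vector(tidx(lo_y, lo_x)), as.vector(li))] +
         (1 - wy) * wx       * maps[cbind(as.vector(tidx(lo_y, hi_x)), as.vector(li))] +
         wy       * (1 - wx) * maps[cbind(as.vector(tidx(hi_y, lo_x)), as.vector(li))] +
         wy       * wx       * maps[cbind(as.vector(tidx(hi_y, hi_x)), as.vector(li))]
  pmin((matrix(out, h, w) + frac) / L * 256, 255)
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Per-tile clipped-histogram equalisation with bilinear interpolation
#' between tile mappings. By default the equalisation acts on the
#' luminance channel and the RGB channels are rescaled proportionally so
#' chroma is preserved; a per-channel mode is available. Tiles whose
#' pixels share a single intensity map to themselves (identity), so
#' constant images pass through unchanged.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param cfg a [clahe_config()].
#' @return contrast-enhanced image (doubles, same shape, in \[0, 255\]).
#' @export
clahe <- function(img, cfg = clahe_config()) {
  assert_rgb_image(img)
  stopifnot(inherits(cfg, "clahe_config"))
  if (cfg$channels == "rgb") {
    out <- img
    for (c in 1:3) out[, , c] <- clahe_channel(img[, , c], cfg)
    return(clip_255(out))
  }
  lum <- rgb_to_gray(img)
  new_lum <- clahe_channel(lum, cfg)
  out <- img
  nz <- lum > 0
  for (c in 1:3) {
    ch <- img[, , c]
    ch[nz] <- ch[nz] * (new_lum[nz] / lum[nz])
    ch[!nz] <- new_lum[!nz]
    out[, , c] <- ch
  }
  clip_255(out)
}

#' Full enhancement chain
#'
#' Composes gray-world balance, the neighbourhood averaging filter and
#' CLAHE, in that fixed order, then (by default) quantizes the result
#' back to 8-bit integers in a single final step.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param avg_cfg an [average_filter_config()].
#' @param clahe_cfg a [clahe_config()].
#' @param quantize round and clip the final image to integers.
#' @return enhanced image (same shape).
#' @export
enhance <- function(img, avg_cfg = average_filter_config(),
                    clahe_cfg = clahe_config(), quantize = TRUE) {
  out <- clahe(average_filter(gray_world_balance(img), avg_cfg), clahe_cfg)
  if (quantize) out <- quantize_image(out)
  out
}
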