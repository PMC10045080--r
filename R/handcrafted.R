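# Four handcrafted descriptors and their 244-dimensional concatenation:
#   - Haar wavelet subband statistics (12 features)
#   - local binary pattern histogram  (203 features)
#   - fuzzy colour histogram          (16 features)
#   - GLCM / Haralick statistics      (13 features)

# ---------------------------------------------------------------------------
# Discrete wavelet transform (single-level orthonormal Haar)

#' Single-level orthonormal Haar wavelet decomposition
#'
#' Splits the image into approximation (LL) and detail (LH, HL, HH)
#' subbands. With the orthonormal convention each 2 x 2 block
#' \[\[a, b\], \[c, d\]\] maps to LL = (a+b+c+d)/2, LH = (a+b-c-d)/2,
#' HL = (a-b+c-d)/2 and HH = (a-b-c+d)/2, so the total squared energy is
#' conserved. Odd dimensions are cropped by one pixel.
#'
#' @param gray H x W matrix.
#' @return list with matrices `LL`, `LH`, `HL`, `HH`.
#' @export
dwt_haar <- function(gray) {
  assert_gray_image(gray, min_side = 2L)
  h <- nrow(gray) %/% 2L * 2L
  w <- ncol(gray) %/% 2L * 2L
  x <- gray[seq_len(h), seq_len(w), drop = FALSE]
  oi <- seq(1L, h, by = 2L); oj <- seq(1L, w, by = 2L)
  a <- x[oi, oj, drop = FALSE];      b <- x[oi, oj + 1L, drop = FALSE]
  cc <- x[oi + 1L, oj, drop = FALSE]; d <- x[oi + 1L, oj + 1L, drop = FALSE]
  list(LL = (a + b + cc + d) / 2, LH = (a + b - cc - d) / 2,
       HL = (a - b + cc - d) / 2, HH = (a - b - cc + d) / 2)
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Wavelet subband statistics (12 features)
#'
#' Mean, variance and standard deviation of each of the four single-level
#' Haar subbands, in the fixed order LL, LH, HL, HH. Variances are
#' population variances (divide by n), so 1 x 1 subbands yield 0.
#'
#' @param gray H x W matrix in \[0, 255\].
#' @return named numeric vector of length 12.
#' @export
dwt_features <- function(gray) {
  sb <- dwt_haar(gray)
  out <- unlist(lapply(sb, function(m) {
    v <- pop_var(m)
    c(mean = mean(m), var = v, sd = sqrt(v))
  }))
  names(out) <- paste0("dwt_", names(out))
  out
}

# ---------------------------------------------------------------------------
# Local binary patterns

#' Configuration for the local binary pattern descriptor
#'
#' Defaults follow the pipeline's settings: P = 15 circular neighbours at
#' radius R = 2, with the 2^15 possible codes binned into 203 equal-width
#' histogram bins.
#'
#' @param P number of circular neighbours (>= 4).
#' @param R sampling radius in pixels.
#' @param n_bins histogram length (>= 2).
#' @return an `lbp_config` list.
#' @export
lbp_config <- function(P = 15L, R = 2L, n_bins = 203L) {
  stopifnot(P >= 4L, R >= 1, n_bins >= 2L)
  structure(list(P = P, R = R, n_bins = n_bins), class = "lbp_config")
}

# Neighbour offsets on the radius-R circle, counter-clockwise from angle
# 0. Offsets within 1e-9 of an integer are snapped so axis-aligned
# neighbours are sampled exactly; others are bilinearly interpolated.
lbp_offsets <- function(cfg) {
  th <- 2 * pi * (seq_len(cfg$P) - 1L) / cfg$P
  dx <- cfg$R * cos(th)
  dy <- -cfg$R * sin(th)
  snap <- function(v) ifelse(abs(v - round(v)) < 1e-9, round(v), v)
  list(dy = snap(dy), dx = snap(dx))
}

# Sample intensities at fractional offsets for every pixel of the valid
# region, by bilinear interpolation of four integer-shifted copies.
# Sampled values are rounded at 1e-8 before thresholding, a stated
# convention that stabilises exact ties between the centre and an
# interpolated neighbour.
lbp_sample <- function(gray, rows, cols, dy, dx) {
  fy <- floor(dy); fx <- floor(dx)
  wy <- dy - fy; wx <- dx - fx
  fy2 <- fy + (wy > 0); fx2 <- fx + (wx > 0)  # avoid indexing past the margin
  g <- function(dr, dc) gray[rows + dr, cols + dc, drop = FALSE]
  v <- (1 - wy) * (1 - wx) * g(fy, fx) +
       (1 - wy) * wx       * g(fy, fx2) +
       wy       * (1 - wx) * g(fy2, fx) +
       wy       * wx       * g(fy2, fx2)
  round(v, 8)
}

#' Local binary pattern codes for every valid pixel
#'
#' The code of a pixel with intensity `gc` is `sum_p s(gp - gc) 2^p`
#' where `s(x) = 1` for `x >= 0` (ties count as 1) and the `gp` are P
#' neighbours sampled counter-clockwise on the radius-R circle with
#' bilinear interpolation. Pixels closer than `ceiling(R)` to the border
#' have no valid neighbourhood and are excluded.
#'
#' @param gray H x W matrix.
#' @param cfg an [lbp_config()].
#' @return numeric matrix of codes for the valid interior region.
#' @export
lbp_codes <- function(gray, cfg = lbp_config()) {
  assert_gray_image(gray)
  m <- ceiling(cfg$R)
  if (nrow(gray) < 2 * m + 1L || ncol(gray) < 2 * m + 1L)
    stop("image too small for LBP radius ", cfg$R, call. = FALSE)
  rows <- (m + 1L):(nrow(gray) - m)
  cols <- (m + 1L):(ncol(gray) - m)
  off <- lbp_offsets(cfg)
  gc <- gray[rows, cols, drop = FALSE]
  code <- matrix(0, length(rows), length(cols))
  for (p in seq_len(cfg$P)) {
    gp <- lbp_sample(gray, rows, cols, off$dy[p], off$dx[p])
    code <- code + (gp >= gc) * 2^(p - 1L)
  }
  code
}

#' Local binary pattern code for a single pixel
#'
#' @param gray H x W matrix.
#' @param cfg an [lbp_config()].
#' @param row,col pixel position (must be at least `ceiling(R)` from the
#'   border).
#' @return the integer-valued code in `[0, 2^P - 1]`.
#' @export
lbp_code <- function(gray, cfg = lbp_config(), row, col) {
  m <- ceiling(cfg$R)
  if (row <= m || col <= m || row > nrow(gray) - m || col > ncol(gray) - m)
    stop("pixel has no valid LBP neighbourhood", call. = FALSE)
  off <- lbp_offsets(cfg)
  gc <- gray[row, col]
  sum(vapply(seq_len(cfg$P), function(p) {
    gp <- lbp_sample(gray, row, col, off$dy[p], off$dx[p])[1, 1]
    (gp >= gc) * 2^(p - 1L)
  }, numeric(1)))
}

#' Local binary pattern histogram (203 features)
#'
#' Normalised histogram (summing to 1) of the LBP codes of all valid
#' pixels, over `n_bins` equal-width bins spanning `[0, 2^P - 1]`.
#'
#' @param gray H x W matrix.
#' @param cfg an [lbp_config()].
#' @return named numeric vector of length `cfg$n_bins`.
#' @export
lbp_features <- function(gray, cfg = lbp_config()) {
  code <- lbp_codes(gray, cfg)
  if (length(code) == 0L) stop("no valid LBP pixels", call. = FALSE)
  breaks <- seq(0, 2^cfg$P - 1, length.out = cfg$n_bins + 1L)
  bin <- .bincode(as.vector(code), breaks, right = TRUE, include.lowest = TRUE)
  h <- tabulate(bin, nbins = cfg$n_bins)
  out <- h / sum(h)
  names(out) <- sprintf("lbp_bin%03d", seq_len(cfg$n_bins))
  out
}

# ---------------------------------------------------------------------------
# Fuzzy colour histogram

#' Configuration for the fuzzy colour histogram
#'
#' Bin centres are obtained once per seed by fuzzy c-means clustering of
#' a fixed 4 x 4 x 4 RGB lattice into `n_bins` colour prototypes
#' (deterministic given the seed), or may be supplied directly.
#'
#' @param n_bins number of colour bins (16).
#' @param m fuzziness exponent (> 1).
#' @param seed seed for the c-means initialisation.
#' @param bin_centers optional `n_bins` x 3 matrix of RGB centres.
#' @return an `fch_config` list with resolved `bin_centers`.
#' @export
fch_config <- function(n_bins = 16L, m = 2, seed = 7L, bin_centers = NULL) {
  stopifnot(n_bins >= 2L, m > 1)
  if (is.null(bin_centers)) bin_centers <- fch_bin_centers(n_bins, m, seed)
  bin_centers <- as.matrix(bin_centers)
  stopifnot(nrow(bin_centers) == n_bins, ncol(bin_centers) == 3L)
  if (anyDuplicated(bin_centers) > 0)
    stop("bin centres must be distinct", call. = FALSE)
  structure(list(n_bins = n_bins, m = m, seed = seed,
                 bin_centers = bin_centers), class = "fch_config")
}

#' Derive fuzzy colour histogram bin centres
#'
#' Runs fuzzy c-means (via \pkg{e1071}) on the 64 centres of a 4 x 4 x 4
#' partition of RGB space, with a seeded draw of the initial prototypes,
#' yielding a deterministic set of `n_bins` colour centres.
#'
#' @param n_bins number of centres.
#' @param m fuzziness exponent.
#' @param seed integer seed.
#' @return `n_bins` x 3 matrix of RGB centres in \[0, 255\].
#' @export
fch_bin_centers <- function(n_bins = 16L, m = 2, seed = 7L) {
  ax <- (seq_len(4L) - 0.5) / 4 * 255
  lattice <- as.matrix(expand.grid(R = ax, G = ax, B = ax))
  with_preserved_seed(seed, {
    init <- lattice[sample.int(nrow(lattice), n_bins), , drop = FALSE]
    fit <- e1071::cmeans(lattice, centers = init, m = m, iter.max = 300L,
                         method = "cmeans")
    unname(fit$centers)
  })
}

#' Fuzzy colour histogram (16 features)
#'
#' Each pixel spreads a unit of mass over all colour bins with fuzzy
#' c-means memberships `u_k \propto (1 / d_k^2)^(1 / (m - 1))`, where
#' `d_k` is the distance to bin centre k. A pixel lying exactly on a
#' centre takes full membership there (limit convention). The histogram
#' is the total membership mass per bin, normalised to sum to 1.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param cfg an [fch_config()].
#' @return named numeric vector of length `cfg$n_bins` summing to 1.
#' @export
fch_features <- function(img, cfg = fch_config()) {
  assert_rgb_image(img)
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
              as.vector(img[, , 3]))
  ctr <- cfg$bin_centers
  d2 <- outer(rowSums(px^2), rep(1, nrow(ctr))) -
    2 * px %*% t(ctr) + outer(rep(1, nrow(px)), rowSums(ctr^2))
  d2[d2 < 0] <- 0
  w <- d2^(-1 / (cfg$m - 1))
  exact <- !is.finite(w) | d2 == 0
  u <- w / rowSums(w)
  hit <- which(rowSums(exact) > 0)
  if (length(hit)) {
    u[hit, ] <- exact[hit, , drop = FALSE] /
      rowSums(exact[hit, , drop = FALSE])
  }
  out <- colSums(u) / nrow(u)
  names(out) <- sprintf("fch_bin%02d", seq_len(cfg$n_bins))
  out
}

# ---------------------------------------------------------------------------
# Grey-level co-occurrence matrices and Haralick statistics

glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Grey-level co-occurrence matrix
#'
#' Counts co-occurring level pairs at offset (d, angle), symmetrised
#' (each pair counted in both directions) and normalised to
#' probabilities. The input must already be quantized to `levels` gray
#' levels (see [quantize_gray()]).
#'
#' @param qimg integer matrix with values in `0..levels-1`.
#' @param d offset distance (>= 1).
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @param levels number of gray levels.
#' @return a `glcm` object: list with `prob` (levels x levels matrix
#'   summing to 1), `d`, `angle`, `levels`.
#' @export
glcm_matrix <- function(qimg, d = 1L, angle = 0, levels = 8L) {
  stopifnot(is.matrix(qimg), d >= 1L)
  if (min(qimg) < 0 || max(qimg) > levels - 1L)
    stop("image must be quantized to 0..levels-1", call. = FALSE)
  off <- glcm_offset(angle, as.integer(d))
  h <- nrow(qimg); w <- ncol(qimg)
  ri <- seq_len(h); ci <- seq_len(w)
  r2 <- ri + off[1]; c2 <- ci + off[2]
  rok <- ri[r2 >= 1L & r2 <= h]; cok <- ci[c2 >= 1L & c2 <= w]
  if (length(rok) == 0L || length(cok) == 0L)
    stop("image too small for offset d = ", d, call. = FALSE)
  a <- qimg[rok, cok, drop = FALSE]
  b <- qimg[rok + off[1], cok + off[2], drop = FALSE]
  idx <- as.vector(a) * levels + as.vector(b) + 1L
  counts <- matrix(tabulate(idx, nbins = levels^2), levels, levels,
                   byrow = TRUE)
  counts <- counts + t(counts)
  structure(list(prob = counts / sum(counts), d = as.integer(d),
                 angle = angle, levels = levels), class = "glcm")
}

# log2 with the 0 * log 0 = 0 convention
xlog2 <- function(p) ifelse(p > 0, log2(p), 0)

haralick_names <- c("asm", "contrast", "correlation", "variance", "idm",
                    "sum_average", "sum_variance", "sum_entropy", "entropy",
                    "diff_variance", "diff_entropy", "imc1", "imc2")

# The 13 classical co-occurrence statistics of a single normalised GLCM.
haralick13 <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(L) - muy)^2 * py))
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sx * sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  variance <- sum((i - mux)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  # distributions of i + j (2..2L) and |i - j| (0..L-1)
  psum <- vapply(2:(2 * L), function(k) sum(P[i + j == k]), numeric(1))
  pdif <- vapply(0:(L - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * L); kd <- 0:(L - 1)
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(psum * xlog2(psum))
  entropy <- -sum(P * xlog2(P))
  mud <- sum(kd * pdif)
  diff_variance <- sum((kd - mud)^2 * pdif)
  diff_entropy <- -sum(pdif * xlog2(pdif))
  hx <- -sum(px * xlog2(px)); hy <- -sum(py * xlog2(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * xlog2(pxy))
  hxy2 <- -sum(pxy * xlog2(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  stats::setNames(c(asm, contrast, correlation, variance, idm, sum_average,
                    sum_variance, sum_entropy, entropy, diff_variance,
                    diff_entropy, imc1, imc2), haralick_names)
}

#' Haralick texture statistics (13 features)
#'
#' The 13 classical co-occurrence statistics (angular second moment,
#' contrast, correlation, variance, inverse difference moment, sum
#' average, sum variance, sum entropy, entropy, difference variance,
#' difference entropy, and the two information measures of correlation),
#' each averaged over the supplied co-occurrence matrices (conventionally
#' the four angles at a fixed distance). Entropies use log base 2 with
#' `0 log 0 = 0`.
#'
#' @param glcms a `glcm` or a list of `glcm` objects.
#' @return named numeric vector of length 13.
#' @export
haralick_features <- function(glcms) {
  if (inherits(glcms, "glcm")) glcms <- list(glcms)
  stopifnot(length(glcms) >= 1L, all(vapply(glcms, inherits, TRUE, "glcm")))
  for (g in glcms) {
    if (abs(sum(g$prob) - 1) > 1e-8)
      stop("GLCM probabilities must sum to 1", call. = FALSE)
  }
  mats <- vapply(glcms, function(g) haralick13(g$prob),
                 numeric(length(haralick_names)))
  out <- rowMeans(mats)
  names(out) <- paste0("glcm_", haralick_names)
  out
}

# ---------------------------------------------------------------------------

#' Full handcrafted descriptor (244 features)
#'
#' Concatenation of the four descriptors in the fixed order
#' DWT (12) | LBP (203) | FCH (16) | GLCM (13), computed on the grayscale
#' conversion for the texture descriptors and on the RGB image for the
#' colour histogram. Feature names record the source descriptor.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param lbp an [lbp_config()].
#' @param fch an [fch_config()].
#' @param glcm_d co-occurrence distance.
#' @param glcm_levels number of gray levels for the co-occurrence matrix.
#' @return named numeric vector of length 244 at the default settings.
#' @export
handcrafted_vector <- function(img, lbp = lbp_config(), fch = fch_config(),
                               glcm_d = 1L, glcm_levels = 8L) {
  assert_rgb_image(img, min_side = 8L)
  gray <- rgb_to_gray(img)
  q <- quantize_gray(gray, glcm_levels)
  glcms <- lapply(c(0, 45, 90, 135), function(a)
    glcm_matrix(q, d = glcm_d, angle = a, levels = glcm_levels))
  c(dwt_features(gray), lbp_features(gray, lbp), fch_features(img, fch),
    haralick_features(glcms))
}

#' Handcrafted feature matrix for a set of images
#'
#' @param images list of RGB arrays.
#' @param labels class label per image.
#' @param ... passed to [handcrafted_vector()].
#' @return a [feature_matrix()] with one 244-dimensional row per image.
#' @export
handcrafted_feature_matrix <- function(images, labels, ...) {
  vecs <- t(sapply(images, handcrafted_vector, ...))
  feature_matrix(vecs, labels, source_tag = "handcrafted")
}
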