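# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately use naive double loops and, where
# a convention is shared with the implementation (sampling order,
# tie rounding), restate it explicitly rather than calling package code.

# mean filter by direct double loop with symmetric reflective padding
oracle_avg_filter <- function(mat, offsets) {
  n <- nrow(mat); m <- ncol(mat)
  reflect <- function(i, k) {
    while (i < 1L || i > k) {
      if (i < 1L) i <- 1L - i
      if (i > k) i <- 2L * k + 1L - i
    }
    i
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- 0
    for (q in seq_len(nrow(offsets))) {
      s <- s + mat[reflect(i + offsets$dr[q], n), reflect(j + offsets$dc[q], m)]
    }
    out[i, j] <- s / nrow(offsets)
  }
  out
}

# per-pixel LBP codes by direct loops; P neighbours counter-clockwise
# from angle 0 at radius R, bilinear interpolation, offsets snapped to
# integers within 1e-9, sampled values rounded at 1e-8, s(0) = 1
oracle_lbp_codes <- function(gray, P, R) {
  m <- ceiling(R)
  h <- nrow(gray); w <- ncol(gray)
  out <- matrix(NA_real_, h - 2 * m, w - 2 * m)
  for (i in (m + 1):(h - m)) for (j in (m + 1):(w - m)) {
    gc <- gray[i, j]
    code <- 0
    for (p in 0:(P - 1)) {
      th <- 2 * pi * p / P
      dy <- -R * sin(th); dx <- R * cos(th)
      if (abs(dy - round(dy)) < 1e-9) dy <- round(dy)
      if (abs(dx - round(dx)) < 1e-9) dx <- round(dx)
      y <- i + dy; x <- j + dx
      y0 <- floor(y); x0 <- floor(x)
      fy <- y - y0; fx <- x - x0
      y1 <- if (fy > 0) y0 + 1 else y0
      x1 <- if (fx > 0) x0 + 1 else x0
      gp <- (1 - fy) * (1 - fx) * gray[y0, x0] +
            (1 - fy) * fx * gray[y0, x1] +
            fy * (1 - fx) * gray[y1, x0] +
            fy * fx * gray[y1, x1]
      gp <- round(gp, 8)
      if (gp >= gc) code <- code + 2^p
    }
    out[i - m, j - m] <- code
  }
  out
}

# symmetric co-occurrence counts by explicit pair enumeration
oracle_glcm_counts <- function(qimg, d, angle, levels) {
  off <- switch(as.character(angle),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  cnt <- matrix(0, levels, levels)
  for (i in seq_len(nrow(qimg))) for (j in seq_len(ncol(qimg))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 >= 1 && i2 <= nrow(qimg) && j2 >= 1 && j2 <= ncol(qimg)) {
      a <- qimg[i, j] + 1L; b <- qimg[i2, j2] + 1L
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1
    }
  }
  cnt
}

# pooling by explicit window scan
oracle_pool2d <- function(map, k, p, mode) {
  i0 <- seq(1, nrow(map) - k + 1, by = p)
  j0 <- seq(1, ncol(map) - k + 1, by = p)
  out <- matrix(0, length(i0), length(j0))
  for (a in seq_along(i0)) for (b in seq_along(j0)) {
    win <- map[i0[a]:(i0[a] + k - 1), j0[b]:(j0[b] + k - 1)]
    out[a, b] <- if (mode == "max") max(win) else mean(win)
  }
  out
}

# AUC by all-pairs counting with ties worth 1/2
oracle_auc_pairs <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  100 * tot / (length(pos) * length(neg))
}

# one-vs-rest metrics recomputed from raw label pairs, no matrix algebra
oracle_ovr_metrics <- function(true, pred, cls) {
  tp <- sum(true == cls & pred == cls)
  fn <- sum(true == cls & pred != cls)
  fp <- sum(true != cls & pred == cls)
  tn <- sum(true != cls & pred != cls)
  pct <- function(a, b) if (b == 0) NA_real_ else 100 * a / b
  c(sensitivity = pct(tp, tp + fn), precision = pct(tp, tp + fp),
    accuracy = pct(tp + tn, tp + tn + fp + fn),
    specificity = pct(tn, tn + fp))
}

# plain global histogram equalization on the 0..255 scale
oracle_histeq <- function(chan, L = 256) {
  lev <- pmin(floor(chan / 256 * L), L - 1)
  cdf <- cumsum(tabulate(lev + 1, nbins = L)) / length(lev)
  matrix(cdf[lev + 1] * (L - 1) / L * 256, nrow(chan), ncol(chan))
}

# small random helpers
rand_gray <- function(n, m = n, lo = 0, hi = 255) {
  matrix(sample(lo:hi, n * m, replace = TRUE), n, m)
}
rand_rgb <- function(n, m = n) {
  array(sample(0:255, n * m * 3, replace = TRUE), c(n, m, 3))
}
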