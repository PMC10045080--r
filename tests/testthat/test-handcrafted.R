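# --- wavelet subband statistics -------------------------------------------

test_that("Haar butterfly matches hand-computed coefficients", {
  sb <- dwt_haar(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(sb$LL[1, 1], 5)
  expect_equal(sb$LH[1, 1], -2)
  expect_equal(sb$HL[1, 1], -1)
  expect_equal(sb$HH[1, 1], 0)
})

test_that("constant images have detail-free wavelet statistics", {
  f <- dwt_features(matrix(60, 8, 8))
  expect_length(f, 12L)
  expect_equal(unname(f["dwt_LL.mean"]), 120)       # orthonormal scaling: 2c
  expect_equal(unname(f[c("dwt_LL.var", "dwt_LH.mean", "dwt_LH.var",
                          "dwt_HL.mean", "dwt_HH.sd")]), rep(0, 5))
})

test_that("single-level Haar conserves energy and crops odd sizes", {
  for (s in 1:20) {
    set.seed(s)
    g <- rand_gray(sample(4:16, 1), sample(4:16, 1))
    sb <- dwt_haar(g)
    h <- nrow(g) %/% 2 * 2; w <- ncol(g) %/% 2 * 2
    expect_equal(sum(sapply(sb, function(m) sum(m^2))),
                 sum(g[1:h, 1:w]^2), tolerance = 1e-9)
  }
  expect_length(dwt_features(rand_gray(9, 11)), 12L)
})

# --- local binary patterns ------------------------------------------------

test_that("LBP threshold convention gives all-ones code on flat patches", {
  cfg <- lbp_config()
  g <- matrix(42, 9, 9)
  expect_equal(lbp_code(g, cfg, 5, 5), 2^15 - 1)
  expect_true(all(lbp_codes(g, cfg) == 2^15 - 1))
})

test_that("LBP code follows the sign-weighted bit sum on a linear patch", {
  # intensity 5 + 2*dy - 0.5*dx is exact under bilinear interpolation,
  # so neighbours p = 0..3 (upper half) fall below the centre and
  # p = 4..7 at or above it: bits 00001111 -> code 240
  cfg <- lbp_config(P = 8L, R = 1L)
  g <- outer(-1:1, -1:1, function(r, c) 5 + 2 * r - 0.5 * c)
  expect_equal(lbp_code(g, cfg, 2, 2), 240)
  expect_error(lbp_code(g, cfg, 1, 1), "neighbourhood")
})

test_that("LBP codes stay in range and match the double-loop oracle", {
  cfg <- lbp_config()
  for (s in 1:60) {
    set.seed(s)
    g <- rand_gray(sample(8:16, 1))
    codes <- lbp_codes(g, cfg)
    expect_true(all(codes >= 0 & codes <= 2^15 - 1))
    expect_identical(codes, oracle_lbp_codes(g, cfg$P, cfg$R))
  }
})

test_that("LBP histogram is the normalised binned code count", {
  cfg <- lbp_config()
  set.seed(99)
  g <- rand_gray(16)
  h <- lbp_features(g, cfg)
  expect_length(h, 203L)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  # independent binning of oracle codes with the same stated breaks
  codes <- as.vector(oracle_lbp_codes(g, cfg$P, cfg$R))
  breaks <- seq(0, 2^15 - 1, length.out = 204)
  ref <- as.vector(table(cut(codes, breaks, include.lowest = TRUE)))
  expect_equal(unname(h) * length(codes), ref)
  # constant image: all mass in the bin containing 2^P - 1
  hc <- lbp_features(matrix(9, 10, 10), cfg)
  expect_equal(unname(hc[203]), 1)
})

# --- fuzzy colour histogram -----------------------------------------------

test_that("fuzzy colour histogram honours the limit and mass conventions", {
  cfg <- fch_config(seed = 7)
  ctr <- round(cfg$bin_centers)
  # single-colour image exactly at a bin centre -> indicator histogram
  img1 <- array(rep(cfg$bin_centers[4, ], each = 16), c(4, 4, 3))
  h1 <- fch_features(img1, cfg)
  expect_equal(unname(h1[4]), 1)
  expect_equal(sum(h1), 1)
  # 50/50 two-colour image at two centres -> 0.5 / 0.5
  img2 <- array(0, c(4, 4, 3))
  for (c in 1:3) {
    img2[, 1:2, c] <- cfg$bin_centers[2, c]
    img2[, 3:4, c] <- cfg$bin_centers[9, c]
  }
  h2 <- fch_features(img2, cfg)
  expect_equal(unname(h2[c(2, 9)]), c(0.5, 0.5))
  expect_equal(sum(h2), 1, tolerance = 1e-9)
})

test_that("fuzzy colour histogram length, normalisation and determinism", {
  cfg <- fch_config(seed = 7)
  set.seed(8)
  img <- rand_rgb(12)
  h <- fch_features(img, cfg)
  expect_length(h, 16L)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_true(all(h >= 0))
  expect_identical(h, fch_features(img, fch_config(seed = 7)))
  # centres are distinct and reproducible per seed
  expect_identical(cfg$bin_centers, fch_bin_centers(16, 2, 7))
  expect_false(identical(cfg$bin_centers, fch_bin_centers(16, 2, 8)))
})

# --- co-occurrence matrices and Haralick statistics -----------------------

test_that("GLCM matches pair enumeration and normalises to 1", {
  # 2x2 worked example at d=1, 0 degrees
  q <- matrix(c(0L, 0L, 1L, 1L), 2, 2)       # [[0,1],[0,1]]
  gm <- glcm_matrix(q, 1, 0, levels = 2)
  expect_equal(gm$prob, matrix(c(0, .5, .5, 0), 2, 2))
  # constant image: single diagonal entry
  gc <- glcm_matrix(matrix(3L, 4, 4), 1, 90, levels = 8)
  expect_equal(gc$prob[4, 4], 1)
  expect_equal(sum(gc$prob), 1)
  # random images, all four angles, against the enumeration oracle
  for (s in 1:40) {
    set.seed(s)
    g <- rand_gray(sample(4:16, 1))
    q <- quantize_gray(g, 8)
    ang <- sample(c(0, 45, 90, 135), 1)
    gm <- glcm_matrix(q, 1, ang, 8)
    cnt <- oracle_glcm_counts(q, 1, ang, 8)
    expect_equal(gm$prob, cnt / sum(cnt))
    expect_equal(sum(gm$prob), 1, tolerance = 1e-12)
  }
  expect_error(glcm_matrix(matrix(0L, 1, 1), 2, 0, 8), "too small")
})

test_that("Haralick statistics match closed forms on simple matrices", {
  # degenerate distribution: one cell holds all the mass
  gm1 <- glcm_matrix(matrix(0L, 4, 4), 1, 0, levels = 2)
  h1 <- haralick_features(gm1)
  expect_length(h1, 13L)
  expect_equal(unname(h1[c("glcm_asm", "glcm_contrast", "glcm_entropy")]),
               c(1, 0, 0))
  # uniform 2-level GLCM: all four cells 0.25
  gm2 <- structure(list(prob = matrix(0.25, 2, 2), d = 1L, angle = 0,
                        levels = 2L), class = "glcm")
  h2 <- haralick_features(gm2)
  expect_equal(unname(h2["glcm_asm"]), 0.25)
  expect_equal(unname(h2["glcm_entropy"]), 2)
  expect_equal(unname(h2["glcm_contrast"]), 0.5)
  expect_error(haralick_features(structure(list(prob = matrix(1, 2, 2)),
                                           class = "glcm")), "sum to 1")
})

# --- concatenated handcrafted vector --------------------------------------

test_that("handcrafted vector is the 244-long ordered concatenation", {
  set.seed(10)
  img <- rand_rgb(16)
  v <- handcrafted_vector(img)
  expect_length(v, 244L)
  gray <- rgb_to_gray(img)
  expect_equal(v[1:12], dwt_features(gray))
  expect_equal(v[13:215], lbp_features(gray))
  expect_equal(v[216:231], fch_features(img))
  q <- quantize_gray(gray, 8)
  glcms <- lapply(c(0, 45, 90, 135), function(a) glcm_matrix(q, 1, a, 8))
  expect_equal(v[232:244], haralick_features(glcms))
  # pure function: identical input, identical output
  expect_identical(v, handcrafted_vector(img))
})

test_that("handcrafted feature matrix aligns rows with labels", {
  set.seed(11)
  imgs <- lapply(1:6, function(i) rand_rgb(16))
  fm <- handcrafted_feature_matrix(imgs, rep(c("a", "b", "c"), 2))
  expect_equal(dim(fm), c(6L, 244L))
  expect_equal(fm$values[3, ], handcrafted_vector(imgs[[3]]))
  expect_equal(fm$source_tag, "handcrafted")
})
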