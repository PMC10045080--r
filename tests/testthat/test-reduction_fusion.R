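test_that("PCA recovers an axis-aligned variance direction", {
  set.seed(30)
  x <- cbind(rnorm(40, sd = 3), 0, 0)
  x <- x - rep(colMeans(x), each = 40)
  mod <- pca_fit(x + 5, 2)
  expect_equal(abs(mod$components[1, ]), c(1, 0, 0), tolerance = 1e-10)
  expect_equal(mod$explained_variance[1], var(x[, 1]), tolerance = 1e-8)
  expect_equal(mod$explained_variance[2], 0, tolerance = 1e-10)
})

test_that("explained variance sums to the total variance of centred data", {
  set.seed(31)
  x <- matrix(rnorm(50 * 10), 50, 10) %*% diag(sqrt(1:10))
  mod <- pca_fit(x, 10)
  expect_equal(sum(mod$explained_variance), sum(apply(x, 2, var)),
               tolerance = 1e-10)
  expect_true(all(diff(mod$explained_variance) <= 1e-12))
  # components are orthonormal rows
  expect_equal(mod$components %*% t(mod$components), diag(10),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("full-rank PCA reconstruction and isometry hold", {
  set.seed(32)
  x <- matrix(rnorm(50 * 10), 50, 10)
  mod <- pca_fit(x, 10)
  sc <- pca_transform(mod, x)
  expect_equal(pca_inverse_transform(mod, sc), x, tolerance = 1e-8,
               ignore_attr = TRUE)
  # projection at full rank preserves pairwise distances
  d0 <- dist(x); d1 <- dist(sc)
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-8)
})

test_that("PCA transform centres training data and matches variances", {
  set.seed(33)
  fm <- feature_matrix(matrix(rnorm(60 * 6), 60, 6), rep(letters[1:5], 12))
  mod <- pca_fit(fm, 4)
  expect_equal(as.vector(pca_transform(mod, matrix(mod$mean, 1))),
               rep(0, 4), tolerance = 1e-10)
  sc <- pca_transform(mod, fm)
  expect_s3_class(sc, "feature_matrix")
  expect_equal(unname(apply(sc$values, 2, var)), mod$explained_variance,
               tolerance = 1e-10)
  expect_identical(sc$labels, fm$labels)
  expect_error(pca_transform(mod, matrix(0, 2, 5)), "dimension mismatch")
})

test_that("PCA fit validates its preconditions and sign convention", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(pca_fit(x, 3), "n_components")
  expect_error(pca_fit(matrix(1, 10, 2), 1), "zero-variance")
  # deterministic sign: largest-magnitude loading positive
  set.seed(34)
  for (s in 1:5) {
    y <- matrix(rnorm(30 * 4), 30, 4)
    mod <- pca_fit(y, 4)
    for (k in 1:4)
      expect_gt(mod$components[k, which.max(abs(mod$components[k, ]))], 0)
  }
})

make_branch <- function(n, d, tag, seed) {
  set.seed(seed)
  feature_matrix(matrix(rnorm(n * d), n, d), rep(letters[1:5], n / 5),
                 source_tag = tag)
}

test_that("fusion strategies produce the contracted dimensions", {
  a <- make_branch(40, 30, "deep_a", 40)
  b <- make_branch(40, 25, "deep_b", 41)
  hc <- make_branch(40, 12, "handcrafted", 42)
  f1 <- fuse(list(a), "separate", n_components = 8)
  expect_equal(ncol(f1$values), 8L)
  f2 <- fuse(list(a, b), "merge_after_pca", n_components = c(8, 7))
  expect_equal(ncol(f2$values), 15L)
  expect_true(any(grepl("^deep_a_PC", f2$feature_names)))
  expect_true(any(grepl("^deep_b_PC", f2$feature_names)))
  f3 <- fuse(list(a, b), "merge_before_pca", n_components = 10)
  expect_equal(ncol(f3$values), 10L)
  f4 <- fuse(list(a, hc), "cnn_plus_handcrafted", n_components = 9)
  expect_equal(ncol(f4$values), 21L)               # 9 + 12
  expect_true(any(grepl("handcrafted", f4$feature_names)))
})

test_that("fusion reaches the reference 910 and 740 widths at scale", {
  g <- make_branch(800, 500, "googlenet_like", 43)
  v <- make_branch(800, 500, "vgg_like", 44)
  f910 <- fuse(list(g, v), "merge_after_pca", n_components = 455)
  expect_equal(ncol(f910$values), 910L)
  f740 <- fuse(list(g, v), "merge_before_pca", n_components = 740)
  expect_equal(ncol(f740$values), 740L)
})

test_that("fusion validates row alignment and caps component counts", {
  a <- make_branch(40, 10, "a", 45)
  b <- make_branch(35, 10, "b", 46)
  expect_error(fuse(list(a, b), "merge_after_pca"), "row counts")
  b2 <- make_branch(40, 10, "b", 47)
  b2$labels <- rev(b2$labels)
  expect_error(fuse(list(a, b2), "merge_after_pca", 5), "labels differ")
  expect_message(f <- fuse(list(a), "separate", n_components = 100),
                 "capping")
  expect_equal(ncol(f$values), 10L)
})

test_that("fused rows depend only on the same input rows", {
  a <- make_branch(30, 8, "a", 48)
  b <- make_branch(30, 6, "b", 49)
  tr <- 1:20
  f <- fuse(list(a, b), "merge_after_pca", n_components = c(4, 3),
            train_idx = tr)
  perm <- c(tr, sample(21:30))
  fp <- fuse(list(a[perm], b[perm]), "merge_after_pca",
             n_components = c(4, 3), train_idx = tr)
  expect_equal(fp$values, f$values[perm, ], ignore_attr = TRUE)
})

test_that("pooled PCA explains at least as much variance as any branch", {
  set.seed(50)
  a <- make_branch(60, 12, "a", 51)
  b <- make_branch(60, 12, "b", 52)
  k <- 5
  pooled <- pca_fit(cbind(a$values, b$values), k)
  branch <- pca_fit(a$values, k)
  expect_gte(sum(pooled$explained_variance) + 1e-10,
             sum(branch$explained_variance))
})
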