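test_that("mean squared error follows the per-element definition", {
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse_loss(c(1, 0), c(0, 0)), 0.5)
  for (s in 1:20) {
    set.seed(s)
    a <- rnorm(7); b <- rnorm(7)
    ref <- 0
    for (i in 1:7) ref <- ref + (a[i] - b[i])^2
    expect_equal(mse_loss(a, b), ref / 7)
  }
  expect_error(mse_loss(1:3, 1:2), "lengths differ")
})

two_cluster_data <- function(n, gap = 6, seed = 60) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 2), n, 2),
             matrix(rnorm(n * 2) + gap, n, 2))
  feature_matrix(x, rep(c("neg", "pos"), each = n))
}

test_that("analytic gradients match finite differences for both losses", {
  set.seed(61)
  x <- matrix(rnorm(12), 6, 2)
  y <- histofuse:::one_hot(rep(c("a", "b", "c"), 2), c("a", "b", "c"))
  for (loss in c("cross_entropy", "mse")) {
    model <- mlp_init(2, hidden_units = 4, class_names = c("a", "b", "c"),
                      loss = loss, seed = 5)
    lg <- histofuse:::mlp_loss_grad(model, x, y)
    eps <- 1e-6
    for (nm in c("w1", "b1", "w2", "b2")) {
      w <- model[[nm]]
      idx <- seq_len(min(length(w), 6L))
      for (q in idx) {
        mp <- model; mp[[nm]][q] <- mp[[nm]][q] + eps
        mm <- model; mm[[nm]][q] <- mm[[nm]][q] - eps
        fd <- (histofuse:::mlp_loss_grad(mp, x, y)$loss -
               histofuse:::mlp_loss_grad(mm, x, y)$loss) / (2 * eps)
        expect_equal(lg$grads[[nm]][q], fd, tolerance = 1e-5)
      }
    }
  }
})

test_that("training separates a linearly separable two-cluster set", {
  tr <- two_cluster_data(40, seed = 62)
  va <- two_cluster_data(10, seed = 63)
  fit <- ann_train(tr, va, hidden_units = 8, max_epochs = 200, seed = 1)
  pred <- ann_predict(fit$model, tr)
  expect_gte(mean(pred$labels == tr$labels), 0.99)
  # training loss at the returned model is below the initial loss
  h <- fit$history$epochs
  expect_lt(h$train_loss[fit$history$best_epoch], h$train_loss[1])
})

test_that("training is bit-reproducible under a fixed seed", {
  tr <- two_cluster_data(20, seed = 64)
  va <- two_cluster_data(8, seed = 65)
  f1 <- ann_train(tr, va, max_epochs = 30, seed = 9)
  f2 <- ann_train(tr, va, max_epochs = 30, seed = 9)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$history$epochs, f2$history$epochs)
})

test_that("validation failures stop training max_fail epochs after the best", {
  # tiny training set with a noisy validation set: overfitting sets in
  # and validation loss stops improving early
  set.seed(66)
  tr <- two_cluster_data(15, gap = 2, seed = 67)
  va <- two_cluster_data(10, gap = 2, seed = 68)
  va$labels <- sample(va$labels)          # decorrelate validation labels
  fit <- ann_train(tr, va, hidden_units = 12, max_fail = 6,
                   max_epochs = 500, seed = 2)
  expect_equal(fit$history$stop_reason, "max_fail")
  h <- fit$history$epochs
  expect_equal(nrow(h), fit$history$best_epoch + 6L)
  expect_equal(h$val_failures[nrow(h)], 6L)
  # failure counter resets at improvements and never exceeds max_fail
  expect_true(all(h$val_failures <= 6L))
  # returned model is the best-validation snapshot
  expect_equal(h$val_loss[fit$history$best_epoch], min(h$val_loss))
})

test_that("a zero-epoch budget returns the initialised model untouched", {
  tr <- two_cluster_data(10, seed = 69)
  va <- two_cluster_data(5, seed = 70)
  fit <- ann_train(tr, va, max_epochs = 0, seed = 3)
  expect_equal(nrow(fit$history$epochs), 0L)
  expect_equal(fit$history$stop_reason, "zero_epoch_budget")
  init <- mlp_init(2, 20, sort(unique(tr$labels)), "cross_entropy", seed = 3)
  expect_equal(fit$model$w1, init$w1)
})

test_that("prediction normalises scores and takes the row argmax", {
  model <- mlp_init(3, 4, c("a", "b", "c", "d", "e"), "cross_entropy", seed = 4)
  set.seed(71)
  x <- matrix(rnorm(15), 5, 3)
  pr <- ann_predict(model, x)
  expect_equal(rowSums(pr$scores), rep(1, 5), tolerance = 1e-12)
  ref <- apply(pr$scores, 1, function(r) colnames(pr$scores)[which.max(r)])
  expect_equal(pr$labels, unname(ref))
  # zero weights: uniform softmax scores
  model$w1[] <- 0; model$w2[] <- 0
  expect_equal(unname(ann_predict(model, x)$scores),
               matrix(0.2, 5, 5), tolerance = 1e-12)
  expect_error(ann_predict(model, matrix(0, 2, 7)), "dimension mismatch")
})

test_that("error histogram spans the observed range and counts every pair", {
  # perfect predictions: all mass in the bin containing zero
  t0 <- diag(5); o0 <- diag(5)
  eh0 <- error_histogram(t0, o0)
  expect_equal(sum(eh0$counts), 25L)
  expect_equal(max(eh0$counts), 25L)
  # errors at the two extremes split between the outer bins
  eh1 <- error_histogram(c(0, 2), c(1, 1), n_bins = 20)
  expect_equal(unname(eh1$counts[1, c(1, 20)]), c(1L, 1L))
  expect_equal(sum(eh1$counts), 2L)
  # counts sum to n_samples x n_units, per split
  set.seed(72)
  tg <- matrix(rbinom(40, 1, 0.5), 8, 5)
  ot <- matrix(runif(40), 8, 5)
  sp <- rep(c("train", "test"), 4)
  eh <- error_histogram(tg, ot, split = sp)
  expect_equal(sum(eh$counts), 40L)
  expect_equal(unname(rowSums(eh$counts)), c(20L, 20L))
})

test_that("regression diagnostic equals the Pearson formula in percent", {
  set.seed(73)
  t <- matrix(rnorm(20), 4, 5)
  expect_equal(regression_r(t, t), 100)
  expect_equal(regression_r(t, -t), -100)
  o <- matrix(rnorm(20), 4, 5)
  tv <- as.vector(t); ov <- as.vector(o)
  ref <- sum((tv - mean(tv)) * (ov - mean(ov))) /
    sqrt(sum((tv - mean(tv))^2) * sum((ov - mean(ov))^2))
  expect_equal(regression_r(t, o), 100 * ref)
  expect_error(regression_r(rep(1, 4), rnorm(4)), "zero-variance")
})
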