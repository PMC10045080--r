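# Feed-forward classifier: one hidden layer of tanh units, a five-unit
# output layer, full-batch gradient training with an adaptive step,
# validation-failure early stopping (max_fail), and complete per-epoch
# history capture (losses, gradient norm, validation failures).

#' Mean squared error
#'
#' `(1/m) * sum((actual - expected)^2)` over the `m` paired entries.
#'
#' @param actual,expected numeric vectors of equal length.
#' @return the mean squared error.
#' @export
mse_loss <- function(actual, expected) {
  if (length(actual) != length(expected))
    stop("actual and expected lengths differ", call. = FALSE)
  if (length(actual) == 0L) stop("empty vectors", call. = FALSE)
  mean((actual - expected)^2)
}

one_hot <- function(labels, class_names) {
  idx <- match(labels, class_names)
  if (anyNA(idx)) stop("label outside the class vocabulary", call. = FALSE)
  y <- matrix(0, length(labels), length(class_names))
  y[cbind(seq_along(idx), idx)] <- 1
  colnames(y) <- class_names
  y
}

#' Initialise a feed-forward network
#'
#' Weights are drawn uniformly in `+/- 1/sqrt(fan_in)` under the given
#' seed; inputs are standardised internally using training statistics
#' stored on the model.
#'
#' @param input_dim number of input features.
#' @param hidden_units hidden layer width (default 20).
#' @param class_names output class vocabulary (one unit per class).
#' @param loss `"cross_entropy"` (softmax outputs) or `"mse"` (logistic
#'   outputs).
#' @param seed integer seed for the weight draw.
#' @return an `mlp_model`.
#' @export
mlp_init <- function(input_dim, hidden_units = 20L,
                     class_names = c("colon_aca", "colon_bnt", "lung_aca",
                                     "lung_bnt", "lung_scc"),
                     loss = c("cross_entropy", "mse"), seed = 1L) {
  loss <- match.arg(loss)
  k <- length(class_names)
  with_preserved_seed(seed, {
    w1 <- matrix(stats::runif(input_dim * hidden_units, -1, 1) / sqrt(input_dim),
                 input_dim, hidden_units)
    w2 <- matrix(stats::runif(hidden_units * k, -1, 1) / sqrt(hidden_units),
                 hidden_units, k)
    structure(list(w1 = w1, b1 = numeric(hidden_units), w2 = w2,
                   b2 = numeric(k), class_names = class_names, loss = loss,
                   x_center = numeric(input_dim),
                   x_scale = rep(1, input_dim), seed = seed),
              class = "mlp_model")
  })
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("<mlp_model> ", nrow(x$w1), " -> ", ncol(x$w1), " -> ",
      length(x$b2), " (", x$loss, ")\n", sep = "")
  invisible(x)
}

mlp_standardize <- function(model, x) {
  sweep(sweep(x, 2, model$x_center), 2, model$x_scale, "/")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_forward <- function(model, x) {
  h <- tanh(sweep(x %*% model$w1, 2, model$b1, "+"))
  z <- sweep(h %*% model$w2, 2, model$b2, "+")
  out <- if (model$loss == "cross_entropy") softmax_rows(z)
         else 1 / (1 + exp(-z))
  list(h = h, z = z, out = out)
}

mlp_loss_value <- function(model, out, y) {
  if (model$loss == "cross_entropy") {
    p <- pmax(out[y == 1], 1e-12)
    -mean(log(p))
  } else {
    mean((out - y)^2)
  }
}

# Loss and analytic gradients for standardized inputs x and one-hot y.
mlp_loss_grad <- function(model, x, y) {
  n <- nrow(x)
  fwd <- mlp_forward(model, x)
  loss <- mlp_loss_value(model, fwd$out, y)
  if (model$loss == "cross_entropy") {
    dz <- (fwd$out - y) / n
  } else {
    dz <- 2 * (fwd$out - y) * fwd$out * (1 - fwd$out) / length(y)
  }
  dw2 <- t(fwd$h) %*% dz
  db2 <- unname(colSums(dz))
  dh <- dz %*% t(model$w2) * (1 - fwd$h^2)
  dw1 <- t(x) %*% dh
  db1 <- unname(colSums(dh))
  list(loss = loss,
       grads = list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2))
}

grad_norm <- function(g) sqrt(sum(unlist(g)^2))

split_loss <- function(model, x, y) {
  mlp_loss_value(model, mlp_forward(model, x)$out, y)
}

#' Train the feed-forward classifier
#'
#' Full-batch gradient descent with momentum and a bold-driver adaptive
#' step (the learning rate grows while the training loss falls and is
#' halved when it rises). Training stops when the validation loss has
#' failed to improve for `max_fail` consecutive epochs, when the
#' gradient norm drops below `grad_tol`, or at `max_epochs`; the
#' returned weights are those of the epoch with the lowest validation
#' loss. A `max_epochs = 0` budget returns the initialised model with an
#' empty history.
#'
#' @param train,validation [feature_matrix()] objects (validation
#'   non-empty); an optional `test` matrix is only monitored.
#' @param hidden_units hidden layer width.
#' @param loss `"cross_entropy"` or `"mse"`.
#' @param max_fail consecutive validation failures tolerated (default 6).
#' @param max_epochs epoch budget.
#' @param learning_rate initial step size.
#' @param grad_tol gradient-norm stopping threshold.
#' @param seed seed for weight initialisation.
#' @param test optional held-out matrix whose loss is recorded per epoch.
#' @return list with `model` (best-epoch `mlp_model`) and `history` (a
#'   `training_history`: per-epoch data frame plus `stop_reason` and
#'   `best_epoch`).
#' @export
ann_train <- function(train, validation, hidden_units = 20L,
                      loss = c("cross_entropy", "mse"), max_fail = 6L,
                      max_epochs = 300L, learning_rate = 0.5,
                      grad_tol = 1e-6, seed = 1L, test = NULL) {
  loss <- match.arg(loss)
  stopifnot(inherits(train, "feature_matrix"),
            inherits(validation, "feature_matrix"))
  if (nrow(validation$values) == 0L)
    stop("validation set must be non-empty", call. = FALSE)
  class_names <- sort(unique(c(train$labels, validation$labels)))
  model <- mlp_init(ncol(train$values), hidden_units, class_names, loss, seed)
  ctr <- colMeans(train$values)
  scl <- apply(train$values, 2, stats::sd)
  scl[scl == 0] <- 1
  model$x_center <- ctr
  model$x_scale <- scl
  xt <- mlp_standardize(model, train$values)
  yt <- one_hot(train$labels, class_names)
  xv <- mlp_standardize(model, validation$values)
  yv <- one_hot(validation$labels, class_names)
  if (!is.null(test)) {
    xs <- mlp_standardize(model, test$values)
    ys <- one_hot(test$labels, class_names)
  }

  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), test_loss = numeric(),
                     grad_norm = numeric(), val_failures = integer())
  if (max_epochs < 1L) {
    return(list(model = model,
                history = structure(list(epochs = hist,
                                         stop_reason = "zero_epoch_budget",
                                         best_epoch = 0L),
                                    class = "training_history")))
  }

  lr <- learning_rate
  mom <- 0.9
  vel <- list(w1 = model$w1 * 0, b1 = model$b1 * 0,
              w2 = model$w2 * 0, b2 = model$b2 * 0)
  best_val <- Inf; best_epoch <- 0L; best_model <- model
  fails <- 0L; prev_loss <- Inf
  stop_reason <- "max_epochs"
  for (epoch in seq_len(max_epochs)) {
    lg <- mlp_loss_grad(model, xt, yt)
    gn <- grad_norm(lg$grads)
    if (!is.finite(lg$loss))
      stop("training diverged (non-finite loss) at epoch ", epoch,
           call. = FALSE)
    if (lg$loss > prev_loss) {
      lr <- lr * 0.5
      vel <- lapply(vel, function(v) v * 0)
    } else {
      lr <- lr * 1.05
    }
    prev_loss <- lg$loss
    for (nm in names(vel)) {
      vel[[nm]] <- mom * vel[[nm]] - lr * lg$grads[[nm]]
      model[[nm]] <- model[[nm]] + vel[[nm]]
    }
    vl <- split_loss(model, xv, yv)
    tl <- if (!is.null(test)) split_loss(model, xs, ys) else NA_real_
    if (vl < best_val - 1e-12) {
      best_val <- vl; best_epoch <- epoch; best_model <- model; fails <- 0L
    } else {
      fails <- fails + 1L
    }
    hist[nrow(hist) + 1L, ] <- list(epoch, lg$loss, vl, tl, gn, fails)
    if (fails >= max_fail) { stop_reason <- "max_fail"; break }
    if (gn < grad_tol) { stop_reason <- "gradient"; break }
  }
  list(model = best_model,
       history = structure(list(epochs = hist, stop_reason = stop_reason,
                                best_epoch = best_epoch),
                           class = "training_history"))
}

#' @export
print.training_history <- function(x, ...) {
  cat("<training_history> ", nrow(x$epochs), " epochs, stopped by ",
      x$stop_reason, ", best epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Predict class scores and labels
#'
#' Scores are softmax-normalised (cross-entropy mode, rows sum to 1) or
#' raw logistic outputs (MSE mode); the predicted label is the argmax.
#'
#' @param model an `mlp_model`.
#' @param X a [feature_matrix()] or numeric matrix.
#' @return list with `scores` (n x classes) and `labels`.
#' @export
ann_predict <- function(model, X) {
  stopifnot(inherits(model, "mlp_model"))
  x <- fm_values(X)
  if (ncol(x) != nrow(model$w1))
    stop("dimension mismatch: model expects ", nrow(model$w1), " features",
         call. = FALSE)
  out <- mlp_forward(model, mlp_standardize(model, x))$out
  colnames(out) <- model$class_names
  list(scores = out,
       labels = model$class_names[max.col(out, ties.method = "first")])
}

#' Prediction-error histogram
#'
#' Histogram of the `target - output` errors over `n_bins` equal-width
#' bins spanning the observed error range, with counts reported per
#' split when a split assignment is given.
#'
#' @param targets,outputs numeric matrices or vectors of equal shape
#'   (targets are one-hot class indicators in the classification
#'   setting).
#' @param n_bins number of bins (default 20).
#' @param split optional split tag per sample (recycled across output
#'   units).
#' @return list with `breaks`, `mids` and `counts` (one row per split).
#' @export
error_histogram <- function(targets, outputs, n_bins = 20L, split = NULL) {
  if (length(targets) == 0L) stop("empty input", call. = FALSE)
  if (length(targets) != length(outputs))
    stop("targets and outputs differ in length", call. = FALSE)
  err <- as.vector(as.matrix(targets) - as.matrix(outputs))
  if (is.null(split)) split <- rep("all", NROW(targets))
  units <- length(err) / length(split)
  split_full <- rep(split, times = units)
  rng <- range(err)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * max(1e-6, abs(rng[1]) * 1e-6)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- .bincode(err, breaks, right = TRUE, include.lowest = TRUE)
  levs <- unique(split)
  counts <- t(vapply(levs, function(s)
    tabulate(bin[split_full == s], nbins = n_bins), integer(n_bins)))
  rownames(counts) <- levs
  list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       counts = counts)
}

#' Regression diagnostic (Pearson R, percent)
#'
#' Pearson correlation between the flattened targets and outputs,
#' reported as a percentage, as in network regression plots.
#'
#' @param targets,outputs numeric matrices or vectors of equal shape.
#' @return correlation in percent.
#' @export
regression_r <- function(targets, outputs) {
  t <- as.vector(as.matrix(targets)); o <- as.vector(as.matrix(outputs))
  if (length(t) != length(o)) stop("length mismatch", call. = FALSE)
  if (stats::sd(t) == 0 || stats::sd(o) == 0)
    stop("zero-variance input: correlation undefined", call. = FALSE)
  100 * stats::cor(t, o)
}
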