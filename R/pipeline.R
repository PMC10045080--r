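# End-to-end convenience runner: synthesize -> enhance -> handcrafted
# descriptors -> PCA -> feed-forward classifier -> metrics. This is the
# recovery experiment used to validate the whole pipeline on data whose
# class structure is known by construction.

#' Run the full pipeline on a synthetic five-class dataset
#'
#' Generates a balanced synthetic dataset at the requested separability,
#' enhances every image, extracts the 244-dimensional handcrafted
#' descriptor, performs a two-level stratified train/validation/test
#' split, fits PCA on the training rows (component count capped at
#' `min(n_train - 1, 244)`), trains the feed-forward classifier with
#' validation-failure early stopping, and evaluates on the held-out test
#' split.
#'
#' @param n_per_class images per class.
#' @param size image side in pixels.
#' @param separability class separability in \[0, 1\].
#' @param seed master seed for generation, splitting and training.
#' @param n_components PCA component target (capped for small runs).
#' @param hidden_units classifier hidden width.
#' @param max_fail validation-failure budget for early stopping.
#' @param max_epochs training epoch budget.
#' @param loss training loss.
#' @param enhance_images apply the enhancement chain before descriptor
#'   extraction.
#' @return list with `test_accuracy` (percent), `report` (a
#'   [metrics_report()]), `history`, `model`, and the split `manifest`.
#' @export
run_synthetic_pipeline <- function(n_per_class = 100L, size = 64L,
                                   separability = 1, seed = 7L,
                                   n_components = 455L, hidden_units = 20L,
                                   max_fail = 6L, max_epochs = 300L,
                                   loss = "cross_entropy",
                                   enhance_images = TRUE) {
  ds <- generate_dataset(n_per_class, default_class_specs(separability),
                         size, seed)
  imgs <- if (enhance_images) lapply(ds$images, enhance) else ds$images
  fm <- handcrafted_feature_matrix(imgs, ds$manifest$records$label)
  man <- split_dataset(ds$manifest, 0.2, 0.2, seed = seed)
  idx <- split(seq_len(nrow(man$records)), man$records$split)
  k <- min(n_components, length(idx$train) - 1L, ncol(fm$values))
  pca <- pca_fit(fm[idx$train], k)
  red <- pca_transform(pca, fm, source_tag = "handcrafted_pca")
  fit <- ann_train(red[idx$train], red[idx$validation],
                   hidden_units = hidden_units, loss = loss,
                   max_fail = max_fail, max_epochs = max_epochs, seed = seed,
                   test = red[idx$test])
  pred <- ann_predict(fit$model, red[idx$test])
  cm <- confusion(red$labels[idx$test], pred$labels, man$class_names)
  rep <- metrics_report(cm, pred$scores, red$labels[idx$test])
  list(test_accuracy = rep$micro_accuracy, report = rep,
       history = fit$history, model = fit$model, pca = pca, manifest = man)
}
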