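# Synthetic five-class texture generator. Each class pairs a base
# colour with a texture family (glandular blobs, smooth, stripes,
# speckle, checker) so every descriptor family in the pipeline has
# signal to detect; a separability knob interpolates every
# class-specific parameter toward a common mid-grey smooth profile, so
# at separability 0 the five classes are exchangeable by construction.

#' Specification of one synthetic image class
#'
#' @param class_name label string.
#' @param base_color RGB triple in \[0, 255\].
#' @param texture one of `"blobs"`, `"smooth"`, `"stripes"`,
#'   `"speckle"`, `"checker"`.
#' @param period texture period / scale parameter in pixels.
#' @param amplitude texture contrast amplitude in intensity units.
#' @param color_jitter per-image base colour jitter (sd, intensity
#'   units).
#' @param noise_std per-pixel Gaussian noise sd (intensity units).
#' @return a `class_spec` list.
#' @export
class_spec <- function(class_name, base_color, texture, period = 8,
                       amplitude = 50, color_jitter = 6, noise_std = 8) {
  texture <- match.arg(texture,
                       c("blobs", "smooth", "stripes", "speckle", "checker"))
  stopifnot(length(base_color) == 3L, all(base_color >= 0 & base_color <= 255),
            period > 0, amplitude >= 0, color_jitter >= 0, noise_std >= 0)
  structure(list(class_name = class_name, base_color = base_color,
                 texture = texture, period = period, amplitude = amplitude,
                 color_jitter = color_jitter, noise_std = noise_std),
            class = "class_spec")
}

#' Default five-class specifications
#'
#' Five texture/colour regimes loosely evoking the visual variety of
#' stained lung and colon tissue classes (no biological claim): blob-like
#' glandular structure, smooth benign tissue, striped, speckled, and
#' checkered micro-pattern, each with a distinct base colour.
#' `separability` in \[0, 1\] linearly interpolates each class's colour
#' offset and texture amplitude toward a common mid-grey smooth profile:
#' at 1 the classes are fully distinct, at 0 they share one generating
#' distribution.
#'
#' @param separability real in \[0, 1\].
#' @return named list of five [class_spec()] objects, in alphabetical
#'   class order.
#' @export
default_class_specs <- function(separability = 1) {
  stopifnot(separability >= 0, separability <= 1)
  s <- separability
  base <- list(
    colon_aca = list(color = c(160, 105, 170), texture = "blobs",
                     period = 10, amplitude = 55),
    colon_bnt = list(color = c(205, 160, 185), texture = "smooth",
                     period = 16, amplitude = 25),
    lung_aca  = list(color = c(150, 120, 105), texture = "stripes",
                     period = 7, amplitude = 50),
    lung_bnt  = list(color = c(120, 165, 140), texture = "speckle",
                     period = 4, amplitude = 60),
    lung_scc  = list(color = c(175, 145, 95), texture = "checker",
                     period = 6, amplitude = 50))
  specs <- lapply(names(base), function(nm) {
    b <- base[[nm]]
    class_spec(nm,
               base_color = 128 + s * (b$color - 128),
               texture = b$texture, period = b$period,
               amplitude = s * b$amplitude)
  })
  stats::setNames(specs, names(base))
}

texture_pattern <- function(texture, size, period) {
  x <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  y <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  switch(texture,
    checker = ((floor((x - 1) / period) + floor((y - 1) / period)) %% 2) * 2 - 1,
    stripes = {
      phi <- stats::runif(1, 0, 2 * pi)
      ang <- pi / 5
      sin(2 * pi * (x * cos(ang) + y * sin(ang)) / period + phi)
    },
    blobs = {
      k <- max(3L, round(size^2 / (period^2 * 8)))
      cx <- stats::runif(k, 1, size); cy <- stats::runif(k, 1, size)
      m <- matrix(0, size, size)
      for (q in seq_len(k))
        m <- m + exp(-((x - cx[q])^2 + (y - cy[q])^2) / (2 * (period / 2)^2))
      m <- m / max(m)
      m * 2 - 1
    },
    speckle = {
      m <- matrix(0, size, size)
      hits <- stats::runif(size^2) < 0.12
      m[hits] <- sample(c(-1, 1), sum(hits), replace = TRUE)
      m
    },
    smooth = {
      th <- stats::runif(1, 0, 2 * pi)
      g <- (x * cos(th) + y * sin(th)) / size
      (g - mean(g)) * 0.6
    })
}

#' Generate one synthetic class image
#'
#' Draws the class texture pattern, tints it with the base colour, adds
#' a per-image colour jitter and per-pixel Gaussian noise, and clips to
#' \[0, 255\]. Deterministic given `(spec, size, seed)`.
#'
#' @param spec a [class_spec()].
#' @param size image side in pixels (>= 32).
#' @param seed integer seed.
#' @return H x W x 3 integer-valued array in \[0, 255\].
#' @export
generate_image <- function(spec, size = 64L, seed = 1L) {
  stopifnot(inherits(spec, "class_spec"))
  if (size < 32L) stop("size must be at least 32", call. = FALSE)
  with_preserved_seed(seed, {
    pat <- texture_pattern(spec$texture, size, spec$period)
    jit <- stats::rnorm(3, 0, spec$color_jitter)
    img <- array(0, c(size, size, 3L))
    for (c in 1:3) {
      img[, , c] <- spec$base_color[c] + jit[c] + spec$amplitude * pat +
        stats::rnorm(size^2, 0, spec$noise_std)
    }
    quantize_image(img)
  })
}

#' Generate a balanced synthetic dataset
#'
#' Produces `n_per_class` images per class with per-image seeds derived
#' from the master seed. When `out_dir` is given the images are written
#' as PNG files and a `manifest.csv` alongside; otherwise the images are
#' returned in memory with the manifest.
#'
#' @param n_per_class images per class (>= 5).
#' @param specs list of [class_spec()] objects (default
#'   [default_class_specs()]).
#' @param size image side in pixels.
#' @param seed master seed.
#' @param out_dir optional directory to write PNGs and the manifest.
#' @return list with `manifest` (a `dataset_manifest`) and `images`
#'   (list of arrays, ordered as the manifest records).
#' @export
generate_dataset <- function(n_per_class = 100L,
                             specs = default_class_specs(), size = 64L,
                             seed = 7L, out_dir = NULL) {
  stopifnot(n_per_class >= 5L, length(specs) >= 2L)
  classes <- vapply(specs, function(s) s$class_name, character(1))
  n_total <- n_per_class * length(specs)
  im_seeds <- with_preserved_seed(seed,
                                  sample.int(.Machine$integer.max - 1L, n_total))
  images <- vector("list", n_total)
  paths <- character(n_total)
  labels <- character(n_total)
  i <- 0L
  for (sp in specs) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1L
      images[[i]] <- generate_image(sp, size, im_seeds[i])
      labels[i] <- sp$class_name
      paths[i] <- sprintf("%s_%04d.png", sp$class_name, r)
    }
  }
  rec <- data.frame(path = paths, label = labels, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    rec$path <- file.path(out_dir, rec$path)
    for (i in seq_len(n_total)) write_image(images[[i]], rec$path[i])
    write_manifest(new_manifest(rec, sort(unique(labels))),
                   file.path(out_dir, "manifest.csv"))
  }
  list(manifest = new_manifest(rec, sort(unique(labels))), images = images)
}
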