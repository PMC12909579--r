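#' Synthetic staged-image and tabular data generators
#'
#' Stand-ins for staged-MRI data that let the whole two-tier pipeline run and
#' be tested at desk scale. Images are 32 x 32 RGB renderings of a centred
#' ring/disc whose outer radius and interior intensity grow monotonically with
#' the class index, scaled by a separability parameter (a crude proxy for
#' progressive atrophy); each image gets an integer translation of up to 2
#' pixels and Gaussian pixel noise. At separability 0 all four
#' class-conditional distributions are identical, so no classifier can beat
#' chance in expectation. The generators are deterministic given their seed.
#'
#' @name synthetic_data
NULL

IMG_SIZE <- 32L
N_CHANNELS <- 3L
N_CLASSES <- 4L

#' Specification of a synthetic image dataset
#'
#' @param n_per_class Integer vector of per-class counts; default the
#'   test-split supports `c(384, 336, 300, 300)` of the four-stage study
#'   layout.
#' @param separability Non-negative scalar controlling how far apart the class
#'   templates are; 0 makes classes indistinguishable. Default 2.
#' @param noise_sd Gaussian pixel-noise standard deviation (intensity units,
#'   images live in `[0, 1]`). Default 0.15.
#' @param image_size Image side in pixels (fixed at 32 by the pipeline).
#' @param seed Random seed.
#' @return A `synthetic_image_spec` list.
#' @export
synthetic_image_spec <- function(n_per_class = c(384L, 336L, 300L, 300L),
                                 separability = 2, noise_sd = 0.15,
                                 image_size = IMG_SIZE, seed = 1L) {
  stopifnot(length(n_per_class) == N_CLASSES, all(n_per_class >= 0),
            separability >= 0, noise_sd >= 0, image_size == IMG_SIZE)
  structure(list(n_per_class = as.integer(n_per_class),
                 separability = separability, noise_sd = noise_sd,
                 image_size = as.integer(image_size), seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

# class template on the [0,1] intensity scale; u = separability * class_index.
# Increments are deliberately small relative to the pixel noise so that the
# default separability of 2 puts a CNN from the tuned architecture ranges in an intermediate
# (neither chance nor ceiling) performance band.
class_template <- function(u, cx, cy, size = IMG_SIZE) {
  u <- min(u, 10)
  r_out <- 7 + 0.45 * u                  # outer ring radius, px
  ring_w <- 2.5                          # ring thickness, px
  interior <- 0.3 + 0.06 * u             # interior intensity
  g <- expand.grid(x = seq_len(size) - 0.5, y = seq_len(size) - 0.5)
  d <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  img <- rep(0.15, size * size)          # background
  img[d <= r_out] <- 0.8                # ring band (overwritten inside)
  img[d <= r_out - ring_w] <- interior
  matrix(img, size, size)                # [x, y] with x fastest
}

#' Generate a labeled synthetic image dataset
#'
#' @param spec A [synthetic_image_spec()].
#' @param dir Optional directory; when given, images are written as PNG files
#'   in one subdirectory per class (`class_0` ... `class_3`) together with a
#'   `manifest.csv` (path, label).
#' @return An `image_dataset`: `x` is an `n x 3072` numeric matrix (rows are
#'   images, feature order channel-major: channel, then row, then column),
#'   `y` the integer class labels 0--3, plus the generating `spec`.
#' @export
generate_images <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  set.seed(spec$seed)
  size <- spec$image_size
  n_total <- sum(spec$n_per_class)
  x <- matrix(0, n_total, size * size * N_CHANNELS)
  y <- integer(n_total)
  row <- 0L
  for (k in 0:(N_CLASSES - 1L)) {
    nk <- spec$n_per_class[k + 1L]
    u <- spec$separability * k
    for (i in seq_len(nk)) {
      row <- row + 1L
      dx <- sample(-2:2, 1L); dy <- sample(-2:2, 1L)
      tmpl <- class_template(u, size / 2 + 0.5 + dx, size / 2 + 0.5 + dy, size)
      noisy <- tmpl + matrix(stats::rnorm(size * size, 0, spec$noise_sd), size, size)
      noisy <- pmin(pmax(noisy, 0), 1)
      # grayscale replicated onto 3 channels; layout: channel-major planes,
      # within a plane row-major (y outer, x inner)
      plane <- as.numeric(t(noisy))      # y outer, x inner
      x[row, ] <- rep(plane, N_CHANNELS)
      y[row] <- k
    }
  }
  ds <- structure(list(x = x, y = y, image_size = size, spec = spec),
                  class = "image_dataset")
  if (!is.null(dir)) write_image_dataset(ds, dir)
  ds
}

#' @export
print.image_dataset <- function(x, ...) {
  cat("image_dataset:", nrow(x$x), "images of", x$image_size, "x",
      x$image_size, "x 3, class counts:",
      paste(tabulate(x$y + 1L, N_CLASSES), collapse = "/"), "\n")
  invisible(x)
}

#' Subset an image dataset by row indices
#' @param ds An `image_dataset`.
#' @param idx Integer row indices.
#' @return An `image_dataset` restricted to `idx`.
#' @export
subset_images <- function(ds, idx) {
  structure(list(x = ds$x[idx, , drop = FALSE], y = ds$y[idx],
                 image_size = ds$image_size, spec = ds$spec),
            class = "image_dataset")
}

row_to_array <- function(v, size = IMG_SIZE) {
  # inverse of the channel-major flattening: returns [y, x, channel]
  a <- array(0, c(size, size, N_CHANNELS))
  plane_len <- size * size
  for (c in seq_len(N_CHANNELS)) {
    plane <- v[((c - 1L) * plane_len + 1L):(c * plane_len)]
    a[, , c] <- matrix(plane, size, size, byrow = TRUE)
  }
  a
}

array_to_row <- function(a) {
  size <- dim(a)[1L]
  as.numeric(vapply(seq_len(N_CHANNELS),
                    function(c) as.numeric(t(a[, , c])),
                    numeric(size * size)))
}

#' Write an image dataset as PNG files (directory per class)
#' @param ds An `image_dataset`.
#' @param dir Output directory; created if missing.
#' @return `dir` invisibly; also writes `manifest.csv` (path, label).
#' @export
write_image_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(ds$x))
  for (k in sort(unique(ds$y)))
    dir.create(file.path(dir, paste0("class_", k)), showWarnings = FALSE)
  counter <- integer(N_CLASSES)
  for (i in seq_len(nrow(ds$x))) {
    k <- ds$y[i]
    counter[k + 1L] <- counter[k + 1L] + 1L
    rel <- file.path(paste0("class_", k),
                     sprintf("img_%04d.png", counter[k + 1L]))
    png::writePNG(row_to_array(ds$x[i, ], ds$image_size), file.path(dir, rel))
    paths[i] <- rel
  }
  utils::write.csv(data.frame(path = paths, label = ds$y),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

bilinear_resize <- function(a, size) {
  din <- dim(a)
  if (din[1L] == size && din[2L] == size) return(a)
  out <- array(0, c(size, size, dim(a)[3L]))
  sy <- din[1L] / size; sx <- din[2L] / size
  yc <- pmin(pmax((seq_len(size) - 0.5) * sy + 0.5, 1), din[1L])
  xc <- pmin(pmax((seq_len(size) - 0.5) * sx + 0.5, 1), din[2L])
  y0 <- floor(yc); y1 <- pmin(y0 + 1, din[1L]); wy <- yc - y0
  x0 <- floor(xc); x1 <- pmin(x0 + 1, din[2L]); wx <- xc - x0
  for (c in seq_len(dim(a)[3L])) {
    m <- a[, , c]
    top <- m[y0, x0, drop = FALSE] * outer(1 - wy, 1 - wx) +
           m[y0, x1, drop = FALSE] * outer(1 - wy, wx)
    bot <- m[y1, x0, drop = FALSE] * outer(wy, 1 - wx) +
           m[y1, x1, drop = FALSE] * outer(wy, wx)
    out[, , c] <- top + bot
  }
  out
}

#' Load a directory-per-class PNG dataset
#'
#' Expects one subdirectory per class named `class_<k>` (or any names, sorted,
#' mapped to labels 0, 1, ...). Images are converted to RGB (grayscale
#' replicated) and bilinearly resized to 32 x 32.
#'
#' @param dir Dataset root directory.
#' @return An `image_dataset`.
#' @export
load_image_dir <- function(dir) {
  classes <- sort(list.dirs(dir, recursive = FALSE))
  if (length(classes) == 0) stop("load_image_dir: no class subdirectories in ", dir)
  xs <- list(); ys <- integer(0)
  for (k in seq_along(classes)) {
    files <- sort(list.files(classes[k], pattern = "\\.png$", full.names = TRUE,
                             ignore.case = TRUE))
    for (f in files) {
      a <- png::readPNG(f)
      if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
      if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
      if (dim(a)[3L] == 1L) a <- array(rep(a, 3), c(dim(a)[1:2], 3L))
      a <- bilinear_resize(a, IMG_SIZE)
      xs[[length(xs) + 1L]] <- array_to_row(a)
      ys <- c(ys, k - 1L)
    }
  }
  structure(list(x = do.call(rbind, xs), y = ys, image_size = IMG_SIZE,
                 spec = NULL),
            class = "image_dataset")
}

#' Embedding sets
#'
#' Container for per-sample feature vectors with class labels, as produced by
#' the truncated CNN or the tabular generator.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Integer class labels.
#' @param provenance Optional free-form record of how the features were made.
#' @return An `embedding_set`.
#' @export
embedding_set <- function(features, labels, provenance = NULL) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  colnames(features) <- paste0("f", seq_len(ncol(features)) - 1L)
  structure(list(features = features, labels = as.integer(labels),
                 provenance = provenance), class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat("embedding_set:", nrow(x$features), "samples x", ncol(x$features),
      "features,", length(unique(x$labels)), "classes\n")
  invisible(x)
}

#' Subset an embedding set by row indices
#' @param es An `embedding_set`.
#' @param idx Integer row indices.
#' @return An `embedding_set`.
#' @export
subset_embeddings <- function(es, idx) {
  embedding_set(es$features[idx, , drop = FALSE], es$labels[idx],
                provenance = es$provenance)
}

#' Read/write embedding sets as CSV (columns f0..f{d-1}, label)
#' @param es An `embedding_set`.
#' @param path CSV file path.
#' @return `write_embeddings` returns `path` invisibly; `read_embeddings`
#'   returns an `embedding_set`.
#' @export
write_embeddings <- function(es, path) {
  df <- as.data.frame(es$features)
  df$label <- es$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.csv(path)
  if (!"label" %in% names(df)) stop("read_embeddings: no 'label' column")
  embedding_set(as.matrix(df[setdiff(names(df), "label")]), df$label)
}

#' Generate class-conditional Gaussian tabular data
#'
#' Each class k gets a mean offset of `separability * k` along a random unit
#' direction (one direction per class, drawn from the seed), unit covariance.
#' Useful for testing the booster layer without CNN training.
#'
#' @param n_per_class Integer vector of per-class counts.
#' @param n_features Feature dimensionality (>= 1).
#' @param separability Non-negative mean-offset scale.
#' @param seed Random seed.
#' @return An `embedding_set`.
#' @export
generate_tabular <- function(n_per_class, n_features, separability, seed = 1L) {
  stopifnot(n_features >= 1, separability >= 0, all(n_per_class >= 0))
  set.seed(seed)
  K <- length(n_per_class)
  dirs <- matrix(stats::rnorm(K * n_features), K, n_features)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  n <- sum(n_per_class)
  X <- matrix(0, n, n_features); y <- integer(n)
  row <- 0L
  for (k in seq_len(K)) {
    mu <- separability * (k - 1L) * dirs[k, ]
    for (i in seq_len(n_per_class[k])) {
      row <- row + 1L
      X[row, ] <- mu + stats::rnorm(n_features)
      y[row] <- k - 1L
    }
  }
  embedding_set(X, y, provenance = list(generator = "gaussian_clusters",
                                        separability = separability,
                                        seed = seed))
}

#' Standard continuous benchmark objectives
#'
#' Returns the negated closed form (so that maximization conventions apply);
#' the optimum value is 0 at the origin (sphere, rastrigin) or at
#' `(1, ..., 1)` (rosenbrock). The number of evaluations made through the
#' returned function is observable via [evaluation_count()].
#'
#' @param name One of `"sphere"`, `"rastrigin"`, `"rosenbrock"`.
#' @param dim Dimensionality (>= 1; >= 2 for rosenbrock).
#' @return A function `x -> -f(x)` with an internal evaluation counter.
#' @export
benchmark_objective <- function(name = c("sphere", "rastrigin", "rosenbrock"),
                                dim) {
  name <- match.arg(name)
  stopifnot(dim >= 1)
  if (name == "rosenbrock" && dim < 2)
    stop("rosenbrock needs dim >= 2")
  raw <- switch(name,
    sphere = function(x) sum(x^2),
    rastrigin = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
    rosenbrock = function(x) {
      i <- seq_len(length(x) - 1L)
      sum(100 * (x[i + 1L] - x[i]^2)^2 + (1 - x[i])^2)
    })
  count <- 0L
  f <- function(x) {
    count <<- count + 1L
    -raw(as.numeric(x))
  }
  attr(f, "benchmark") <- name
  f
}

#' Evaluation count of a benchmark objective
#' @param fn A function returned by [benchmark_objective()].
#' @return Integer number of calls made so far.
#' @export
evaluation_count <- function(fn) environment(fn)$count

#' A box search space for benchmark objectives
#' @param dim Dimensionality.
#' @param low,high Shared bounds per dimension (defaults -5.12, 5.12).
#' @return A `search_space` of `dim` continuous parameters.
#' @export
benchmark_space <- function(dim, low = -5.12, high = 5.12) {
  search_space(lapply(seq_len(dim), function(j)
    param_spec(paste0("x", j), "continuous", low, high)), id = "benchmark")
}
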