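#' Shapley-value feature attribution for the booster layer
#'
#' Explains individual predictions of the L2 classifier over CNN embeddings.
#' Absent features are replaced by background-set values and the model output
#' averaged over the background (the interventional/marginal convention), so
#' the value of a coalition S is
#' `v(S) = mean_b f(x_S, b_{S^c})`. [shapley_exact()] enumerates all 2^d
#' coalitions (the test oracle, d <= 12); [shapley_kernel()] estimates the
#' same quantity by weighted least squares over sampled coalitions with the
#' Shapley kernel weights, with the efficiency constraint
#' `base_value + sum(phi) = f(x)` enforced exactly in both.
#'
#' @name attribution
NULL

coalition_values <- function(f, x, background, Z) {
  # Z: m x d binary matrix of coalitions; returns v(z) for each row
  d <- length(x)
  nb <- nrow(background)
  m <- nrow(Z)
  X <- background[rep(seq_len(nb), times = m), , drop = FALSE]
  for (j in seq_len(d)) {
    on <- rep(Z[, j] == 1, each = nb)
    X[on, j] <- x[j]
  }
  out <- f(X)
  if (length(out) != nrow(X))
    stop("attribution: model function must return one value per row")
  unname(rowsum(out, rep(seq_len(m), each = nb))[, 1]) / nb
}

#' Exact Shapley attribution by coalition enumeration
#'
#' @param f Model output function: numeric matrix (rows = samples) ->
#'   numeric vector (e.g. the probability of one class). Wrap multiclass
#'   models with [booster_class_fun()].
#' @param x Numeric vector, the sample to explain (d <= 12 features).
#' @param background Numeric matrix of background samples (columns match `x`).
#' @return An `attribution_result`: `phi` (per-feature values), `base_value`
#'   (mean model output over the background), `fx` (output at `x`), `method`.
#' @export
shapley_exact <- function(f, x, background) {
  x <- as.numeric(x)
  d <- length(x)
  if (d > 12) stop("shapley_exact: enumeration limited to d <= 12 features")
  background <- as.matrix(background)
  stopifnot(ncol(background) == d)

  Z <- as.matrix(expand.grid(rep(list(0:1), d)))[, seq_len(d), drop = FALSE]
  storage.mode(Z) <- "integer"
  v <- coalition_values(f, x, background, Z)
  sizes <- rowSums(Z)
  # weight for adding player i to S: |S|! (d - |S| - 1)! / d!
  wt <- exp(lfactorial(0:(d - 1)) + lfactorial(d - 1 - 0:(d - 1)) - lfactorial(d))
  phi <- numeric(d)
  for (i in seq_len(d)) {
    without <- Z[, i] == 0L
    idx_wo <- which(without)
    # index of S + i: flipping bit i adds 2^(i-1) in the expand.grid ordering
    idx_wi <- idx_wo + 2L^(i - 1L)
    phi[i] <- sum(wt[sizes[idx_wo] + 1L] * (v[idx_wi] - v[idx_wo]))
  }
  base <- v[1L]          # empty coalition
  fx <- v[length(v)]     # full coalition
  structure(list(phi = phi, base_value = base, fx = fx, method = "exact"),
            class = "attribution_result")
}

shapley_kernel_weight <- function(d, s) (d - 1) / (choose(d, s) * s * (d - s))

#' Kernel Shapley attribution (weighted least squares)
#'
#' Solves the Shapley-kernel weighted regression over coalitions of size
#' 1..d-1. When `n_coalitions >= 2^d - 2` every proper coalition is
#' enumerated and weighted exactly, which recovers the exact Shapley values;
#' otherwise coalitions are sampled (sizes drawn proportional to the kernel
#' mass `(d-1)/(s(d-s))`, members uniform within a size, duplicates
#' aggregated by count). Efficiency is enforced through the constraint
#' `sum(phi) = f(x) - base_value`.
#'
#' @inheritParams shapley_exact
#' @param n_coalitions Number of coalition evaluations (>= d + 2).
#' @param seed Sampling seed.
#' @return An `attribution_result` with `method = "kernel"`.
#' @export
shapley_kernel <- function(f, x, background, n_coalitions, seed = 1L) {
  x <- as.numeric(x)
  d <- length(x)
  if (n_coalitions < d + 2) stop("shapley_kernel: need n_coalitions >= d + 2")
  background <- as.matrix(background)
  stopifnot(ncol(background) == d)
  if (d < 2) stop("shapley_kernel: need at least 2 features")

  full_enum <- d <= 25 && n_coalitions >= 2^d - 2
  if (full_enum) {
    Z <- as.matrix(expand.grid(rep(list(0:1), d)))[, seq_len(d), drop = FALSE]
    sizes <- rowSums(Z)
    keep <- sizes > 0 & sizes < d
    Z <- Z[keep, , drop = FALSE]
    w <- shapley_kernel_weight(d, rowSums(Z))
  } else {
    set.seed(seed)
    size_mass <- (d - 1) / ((1:(d - 1)) * (d - (1:(d - 1))))
    sizes <- sample(1:(d - 1), n_coalitions, replace = TRUE,
                    prob = size_mass / sum(size_mass))
    Z <- matrix(0L, n_coalitions, d)
    for (r in seq_len(n_coalitions))
      Z[r, sample.int(d, sizes[r])] <- 1L
    # aggregate duplicates; sampling already carries the kernel weights
    key <- apply(Z, 1, paste, collapse = "")
    tab <- table(key)
    Z <- Z[!duplicated(key), , drop = FALSE]
    w <- as.numeric(tab[apply(Z, 1, paste, collapse = "")])
  }
  storage.mode(Z) <- "integer"

  v <- coalition_values(f, x, background, Z)
  base <- mean(f(background))
  fx <- unname(as.numeric(f(matrix(x, nrow = 1))))
  delta <- fx - base

  # eliminate phi_d via the efficiency constraint
  zd <- Z[, d]
  Xr <- Z[, -d, drop = FALSE] - zd
  yr <- v - base - zd * delta
  XtW <- t(Xr * w)
  A <- XtW %*% Xr
  sol <- tryCatch(solve(A, XtW %*% yr),
                  error = function(e)
                    stop("shapley_kernel: degenerate coalition sample (",
                         conditionMessage(e), ")"))
  phi <- c(as.numeric(sol), delta - sum(sol))
  structure(list(phi = phi, base_value = base, fx = fx, method = "kernel"),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("%s Shapley attribution: base %.6f, f(x) %.6f, residual %.2e\n",
              x$method, x$base_value, x$fx,
              x$fx - x$base_value - sum(x$phi)))
  print(round(x$phi, 6))
  invisible(x)
}

#' Wrap a fitted booster as a single-class output function
#'
#' @param booster Fitted `stage_booster`.
#' @param class_index Class to explain (0-based, matching the labels).
#' @return Function mapping a feature matrix to that class's probability.
#' @export
booster_class_fun <- function(booster, class_index) {
  if (is.null(booster$fit)) stop("booster_class_fun: booster is not fitted")
  k <- as.integer(class_index) + 1L
  function(X) {
    X <- as.matrix(X)
    p <- predict(booster$fit, xgboost::xgb.DMatrix(X))
    if (is.null(dim(p)))
      p <- matrix(p, ncol = booster$params$num_class, byrow = TRUE)
    p[, k]
  }
}

#' Seeded background subsample for attribution
#' @param embeddings An `embedding_set`.
#' @param size Maximum background rows (default 100).
#' @param seed Subsampling seed.
#' @return Numeric matrix of background samples.
#' @export
attribution_background <- function(embeddings, size = 100L, seed = 1L) {
  n <- nrow(embeddings$features)
  set.seed(seed)
  idx <- if (n <= size) seq_len(n) else sample.int(n, size)
  embeddings$features[idx, , drop = FALSE]
}
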