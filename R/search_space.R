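#' Typed, bounded hyperparameter search spaces
#'
#' A search space is an ordered list of box-constrained parameters, each either
#' continuous or integer-valued. Genotypes (candidate hyperparameter vectors)
#' are plain named numeric vectors laid out in space order; all optimizers in
#' the package operate on this shared encoding.
#'
#' @name search_space
NULL

#' Define a single search-space parameter
#'
#' @param name Parameter identifier (unique within a space).
#' @param kind `"continuous"` or `"integer"`.
#' @param low,high Inclusive bounds; for integer parameters both must be whole
#'   numbers.
#' @param active_when Optional predicate `function(values)` on a full genotype
#'   deciding whether the parameter is active at decode time (used for
#'   per-layer widths whose layer may be absent). Inactive parameters stay in
#'   the genotype so its length is fixed for the optimizer.
#' @return A `param_spec` object.
#' @export
param_spec <- function(name, kind = c("continuous", "integer"), low, high,
                       active_when = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low > high)
    stop("param_spec: need finite bounds with low <= high for '", name, "'")
  if (kind == "integer" && (low != round(low) || high != round(high)))
    stop("param_spec: integer parameter '", name, "' needs integer bounds")
  if (!is.null(active_when) && !is.function(active_when))
    stop("param_spec: active_when must be a function or NULL")
  structure(list(name = name, kind = kind, low = low, high = high,
                 active_when = active_when),
            class = "param_spec")
}

#' Assemble a search space from parameter specs
#'
#' @param ... `param_spec` objects, or a single list of them.
#' @param id Optional identifier carried along for printing/serialization.
#' @return A `search_space` object.
#' @export
search_space <- function(..., id = NULL) {
  params <- list(...)
  if (length(params) == 1L && !inherits(params[[1L]], "param_spec"))
    params <- params[[1L]]
  if (length(params) < 1L) stop("search_space: need at least one parameter")
  ok <- vapply(params, inherits, logical(1), "param_spec")
  if (!all(ok)) stop("search_space: all arguments must be param_spec objects")
  nm <- vapply(params, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("search_space: parameter names must be unique")
  names(params) <- nm
  structure(list(params = params, id = id), class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat("search_space", if (!is.null(x$id)) paste0("'", x$id, "'"), "with",
      space_dim(x), "parameters\n")
  for (p in x$params) {
    cat(sprintf("  %-18s %-10s [%g, %g]%s\n", p$name, p$kind, p$low, p$high,
                if (is.null(p$active_when)) "" else "  (conditional)"))
  }
  invisible(x)
}

#' Dimensionality of a search space
#' @param space A `search_space`.
#' @return Integer number of parameters.
#' @export
space_dim <- function(space) {
  stopifnot(inherits(space, "search_space"))
  length(space$params)
}

space_lower <- function(space) vapply(space$params, `[[`, numeric(1), "low")
space_upper <- function(space) vapply(space$params, `[[`, numeric(1), "high")
space_is_int <- function(space)
  vapply(space$params, function(p) p$kind == "integer", logical(1))

#' Built-in search spaces of the dual-layer framework
#'
#' Returns the tuning space of one framework layer:
#' \describe{
#'   \item{`L1_CNN`}{9 parameters: learning rate (0.0001--0.003), dropout
#'     (0.05--0.2), epochs (10--30), number of convolutional layers (1--2),
#'     number of dense layers (1--2), and four per-layer widths (32--96 cells:
#'     conv1, conv2, dense1, dense2). The second conv/dense widths are active
#'     only when the corresponding layer count is 2; they remain in the
#'     genotype so its length is fixed.}
#'   \item{`L2_XGB`}{6 parameters: learning rate (0.1--0.9), minimum child
#'     weight (1--5), subsample (0.01--1), column sample by tree (0.01--1),
#'     max depth (integer 1--5), gamma (0--0.8).}
#'   \item{`L2_LGBM`}{10 parameters: number of boosting rounds (integer 5--20),
#'     max depth (3--10), number of leaves (3--10), minimum child weight
#'     (1--5), feature fraction (0.1--0.9), bagging fraction (0.5--1), minimum
#'     split gain (0.001--0.1), L1 penalty (0--5), L2 penalty (0--3), learning
#'     rate (0.01--0.9).}
#' }
#'
#' @param layer_id One of `"L1_CNN"`, `"L2_XGB"`, `"L2_LGBM"`.
#' @return A `search_space`.
#' @export
builtin_space <- function(layer_id = c("L1_CNN", "L2_XGB", "L2_LGBM")) {
  layer_id <- match.arg(layer_id)
  switch(layer_id,
    L1_CNN = search_space(
      param_spec("learning_rate", "continuous", 0.0001, 0.003),
      param_spec("dropout", "continuous", 0.05, 0.2),
      param_spec("epochs", "integer", 10, 30),
      param_spec("n_conv_layers", "integer", 1, 2),
      param_spec("n_dense_layers", "integer", 1, 2),
      param_spec("conv1_width", "integer", 32, 96),
      param_spec("conv2_width", "integer", 32, 96,
                 active_when = function(v) v[["n_conv_layers"]] == 2),
      param_spec("dense1_width", "integer", 32, 96),
      param_spec("dense2_width", "integer", 32, 96,
                 active_when = function(v) v[["n_dense_layers"]] == 2),
      id = "L1_CNN"),
    L2_XGB = search_space(
      param_spec("learning_rate", "continuous", 0.1, 0.9),
      param_spec("min_child_weight", "continuous", 1, 5),
      param_spec("subsample", "continuous", 0.01, 1),
      param_spec("colsample_bytree", "continuous", 0.01, 1),
      param_spec("max_depth", "integer", 1, 5),
      param_spec("gamma", "continuous", 0, 0.8),
      id = "L2_XGB"),
    L2_LGBM = search_space(
      param_spec("n_rounds", "integer", 5, 20),
      param_spec("max_depth", "integer", 3, 10),
      param_spec("n_leaves", "integer", 3, 10),
      param_spec("min_child_weight", "continuous", 1, 5),
      param_spec("feature_fraction", "continuous", 0.1, 0.9),
      param_spec("bagging_fraction", "continuous", 0.5, 1),
      param_spec("min_split_gain", "continuous", 0.001, 0.1),
      param_spec("lambda_l1", "continuous", 0, 5),
      param_spec("lambda_l2", "continuous", 0, 3),
      param_spec("learning_rate", "continuous", 0.01, 0.9),
      id = "L2_LGBM"))
}

#' Draw a uniform random genotype
#'
#' Each continuous parameter is drawn uniformly on its interval; integer
#' parameters are drawn uniformly then rounded half-up and clipped. Uses R's
#' global random stream (seed with [set.seed()]).
#'
#' @param space A `search_space`.
#' @return A named numeric genotype in space order.
#' @export
sample_uniform <- function(space) {
  stopifnot(inherits(space, "search_space"))
  lo <- space_lower(space); hi <- space_upper(space)
  repair(stats::runif(space_dim(space), lo, hi), space)
}

round_half_up <- function(x) floor(x + 0.5)

#' Repair a genotype onto its search space
#'
#' Clips every value into its bounds; integer parameters are rounded half-up
#' before clipping. Idempotent.
#'
#' @param genotype Numeric vector, one value per parameter (names optional).
#' @param space A `search_space`.
#' @return A valid named genotype.
#' @export
repair <- function(genotype, space) {
  stopifnot(inherits(space, "search_space"))
  if (length(genotype) != space_dim(space))
    stop("repair: genotype length ", length(genotype),
         " does not match space dimensionality ", space_dim(space))
  g <- as.numeric(genotype)
  isint <- space_is_int(space)
  g[isint] <- round_half_up(g[isint])
  g <- pmin(pmax(g, space_lower(space)), space_upper(space))
  g[isint] <- round_half_up(g[isint])  # bounds are integers, keeps integrality
  names(g) <- names(space$params)
  g
}

#' Check a genotype against its space
#' @param genotype Named numeric vector.
#' @param space A `search_space`.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_genotype <- function(genotype, space) {
  if (length(genotype) != space_dim(space))
    stop("genotype length does not match space dimensionality")
  lo <- space_lower(space); hi <- space_upper(space)
  if (any(genotype < lo - 1e-12) || any(genotype > hi + 1e-12))
    stop("genotype value out of bounds")
  isint <- space_is_int(space)
  if (any(genotype[isint] != round(genotype[isint])))
    stop("integer-kind genotype entry is not an integer")
  invisible(TRUE)
}

#' Serialize / deserialize a search space
#'
#' Spaces are written as a YAML list with one `name`/`kind`/`low`/`high` entry
#' per parameter. Conditional activation rules (only used by the built-in CNN
#' space) are re-attached by `read_space` when the file declares
#' `builtin: <layer_id>`.
#'
#' @param space A `search_space`.
#' @param path File path.
#' @return `write_space` returns `path` invisibly; `read_space` returns a
#'   `search_space`.
#' @export
write_space <- function(space, path) {
  stopifnot(inherits(space, "search_space"))
  obj <- list(
    id = space$id,
    params = lapply(unname(space$params), function(p)
      list(name = p$name, kind = p$kind, low = p$low, high = p$high)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_space
#' @export
read_space <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$id) && obj$id %in% c("L1_CNN", "L2_XGB", "L2_LGBM")) {
    sp <- builtin_space(obj$id)
    # sanity: file must agree with the builtin definition it names
    filed <- vapply(obj$params, `[[`, character(1), "name")
    if (!identical(filed, names(sp$params)))
      stop("read_space: file claims builtin '", obj$id,
           "' but parameter list differs")
    return(sp)
  }
  search_space(lapply(obj$params, function(p)
    param_spec(p$name, p$kind, p$low, p$high)), id = obj$id)
}
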