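#' Repeated-run evaluation protocol and benchmark statistics
#'
#' Metaheuristic results from a single run are unreliable; the evaluation
#' protocol executes every algorithm `n_runs` times, run i seeded with
#' `base_seed + i`, summarizes each result vector with
#' best/worst/mean/median/std/var, and compares algorithms with
#' nonparametric tests: Levene for homoscedasticity, Shapiro-Wilk per group
#' for normality, and paired Wilcoxon signed-rank of a reference algorithm
#' against each competitor.
#'
#' @name experiment
NULL

#' Run every algorithm repeatedly under a shared seed ledger
#'
#' @param algorithms Named list of functions `f(seed)` returning either a
#'   single number (the run's objective) or a named list/vector of metrics.
#' @param n_runs Number of repetitions (>= 1).
#' @param base_seed Run i uses seed `base_seed + i`.
#' @return Long data frame: `algorithm`, `run`, `seed`, one column per metric
#'   (single numbers become a column named `objective`).
#' @export
run_repeated <- function(algorithms, n_runs, base_seed = 0L) {
  stopifnot(n_runs >= 1, length(algorithms) >= 1,
            !is.null(names(algorithms)), all(nzchar(names(algorithms))))
  rows <- list()
  for (alg in names(algorithms)) {
    for (i in seq_len(n_runs)) {
      seed <- as.integer(base_seed + i)
      res <- algorithms[[alg]](seed)
      if (is.numeric(res) && is.null(names(res)) && length(res) == 1L)
        res <- list(objective = res)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(algorithm = alg, run = i, seed = seed),
              as.data.frame(as.list(res)))
    }
  }
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(cols, names(r))) r[[m]] <- NA_real_
    r[cols]
  })
  do.call(rbind, rows)
}

#' Six-number summary of a result vector
#'
#' @param x Non-empty numeric vector of per-run results.
#' @param maximize If `TRUE` (default) `best = max(x)`, else `best = min(x)`.
#' @param population If `TRUE` (default) std/var use the population
#'   convention (denominator n), else the sample convention.
#' @return Named vector: best, worst, mean, median, std, var.
#' @export
summarize_runs <- function(x, maximize = TRUE, population = TRUE) {
  if (length(x) == 0) stop("summarize_runs: empty result vector")
  v <- if (population) mean((x - mean(x))^2) else stats::var(x)
  if (length(x) == 1L) v <- 0
  c(best = if (maximize) max(x) else min(x),
    worst = if (maximize) min(x) else max(x),
    mean = mean(x), median = stats::median(x),
    std = sqrt(v), var = v)
}

#' Summary table over all algorithms of a results frame
#' @param results Data frame from [run_repeated()].
#' @param metric Column to summarize (default `"objective"`).
#' @inheritParams summarize_runs
#' @return Data frame, one row per algorithm, columns algorithm + the six
#'   statistics.
#' @export
summarize_all <- function(results, metric = "objective", maximize = TRUE,
                          population = TRUE) {
  algs <- unique(results$algorithm)
  out <- lapply(algs, function(a) {
    s <- summarize_runs(results[[metric]][results$algorithm == a],
                        maximize = maximize, population = population)
    cbind(data.frame(algorithm = a), as.data.frame(as.list(s)))
  })
  do.call(rbind, out)
}

#' Nonparametric comparison of algorithms over repeated runs
#'
#' Levene's test (mean-centered by default) across all groups, Shapiro-Wilk
#' per group, and paired two-sided Wilcoxon signed-rank tests of the
#' reference algorithm against every other (runs are paired by seed). Pairs
#' whose differences are all zero are degenerate for the signed-rank
#' statistic and are reported as p = 1 with a flag.
#'
#' @param results Data frame from [run_repeated()] (>= 2 algorithms, >= 5
#'   runs each).
#' @param reference Name of the reference algorithm.
#' @param metric Metric column (default `"objective"`).
#' @param alpha Significance level recorded in the report (default 0.05).
#' @param levene_center `"mean"` (classic Levene, default) or `"median"`.
#' @return A `stat_test_report`: `levene_p`, `shapiro` (data frame of
#'   per-group p), `wilcoxon` (data frame: comparison, p, degenerate),
#'   `alpha`.
#' @export
statistical_tests <- function(results, reference, metric = "objective",
                              alpha = 0.05, levene_center = c("mean", "median")) {
  levene_center <- match.arg(levene_center)
  algs <- unique(results$algorithm)
  if (length(algs) < 2) stop("statistical_tests: need >= 2 algorithms")
  if (!reference %in% algs) stop("statistical_tests: unknown reference")
  series <- lapply(algs, function(a) {
    d <- results[results$algorithm == a, ]
    d[[metric]][order(d$run)]
  })
  names(series) <- algs
  ns <- lengths(series)
  if (any(ns < 5)) stop("statistical_tests: need >= 5 runs per algorithm")

  lev <- car::leveneTest(
    unlist(series), factor(rep(algs, ns)),
    center = if (levene_center == "mean") mean else stats::median)
  levene_p <- lev[["Pr(>F)"]][1]

  shapiro <- data.frame(
    algorithm = algs,
    p = vapply(series, function(v) {
      if (length(unique(v)) == 1L) NA_real_ else stats::shapiro.test(v)$p.value
    }, numeric(1)), row.names = NULL)

  others <- setdiff(algs, reference)
  wilc <- lapply(others, function(a) {
    d <- series[[reference]] - series[[a]]
    if (all(d == 0))
      return(data.frame(comparison = paste(reference, "vs", a),
                        p = 1, degenerate = TRUE))
    wt <- suppressWarnings(stats::wilcox.test(series[[reference]], series[[a]],
                                              paired = TRUE))
    data.frame(comparison = paste(reference, "vs", a),
               p = wt$p.value, degenerate = FALSE)
  })
  structure(list(levene_p = levene_p, shapiro = shapiro,
                 wilcoxon = do.call(rbind, wilc), alpha = alpha),
            class = "stat_test_report")
}

#' @export
print.stat_test_report <- function(x, ...) {
  cat(sprintf("Levene p = %.4f (alpha = %g)\n", x$levene_p, x$alpha))
  cat("Shapiro-Wilk per group:\n"); print(x$shapiro, row.names = FALSE)
  cat("Paired Wilcoxon signed-rank:\n"); print(x$wilcoxon, row.names = FALSE)
  invisible(x)
}

#' Export result tables, summaries and convergence traces as CSV
#'
#' @param results Data frame from [run_repeated()].
#' @param summaries Data frame from [summarize_all()] (or a list of them).
#' @param histories Optional named list (per algorithm) of per-run best-so-far
#'   fitness matrices or vectors; flattened into a long convergence CSV.
#' @param dir Output directory (created if missing).
#' @return Invisible character vector of the files written.
#' @export
export_artifacts <- function(results, summaries, histories = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(dir, "results.csv")
  utils::write.csv(results, f, row.names = FALSE); files <- c(files, f)
  if (is.data.frame(summaries)) summaries <- list(summary = summaries)
  for (nm in names(summaries)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(summaries[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(histories)) {
    rows <- list()
    for (alg in names(histories)) {
      hs <- histories[[alg]]
      if (!is.list(hs)) hs <- list(hs)
      for (r in seq_along(hs))
        rows[[length(rows) + 1L]] <-
          data.frame(algorithm = alg, run = r,
                     iteration = seq_along(hs[[r]]),
                     best_fitness = as.numeric(hs[[r]]))
    }
    f <- file.path(dir, "convergence.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
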