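#' Variable neighborhood search and its stagnation-aware variant
#'
#' [run_vns()] implements a population variant of continuous VNS: each agent
#' follows its own shake / local-search / greedy-accept / neighborhood-advance
#' trajectory while a shared elite tracks the best solution ever evaluated.
#' [run_qsavns()] adds two mechanisms: quasi-reflexive population
#' initialization (half the agents are sampled between the box midpoint and a
#' uniformly drawn counterpart, widening early coverage) and an elitist soft
#' rollback that regenerates every non-elite agent after `s_tresh = ceil(T/3)`
#' consecutive iterations without improvement of the global best.
#'
#' The cost unit is the fitness-function evaluation (FFE): one objective call,
#' i.e. one model training/validation cycle when tuning hyperparameters. With
#' local search disabled (the default) a run spends exactly `N * (T + 1)` FFEs:
#' N at initialization plus one shaken candidate per agent per iteration.
#' Rollback regeneration marks agents unevaluated instead of spending extra
#' FFEs; a regenerated agent is first scored through its next shaken candidate.
#'
#' @name optimizer
NULL

#' Optimizer configuration
#'
#' @param N Population size (>= 1).
#' @param T Number of iterations (>= 1).
#' @param k_max Number of neighborhood structures (default 3).
#' @param seed Base random seed for the run.
#' @param s_tresh Stagnation threshold; default `ceiling(T / 3)`.
#' @param local_search_tries Perturbation budget of the first-improvement hill
#'   climb applied to each shaken candidate; 0 disables local search.
#' @param r0 Base shake radius as a fraction of each parameter's range.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(N, T, k_max = 3L, seed = 1L, s_tresh = NULL,
                             local_search_tries = 0L, r0 = 0.3) {
  stopifnot(N >= 1, T >= 1, k_max >= 1, local_search_tries >= 0, r0 > 0)
  if (is.null(s_tresh)) s_tresh <- ceiling(T / 3)
  stopifnot(s_tresh >= 1)
  structure(list(N = as.integer(N), T = as.integer(T),
                 k_max = as.integer(k_max), seed = as.integer(seed),
                 s_tresh = as.integer(s_tresh),
                 local_search_tries = as.integer(local_search_tries),
                 r0 = r0),
            class = "optimizer_config")
}

#' Quasi-reflexive image of a genotype
#'
#' For each dimension j with box `[lb_j, ub_j]` and midpoint
#' `m_j = (lb_j + ub_j) / 2`, draws uniformly on
#' `[min(m_j, x_j), max(m_j, x_j)]`, then repairs integer dimensions. When
#' `x_j` equals the midpoint the interval is degenerate and `x_j` is returned.
#'
#' @param genotype A valid genotype.
#' @param space Its `search_space`.
#' @return A repaired genotype.
#' @export
qrl_reflect <- function(genotype, space) {
  lo <- space_lower(space); hi <- space_upper(space)
  m <- (lo + hi) / 2
  a <- pmin(m, genotype); b <- pmax(m, genotype)
  repair(stats::runif(length(genotype), a, b), space)
}

#' Initialize a population with quasi-reflexive diversification
#'
#' `ceiling(N/2)` agents are drawn uniformly; the remaining `floor(N/2)` are
#' quasi-reflexive images of the uniform subset (cycled when N is odd). All
#' agents start unevaluated (`fitness = NA`).
#'
#' @param space A `search_space`.
#' @param N Population size.
#' @param qrl If `FALSE`, all N agents are uniform draws (baseline VNS).
#' @return List of agents, each `list(genotype, fitness = NA)`.
#' @export
initialize_population <- function(space, N, qrl = TRUE) {
  stopifnot(N >= 1)
  n_u <- if (qrl) ceiling(N / 2) else N
  agents <- vector("list", N)
  for (i in seq_len(n_u))
    agents[[i]] <- list(genotype = sample_uniform(space), fitness = NA_real_)
  if (N > n_u) {
    for (i in seq_len(N - n_u)) {
      src <- agents[[((i - 1L) %% n_u) + 1L]]$genotype
      agents[[n_u + i]] <- list(genotype = qrl_reflect(src, space),
                                fitness = NA_real_)
    }
  }
  agents
}

#' Shake a genotype within neighborhood k
#'
#' Perturbs every dimension by a uniform draw on
#' `+/- (k / k_max) * r0 * (ub_j - lb_j)` around the current value, then
#' repairs. Larger k gives stochastically larger moves; at `k = k_max` with
#' `r0 = 1` the whole box is reachable.
#'
#' @param genotype Current genotype.
#' @param k Neighborhood index in `1..k_max`.
#' @param space A `search_space`.
#' @param k_max Number of neighborhoods.
#' @param r0 Base radius fraction.
#' @return A repaired genotype.
#' @export
shake <- function(genotype, k, space, k_max = 3L, r0 = 0.3) {
  if (k < 1 || k > k_max) stop("shake: k must be in 1..k_max")
  rad <- (k / k_max) * r0 * (space_upper(space) - space_lower(space))
  repair(genotype + stats::runif(length(genotype), -rad, rad), space)
}

#' First-improvement local search
#'
#' Applies up to `tries` small perturbations (neighborhood-1 radius scaled by
#' 0.1) to `candidate`, accepting the first strict improvement and stopping.
#' The candidate's own fitness is supplied by the caller (or computed here if
#' missing, which is not counted in `evals`); `evals` counts perturbation
#' evaluations only, so `evals <= tries`.
#'
#' @param candidate Genotype to refine.
#' @param space A `search_space`.
#' @param objective Function `genotype -> fitness` (maximized).
#' @param tries Maximum perturbation evaluations (>= 0).
#' @param candidate_fitness Fitness of `candidate`, if already known.
#' @param k_max,r0 Shake geometry (the step radius is `0.1 * r0 / k_max`).
#' @return `list(genotype, fitness, evals)`.
#' @export
local_search <- function(candidate, space, objective, tries,
                         candidate_fitness = NULL, k_max = 3L, r0 = 0.3) {
  stopifnot(tries >= 0)
  if (tries == 0)
    return(list(genotype = candidate, fitness = candidate_fitness, evals = 0L))
  f0 <- if (is.null(candidate_fitness)) objective(candidate) else candidate_fitness
  rad <- 0.1 * (1 / k_max) * r0 * (space_upper(space) - space_lower(space))
  evals <- 0L
  for (i in seq_len(tries)) {
    trial <- repair(candidate + stats::runif(length(candidate), -rad, rad), space)
    ft <- objective(trial)
    evals <- evals + 1L
    if (ft > f0) {
      candidate <- trial; f0 <- ft
      break
    }
  }
  list(genotype = candidate, fitness = f0, evals = evals)
}

#' Elitist rollback of a stagnated population
#'
#' Keeps the elite agent verbatim and regenerates the other `N - 1` agents by
#' the quasi-reflexive initialization scheme; resets the stagnation counter.
#' Regenerated agents are unevaluated.
#'
#' @param state Optimizer state as used internally by [run_qsavns()]:
#'   `list(population, best, s_count, ...)` with `s_count == s_tresh`.
#' @param space A `search_space`.
#' @param s_tresh Stagnation threshold the state is checked against.
#' @return The state with a fresh population, elite preserved, `s_count = 0`.
#' @export
rollback <- function(state, space, s_tresh) {
  if (state$s_count < s_tresh)
    stop("rollback: called with s_count < s_tresh")
  N <- length(state$population)
  if (N > 1) {
    fresh <- initialize_population(space, N - 1L, qrl = TRUE)
    state$population <- c(list(state$best), fresh)
  }
  state$s_count <- 0L
  state
}

vns_engine <- function(space, objective, config, qrl, stagnation) {
  stopifnot(inherits(config, "optimizer_config"))
  N <- config$N; T <- config$T; k_max <- config$k_max
  set.seed(config$seed)

  eval_count <- 0L
  f <- function(g) {
    val <- objective(g)
    if (!is.numeric(val) || length(val) != 1L || is.na(val))
      stop("objective must return a single non-missing number; got ",
           paste(utils::head(val), collapse = ", "))
    eval_count <<- eval_count + 1L
    val
  }

  pop <- initialize_population(space, N, qrl = qrl)
  for (i in seq_len(N)) pop[[i]]$fitness <- f(pop[[i]]$genotype)
  bi <- which.max(vapply(pop, `[[`, numeric(1), "fitness"))
  best <- pop[[bi]]

  k_i <- rep(1L, N)
  s_count <- 0L
  history <- numeric(T)
  rollback_events <- integer(0)

  for (iter in seq_len(T)) {
    improved_best <- FALSE
    for (i in seq_len(N)) {
      cand <- shake(pop[[i]]$genotype, k_i[i], space, k_max, config$r0)
      fc <- f(cand)
      ls <- local_search(cand, space, f, config$local_search_tries,
                         candidate_fitness = fc, k_max = k_max, r0 = config$r0)
      if (is.na(pop[[i]]$fitness) || ls$fitness > pop[[i]]$fitness) {
        pop[[i]] <- list(genotype = ls$genotype, fitness = ls$fitness)
        k_i[i] <- 1L
      } else {
        k_i[i] <- (k_i[i] %% k_max) + 1L
      }
      if (ls$fitness > best$fitness) {
        best <- list(genotype = ls$genotype, fitness = ls$fitness)
        improved_best <- TRUE
      }
    }
    history[iter] <- best$fitness
    if (stagnation) {
      if (!improved_best) {
        s_count <- s_count + 1L
        if (s_count == config$s_tresh) {
          st <- rollback(list(population = pop, best = best, s_count = s_count),
                         space, config$s_tresh)
          pop <- st$population
          s_count <- st$s_count
          k_i <- rep(1L, N)
          rollback_events <- c(rollback_events, iter)
        }
      } else {
        s_count <- 0L
      }
    }
  }

  structure(list(best = best, history = history, ffe_count = eval_count,
                 rollback_events = rollback_events, config = config,
                 algorithm = if (stagnation) "qsavns" else "vns"),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("%s: best fitness %.6f after %d FFEs (%d iterations)\n",
              toupper(x$algorithm), x$best$fitness, x$ffe_count,
              length(x$history)))
  if (length(x$rollback_events))
    cat("rollbacks at iterations:", paste(x$rollback_events, collapse = ", "), "\n")
  invisible(x)
}

#' Run baseline variable neighborhood search
#'
#' @param space A `search_space`.
#' @param objective Function `genotype -> fitness`, maximized. Minimization
#'   problems should return the negated value.
#' @param config An [optimizer_config()].
#' @return An `optimization_result`: `best` (genotype + fitness), per-iteration
#'   `history` of the best fitness, `ffe_count`, `rollback_events` (empty for
#'   baseline VNS).
#' @export
run_vns <- function(space, objective, config) {
  vns_engine(space, objective, config, qrl = FALSE, stagnation = FALSE)
}

#' Run quasi-reflexive stagnation-aware VNS
#'
#' As [run_vns()] plus quasi-reflexive initialization and elitist rollback
#' after `s_tresh` improvement-free iterations.
#'
#' @inheritParams run_vns
#' @return An `optimization_result`.
#' @export
run_qsavns <- function(space, objective, config) {
  vns_engine(space, objective, config, qrl = TRUE, stagnation = TRUE)
}
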