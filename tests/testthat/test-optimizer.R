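test_that("quasi-reflexive reflection stays between midpoint and the solution", {
  sp <- search_space(param_spec("x", "continuous", 0, 10))
  set.seed(3)
  # x at the midpoint: degenerate interval, fixed point
  expect_equal(unname(qrl_reflect(c(x = 5), sp)), 5)
  # x below the midpoint: draw lands in [x, m]
  for (i in 1:50) {
    v <- qrl_reflect(c(x = 2), sp)
    expect_true(v >= 2 && v <= 5)
  }
  # learning-rate bounds: reflection of the upper bound stays in [m, ub]
  lr <- search_space(param_spec("lr", "continuous", 0.0001, 0.003))
  for (i in 1:50) {
    v <- qrl_reflect(c(lr = 0.003), lr)
    expect_true(v >= 0.00155 && v <= 0.003)
  }
  # property over random spaces and points (integer dims repaired afterwards)
  for (i in 1:100) {
    lo <- runif(1, -5, 0); hi <- lo + runif(1, 0.5, 10)
    spi <- search_space(param_spec("x", "continuous", lo, hi))
    x <- runif(1, lo, hi); m <- (lo + hi) / 2
    v <- qrl_reflect(c(x = x), spi)
    expect_true(v >= min(m, x) - 1e-12 && v <= max(m, x) + 1e-12)
  }
})

test_that("population initialization mixes uniform draws with QRL images", {
  sp <- builtin_space("L2_XGB")
  set.seed(4)
  pop <- initialize_population(sp, 8)
  expect_length(pop, 8)
  expect_true(all(vapply(pop, function(a) is.na(a$fitness), logical(1))))
  lo <- vapply(sp$params, `[[`, numeric(1), "low")
  hi <- vapply(sp$params, `[[`, numeric(1), "high")
  for (a in pop) expect_true(all(a$genotype >= lo & a$genotype <= hi))
  # smallest population: one uniform agent, no reflections
  one <- initialize_population(sp, 1)
  expect_length(one, 1)
})

test_that("shake produces repaired genotypes with k-ordered perturbation size", {
  sp <- search_space(param_spec("x", "continuous", 0, 10))
  g <- c(x = 5)
  expect_error(shake(g, 4, sp, k_max = 3), "k must be")
  set.seed(8)
  d1 <- replicate(1000, abs(shake(g, 1, sp)[1] - 5))
  d3 <- replicate(1000, abs(shake(g, 3, sp)[1] - 5))
  expect_true(all(d1 <= (1 / 3) * 0.3 * 10 + 1e-12))
  expect_gt(mean(d3), mean(d1))
  # empirical CDF of k=1 magnitudes dominates k=3 (larger k, larger moves)
  qs <- seq(0.1, 0.9, by = 0.2)
  expect_true(all(quantile(d1, qs) <= quantile(d3, qs)))
})

test_that("local search never worsens and respects its evaluation budget", {
  sp <- benchmark_space(1)
  f <- benchmark_objective("sphere", 1)
  # disabled: candidate unchanged, no evaluations
  out0 <- local_search(c(x1 = 1), sp, f, tries = 0)
  expect_equal(unname(out0$genotype), 1)
  expect_equal(out0$evals, 0L)
  expect_equal(evaluation_count(f), 0L)

  set.seed(2)
  f1 <- benchmark_objective("sphere", 1)
  out <- local_search(c(x1 = 1), sp, f1, tries = 50, candidate_fitness = f1(c(1)))
  expect_gte(out$fitness, -1)          # non-worsening from f(1) = -1
  expect_lte(out$evals, 50L)
})

test_that("VNS is elitist, budget-exact and reproducible", {
  sp <- benchmark_space(2)
  run1 <- run_vns(sp, benchmark_objective("sphere", 2),
                  optimizer_config(8, 20, seed = 10))
  expect_length(run1$history, 20)
  expect_true(all(diff(run1$history) >= 0))
  expect_equal(run1$best$fitness, max(run1$history))
  expect_equal(run1$ffe_count, 8 * (20 + 1))      # exact with tries = 0
  expect_length(run1$rollback_events, 0)

  run2 <- run_vns(sp, benchmark_objective("sphere", 2),
                  optimizer_config(8, 20, seed = 10))
  expect_identical(run1$best, run2$best)
  expect_identical(run1$history, run2$history)

  # with local search enabled the closed-form cap still holds
  run3 <- run_vns(sp, benchmark_objective("sphere", 2),
                  optimizer_config(4, 10, seed = 3, local_search_tries = 2))
  expect_lte(run3$ffe_count, 4 * (1 + 10 * (1 + 2)))
})

test_that("stagnation rollback fires exactly on the ceil(T/3) schedule", {
  sp <- benchmark_space(3)
  flat <- function(g) 1                     # constant objective: never improves
  res <- run_qsavns(sp, flat, optimizer_config(8, 10, seed = 1))
  expect_equal(ceiling(10 / 3), 4)
  expect_equal(res$rollback_events, c(4L, 8L))
  expect_equal(res$best$fitness, 1)
  expect_equal(res$ffe_count, 8 * 11)       # rollback spends no evaluations

  res2 <- run_qsavns(sp, flat, optimizer_config(5, 9, seed = 2))
  expect_equal(res2$rollback_events, c(3L, 6L, 9L))
})

test_that("rollback preserves the elite verbatim and requires saturation", {
  sp <- builtin_space("L2_XGB")
  set.seed(6)
  pop <- initialize_population(sp, 8)
  for (i in seq_along(pop)) pop[[i]]$fitness <- runif(1)
  best <- pop[[which.max(vapply(pop, `[[`, numeric(1), "fitness"))]]
  st <- list(population = pop, best = best, s_count = 4L)
  expect_error(rollback(list(population = pop, best = best, s_count = 2L),
                        sp, s_tresh = 4L), "s_count")
  out <- rollback(st, sp, s_tresh = 4L)
  expect_equal(out$s_count, 0L)
  expect_identical(out$population[[1L]], best)
  # regenerated agents are fresh draws: identical genotypes have probability 0
  regen <- vapply(out$population[-1L], function(a)
    any(vapply(pop, function(b) identical(b$genotype, a$genotype), logical(1))),
    logical(1))
  expect_false(any(regen))
})

test_that("QSAVNS beats equal-budget random search on rastrigin", {
  sp <- benchmark_space(5)
  seeds <- 1:30
  diffs <- vapply(seeds, function(s) {
    f <- benchmark_objective("rastrigin", 5)
    res <- run_qsavns(sp, f, optimizer_config(10, 50, seed = s))
    set.seed(s + 10000)
    rnd <- max(vapply(seq_len(res$ffe_count),
                      function(i) f(runif(5, -5.12, 5.12)), numeric(1)))
    res$best$fitness - rnd
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("QSAVNS converges on a smooth unimodal surface", {
  sp <- benchmark_space(2)
  hits <- vapply(1:30, function(s) {
    f <- benchmark_objective("sphere", 2)
    res <- run_qsavns(sp, f, optimizer_config(10, 50, seed = s,
                                              local_search_tries = 2))
    res$best$fitness >= -1e-2
  }, logical(1))
  expect_gte(sum(hits), 27)
})

test_that("objective errors abort with context and bad returns are rejected", {
  sp <- benchmark_space(2)
  expect_error(run_vns(sp, function(g) stop("boom"), optimizer_config(2, 2)),
               "boom")
  expect_error(run_vns(sp, function(g) c(1, 2), optimizer_config(2, 2)),
               "single")
})
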