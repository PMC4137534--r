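surrogate <- function(x) -sum((x - 0.5001)^2)

test_that("decode selects strictly-greater-than-0.5 components", {
  expect_equal(decode(c(0.6, 0.4, 0.51)), c(1L, 3L))
  expect_equal(decode(c(0.5, 0.5, 0.500000001)), 3L)   # 0.5 excluded
  expect_equal(decode(rep(0, 4)), integer(0))
  expect_equal(decode(rep(1, 3)), 1:3)
  expect_error(decode(c(0.2, NaN)), "non-finite")
})

test_that("levy_step: scale identity, determinism, parameter validation", {
  set.seed(1)
  expect_identical(levy_step(1.5, 0, 100), rep(0, 100))
  set.seed(42); x1 <- levy_step(1.5, 1, 50)
  set.seed(42); x2 <- levy_step(1.5, 1, 50)
  expect_identical(x1, x2)
  expect_error(levy_step(0.9, 1, 10), "lambda")
  expect_error(levy_step(3, 1, 10), "lambda")
  expect_error(levy_step(1.5, -1, 10), "alpha")
  expect_warning(levy_step(2.5, 1, 10), "clamping")
})

test_that("pso_step reproduces the hand-evaluated update under forced draws", {
  cfg <- optimizer_config("pso", dim = 1, w = 1, c1 = 1, c2 = 1, vmax = 10)
  state <- list(X = matrix(0.2), V = matrix(0), P = matrix(0.4),
                pfit = 1e6,      # never improved, bests stay fixed
                gbest = 0.6, gfit = 1e6, cfg = cfg)
  out <- pso_step(state, function(x) 0, rand_fn = function(n) rep(1, n))
  expect_equal(out$V[1, 1], 0.6)   # 1*0 + 1*(0.4-0.2) + 1*(0.6-0.2)
  expect_equal(out$X[1, 1], 0.8)
})

test_that("pso_step degenerate coefficients freeze the swarm", {
  cfg <- optimizer_config("pso", dim = 3, w = 0, c1 = 0, c2 = 0)
  set.seed(2)
  x <- matrix(runif(15), 5, 3)
  state <- list(X = x, V = matrix(runif(15), 5, 3), P = x,
                pfit = rep(0, 5), gbest = x[1, ], gfit = 0, cfg = cfg)
  out <- pso_step(state, surrogate)
  expect_true(all(out$V == 0))
  expect_identical(out$X, x)
})

test_that("pso clamps velocities and positions", {
  cfg <- optimizer_config("pso", dim = 2, w = 1, c1 = 50, c2 = 50,
                          vmax = 0.3)
  set.seed(3)
  x <- matrix(runif(8), 4, 2)
  state <- list(X = x, V = matrix(0, 4, 2), P = matrix(runif(8), 4, 2),
                pfit = rep(-Inf, 4), gbest = runif(2), gfit = -Inf,
                cfg = cfg)
  out <- pso_step(state, surrogate)
  expect_true(all(abs(out$V) <= 0.3))
  expect_true(all(out$X >= 0 & out$X <= 1))
})

test_that("cs_step degenerate rules: pa = 0 and alpha = 0", {
  cfg0 <- optimizer_config("cs", dim = 4, alpha = 0, pa = 0)
  set.seed(5)
  x <- matrix(runif(24), 6, 4)
  fit <- apply(x, 1, surrogate)
  out <- cs_step(list(X = x, fit = fit, cfg = cfg0), surrogate)
  # alpha = 0: proposals equal current positions; pa = 0: no re-init.
  # A proposal can still replace a random *worse* nest with a copy, but the
  # best fitness and the set of fitness values cannot improve beyond the
  # existing maximum.
  expect_equal(max(out$fit), max(fit))
  expect_true(all(out$fit %in% fit))

  cfg1 <- optimizer_config("cs", dim = 4, pa = 0)
  set.seed(6)
  out1 <- cs_step(list(X = x, fit = fit, cfg = cfg1), surrogate)
  expect_gte(max(out1$fit), max(fit))   # elitism: best never degrades
})

test_that("sfl_sort_partition deals sorted frogs round-robin", {
  fit <- c(9, 8, 7, 6, 5, 4, 3, 2, 1)   # already sorted descending
  mem <- sfl_sort_partition(fit, 3)
  expect_equal(mem[[1]], c(1L, 4L, 7L))
  expect_equal(mem[[2]], c(2L, 5L, 8L))
  expect_equal(mem[[3]], c(3L, 6L, 9L))

  # unsorted input: partition follows fitness rank, not index
  fit2 <- c(1, 9, 5)
  mem2 <- sfl_sort_partition(fit2, 1)
  expect_equal(mem2[[1]], c(2L, 3L, 1L))

  expect_error(sfl_sort_partition(rep(1, 10), 3), "not divisible")
})

test_that("sfl_worst_update follows the three-attempt fallback chain", {
  mp <- list(positions = rbind(c(0.8, 0.8), c(0.2, 0.2)),
             fitnesses = c(surrogate(c(0.8, 0.8)), surrogate(c(0.2, 0.2))))
  # forced rand() = 1 and improving fitness: worst frog lands on Xb
  out <- sfl_worst_update(mp, xg = c(0.5, 0.5), surrogate, dmax = 10,
                          rand_fn = function(n) rep(1, n))
  expect_equal(out$memeplex$positions[2, ], c(0.8, 0.8))
  expect_equal(out$evals, 1L)

  # Xw = Xb: attempt 1 is a zero step, falls through to Xg
  mp2 <- list(positions = rbind(c(0.3, 0.3), c(0.3, 0.3)),
              fitnesses = rep(surrogate(c(0.3, 0.3)), 2))
  out2 <- sfl_worst_update(mp2, xg = c(0.5, 0.5), surrogate, dmax = 10,
                           rand_fn = function(n) rep(1, n))
  expect_equal(out2$memeplex$positions[1, ], c(0.5, 0.5))
  expect_equal(out2$evals, 2L)

  # all attempts fail -> fresh uniform random frog
  set.seed(8)
  always_worse <- local({
    calls <- 0
    function(x) { calls <<- calls + 1; -1e9 - calls }
  })
  mp3 <- list(positions = rbind(c(0.6, 0.6), c(0.4, 0.4)),
              fitnesses = c(-1, -2))
  out3 <- sfl_worst_update(mp3, xg = c(0.9, 0.9), always_worse, dmax = 0.5)
  expect_equal(out3$evals, 3L)
  expect_false(identical(out3$memeplex$positions[2, ], c(0.4, 0.4)))
  expect_true(all(out3$memeplex$positions >= 0 &
                    out3$memeplex$positions <= 1))
  expect_equal(out3$memeplex$fitnesses[1], -1)   # only the worst frog moves
})

test_that("sfllf_worst_update with unit Levy vector reproduces sfl with rand 1", {
  mp <- list(positions = rbind(c(0.9, 0.1), c(0.4, 0.6)),
             fitnesses = c(surrogate(c(0.9, 0.1)), surrogate(c(0.4, 0.6))))
  improving <- function(x) surrogate(x)
  a <- sfl_worst_update(mp, xg = c(0.5, 0.5), improving, dmax = 0.5,
                        rand_fn = function(n) rep(1, n))
  b <- sfllf_worst_update(mp, xg = c(0.5, 0.5), improving, lf = 1,
                          dmax = 0.5,
                          levy_fn = function(lambda, alpha, d) rep(1, d))
  expect_equal(a$memeplex$positions, b$memeplex$positions)
  expect_equal(a$memeplex$fitnesses, b$memeplex$fitnesses)

  # lf = 0 degenerates to zero steps: always falls to random replacement
  set.seed(10)
  z <- sfllf_worst_update(mp, xg = c(0.5, 0.5), improving, lf = 0,
                          dmax = 0.5)
  expect_equal(z$evals, 3L)
})

test_that("optimizer_config carries the canonical defaults and validates", {
  cfg <- optimizer_config("pso", dim = 10)
  expect_equal(cfg$population, 50L)
  expect_equal(cfg$generations, 200L)
  expect_equal(cfg$w, 0.9)
  expect_equal(cfg$c1, 2.1)
  expect_equal(cfg$c2, 2.1)
  expect_equal(cfg$alpha, 1)
  expect_equal(cfg$lambda, 1.5)
  expect_equal(cfg$n_memeplexes, 10L)
  expect_equal(cfg$frogs_per_memeplex, 5L)
  expect_equal(cfg$shuffles, 20L)

  expect_error(optimizer_config("sfl", dim = 5, population = 49),
               "must equal")
  expect_error(optimizer_config("sfl", dim = 5, generations = 199),
               "divisible")
  expect_error(optimizer_config("nope", dim = 5))
  expect_error(optimizer_config("cs", dim = 5, pa = 1.5), "pa")
})

test_that("run_optimizer: zero generations returns the best initial candidate", {
  cfg <- optimizer_config("pso", dim = 6, generations = 0)
  r <- run_optimizer(cfg, surrogate, seed = 31)
  manual <- with_seed(31, {
    x <- matrix(runif(50 * 6), 50, 6)
    fits <- apply(x, 1, surrogate)
    list(pos = x[which.max(fits), ], fit = max(fits))
  })
  expect_equal(r$best_fitness, manual$fit)
  expect_equal(r$best_position, manual$pos)
  expect_length(r$trace, 0L)
  expect_equal(r$evaluations, 50L)
})

test_that("all four algorithms: determinism, box constraint, monotone trace", {
  for (algo in c("pso", "cs", "sfl", "sfllf")) {
    cfg <- optimizer_config(algo, dim = 8, population = 10,
                            generations = 20, n_memeplexes = 2,
                            frogs_per_memeplex = 5, shuffles = 4)
    r1 <- run_optimizer(cfg, surrogate, seed = 7)
    r2 <- run_optimizer(cfg, surrogate, seed = 7)
    expect_identical(r1, r2)
    expect_true(all(r1$best_position >= 0 & r1$best_position <= 1))
    expect_true(all(diff(r1$trace) >= 0))
    expect_length(r1$trace, 20L)
    expect_identical(r1$best_mask, decode(r1$best_position))
    r3 <- run_optimizer(cfg, surrogate, seed = 8)
    expect_false(identical(r1$best_position, r3$best_position))
  }
})

test_that("run_optimizer leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  run_optimizer(optimizer_config("cs", dim = 4, population = 5,
                                 generations = 3), surrogate, seed = 1)
  expect_identical(.Random.seed, before)
})
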