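#' Decode a continuous position into a gene mask
#'
#' A candidate is a point in `[0,1]^m` over the top-m candidate genes; gene
#' j is selected iff `position[j]` is strictly greater than 0.5.  A value of
#' exactly 0.5 is excluded.
#'
#' @param position numeric vector with finite components.
#' @return integer vector of selected indices (possibly empty).
#' @examples
#' decode(c(0.6, 0.4, 0.51))  # 1, 3
#' decode(c(0.5, 0.5))        # integer(0)
#' @export
decode <- function(position) {
  if (any(!is.finite(position))) {
    stop("position has non-finite components", call. = FALSE)
  }
  which(position > 0.5)
}

#' Optimizer configuration with canonical defaults
#'
#' Defaults are the benchmark parameterization used throughout the package:
#' population 50, 200 generations, inertia weight `w = 0.9`, acceleration
#' coefficients `c1 = c2 = 2.1`, Levy scale `alpha = 1` and exponent
#' `lambda = 1.5`, 10 memeplexes of 5 frogs with 20 shuffles.  Parameters
#' the benchmark leaves open get canonical values: nest-discovery
#' probability `pa = 0.25`, velocity clamp `vmax = 1`, frog step clamp
#' `dmax = 0.5` (half the unit range), Levy-step scale `lf = 1`.
#'
#' @param algorithm one of `"pso"`, `"cs"`, `"sfl"`, `"sfllf"`.
#' @param dim dimension m of the search space (candidate gene count).
#' @param population population size (for SFL variants this must equal
#'   `n_memeplexes * frogs_per_memeplex`).
#' @param generations total generation budget.  For SFL variants the budget
#'   is organized as `shuffles` shuffles of `generations / shuffles`
#'   worst-frog improvement cycles per memeplex each.
#' @param w,c1,c2,vmax PSO inertia, cognitive and social coefficients, and
#'   componentwise velocity clamp.
#' @param alpha,lambda,pa cuckoo-search step scale, Levy exponent, and
#'   nest-discovery probability.
#' @param n_memeplexes,frogs_per_memeplex,shuffles,dmax SFL partition shape,
#'   shuffle count, and componentwise frog step clamp.
#' @param lf Levy-step scale for the Levy-flight frog variant.
#' @param levy_direction `"best"` (step = Levy draw times the
#'   current-minus-best direction, the canonical cuckoo-search practice) or
#'   `"none"` (undirected `x + alpha * L`).
#' @return an `OptimizerConfig` list.
#' @export
optimizer_config <- function(algorithm = c("pso", "cs", "sfl", "sfllf"),
                             dim,
                             population = 50L, generations = 200L,
                             w = 0.9, c1 = 2.1, c2 = 2.1, vmax = 1,
                             alpha = 1, lambda = 1.5, pa = 0.25,
                             n_memeplexes = 10L, frogs_per_memeplex = 5L,
                             shuffles = 20L, dmax = 0.5, lf = 1,
                             levy_direction = c("best", "none")) {
  algorithm <- match.arg(algorithm)
  cfg <- list(algorithm = algorithm, dim = as.integer(dim),
              population = as.integer(population),
              generations = as.integer(generations),
              w = w, c1 = c1, c2 = c2, vmax = vmax,
              alpha = alpha, lambda = lambda, pa = pa,
              n_memeplexes = as.integer(n_memeplexes),
              frogs_per_memeplex = as.integer(frogs_per_memeplex),
              shuffles = as.integer(shuffles), dmax = dmax, lf = lf,
              levy_direction = match.arg(levy_direction))
  if (cfg$dim < 1L) stop("dim must be >= 1", call. = FALSE)
  if (cfg$population < 2L) stop("population must be >= 2", call. = FALSE)
  if (cfg$generations < 0L) stop("generations must be >= 0", call. = FALSE)
  if (!is.finite(cfg$pa) || cfg$pa < 0 || cfg$pa > 1) {
    stop("pa must lie in [0, 1]", call. = FALSE)
  }
  if (algorithm %in% c("sfl", "sfllf")) {
    if (cfg$population != cfg$n_memeplexes * cfg$frogs_per_memeplex) {
      stop(sprintf(
        "population (%d) must equal n_memeplexes * frogs_per_memeplex (%d x %d)",
        cfg$population, cfg$n_memeplexes, cfg$frogs_per_memeplex),
        call. = FALSE)
    }
    if (cfg$generations > 0L && cfg$generations %% cfg$shuffles != 0L) {
      stop(sprintf("generations (%d) must be divisible by shuffles (%d)",
                   cfg$generations, cfg$shuffles), call. = FALSE)
    }
  }
  structure(cfg, class = "OptimizerConfig")
}

#' One particle-swarm generation
#'
#' Per particle and dimension, with a fresh uniform draw for each term:
#' `V <- w*V + c1*rand()*(pbest - X) + c2*rand()*(gbest - X)`, clamped
#' componentwise to `[-vmax, vmax]`; then `X <- X + V`, clamped to `[0,1]`.
#' Personal and global bests update on strict improvement only (ties keep
#' the incumbent).
#'
#' @param state list with matrices `X`, `V`, `P` (personal best positions),
#'   vector `pfit`, vector `gbest`, scalar `gfit`, and `cfg`.
#' @param fitness_fn function mapping a position vector to a fitness to
#'   maximize.
#' @param rand_fn uniform generator `n -> n draws`; injectable for tests.
#' @return the updated state.
#' @export
pso_step <- function(state, fitness_fn, rand_fn = stats::runif) {
  cfg <- state$cfg
  n <- nrow(state$X)
  m <- ncol(state$X)
  r1 <- matrix(rand_fn(n * m), n, m)
  r2 <- matrix(rand_fn(n * m), n, m)
  gmat <- matrix(state$gbest, n, m, byrow = TRUE)
  v <- cfg$w * state$V +
    cfg$c1 * r1 * (state$P - state$X) +
    cfg$c2 * r2 * (gmat - state$X)
  v <- clamp(v, -cfg$vmax, cfg$vmax)
  x <- clamp01(state$X + v)
  fit <- vapply(seq_len(n), function(i) fitness_fn(x[i, ]), numeric(1L))
  improved <- fit > state$pfit
  state$P[improved, ] <- x[improved, , drop = FALSE]
  state$pfit[improved] <- fit[improved]
  b <- which.max(state$pfit)
  if (state$pfit[b] > state$gfit) {
    state$gfit <- state$pfit[b]
    state$gbest <- state$P[b, ]
  }
  state$X <- x
  state$V <- v
  state
}

#' One cuckoo-search generation
#'
#' Each cuckoo proposes `x + alpha (*) Levy(lambda)` — by default the Levy
#' draw multiplies the `(x - best)` direction entrywise — clamped to the
#' unit box; the proposal replaces a uniformly chosen nest if strictly
#' better.  Then every non-best nest is abandoned with probability `pa` and
#' re-initialized uniformly.  The best nest always survives.
#'
#' @param state list with matrix `X` (one egg per nest), vector `fit`, and
#'   `cfg`.
#' @param fitness_fn fitness to maximize.
#' @return the updated state.
#' @export
cs_step <- function(state, fitness_fn) {
  cfg <- state$cfg
  n <- nrow(state$X)
  m <- ncol(state$X)
  best_i <- which.max(state$fit)
  best <- state$X[best_i, ]
  for (i in seq_len(n)) {
    l <- levy_step(cfg$lambda, cfg$alpha, m)
    step <- if (cfg$levy_direction == "best") l * (state$X[i, ] - best) else l
    cand <- clamp01(state$X[i, ] + step)
    f <- fitness_fn(cand)
    j <- sample.int(n, 1L)
    if (f > state$fit[j]) {
      state$X[j, ] <- cand
      state$fit[j] <- f
    }
  }
  best_i <- which.max(state$fit)
  for (i in seq_len(n)) {
    if (i == best_i) next
    if (stats::runif(1L) < cfg$pa) {
      state$X[i, ] <- stats::runif(m)
      state$fit[i] <- fitness_fn(state$X[i, ])
    }
  }
  state
}

#' Sort a frog population and partition it into memeplexes
#'
#' Frogs are sorted in descending fitness order (stable, so equal fitness
#' keeps the incumbent order) and dealt round-robin: the frog at sorted rank
#' r goes to memeplex `((r - 1) mod m) + 1`, so the first frog goes to the
#' first memeplex, the second to the second, frog m + 1 back to the first,
#' and so on.
#'
#' @param fitnesses numeric vector of frog fitnesses.
#' @param n_memeplexes number of memeplexes m; must divide the population.
#' @return list of m integer vectors of original frog indices.
#' @export
sfl_sort_partition <- function(fitnesses, n_memeplexes) {
  p <- length(fitnesses)
  n_memeplexes <- as.integer(n_memeplexes)
  if (p %% n_memeplexes != 0L) {
    stop(sprintf("population (%d) not divisible by memeplex count (%d)",
                 p, n_memeplexes), call. = FALSE)
  }
  ord <- order(-fitnesses, seq_along(fitnesses))
  lapply(seq_len(n_memeplexes), function(j) {
    ord[seq.int(j, p, by = n_memeplexes)]
  })
}

#' Improve the worst frog of a memeplex
#'
#' The classic worst-frog rule: attempt 1 moves the worst frog toward the
#' memeplex best, `D = rand() * (Xb - Xw)` clamped componentwise to
#' `[-dmax, dmax]`, accepted only on strict fitness improvement; attempt 2
#' repeats with the global best `Xg`; attempt 3 replaces the worst frog with
#' a fresh uniform random position.  Only the worst frog moves.
#'
#' @param memeplex list with matrix `positions` (frogs x dim) and vector
#'   `fitnesses`.
#' @param xg global best position.
#' @param fitness_fn fitness to maximize.
#' @param dmax componentwise step clamp.
#' @param rand_fn uniform generator, injectable for tests; one scalar draw
#'   per attempt.
#' @return list with the updated `memeplex` and `evals`, the number of
#'   fitness evaluations spent.
#' @export
sfl_worst_update <- function(memeplex, xg, fitness_fn, dmax = 0.5,
                             rand_fn = stats::runif) {
  step_fn <- function(target, xw) {
    rand_fn(1L) * (target - xw)
  }
  frog_update(memeplex, xg, fitness_fn, dmax, step_fn)
}

#' Improve the worst frog with a Levy-flight step
#'
#' Identical fallback chain to [sfl_worst_update()], but the step is
#' `D = LF * |L| (*) (Xb - Xw)` (attempt 1) and `D = LF * |L| (*) (Xg - Xw)`
#' (attempt 2), where `L` is a fresh Levy(lambda) vector and `(*)` is the
#' entrywise product.  A Levy flight is defined by heavy-tailed step
#' *lengths* with the direction chosen separately; here the direction is
#' supplied by `(Xb - Xw)`, so the Levy factor enters as a positive length
#' `|L|` — occasional large jumps let the worst frog escape regions where
#' the uniform step keeps reproducing the same poor solution.
#'
#' @inheritParams sfl_worst_update
#' @param lambda Levy tail exponent.
#' @param lf Levy-step scale.
#' @param levy_fn Levy vector generator `(lambda, alpha, dim) -> vector`,
#'   injectable for tests.
#' @return as [sfl_worst_update()].
#' @export
sfllf_worst_update <- function(memeplex, xg, fitness_fn, lambda = 1.5,
                               lf = 1, dmax = 0.5, levy_fn = levy_step) {
  step_fn <- function(target, xw) {
    lf * abs(levy_fn(lambda, 1, length(xw))) * (target - xw)
  }
  frog_update(memeplex, xg, fitness_fn, dmax, step_fn)
}

frog_update <- function(memeplex, xg, fitness_fn, dmax, step_fn) {
  fit <- memeplex$fitnesses
  wi <- which.min(fit)          # ties -> lower index (incumbent order)
  bi <- which.max(fit)
  xw <- memeplex$positions[wi, ]
  xb <- memeplex$positions[bi, ]
  fw <- fit[wi]
  evals <- 0L
  for (target in list(xb, xg)) {
    d <- clamp(step_fn(target, xw), -dmax, dmax)
    cand <- clamp01(xw + d)
    f <- fitness_fn(cand)
    evals <- evals + 1L
    if (f > fw) {
      memeplex$positions[wi, ] <- cand
      memeplex$fitnesses[wi] <- f
      return(list(memeplex = memeplex, evals = evals))
    }
  }
  cand <- stats::runif(length(xw))
  memeplex$positions[wi, ] <- cand
  memeplex$fitnesses[wi] <- fitness_fn(cand)
  list(memeplex = memeplex, evals = evals + 1L)
}

#' Run a population-based optimizer over the unit box
#'
#' Initializes the population uniformly in `[0,1]^m`, applies the configured
#' algorithm for the full generation budget, and returns the best candidate
#' ever evaluated (elitism is enforced by tracking every fitness
#' evaluation, so the best-fitness trace is non-decreasing by
#' construction).  For the frog-leaping variants the budget is organized as
#' `shuffles` shuffles of `generations / shuffles` worst-frog cycles, each
#' cycle improving the worst frog of every memeplex once; one cycle counts
#' as one generation in the trace.
#'
#' @param cfg an [optimizer_config()].
#' @param fitness_fn function mapping a position in `[0,1]^m` to a fitness
#'   to maximize.
#' @param seed integer seed; identical `(cfg, fitness_fn, seed)` give
#'   identical results.
#' @return an `OptimizationResult` list: `best_position`, `best_fitness`,
#'   `best_mask` (the decoded gene subset), `trace` (best-ever fitness after
#'   each generation), `evaluations`, `algorithm`.
#' @export
run_optimizer <- function(cfg, fitness_fn, seed = 1L) {
  stopifnot(inherits(cfg, "OptimizerConfig"))
  tracker <- new.env(parent = emptyenv())
  tracker$best_fit <- -Inf
  tracker$best_pos <- NULL
  tracker$evals <- 0L
  fn <- function(position) {
    f <- fitness_fn(position)
    tracker$evals <- tracker$evals + 1L
    if (f > tracker$best_fit) {
      tracker$best_fit <- f
      tracker$best_pos <- position
    }
    f
  }
  trace <- numeric(cfg$generations)
  with_seed(seed, {
    x <- matrix(stats::runif(cfg$population * cfg$dim),
                cfg$population, cfg$dim)
    fit <- vapply(seq_len(cfg$population), function(i) fn(x[i, ]),
                  numeric(1L))
    if (cfg$generations > 0L) {
      switch(cfg$algorithm,
        pso = {
          b <- which.max(fit)
          state <- list(X = x, V = matrix(0, cfg$population, cfg$dim),
                        P = x, pfit = fit, gbest = x[b, ], gfit = fit[b],
                        cfg = cfg)
          for (g in seq_len(cfg$generations)) {
            state <- pso_step(state, fn)
            trace[g] <- tracker$best_fit
          }
        },
        cs = {
          state <- list(X = x, fit = fit, cfg = cfg)
          for (g in seq_len(cfg$generations)) {
            state <- cs_step(state, fn)
            trace[g] <- tracker$best_fit
          }
        },
        sfl = ,
        sfllf = {
          cycles <- cfg$generations %/% cfg$shuffles
          g <- 0L
          for (s in seq_len(cfg$shuffles)) {
            memeplexes <- sfl_sort_partition(fit, cfg$n_memeplexes)
            for (cy in seq_len(cycles)) {
              for (mem in memeplexes) {
                gi <- which.max(fit)
                mp <- list(positions = x[mem, , drop = FALSE],
                           fitnesses = fit[mem])
                upd <- if (cfg$algorithm == "sfl") {
                  sfl_worst_update(mp, x[gi, ], fn, dmax = cfg$dmax)
                } else {
                  sfllf_worst_update(mp, x[gi, ], fn,
                                     lambda = cfg$lambda, lf = cfg$lf,
                                     dmax = cfg$dmax)
                }
                x[mem, ] <- upd$memeplex$positions
                fit[mem] <- upd$memeplex$fitnesses
              }
              g <- g + 1L
              trace[g] <- tracker$best_fit
            }
          }
        })
    }
  })
  structure(
    list(best_position = tracker$best_pos,
         best_fitness = tracker$best_fit,
         best_mask = decode(tracker$best_pos),
         trace = trace,
         evaluations = tracker$evals,
         algorithm = cfg$algorithm),
    class = "OptimizationResult")
}
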