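#' Optimizer configuration
#'
#' Parameters of the binary Flower Pollination Algorithm (FPA), the
#' beta-hill climbing (beta-hc) local search, and their hybrid. Defaults
#' follow the standard setup for this channel-selection wrapper: switch
#' probability `p = 0.8`, population `N = 64`, `T = 100` outer iterations,
#' `beta = 0.5`; the Levy-flight step uses the Mantegna construction with
#' exponent 1.5, applied unscaled (`levy_scale = 1`): the sigmoid transfer
#' function needs solution components to grow in magnitude before a mask
#' can saturate toward the global best, so shrinking the step freezes the
#' binary search. `D` is always the channel count.
#'
#' @param D Solution dimension (number of channels).
#' @param N Population size.
#' @param T Outer iterations.
#' @param p Global-pollination switch probability in \[0, 1\].
#' @param beta Per-bit random-reset rate of the beta operator in \[0, 1\].
#' @param bhc_inner_iters Inner beta-hc iterations per refined solution.
#' @param levy_lambda Levy exponent (1 < lambda <= 2).
#' @param levy_scale Step multiplier.
#' @param seed Integer seed; runs are reproducible from (config, seed).
#' @param max_evals Optional cap on distinct objective evaluations; the run
#'   stops early once the budget is spent (used for matched-budget
#'   optimizer comparisons).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(D, N = 64, T = 100, p = 0.8, beta = 0.5,
                             bhc_inner_iters = 20, levy_lambda = 1.5,
                             levy_scale = 1, seed = 1, max_evals = Inf) {
  stopifnot(D >= 1, N >= 2, T >= 1, p >= 0, p <= 1, beta >= 0, beta <= 1,
            levy_lambda > 1, levy_lambda <= 2, bhc_inner_iters >= 0,
            max_evals > 0)
  structure(list(D = as.integer(D), N = as.integer(N), T = as.integer(T),
                 p = p, beta = beta,
                 bhc_inner_iters = as.integer(bhc_inner_iters),
                 levy_lambda = levy_lambda, levy_scale = levy_scale,
                 seed = as.integer(seed), max_evals = max_evals),
            class = "optimizer_config")
}

#' Sigmoid transfer function
#'
#' Maps a real-valued solution component to a selection probability,
#' converting the continuous pollination moves to a binary channel mask.
#'
#' @param x Numeric vector.
#' @return `1 / (1 + exp(-x))`, elementwise.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binarize a real-valued solution through the sigmoid transfer function
#'
#' Each bit is set to 1 with probability `sigmoid(real_vec[i])` (a fresh
#' uniform draw per dimension). An all-zero result is repaired by setting
#' one uniformly chosen bit, since an empty channel subset is not a valid
#' solution.
#'
#' @param real_vec Numeric vector (finite).
#' @return Integer 0/1 mask of the same length.
#' @export
binarize <- function(real_vec) {
  stopifnot(all(is.finite(real_vec)))
  mask <- as.integer(sigmoid(real_vec) > stats::runif(length(real_vec)))
  repair_mask(mask)
}

#' Repair an all-zero mask by selecting one random channel
#' @param mask Integer 0/1 vector.
#' @return The mask, with one uniformly chosen bit set if it was all zero.
#' @export
repair_mask <- function(mask) {
  if (sum(mask) == 0) mask[sample.int(length(mask), 1)] <- 1L
  mask
}

#' Heavy-tailed Levy step vector (Mantegna construction)
#'
#' `step_i = scale * u_i / |v_i|^(1/lambda)` with `u ~ N(0, sigma_u^2)`,
#' `v ~ N(0, 1)` and `sigma_u` chosen so the steps follow a symmetric Levy
#' stable law of exponent `lambda`.
#'
#' @param D Dimension.
#' @param lambda Stability exponent (1 < lambda <= 2).
#' @param scale Step multiplier.
#' @return Numeric vector of `D` i.i.d. steps.
#' @export
levy_step <- function(D, lambda = 1.5, scale = 0.01) {
  stopifnot(lambda > 1, lambda <= 2)
  sigma_u <- (gamma(1 + lambda) * sin(pi * lambda / 2) /
                (gamma((1 + lambda) / 2) * lambda * 2^((lambda - 1) / 2)))^(1 / lambda)
  u <- stats::rnorm(D, sd = sigma_u)
  v <- stats::rnorm(D)
  scale * u / abs(v)^(1 / lambda)
}

#' Global pollination move
#'
#' Levy-flight attraction toward the global best:
#' `sol + L * (gbest - sol)` elementwise, with `L` a [levy_step()].
#'
#' @param sol,gbest Real vectors of equal length.
#' @param cfg An [optimizer_config()] (Levy parameters).
#' @return The moved real vector.
#' @export
global_pollination <- function(sol, gbest, cfg) {
  L <- levy_step(length(sol), cfg$levy_lambda, cfg$levy_scale)
  sol + L * (gbest - sol)
}

#' Local pollination move
#'
#' `sol + eps * (sol_j - sol_k)` with a single scalar `eps ~ U(0, 1)` and
#' `sol_j`, `sol_k` two population members.
#'
#' @param sol,sol_j,sol_k Real vectors of equal length.
#' @return The moved real vector.
#' @export
local_pollination <- function(sol, sol_j, sol_k) {
  sol + stats::runif(1) * (sol_j - sol_k)
}

#' Neighbourhood operator: flip exactly one uniformly chosen bit
#'
#' @param mask Integer 0/1 vector.
#' @return Mask at Hamming distance 1 from the input.
#' @export
n_operator <- function(mask) {
  i <- sample.int(length(mask), 1)
  mask[i] <- 1L - mask[i]
  mask
}

#' Beta operator: per-bit random reset
#'
#' Independently per bit, with probability `beta` the bit is replaced by a
#' fresh uniform random bit (so each bit actually changes with probability
#' `beta / 2`); otherwise it is kept.
#'
#' @param mask Integer 0/1 vector.
#' @param beta Reset probability in \[0, 1\].
#' @return The mutated mask.
#' @export
beta_operator <- function(mask, beta) {
  reset <- stats::runif(length(mask)) < beta
  if (any(reset)) {
    mask[reset] <- sample(c(0L, 1L), sum(reset), replace = TRUE)
  }
  mask
}

## Internal counting + memoizing wrapper so budget accounting (and the
## evaluations field of run histories) is identical for any objective.
.counted_fitness <- function(fitness_fn) {
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  f <- function(mask) {
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    evals <<- evals + 1L
    val <- fitness_fn(mask)
    cache[[key]] <- val
    val
  }
  list(f = f, evals = function() evals)
}

#' Beta-hill climbing refinement of a channel mask
#'
#' Iterates `bhc_inner_iters` times: a candidate is produced by the
#' neighbourhood operator (one bit flipped) followed by the beta operator
#' (per-bit random reset with probability `beta`), repaired if empty, and
#' accepted iff its fitness is not worse than the current one. The returned
#' fitness is therefore never below the input mask's fitness.
#'
#' @param mask Integer 0/1 vector with at least one 1.
#' @param fitness_fn Objective over masks (percent, maximized).
#' @param cfg An [optimizer_config()].
#' @return List with `mask` and `fitness`.
#' @export
bhc_refine <- function(mask, fitness_fn, cfg) {
  stopifnot(sum(mask) >= 1)
  cur_fit <- fitness_fn(mask)
  if (cfg$bhc_inner_iters > 0) {
    for (i in seq_len(cfg$bhc_inner_iters)) {
      cand <- repair_mask(beta_operator(n_operator(mask), cfg$beta))
      cand_fit <- fitness_fn(cand)
      if (cand_fit >= cur_fit) {
        mask <- cand
        cur_fit <- cand_fit
      }
    }
  }
  list(mask = mask, fitness = cur_fit)
}

.new_history <- function(method, cfg) {
  structure(list(method = method,
                 best_fitness_per_iter = rep(NA_real_, cfg$T),
                 best_mask = NULL, best_fitness = -Inf,
                 evaluations = NA_integer_,
                 selection_counts = integer(cfg$D),
                 config = cfg),
            class = "run_history")
}

#' @export
print.run_history <- function(x, ...) {
  cat(sprintf("run_history [%s]: best %.4f with %d/%d channels, %d evaluations\n",
              x$method, x$best_fitness, sum(x$best_mask),
              length(x$best_mask), x$evaluations))
  invisible(x)
}

## Shared driver for FPA with or without the beta-hc refinement step.
.fpa_driver <- function(fitness_fn, cfg, hybrid) {
  set.seed(cfg$seed)
  cf <- .counted_fitness(fitness_fn)
  D <- cfg$D; N <- cfg$N

  real <- matrix(stats::runif(N * D, -1, 1), N, D)
  bins <- vector("list", N)
  fits <- numeric(N)
  for (i in seq_len(N)) {
    bins[[i]] <- binarize(real[i, ])
    fits[i] <- cf$f(bins[[i]])
  }
  gi <- which.max(fits)
  gbest_real <- real[gi, ]; gbest_bin <- bins[[gi]]; gbest_fit <- fits[gi]

  hist <- .new_history(if (hybrid) "fpa_bhc" else "fpa", cfg)
  for (t in seq_len(cfg$T)) {
    if (cf$evals() >= cfg$max_evals) {
      hist$best_fitness_per_iter[t:cfg$T] <- gbest_fit
      break
    }
    for (i in seq_len(N)) {
      if (cf$evals() >= cfg$max_evals) break
      new_real <- if (stats::runif(1) <= cfg$p) {
        global_pollination(real[i, ], gbest_real, cfg)
      } else {
        jk <- sample.int(N, 2)
        local_pollination(real[i, ], real[jk[1], ], real[jk[2], ])
      }
      new_bin <- binarize(new_real)
      if (hybrid) {
        ref <- bhc_refine(new_bin, cf$f, cfg)
        new_bin <- ref$mask
        new_fit <- ref$fitness
      } else {
        new_fit <- cf$f(new_bin)
      }
      real[i, ] <- new_real
      bins[[i]] <- new_bin
      fits[i] <- new_fit
      if (new_fit > gbest_fit) {
        gbest_fit <- new_fit
        gbest_bin <- new_bin
        gbest_real <- new_real
      }
    }
    hist$best_fitness_per_iter[t] <- gbest_fit
  }
  hist$best_mask <- gbest_bin
  hist$best_fitness <- gbest_fit
  hist$evaluations <- cf$evals()
  hist$selection_counts <- as.integer(Reduce(`+`, bins))
  hist
}

#' Hybrid FPA / beta-hill climbing channel-subset search
#'
#' The population metaheuristic: `N` pollens hold real vectors initialized
#' U(-1, 1), binarized through the sigmoid transfer function and evaluated.
#' Each iteration moves every pollen by global pollination (Levy flight
#' toward the global best, probability `p`) or local pollination (scaled
#' difference of two random members), re-binarizes, then refines the binary
#' solution with [bhc_refine()] and replaces the pollen with the refined
#' solution. The global best is updated on strict improvement, so the
#' per-iteration best-fitness series is non-decreasing.
#'
#' @param fitness_fn Objective over 0/1 masks of length `cfg$D` (percent,
#'   maximized), e.g. from [make_fitness_fn()].
#' @param cfg An [optimizer_config()].
#' @return A `run_history` with the best mask, best fitness, per-iteration
#'   best-fitness series, evaluation count (distinct masks evaluated) and
#'   per-channel selection counts across the final population.
#' @export
fpa_bhc_optimize <- function(fitness_fn, cfg) {
  .fpa_driver(fitness_fn, cfg, hybrid = TRUE)
}

#' Standard binary Flower Pollination Algorithm (no local-search refinement)
#'
#' @inheritParams fpa_bhc_optimize
#' @return A `run_history`; `bhc_inner_iters` is ignored.
#' @export
fpa_optimize <- function(fitness_fn, cfg) {
  .fpa_driver(fitness_fn, cfg, hybrid = FALSE)
}

#' Standalone beta-hill climbing over channel masks
#'
#' Single-solution search from one random mask, run for an `N * T`
#' evaluation budget (matching the population methods' budget shape); the
#' best fitness is recorded at `T` evenly spaced checkpoints.
#'
#' @inheritParams fpa_bhc_optimize
#' @return A `run_history`.
#' @export
bhc_optimize <- function(fitness_fn, cfg) {
  set.seed(cfg$seed)
  cf <- .counted_fitness(fitness_fn)
  budget <- min(cfg$N * cfg$T, cfg$max_evals)

  cur <- repair_mask(as.integer(stats::runif(cfg$D) < 0.5))
  cur_fit <- cf$f(cur)
  hist <- .new_history("bhc", cfg)
  steps <- 0L
  checkpoint <- 0L
  while (cf$evals() < budget && steps < cfg$N * cfg$T * 10L) {
    steps <- steps + 1L
    cand <- repair_mask(beta_operator(n_operator(cur), cfg$beta))
    cand_fit <- cf$f(cand)
    if (cand_fit >= cur_fit) {
      cur <- cand
      cur_fit <- cand_fit
    }
    cp <- min(cfg$T, ceiling(cf$evals() / (budget / cfg$T)))
    if (cp > checkpoint) {
      hist$best_fitness_per_iter[(checkpoint + 1L):cp] <- cur_fit
      checkpoint <- cp
    }
  }
  if (checkpoint < cfg$T) {
    hist$best_fitness_per_iter[(checkpoint + 1L):cfg$T] <- cur_fit
  }
  hist$best_mask <- cur
  hist$best_fitness <- cur_fit
  hist$evaluations <- cf$evals()
  hist$selection_counts <- as.integer(cur)
  hist
}
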