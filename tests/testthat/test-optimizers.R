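test_that("the sigmoid transfer function has its closed-form values", {
  expect_equal(sigmoid(0), 0.5)
  x <- c(-3.2, -1, 0.4, 2, 7)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_equal(round(sigmoid(2), 4), 0.8808)
  expect_true(all(diff(sigmoid(seq(-10, 10, by = 0.1))) > 0))
})

test_that("binarization follows the sigmoid selection probabilities", {
  set.seed(1)
  # saturated components are (almost) deterministic
  hits <- replicate(200, binarize(c(20, 20, -20)))
  expect_true(all(hits[1, ] == 1) && all(hits[2, ] == 1))
  expect_true(mean(hits[3, ]) < 0.05)

  # empirical selection rate matches sigma(x) within 3 SE (many i.i.d. dims)
  x <- 0.7
  n <- 1e5
  rate <- mean(binarize(rep(x, n)))
  p <- sigmoid(x)
  expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / n))

  # all-zero results are repaired to exactly one selected channel
  reps <- replicate(100, sum(binarize(rep(-20, 6))))
  expect_true(all(reps == 1))
})

test_that("Levy steps are heavy-tailed, scaled and reproducible", {
  expect_equal(levy_step(5, 1.5, 0), rep(0, 5))
  set.seed(3)
  a <- levy_step(10, 1.5, 0.01)
  set.seed(3)
  b <- levy_step(10, 1.5, 0.01)
  expect_identical(a, b)

  set.seed(4)
  steps <- levy_step(1e5, 1.5, 1)
  expect_gt(max(abs(steps)) / sd(steps), 10)  # far beyond Gaussian tails
})

test_that("pollination moves follow their update equations", {
  sol <- c(0.3, -0.2, 1)
  # zero difference leaves the solution unchanged
  cfg <- optimizer_config(D = 3, seed = 1)
  expect_equal(global_pollination(sol, sol, cfg), sol)

  set.seed(9)
  moved <- global_pollination(sol, c(1, 1, 1), cfg)
  set.seed(9)
  L <- levy_step(3, cfg$levy_lambda, cfg$levy_scale)
  expect_equal(moved, sol + L * (c(1, 1, 1) - sol))

  expect_equal(local_pollination(sol, c(1, 2, 3), c(1, 2, 3)), sol)
  set.seed(11)
  lp <- local_pollination(c(0, 2), c(2, 0), c(0, 0))
  set.seed(11)
  eps <- runif(1)
  expect_equal(lp, c(0, 2) + eps * c(2, 0))

  # E[eps] = 1/2 -> mean displacement is half the member difference
  set.seed(12)
  disp <- replicate(1e4, local_pollination(c(0, 0), c(1, 2), c(0, 1)))
  expect_equal(rowMeans(disp), 0.5 * c(1, 1), tolerance = 0.05)
})

test_that("the neighbourhood operator flips exactly one uniform bit", {
  set.seed(5)
  mask <- make_mask(c(1, 4), 10)
  flips <- integer(10)
  for (i in 1:5000) {
    out <- n_operator(mask)
    d <- which(out != mask)
    expect_length(d, 1)
    flips[d] <- flips[d] + 1L
  }
  p <- 1 / 10
  se <- sqrt(p * (1 - p) / 5000)
  expect_true(all(abs(flips / 5000 - p) < 4 * se))
  # D = 1: the single bit toggles
  expect_equal(n_operator(c(1L)), c(0L))
})

test_that("the beta operator resets bits at the configured rate", {
  mask <- rep(c(0L, 1L), 10)
  expect_identical(beta_operator(mask, 0), mask)

  set.seed(6)
  n <- 1e4
  ones <- replicate(n, mean(beta_operator(rep(0L, 20), 1)))
  expect_lt(abs(mean(ones) - 0.5), 3 * sqrt(0.25 / (20 * n)))

  # expected Hamming distance D * beta / 2
  set.seed(7)
  hd <- replicate(n, sum(beta_operator(mask, 0.4) != mask))
  expect_lt(abs(mean(hd) - 20 * 0.4 / 2), 0.1)
})

test_that("beta-hill climbing refinement never worsens fitness", {
  cfg <- optimizer_config(D = 10, bhc_inner_iters = 50, seed = 2)
  set.seed(2)
  start <- make_mask(10, 10)
  out <- bhc_refine(start, onemax_fitness, cfg)
  expect_gte(out$fitness, onemax_fitness(start))

  # zero inner iterations is the identity
  cfg0 <- optimizer_config(D = 10, bhc_inner_iters = 0, seed = 2)
  out0 <- bhc_refine(start, onemax_fitness, cfg0)
  expect_identical(out0$mask, start)
})

test_that("refinement reaches a known single optimum almost always", {
  D <- 8
  target <- make_mask(c(2, 5, 7), D)
  single_opt <- function(mask) 100 - 100 * sum(mask != target) / D
  cfg <- optimizer_config(D = D, bhc_inner_iters = 200, seed = 1)
  hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    start <- repair_mask(as.integer(runif(D) < 0.5))
    out <- bhc_refine(start, single_opt, cfg)
    if (out$fitness == 100) hits <- hits + 1L
  }
  expect_gte(hits, 48)  # >= 95% of 50 seeds
})

test_that("the hybrid optimizer solves OneMax and is monotone and reproducible", {
  solved <- 0L
  for (s in 1:20) {
    cfg <- optimizer_config(D = 12, N = 10, T = 30, bhc_inner_iters = 20,
                            seed = s)
    h <- fpa_bhc_optimize(onemax_fitness, cfg)
    expect_false(is.unsorted(h$best_fitness_per_iter))
    expect_length(h$best_fitness_per_iter, 30)
    if (h$best_fitness == 100) solved <- solved + 1L
  }
  expect_gte(solved, 18)  # >= 90% of 20 seeds

  cfg <- optimizer_config(D = 16, N = 10, T = 10, seed = 4)
  h1 <- fpa_bhc_optimize(onemax_fitness, cfg)
  h2 <- fpa_bhc_optimize(onemax_fitness, cfg)
  expect_identical(h1, h2)
})

test_that("the hybrid dominates plain FPA on OneMax at matched budget", {
  cmp <- vapply(1:20, function(s) {
    h <- fpa_bhc_optimize(onemax_fitness,
                          optimizer_config(D = 16, N = 10, T = 30,
                                           bhc_inner_iters = 20, seed = s))
    f <- fpa_optimize(onemax_fitness,
                      optimizer_config(D = 16, N = 10, T = 30, seed = s,
                                       max_evals = h$evaluations))
    h$best_fitness - f$best_fitness
  }, numeric(1))
  expect_gte(median(cmp), 0)
  expect_gt(mean(cmp > 0), 0.5)
})

test_that("plain FPA beats random search at a matched evaluation budget", {
  diffs <- vapply(1:20, function(s) {
    cfg <- optimizer_config(D = 16, N = 10, T = 30, seed = s)
    h <- fpa_optimize(onemax_fitness, cfg)
    expect_false(is.unsorted(h$best_fitness_per_iter))
    set.seed(1000 + s)
    rand_best <- max(vapply(seq_len(h$evaluations), function(i) {
      onemax_fitness(as.integer(runif(16) < 0.5))
    }, numeric(1)))
    h$best_fitness - rand_best
  }, numeric(1))
  expect_gte(median(diffs), 0)
  expect_gt(mean(diffs), 0)
})

test_that("plain FPA ignores the inner-iteration count and is reproducible", {
  c1 <- optimizer_config(D = 12, N = 8, T = 10, bhc_inner_iters = 0, seed = 3)
  c2 <- optimizer_config(D = 12, N = 8, T = 10, bhc_inner_iters = 50, seed = 3)
  h1 <- fpa_optimize(onemax_fitness, c1)
  h2 <- fpa_optimize(onemax_fitness, c2)
  expect_equal(h1$best_mask, h2$best_mask)
  expect_equal(h1$best_fitness_per_iter, h2$best_fitness_per_iter)
})

test_that("standalone beta-hill climbing solves OneMax within its budget", {
  solved <- 0L
  for (s in 1:20) {
    cfg <- optimizer_config(D = 16, N = 100, T = 30, seed = s)  # 3000 evals
    h <- bhc_optimize(onemax_fitness, cfg)
    expect_false(is.unsorted(h$best_fitness_per_iter))
    expect_lte(h$evaluations, 3000)
    if (h$best_fitness == 100) solved <- solved + 1L
  }
  expect_gte(solved, 18)
})

test_that("beta > 0 escapes a deceptive local optimum more often than beta = 0", {
  D <- 6
  target <- make_mask(1, D)
  deceptive <- function(mask) {
    if (all(mask == target)) 100 else 50 * sum(mask) / D
  }
  stalls <- function(beta) {
    sum(vapply(1:16, function(s) {
      cfg <- optimizer_config(D = D, N = 50, T = 40, beta = beta, seed = s)
      bhc_optimize(deceptive, cfg)$best_fitness < 100
    }, logical(1)))
  }
  expect_gt(stalls(0), stalls(0.5))
})

test_that("with a generous budget the hybrid attains the exhaustive optimum", {
  # frozen arbitrary landscape over all 255 non-empty 8-bit masks
  set.seed(99)
  landscape <- runif(255, 0, 100)
  lookup <- function(mask) landscape[sum(mask * 2^(seq_along(mask) - 1))]
  true_max <- max(landscape[1:255])
  hits <- 0L
  for (s in 1:10) {
    cfg <- optimizer_config(D = 8, N = 10, T = 20, bhc_inner_iters = 20,
                            seed = s)
    h <- fpa_bhc_optimize(lookup, cfg)
    expect_lte(h$best_fitness, true_max)
    if (isTRUE(all.equal(h$best_fitness, true_max))) hits <- hits + 1L
  }
  expect_gte(hits, 8)
})

test_that("run histories account for their evaluation budget", {
  cfg <- optimizer_config(D = 10, N = 6, T = 8, bhc_inner_iters = 5, seed = 2,
                          max_evals = 50)
  h <- fpa_bhc_optimize(onemax_fitness, cfg)
  expect_lte(h$evaluations, 50 + cfg$bhc_inner_iters + 1)
  expect_length(h$best_fitness_per_iter, 8)
  expect_false(is.unsorted(h$best_fitness_per_iter))
  expect_equal(length(h$selection_counts), 10)
})
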