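test_that("unconstrained maximum-entropy solution is the symmetric prior", {
  cs <- constraint_set(list(), "g1")
  sol <- solve_mkdip(mkdip_config("maxent", alpha0 = 2), cs)
  expect_true(sol$converged)
  expect_equal(sol$alpha$alpha, c(1, 1), tolerance = 1e-4)
  expect_equal(sol$objective, 0, tolerance = 1e-6)
  # permutation invariance of the optimum at 4 bins
  cs4 <- constraint_set(list(), c("g1", "g2"))
  sol4 <- solve_mkdip(mkdip_config("maxent", alpha0 = 8), cs4)
  expect_lt(diff(range(sol4$alpha$alpha)), 1e-3)
})

test_that("a zero-slack equality constraint pins the prior mean", {
  ct <- conditional_constraint("g1", 1, a = 0.7, direction = "=",
                               slack_range = c(0, 0))
  cs <- constraint_set(list(ct), "g1")
  sol <- solve_mkdip(mkdip_config("maxent", alpha0 = 10), cs)
  expect_true(sol$converged)
  expect_equal(expected_conditional_prob(sol$alpha, ct, "g1"), 0.7,
               tolerance = 1e-5)
  expect_equal(sol$alpha$alpha, c(3, 7), tolerance = 1e-3)
  expect_true(all(sol$margins >= -1e-8))
  expect_equal(sol$alpha$alpha0, 10, tolerance = 1e-8)
})

test_that("solver matches a penalized random-restart oracle on 8 bins", {
  cs <- read_constraints(system.file("extdata", "tp53_mkdip.constraints",
                                     package = "mkdipobc"), tp_features)
  cfg <- mkdip_config("maxent", alpha0 = 30, lambda2 = 0.5)
  sol <- solve_mkdip(cfg, cs)
  expect_true(sol$converged)
  expect_true(all(sol$margins >= -1e-8))
  # oracle: independent penalty formulation + Nelder-Mead restarts
  masksE <- lapply(cs$constraints, function(ct)
    expected_conditional_prob)
  pen_obj <- function(z) {
    s <- exp(z - max(z)); alpha <- 30 * s / sum(s)
    alpha <- pmax(alpha, 1e-9)
    eps <- vapply(cs$constraints, function(ct)
      min(max(ct$a - expected_conditional_prob(alpha, ct, tp_features),
              ct$slack_range[1]), ct$slack_range[2]), 0)
    0.5 * cost_maxent(alpha) + 0.5 * sum(eps)
  }
  set.seed(77)
  best <- Inf
  for (r in 1:60) {
    z0 <- log(rgamma(8, 1) + 1e-3)
    o <- optim(z0, pen_obj, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-12))
    o <- optim(o$par, pen_obj, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  expect_equal(sol$objective, best, tolerance = 1e-3)
})

test_that("slack totals never increase with the slack penalty weight", {
  cs <- read_constraints(system.file("extdata", "tp53_mkdip.constraints",
                                     package = "mkdipobc"), tp_features)
  for (seed in 1:3) {
    sums <- vapply(c(0.1, 0.5, 2), function(l2) {
      sol <- solve_mkdip(mkdip_config("maxent", alpha0 = 30,
                                      lambda2 = l2, seed = seed), cs)
      sum(sol$slacks)
    }, 0)
    expect_true(all(diff(sums) <= 1e-6))
  }
})

test_that("the max-bin bracket is honoured by feasible solutions", {
  pt <- tp53_problem(0.5)
  cs <- derive_constraints(load_tp53(), tp_features)
  csb <- constraint_set(cs$constraints, tp_features,
                        max_bin_bracket(pt$p0))
  sol <- solve_mkdip(mkdip_config("maxent", alpha0 = 30, lambda2 = 0.5),
                     csb)
  expect_true(sol$converged)
  v <- sol$alpha$alpha[csb$max_bin$bin] / sol$alpha$alpha0
  expect_gte(v, csb$max_bin$lo - 1e-8)
  expect_lte(v, csb$max_bin$hi + 1e-8)
})

test_that("oracle precision selection follows the exact criterion", {
  p <- c(0.6, 0.25, 0.1, 0.05)
  grid <- 4 * 2^(0:10)
  # shape equal to truth: more confidence is never worse
  expect_equal(optimal_precision(p, p, 20, grid), max(grid))
  # mass concentrated on the wrong bins: small precision wins
  bad <- rev(p)
  expect_lte(optimal_precision(p, bad, 20, grid), grid[2])
  # returned value attains the criterion minimum on the grid
  sh <- c(0.4, 0.3, 0.2, 0.1)
  crit <- function(a0, n) sum(n * p * (1 - p)) / (a0 + n)^2 +
    sum(((a0 * sh + n * p) / (a0 + n) - p)^2)
  sel <- optimal_precision(p, sh, 15, grid)
  expect_equal(crit(sel, 15), min(vapply(grid, crit, 0, n = 15)))
})

test_that("data-driven precision estimation is sane", {
  set.seed(31)
  sh <- c(0.5, 0.3, 0.15, 0.05)
  grid <- 4 * 2^(-2:10)
  sel_n <- vapply(c(20, 2000), function(n) {
    med <- vapply(1:9, function(s) {
      set.seed(100 + s)
      U <- as.integer(rmultinom(1, n, sh))
      estimate_precision(sh, U, grid)
    }, 0)
    median(med)
  }, 0)
  expect_gt(sel_n[2], sel_n[1])   # precision grows with agreeing data
  off <- as.integer(rmultinom(1, 200, rev(sh)))
  expect_lte(estimate_precision(sh, off, grid), grid[3])
  expect_true(is.finite(estimate_precision(sh, c(1, 0, 0, 0), grid)))
  expect_error(estimate_precision(sh, c(0, 0, 0, 0)), "empty")
})
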