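test_that("transition matrices are exact under both perturbation models", {
  # p = 0: deterministic successor rows (either semantics)
  for (pert in c("single", "node")) {
    m0 <- bnp_model(toy2, 0, perturbation = pert)
    P0 <- build_transition_matrix(m0)
    expect_true(all(rowSums(P0 == 1) == 1))
  }
  # 1-node self-holding network: forced 2x2 kernel under both semantics
  hold <- boolean_network("g")
  for (pert in c("single", "node")) {
    P <- build_transition_matrix(bnp_model(hold, 0.3, perturbation = pert))
    expect_equal(P, matrix(c(0.7, 0.3, 0.3, 0.7), 2, byrow = TRUE))
  }
  # per-node kernel against explicit enumeration of decision vectors
  for (net in list(toy2, toy3)) {
    m <- bnp_model(net, 0.1, perturbation = "node")
    P <- build_transition_matrix(m)
    expect_lt(max(abs(P - tpm_oracle_node(m))), 1e-12)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  }
  # single-flip kernel: 1-p at the logic successor, p/m on each neighbour
  m <- bnp_model(toy3, 0.12, perturbation = "single")
  P <- build_transition_matrix(m)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  x <- c(1L, 0L, 1L)
  f <- evaluate_logic(m, x)
  row <- P[state_to_bin(x), ]
  for (j in 1:3) {
    y <- x; y[j] <- 1L - y[j]
    expect_equal(row[state_to_bin(y)],
                 0.12 / 3 + (1 - 0.12) * all(y == f))
  }
  expect_error(bnp_model(toy2, 1), "p_pert")
})

test_that("steady states are exact, positive and permutation-equivariant", {
  expect_equal(steady_state(matrix(c(.9, .1, .1, .9), 2))$probs,
               c(0.5, 0.5))
  # doubly stochastic -> uniform
  P <- matrix(c(.2, .5, .3, .5, .25, .25, .3, .25, .45), 3, byrow = TRUE)
  expect_equal(steady_state(P)$probs, rep(1 / 3, 3), tolerance = 1e-12)
  # reducible chain rejected
  expect_error(steady_state(diag(2)), "irreducible")
  expect_error(bnp_steady_state(bnp_model(toy2, 0)), "ergodicity")
  # long-run trajectory oracle on a 3-node network
  m <- bnp_model(toy3, 0.05)
  tpm <- build_transition_matrix(m)
  pi_exact <- steady_state(tpm)$probs
  expect_lt(max(abs(crossprod(tpm, pi_exact) - pi_exact)), 1e-12)
  expect_true(all(pi_exact > 0))
  emp <- trajectory_ssd(tpm, 2e5, seed = 11)
  se <- sqrt(pi_exact * (1 - pi_exact) / 2e5) * 8  # crude, autocorrelated
  expect_true(all(abs(emp - pi_exact) < pmax(3 * se, 0.02)))
  # relabeling nodes permutes the stationary distribution accordingly
  perm_net <- boolean_network(c("z", "x", "y"),
                              list(x = str2lang("y & !z"),
                                   y = str2lang("x | z"),
                                   z = str2lang("!x")))
  pi_perm <- bnp_steady_state(bnp_model(perm_net, 0.05))
  back <- marginalize(pi_perm, c("x", "y", "z"))
  expect_equal(back$probs, pi_exact, tolerance = 1e-10)
})

test_that("marginalization and scenario mixtures behave as expected", {
  m <- bnp_model(toy3, 0.08)
  ssd <- bnp_steady_state(m)
  expect_equal(marginalize(ssd, ssd$bin_order)$probs, ssd$probs)
  u <- categorical_distribution(rep(1 / 8, 8), c("x", "y", "z"))
  expect_equal(marginalize(u, c("x", "z"))$probs, rep(0.25, 4))
  # one distribution / identical components
  expect_equal(scenario_mixture(list(ssd), 1)$probs, ssd$probs)
  expect_equal(scenario_mixture(list(ssd, ssd), c(.3, .7))$probs,
               ssd$probs)
  # marginalize commutes with scenario_mixture
  other <- bnp_steady_state(bnp_model(toy3, 0.25))
  mixed <- scenario_mixture(list(ssd, other), c(0.4, 0.6))
  a <- marginalize(mixed, c("y", "z"))$probs
  b <- 0.4 * marginalize(ssd, c("y", "z"))$probs +
    0.6 * marginalize(other, c("y", "z"))$probs
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(scenario_mixture(list(ssd, other), c(.5, .6)),
               "probability")
  expect_error(marginalize(ssd, c("x", "nope")), "subset")
})

test_that("case-study problems compose the pipeline correctly", {
  pc <- cellcycle_problem(0.5)
  expect_equal(pc$b, 128)
  expect_equal(pc$bin_order, cc_features)
  expect_true(all(pc$p0 > 0) && all(pc$p1 > 0))
  expect_equal(sum(pc$p0), 1, tolerance = 1e-12)
  pt <- tp53_problem(0.5)
  expect_equal(pt$b, 8)
  # identical class models give identical class-conditionals
  net <- load_tp53()
  cls <- list(p_pert = 0.03, scenarios = list(c(dna_dsb = 0)))
  same <- class_conditional_ssd(net, tp_features, cls, cls, c = 0.4)
  expect_equal(same$p0, same$p1)
  expect_equal(bayes_error(same), 0.4)
})
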