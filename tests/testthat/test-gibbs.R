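test_that("single-component chains recover the conjugate posterior", {
  b <- 4
  alpha <- c(2, 1, 3, 0.5)
  model <- mixture_model(1, list(dirichlet_hyper(alpha)))
  set.seed(6)
  obs <- sample.int(b, 80, replace = TRUE, prob = c(.4, .1, .3, .2))
  U <- tabulate(obs, nbins = b)
  chain <- run_chain(obs, model, iterations = 6000, burn_in = 1000,
                     thinning = 1, seed = 8)
  thetas <- t(vapply(chain, function(st) st$thetas[[1]], numeric(b)))
  target <- (alpha + U) / (sum(alpha) + length(obs))
  se <- apply(thetas, 2, sd) / sqrt(nrow(thetas) / 10)  # autocorrelation slack
  expect_true(all(abs(colMeans(thetas) - target) < 3 * se + 1e-3))
  # labels are constant when M = 1
  expect_true(all(vapply(chain, function(st) all(st$labels == 1L), TRUE)))
})

test_that("states are valid probability vectors and chains reproduce", {
  b <- 6
  model <- mixture_model(c(1, 1),
                         list(jeffreys_prior(b), jeffreys_prior(b)))
  set.seed(4)
  obs <- sample.int(b, 40, replace = TRUE)
  c1 <- run_chain(obs, model, 300, 100, 2, seed = 99)
  c2 <- run_chain(obs, model, 300, 100, 2, seed = 99)
  expect_identical(c1, c2)
  expect_equal(length(c1), (300 - 100) %/% 2)
  for (st in c1[c(1, 50, 100)]) {
    expect_equal(sum(st$weights), 1, tolerance = 1e-12)
    for (th in st$thetas) expect_equal(sum(th), 1, tolerance = 1e-12)
    expect_true(all(st$labels %in% 1:2))
  }
  expect_error(run_chain(obs, model, 100, 100), "exceed")
})

test_that("dominant weight priors pin the mixture weights", {
  b <- 4
  model <- mixture_model(c(5000, 15000),
                         list(jeffreys_prior(b), jeffreys_prior(b)))
  set.seed(10)
  obs <- sample.int(b, 30, replace = TRUE)
  chain <- run_chain(obs, model, 400, 200, 1, seed = 2)
  wbar <- rowMeans(vapply(chain, `[[`, numeric(2), "weights"))
  expect_equal(wbar, c(0.25, 0.75), tolerance = 0.02)
})

test_that("disjoint supports force perfect label recovery", {
  b <- 8
  p0 <- c(.5, .3, .2, 0, 0, 0, 0, 0)
  p1 <- c(0, 0, 0, 0, .2, .3, .4, .1)
  pri0 <- dirichlet_hyper(100 * pmax(p0, 1e-6))
  pri1 <- dirichlet_hyper(100 * pmax(p1, 1e-6))
  model <- mixture_model(c(1, 1), list(pri0, pri1))
  set.seed(12)
  y <- rbinom(100, 1, 0.4)
  obs <- ifelse(y == 0, sample(1:3, 100, TRUE, p0[1:3]),
                sample(5:8, 100, TRUE, p1[5:8]))
  chain <- run_chain(obs, model, 500, 200, 1, seed = 3)
  acc <- mean(vapply(chain, function(st)
    mean(st$labels == y + 1L), 0))
  expect_equal(acc, 1)
})

test_that("the chain rule reduces to the single-state rule", {
  st <- list(weights = c(.6, .4),
             thetas = list(c(.7, .2, .1), c(.1, .2, .7)),
             labels = 1L)
  expect_equal(obc_mixture_classify(list(st)),
               c(1L, 1L, 2L))
  expect_equal(obc_mixture_classify(rep(list(st), 5)),
               obc_mixture_classify(list(st)))
  expect_error(obc_mixture_classify(list()), "empty")
  # ties break toward the lower component
  tie <- list(weights = c(.5, .5),
              thetas = list(c(.5, .5), c(.5, .5)), labels = 1L)
  expect_equal(obc_mixture_classify(list(tie)), c(1L, 1L))
})

test_that("mixture decisions approach the generating Bayes rule", {
  pt <- tp53_problem(0.6)
  pri0 <- dirichlet_hyper(200 * pmax(pt$p0, 1e-9))
  pri1 <- dirichlet_hyper(200 * pmax(pt$p1, 1e-9))
  model <- mixture_model(c(6, 4), list(pri0, pri1))
  set.seed(15)
  y <- rbinom(500, 1, 1 - pt$c)
  obs <- integer(500)
  obs[y == 0] <- sample.int(8, sum(y == 0), TRUE, pt$p0)
  obs[y == 1] <- sample.int(8, sum(y == 1), TRUE, pt$p1)
  chain <- run_chain(obs, model, 2000, 500, 2, seed = 16)
  rule <- obc_mixture_classify(chain)
  bayes <- bayes_classifier(pt) + 1L
  mass <- pt$c * pt$p0 + (1 - pt$c) * pt$p1
  agreement <- sum(mass[rule == bayes])
  expect_gte(agreement, 0.95)
})

test_that("posterior means recover mixture parameters as n grows", {
  # well-separated synthetic components with weakly informative priors
  p0 <- c(.45, .3, .15, .05, .03, .02)
  p1 <- c(.02, .03, .05, .15, .3, .45)
  ctrue <- c(.6, .4)
  err_at_n <- function(n) {
    errs <- vapply(1:10, function(s) {
      set.seed(400 + s)
      y <- rbinom(n, 1, ctrue[2])
      obs <- integer(n)
      if (any(y == 0)) obs[y == 0] <- sample.int(6, sum(y == 0), TRUE, p0)
      if (any(y == 1)) obs[y == 1] <- sample.int(6, sum(y == 1), TRUE, p1)
      model <- mixture_model(c(1.2, 0.8),
                             list(dirichlet_hyper(6 * p0),
                                  dirichlet_hyper(6 * p1)))
      chain <- run_chain(obs, model, 1500, 500, 2, seed = 500 + s)
      th0 <- rowMeans(vapply(chain, function(st) st$thetas[[1]],
                             numeric(6)))
      th1 <- rowMeans(vapply(chain, function(st) st$thetas[[2]],
                             numeric(6)))
      w <- rowMeans(vapply(chain, `[[`, numeric(2), "weights"))
      sum((th0 - p0)^2) + sum((th1 - p1)^2) + sum((w - ctrue)^2)
    }, 0)
    mean(errs)
  }
  e <- vapply(c(50, 200, 1000), err_at_n, 0)
  expect_true(all(diff(e) < 0))
})
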