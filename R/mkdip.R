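#' Configuration for MKDIP prior construction
#'
#' Bundles the cost function, regularization weights and precision factor
#' of the constrained prior-construction optimization.  `beta` mixes the
#' knowledge-only cost `g1` (maximum entropy or maximal data information)
#' with the data-driven cost `g2` (minus the expected mean log-likelihood);
#' the standard settings are `beta = 0` for `maxent`/`mdip` and `beta = 1`
#' for `remlp`.
#'
#' @param cost One of `"maxent"`, `"mdip"`, `"remlp"`.
#' @param alpha0 Precision factor (sum of the hyperparameters), fixed
#'   during optimization.
#' @param lambda1 Weight of the information cost (default 0.5).
#' @param lambda2 Weight of the summed slackness variables.
#' @param beta Mixing weight in \[0, 1\]; defaults to 0 (`maxent`, `mdip`)
#'   or 1 (`remlp`).
#' @param prior_data Bin counts of the prior-construction sample `D`
#'   (required when `beta > 0`).
#' @param seed Integer seed for the randomised starts of the solver.
#' @return An object of class `mkdip_config`.
#' @export
mkdip_config <- function(cost = c("maxent", "mdip", "remlp"), alpha0,
                         lambda1 = 0.5, lambda2 = 0.25, beta = NULL,
                         prior_data = NULL, seed = 1L) {
  cost <- match.arg(cost)
  if (is.null(beta)) beta <- if (cost == "remlp") 1 else 0
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (beta > 0 && (is.null(prior_data) || sum(prior_data) == 0))
    stop("cost with beta > 0 requires non-empty prior_data")
  if (alpha0 <= 0) stop("alpha0 must be positive")
  if (lambda1 < 0 || lambda2 < 0) stop("lambdas must be non-negative")
  structure(list(cost = cost, alpha0 = alpha0, lambda1 = lambda1,
                 lambda2 = lambda2, beta = beta, prior_data = prior_data,
                 seed = as.integer(seed)),
            class = "mkdip_config")
}

# information cost and gradient for a config
config_cost <- function(config, alpha) {
  g1 <- switch(config$cost,
               maxent = cost_maxent(alpha),
               mdip = cost_mdip(alpha),
               remlp = 0)
  g2 <- if (config$beta > 0) cost_remlp(alpha, config$prior_data) else 0
  (1 - config$beta) * g1 + config$beta * g2
}

config_grad <- function(config, alpha) {
  g1 <- switch(config$cost,
               maxent = grad_maxent(alpha),
               mdip = grad_mdip(alpha),
               remlp = 0)
  g2 <- if (config$beta > 0) grad_remlp(alpha, config$prior_data) else 0
  (1 - config$beta) * g1 + config$beta * g2
}

#' Solve the MKDIP constrained optimization
#'
#' Minimises
#' `lambda1 * E[(1 - beta) g1 + beta g2] + lambda2 * sum(eps_i)`
#' over Dirichlet hyperparameters with fixed precision `alpha0` and
#' slackness variables `eps_i` within their ranges, subject to the
#' expectation constraints of `cset` and its optional max-bin bracket.
#'
#' Because each `eps_i` enters the objective linearly and only relaxes its
#' own constraint, its optimum given `alpha` is available in closed form
#' (the needed slack, clamped to its range); the slackness variables are
#' therefore profiled out and the remaining smooth problem over the scaled
#' simplex is solved by multi-start BFGS with analytic gradients, using an
#' augmented-Lagrangian treatment of the max-bin bracket and of any
#' constraint whose needed slack exceeds its range.  Five starts are used:
#' symmetric, data-proportional (when `D` exists), max-bin-centred, and two
#' seeded random draws; the best feasible objective wins.  As with any
#' non-convex feasible region, global optimality is not guaranteed.
#'
#' @param config An [mkdip_config()].
#' @param cset A [constraint_set()].
#' @return A list of class `mkdip_solution`: `alpha` (a
#'   [dirichlet_hyper()]), `slacks`, `objective` (Eq.-16 value without
#'   penalties), `margins` (feasibility margins, all `>= -1e-8` when
#'   `converged`), `converged`.
#' @export
solve_mkdip <- function(config, cset) {
  b <- 2^length(cset$bin_order)
  a0 <- config$alpha0
  floor_frac <- 1e-6
  scale <- a0 * (1 - b * floor_frac)
  cts <- cset$constraints
  nc <- length(cts)
  masks <- lapply(cts, function(ct) {
    num <- bins_matching(c(stats::setNames(ct$target_value,
                                           ct$target_node),
                           ct$conditioning), cset$bin_order)
    den <- bins_matching(c(stats::setNames(1L - ct$target_value,
                                           ct$target_node),
                           ct$conditioning), cset$bin_order)
    list(num = num, den = den)
  })
  dirs <- vapply(cts, function(ct) ct$direction, "")
  avals <- vapply(cts, function(ct) ct$a, 0)
  slo <- vapply(cts, function(ct) ct$slack_range[1], 0)
  shi <- vapply(cts, function(ct) ct$slack_range[2], 0)
  mb <- cset$max_bin

  alpha_of <- function(z) {
    s <- exp(z - max(z)); s <- s / sum(s)
    a0 * floor_frac + scale * s
  }
  expect_all <- function(alpha) {
    vapply(masks, function(mk) {
      A <- sum(alpha[mk$num]); B <- sum(alpha[mk$den]); A / (A + B)
    }, numeric(1))
  }
  needed_slack <- function(E) {
    switch_need <- numeric(nc)
    for (i in seq_len(nc)) {
      switch_need[i] <- switch(dirs[i],
                               ">=" = avals[i] - E[i],
                               "<=" = E[i] - avals[i],
                               "="  = abs(E[i] - avals[i]))
    }
    switch_need
  }

  # augmented-Lagrangian state for overflow of slack ranges and the bracket
  objective <- function(z, mu, lam, lam_lo, lam_hi) {
    alpha <- alpha_of(z)
    E <- expect_all(alpha)
    need <- needed_slack(E)
    eps <- pmin(pmax(need, slo), shi)
    val <- config$lambda1 * config_cost(config, alpha) +
      config$lambda2 * sum(eps)
    if (nc) {
      g <- need - shi                       # must be <= 0
      val <- val + sum((mu / 2) * pmax(0, lam / mu + g)^2 - lam^2 / (2 * mu))
    }
    if (!is.null(mb)) {
      v <- alpha[mb$bin] / a0
      glo <- mb$lo - v; ghi <- v - mb$hi
      val <- val + (mu / 2) * pmax(0, lam_lo / mu + glo)^2 -
        lam_lo^2 / (2 * mu) +
        (mu / 2) * pmax(0, lam_hi / mu + ghi)^2 - lam_hi^2 / (2 * mu)
    }
    val
  }
  gradient <- function(z, mu, lam, lam_lo, lam_hi) {
    alpha <- alpha_of(z)
    galpha <- config$lambda1 * config_grad(config, alpha)
    E <- expect_all(alpha)
    need <- needed_slack(E)
    for (i in seq_len(nc)) {
      mk <- masks[[i]]
      A <- sum(alpha[mk$num]); B <- sum(alpha[mk$den])
      dE <- numeric(length(alpha))
      dE[mk$num] <- B / (A + B)^2
      dE[mk$den] <- -A / (A + B)^2
      dneed <- switch(dirs[i],
                      ">=" = -dE,
                      "<=" = dE,
                      "="  = sign(E[i] - avals[i]) * dE)
      if (need[i] > slo[i] && need[i] < shi[i])
        galpha <- galpha + config$lambda2 * dneed
      al <- pmax(0, lam[i] + mu * (need[i] - shi[i]))
      if (al > 0) galpha <- galpha + al * dneed
    }
    if (!is.null(mb)) {
      v <- alpha[mb$bin] / a0
      dv <- numeric(length(alpha)); dv[mb$bin] <- 1 / a0
      al <- pmax(0, lam_lo + mu * (mb$lo - v))
      if (al > 0) galpha <- galpha - al * dv
      ah <- pmax(0, lam_hi + mu * (v - mb$hi))
      if (ah > 0) galpha <- galpha + ah * dv
    }
    # chain rule through the softmax parameterisation
    s <- exp(z - max(z)); s <- s / sum(s)
    scale * s * (galpha - sum(galpha * s))
  }

  solve_from <- function(z0) {
    mu <- 100
    lam <- numeric(nc); lam_lo <- 0; lam_hi <- 0
    z <- z0; conv <- FALSE
    for (outer in 1:8) {
      opt <- stats::optim(z, objective, gradient, mu = mu, lam = lam,
                          lam_lo = lam_lo, lam_hi = lam_hi,
                          method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12))
      z <- opt$par
      alpha <- alpha_of(z)
      E <- expect_all(alpha)
      need <- needed_slack(E)
      over <- if (nc) pmax(0, need - shi) else numeric(0)
      bviol <- 0
      if (!is.null(mb)) {
        v <- alpha[mb$bin] / a0
        bviol <- max(0, mb$lo - v, v - mb$hi)
      }
      if (max(c(over, bviol, 0)) < 1e-9) { conv <- TRUE; break }
      if (nc) lam <- pmax(0, lam + mu * (need - shi))
      if (!is.null(mb)) {
        v <- alpha[mb$bin] / a0
        lam_lo <- max(0, lam_lo + mu * (mb$lo - v))
        lam_hi <- max(0, lam_hi + mu * (v - mb$hi))
      }
      mu <- mu * 10
    }
    alpha <- alpha_of(z)
    eps <- pmin(pmax(needed_slack(expect_all(alpha)), slo), shi)
    list(alpha = alpha, slacks = eps, converged = conv,
         objective = config$lambda1 * config_cost(config, alpha) +
           config$lambda2 * sum(eps))
  }

  starts <- list(rep(0, b))
  if (!is.null(config$prior_data) && sum(config$prior_data) > 0)
    starts <- c(starts, list(log(config$prior_data + 0.5)))
  if (!is.null(mb)) {
    p <- rep((1 - (mb$lo + mb$hi) / 2) / (b - 1), b)
    p[mb$bin] <- (mb$lo + mb$hi) / 2
    starts <- c(starts, list(log(p)))
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  while (length(starts) < 5)
    starts <- c(starts, list(log(stats::rgamma(b, 1)) ))
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())

  best <- NULL
  for (z0 in starts) {
    sol <- solve_from(z0)
    if (is.null(best) ||
        (sol$converged && !best$converged) ||
        (sol$converged == best$converged &&
         (sol$objective < best$objective - 1e-12 ||
          (abs(sol$objective - best$objective) <= 1e-12 &&
           sum(sol$slacks) < sum(best$slacks)))))
      best <- sol
  }
  if (!best$converged)
    warning("no feasible point found; returning least-infeasible solution")
  margins <- if (nc) constraint_residuals(best$alpha, cset, best$slacks)
             else numeric(0)
  structure(list(alpha = dirichlet_hyper(best$alpha),
                 slacks = best$slacks, objective = best$objective,
                 margins = margins, converged = best$converged),
            class = "mkdip_solution")
}

#' @export
print.mkdip_solution <- function(x, ...) {
  cat("MKDIP solution: objective", format(x$objective, digits = 6),
      if (x$converged) "(feasible)" else "(NOT feasible)", "\n")
  invisible(x)
}

#' Oracle selection of the precision factor
#'
#' Given the prior shape (normalised hyperparameter direction) and the true
#' bin probabilities of a class, selects the precision `alpha0` on the grid
#' `b * 2^(0:10)` minimising the expected squared distance between the
#' posterior mean and the truth at sample size `n_y`.  Under multinomial
#' sampling this expectation is available in closed form,
#' `sum_j n p_j (1 - p_j) / (alpha0 + n)^2 +
#'  sum_j ((alpha0 s_j + n p_j) / (alpha0 + n) - p_j)^2`,
#' so the selection is exact and deterministic.
#'
#' @param p True bin-probability vector of the class.
#' @param shape Probability vector: the prior mean direction.
#' @param n_y Class sample size of the experiment.
#' @param grid Candidate precision factors.
#' @return The selected `alpha0` (scalar).
#' @export
optimal_precision <- function(p, shape, n_y,
                              grid = length(p) * 2^(0:10)) {
  crit <- vapply(grid, function(a0) {
    sum(n_y * p * (1 - p)) / (a0 + n_y)^2 +
      sum(((a0 * shape + n_y * p) / (a0 + n_y) - p)^2)
  }, numeric(1))
  grid[which.min(crit)]
}

#' Data-driven estimation of the precision factor
#'
#' With the shape fixed, maximises the Dirichlet-multinomial marginal
#' likelihood of the observed counts over a log-spaced precision grid.
#'
#' @param shape Probability vector: the prior mean direction.
#' @param counts Observed bin counts (non-empty).
#' @param grid Candidate precision factors.
#' @return The selected `alpha0` (scalar).
#' @export
estimate_precision <- function(shape, counts,
                               grid = length(shape) * 2^(-2:10)) {
  n <- sum(counts)
  if (n == 0) stop("empty data")
  shape <- pmax(shape, 1e-12); shape <- shape / sum(shape)
  ll <- vapply(grid, function(a0) {
    lgamma(a0) - lgamma(a0 + n) +
      sum(lgamma(a0 * shape + counts) - lgamma(a0 * shape))
  }, numeric(1))
  grid[which.max(ll)]
}
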