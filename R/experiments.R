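#' Stratified sampling from a classification problem
#'
#' Draws `n0 = ceiling(c * n)` class-0 and `n1 = n - n0` class-1
#' observations, each class's bin counts being one multinomial draw from
#' its true bin probabilities.
#'
#' @param problem A [classification_problem()].
#' @param n Total sample size (>= 1).
#' @return List with integer count vectors `counts0`, `counts1` and sizes
#'   `n0`, `n1`.
#' @export
stratified_sample <- function(problem, n) {
  n0 <- ceiling(problem$c * n)
  n1 <- n - n0
  counts0 <- if (n0 > 0) as.integer(stats::rmultinom(1, n0, problem$p0))
             else integer(problem$b)
  counts1 <- if (n1 > 0) as.integer(stats::rmultinom(1, n1, problem$p1))
             else integer(problem$b)
  list(counts0 = counts0, counts1 = counts1, n0 = n0, n1 = n1)
}

#' Subsample counts for prior construction
#'
#' Draws `k` of the `sum(counts)` observations without replacement
#' (multivariate hypergeometric), returning their bin counts.  The full
#' data are still used for posterior inference; only the prior-construction
#' cost sees the subsample.
#'
#' @param counts Integer bin counts.
#' @param k Subsample size, `0 <= k <= sum(counts)`.
#' @return Integer bin counts of the subsample.
#' @export
split_prior_data <- function(counts, k) {
  n <- sum(counts)
  if (k > n) stop("k exceeds the class sample size")
  if (k == n) return(counts)
  if (k == 0) return(integer(length(counts)))
  picked <- sample(rep.int(seq_along(counts), counts), k)
  tabulate(picked, nbins = length(counts))
}

method_cost <- function(method) {
  switch(method,
         "mkdip-e" = , "rmep" = "maxent",
         "mkdip-d" = , "rmdip" = "mdip",
         "mkdip-r" = , "remlp" = "remlp",
         stop("unknown prior-construction method: ", method))
}

method_cset <- function(method, csets_mkdip, csets_edge, class_idx) {
  src <- if (method %in% c("mkdip-e", "mkdip-d", "mkdip-r")) csets_mkdip
         else csets_edge
  if (is.null(src)) stop("no constraint sets supplied for method ", method)
  src[[class_idx + 1L]]
}

# solve for the prior shape of one class (scale-invariant constraints, so
# the precision can be rescaled afterwards without losing feasibility)
solve_prior_shape <- function(method, cset, alpha0_ref, lambda1, lambda2,
                              prior_data = NULL, seed = 1L) {
  cfg <- mkdip_config(method_cost(method), alpha0 = alpha0_ref,
                      lambda1 = lambda1, lambda2 = lambda2,
                      prior_data = prior_data, seed = seed)
  sol <- solve_mkdip(cfg, cset)
  sol$alpha$alpha / sol$alpha$alpha0
}

#' Experiment configuration for the labeled (classification) setting
#'
#' @param problem A [classification_problem()].
#' @param methods Character vector among `"jeffreys"`, `"hist"`,
#'   `"mkdip-e"`, `"mkdip-d"`, `"mkdip-r"`, `"rmep"`, `"rmdip"`, `"remlp"`.
#' @param n_grid Sample sizes.
#' @param reps Monte-Carlo repetitions per cell.
#' @param prior_n Points per class handed to the data-using
#'   prior-construction costs (`remlp`, `mkdip-r`).
#' @param precision `"oracle"` (exact expected-distance criterion against
#'   the known truth) or `"estimate"` (marginal-likelihood grid on the
#'   observed counts).
#' @param csets_mkdip,csets_edge Lists of two [constraint_set()]s (class 0,
#'   class 1) for the regulating-function and the edge-style constraints.
#' @param use_max_bin Add the +/-5% max-bin bracket from the ground truth.
#' @param lambda1,lambda2 Regularization weights.
#' @param alpha0_ref Reference precision at which shapes are solved.
#' @param seed Integer seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(problem, methods, n_grid, reps = 200,
                              prior_n = 10, precision = c("oracle",
                                                          "estimate"),
                              csets_mkdip = NULL, csets_edge = NULL,
                              use_max_bin = TRUE, lambda1 = 0.5,
                              lambda2 = 0.25, alpha0_ref = NULL,
                              seed = 1L) {
  precision <- match.arg(precision)
  if (is.null(alpha0_ref)) alpha0_ref <- problem$b / 2
  structure(list(problem = problem, methods = methods, n_grid = n_grid,
                 reps = reps, prior_n = prior_n, precision = precision,
                 csets_mkdip = csets_mkdip, csets_edge = csets_edge,
                 use_max_bin = use_max_bin, lambda1 = lambda1,
                 lambda2 = lambda2, alpha0_ref = alpha0_ref,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

add_max_bin <- function(cset, p, use) {
  if (!use) return(cset)
  constraint_set(cset$constraints, cset$bin_order, max_bin_bracket(p))
}

#' Monte-Carlo classification experiment
#'
#' Reproduces the labeled simulation protocol: per repetition, stratified
#' sampling at fixed class prior; prior construction per method; optimal
#' Bayesian classifier design from the posterior effective densities; exact
#' true-error evaluation against the generating distributions; and the
#' squared posterior-mean distance for the Bayesian methods.  Monte-Carlo
#' standard errors are reported alongside every mean.  Priors whose
#' construction does not involve the data (Jeffreys, maxent/mdip costs) are
#' solved once per class and reused across repetitions; data-using priors
#' (`remlp`, `mkdip-r`) are re-solved per repetition on a `prior_n`-point
#' subsample.  Solver failures are excluded and counted, never imputed.
#'
#' @param config An [experiment_config()].
#' @return Data frame with one row per (method, n): mean and standard
#'   error of the true error and of the posterior distance, repetitions
#'   used, and failures.
#' @export
run_classification_experiment <- function(config) {
  pr <- config$problem
  b <- pr$b
  set.seed(config$seed)
  static_shapes <- list()   # method -> list(shape0, shape1)
  for (m in setdiff(config$methods,
                    c("jeffreys", "hist", "remlp", "mkdip-r"))) {
    cs0 <- add_max_bin(method_cset(m, config$csets_mkdip,
                                   config$csets_edge, 0L),
                       pr$p0, config$use_max_bin)
    cs1 <- add_max_bin(method_cset(m, config$csets_mkdip,
                                   config$csets_edge, 1L),
                       pr$p1, config$use_max_bin)
    static_shapes[[m]] <- list(
      solve_prior_shape(m, cs0, config$alpha0_ref, config$lambda1,
                        config$lambda2, seed = config$seed),
      solve_prior_shape(m, cs1, config$alpha0_ref, config$lambda1,
                        config$lambda2, seed = config$seed))
  }
  rows <- list()
  for (n in config$n_grid) {
    n0 <- ceiling(pr$c * n); n1 <- n - n0
    acc <- list()
    for (m in config$methods)
      acc[[m]] <- list(err = numeric(0), dist = numeric(0), fail = 0L)
    for (rep in seq_len(config$reps)) {
      smp <- stratified_sample(pr, n)
      for (m in config$methods) {
        res <- tryCatch(
          eval_method_once(m, pr, smp, config, static_shapes),
          error = function(e) NULL)
        if (is.null(res)) {
          acc[[m]]$fail <- acc[[m]]$fail + 1L
        } else {
          acc[[m]]$err <- c(acc[[m]]$err, res$err)
          acc[[m]]$dist <- c(acc[[m]]$dist, res$dist)
        }
      }
    }
    for (m in config$methods) {
      e <- acc[[m]]$err; d <- acc[[m]]$dist
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, n = n,
        mean_error = mean(e),
        se_error = stats::sd(e) / sqrt(length(e)),
        mean_distance = if (all(is.na(d))) NA_real_ else mean(d),
        se_distance = if (all(is.na(d))) NA_real_ else
          stats::sd(d) / sqrt(length(d)),
        reps = length(e), failures = acc[[m]]$fail)
    }
  }
  do.call(rbind, rows)
}

# one repetition of one method; returns err and (for Bayesian rules) dist
eval_method_once <- function(m, pr, smp, config, static_shapes) {
  b <- pr$b
  if (m == "hist") {
    psi <- histogram_rule(smp$counts0, smp$counts1)
    return(list(err = classifier_true_error(psi, pr), dist = NA_real_))
  }
  if (m == "jeffreys") {
    prior0 <- jeffreys_prior(b); prior1 <- jeffreys_prior(b)
  } else {
    if (m %in% c("remlp", "mkdip-r")) {
      d0 <- split_prior_data(smp$counts0, min(config$prior_n, smp$n0))
      d1 <- split_prior_data(smp$counts1, min(config$prior_n, smp$n1))
      cs0 <- add_max_bin(method_cset(m, config$csets_mkdip,
                                     config$csets_edge, 0L),
                         pr$p0, config$use_max_bin)
      cs1 <- add_max_bin(method_cset(m, config$csets_mkdip,
                                     config$csets_edge, 1L),
                         pr$p1, config$use_max_bin)
      shape0 <- solve_prior_shape(m, cs0, config$alpha0_ref,
                                  config$lambda1, config$lambda2,
                                  prior_data = d0, seed = config$seed)
      shape1 <- solve_prior_shape(m, cs1, config$alpha0_ref,
                                  config$lambda1, config$lambda2,
                                  prior_data = d1, seed = config$seed)
    } else {
      shape0 <- static_shapes[[m]][[1]]
      shape1 <- static_shapes[[m]][[2]]
    }
    a0_0 <- switch(config$precision,
                   oracle = optimal_precision(pr$p0, shape0, smp$n0),
                   estimate = estimate_precision(shape0, smp$counts0))
    a0_1 <- switch(config$precision,
                   oracle = optimal_precision(pr$p1, shape1, smp$n1),
                   estimate = estimate_precision(shape1, smp$counts1))
    prior0 <- dirichlet_hyper(a0_0 * shape0)
    prior1 <- dirichlet_hyper(a0_1 * shape1)
  }
  post0 <- dirichlet_posterior(prior0, smp$counts0)
  post1 <- dirichlet_posterior(prior1, smp$counts1)
  psi <- obc_rule(pr$c, effective_density(post0), effective_density(post1))
  list(err = classifier_true_error(psi, pr),
       dist = posterior_distance(post0, post1, pr))
}

#' Monte-Carlo mixture (unlabeled) experiment
#'
#' Per repetition: labels are drawn Bernoulli (not stratified) and hidden;
#' the Dirichlet parameter over the mixture weights is drawn uniformly in
#' a +/-10% interval around the true weights and shared by all methods;
#' each method's component priors drive a Gibbs chain; the Monte-Carlo OBC
#' rule is evaluated exactly against the generating model (expected true
#' error) and on the unlabeled training points.  For `remlp`/`mkdip-r`,
#' prior-construction labels come from a preliminary Jeffreys-prior chain
#' and one fourth of the points are used.  The Jeffreys chain's component
#' identity is resolved by matching its posterior weights to the known
#' weight bracket.
#'
#' @param config An [experiment_config()]; additionally honoured fields of
#'   the underlying list: `iterations`, `burn_in`, `thinning`,
#'   `pdcotp_alpha0`.
#' @return Data frame with one row per (method, n): mean/SE of expected
#'   true error and of training-data error.
#' @export
run_mixture_experiment <- function(config) {
  pr <- config$problem
  b <- pr$b
  iters <- config$iterations %||% 1200
  burn <- config$burn_in %||% 500
  thin <- config$thinning %||% 2
  pd_a0 <- config$pdcotp_alpha0 %||% (100 * b)
  set.seed(config$seed)
  static_shapes <- list()
  for (m in setdiff(config$methods,
                    c("jeffreys", "pdcotp", "remlp", "mkdip-r"))) {
    cs0 <- add_max_bin(method_cset(m, config$csets_mkdip,
                                   config$csets_edge, 0L),
                       pr$p0, config$use_max_bin)
    cs1 <- add_max_bin(method_cset(m, config$csets_mkdip,
                                   config$csets_edge, 1L),
                       pr$p1, config$use_max_bin)
    static_shapes[[m]] <- list(
      solve_prior_shape(m, cs0, config$alpha0_ref, config$lambda1,
                        config$lambda2, seed = config$seed),
      solve_prior_shape(m, cs1, config$alpha0_ref, config$lambda1,
                        config$lambda2, seed = config$seed))
  }
  ctrue <- c(pr$c, 1 - pr$c)
  rows <- list()
  for (n in config$n_grid) {
    acc <- list()
    for (m in config$methods)
      acc[[m]] <- list(err = numeric(0), train = numeric(0), fail = 0L)
    for (rep in seq_len(config$reps)) {
      y <- stats::rbinom(n, 1, 1 - pr$c)          # 1 = class 1 (mutated)
      obs <- integer(n)
      if (any(y == 0))
        obs[y == 0] <- sample.int(b, sum(y == 0), replace = TRUE,
                                  prob = pr$p0)
      if (any(y == 1))
        obs[y == 1] <- sample.int(b, sum(y == 1), replace = TRUE,
                                  prob = pr$p1)
      phi <- ctrue * stats::runif(2, 0.9, 1.1)
      chain_seed <- config$seed + 7919L * rep
      for (m in config$methods) {
        res <- tryCatch({
          priors <- mixture_method_priors(m, pr, obs, config,
                                          static_shapes, phi, pd_a0,
                                          iters, burn, thin, chain_seed)
          model <- mixture_model(phi, priors)
          chain <- run_chain(obs, model, iters, burn, thin,
                             seed = chain_seed)
          swap <- FALSE
          if (m == "jeffreys") {
            wbar <- rowMeans(vapply(chain, `[[`, numeric(2), "weights"))
            swap <- xor(wbar[1] < wbar[2], ctrue[1] < ctrue[2])
          }
          rule <- obc_mixture_classify(chain)
          if (swap) rule <- 3L - rule
          err <- sum(ctrue[1] * pr$p0[rule != 1L]) +
            sum(ctrue[2] * pr$p1[rule != 2L])
          train <- mean(rule[obs] != (y + 1L))
          list(err = err, train = train)
        }, error = function(e) NULL)
        if (is.null(res)) acc[[m]]$fail <- acc[[m]]$fail + 1L
        else {
          acc[[m]]$err <- c(acc[[m]]$err, res$err)
          acc[[m]]$train <- c(acc[[m]]$train, res$train)
        }
      }
    }
    for (m in config$methods) {
      e <- acc[[m]]$err; tr <- acc[[m]]$train
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, n = n,
        mean_error = mean(e), se_error = stats::sd(e) / sqrt(length(e)),
        mean_train_error = mean(tr),
        se_train_error = stats::sd(tr) / sqrt(length(tr)),
        reps = length(e), failures = acc[[m]]$fail)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mixture_method_priors <- function(m, pr, obs, config, static_shapes, phi,
                                  pd_a0, iters, burn, thin, chain_seed) {
  b <- pr$b
  if (m == "jeffreys")
    return(list(jeffreys_prior(b), jeffreys_prior(b)))
  if (m == "pdcotp")
    return(list(dirichlet_hyper(pd_a0 * pmax(pr$p0, 1e-9)),
                dirichlet_hyper(pd_a0 * pmax(pr$p1, 1e-9))))
  if (m %in% c("remlp", "mkdip-r")) {
    # preliminary Jeffreys chain supplies predicted labels
    jmod <- mixture_model(phi, list(jeffreys_prior(b), jeffreys_prior(b)))
    jchain <- run_chain(obs, jmod, iters, burn, thin,
                        seed = chain_seed + 1L)
    wbar <- rowMeans(vapply(jchain, `[[`, numeric(2), "weights"))
    rule <- obc_mixture_classify(jchain)
    if (xor(wbar[1] < wbar[2], pr$c < 0.5)) rule <- 3L - rule
    pred <- rule[obs]
    d <- lapply(1:2, function(j) {
      cj <- tabulate(obs[pred == j], nbins = b)
      split_prior_data(cj, max(1L, floor(sum(cj) / 4)))
    })
    shapes <- lapply(1:2, function(j) {
      cs <- add_max_bin(method_cset(m, config$csets_mkdip,
                                    config$csets_edge, j - 1L),
                        if (j == 1) pr$p0 else pr$p1, config$use_max_bin)
      solve_prior_shape(m, cs, config$alpha0_ref, config$lambda1,
                        config$lambda2, prior_data = d[[j]],
                        seed = config$seed)
    })
  } else {
    shapes <- static_shapes[[m]]
  }
  n0 <- round(length(obs) * pr$c)
  n1 <- length(obs) - n0
  list(dirichlet_hyper(optimal_precision(pr$p0, shapes[[1]], n0) *
                         shapes[[1]]),
       dirichlet_hyper(optimal_precision(pr$p1, shapes[[2]], n1) *
                         shapes[[2]]))
}

#' Format experiment results as text tables
#'
#' Produces a wide methods-by-sample-size table of mean errors with
#' standard errors, both as a tab-separated block and as a Markdown table;
#' deterministic given the input.
#'
#' @param results Data frame from [run_classification_experiment()] or
#'   [run_mixture_experiment()].
#' @param value Column to tabulate (default `"mean_error"`).
#' @param se Matching SE column (default `"se_error"`).
#' @param path Optional file path; the TSV block is written there.
#' @return Invisibly, a list with `tsv` and `markdown` character strings.
#' @export
render_report <- function(results, value = "mean_error",
                          se = "se_error", path = NULL) {
  ns <- sort(unique(results$n))
  methods <- unique(results$method)
  cell <- function(m, n) {
    r <- results[results$method == m & results$n == n, ]
    if (nrow(r) == 0) return("")
    sprintf("%.4f (%.4f)", r[[value]][1], r[[se]][1])
  }
  header <- c("method", if (length(ns)) paste0("n=", ns))
  body <- lapply(methods, function(m)
    c(m, vapply(ns, function(n) cell(m, n), "")))
  tsv <- paste(c(paste(header, collapse = "\t"),
                 vapply(body, paste, "", collapse = "\t")),
               collapse = "\n")
  md_row <- function(x) paste0("| ", paste(x, collapse = " | "), " |")
  markdown <- paste(c(md_row(header),
                      md_row(rep("---", length(header))),
                      vapply(body, md_row, "")),
                    collapse = "\n")
  if (!is.null(path)) writeLines(tsv, path)
  invisible(list(tsv = tsv, markdown = markdown))
}
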