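#' Dirichlet hyperparameters
#'
#' A positive vector `alpha` over the `b` bins of a discrete feature space.
#' Its sum `alpha0` is the precision factor, controlling how concentrated
#' the prior is about its mean `alpha / alpha0`.
#'
#' @param alpha Positive numeric vector.
#' @return An object of class `dirichlet_hyper` with elements `alpha` and
#'   `alpha0`.
#' @export
dirichlet_hyper <- function(alpha) {
  if (any(alpha <= 0)) stop("all Dirichlet parameters must be positive")
  structure(list(alpha = as.numeric(alpha), alpha0 = sum(alpha)),
            class = "dirichlet_hyper")
}

#' @export
print.dirichlet_hyper <- function(x, ...) {
  cat("Dirichlet(", length(x$alpha), " bins), precision alpha0 = ",
      format(x$alpha0, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Jeffreys prior for the multinomial model
#'
#' The symmetric Dirichlet with every parameter equal to 1/2; the
#' non-informative reference prior used as the knowledge-free baseline.
#'
#' @param b Number of bins (>= 2).
#' @return A [dirichlet_hyper()] with `alpha0 = b / 2`.
#' @export
jeffreys_prior <- function(b) {
  if (b < 2) stop("b must be >= 2")
  dirichlet_hyper(rep(0.5, b))
}

#' Conjugate posterior update
#'
#' Dirichlet priors are conjugate for multinomial sampling: observing bin
#' counts `U` turns `alpha` into `alpha + U`.
#'
#' @param prior A [dirichlet_hyper()].
#' @param counts Non-negative integer vector of bin counts, same length.
#' @return The posterior [dirichlet_hyper()].
#' @export
dirichlet_posterior <- function(prior, counts) {
  if (length(prior$alpha) != length(counts))
    stop("length mismatch between prior and counts")
  if (any(counts < 0)) stop("negative counts")
  dirichlet_hyper(prior$alpha + counts)
}

#' Effective class-conditional density
#'
#' The posterior predictive bin probabilities
#' `f(j | y) = (U_j + alpha_j) / (n_y + alpha0) = alpha*_j / alpha*_0`,
#' i.e. the posterior mean of the bin probability vector.  This is the
#' quantity the optimal Bayesian classifier compares across classes.
#'
#' @param posterior A [dirichlet_hyper()] that already includes the data.
#' @return Numeric probability vector over bins (sums to 1).
#' @export
effective_density <- function(posterior) {
  posterior$alpha / posterior$alpha0
}

#' Optimal Bayesian classifier for the Dirichlet-multinomial model
#'
#' Labels bin `j` as class 0 iff
#' `c * f0(j) >= (1 - c) * f1(j)` where `f0`, `f1` are the effective
#' class-conditional densities; ties go to class 0.  Among all `2^b` bin
#' labelings this minimises the posterior expected classification error.
#'
#' @param c_expect Posterior expectation of the class-0 prior, in \[0, 1\].
#' @param f0,f1 Effective densities (probability vectors over the same
#'   bins).
#' @return An integer 0/1 vector of length `b`: the decision per bin.
#' @export
obc_rule <- function(c_expect, f0, f1) {
  if (c_expect < 0 || c_expect > 1) stop("c_expect must be in [0, 1]")
  if (length(f0) != length(f1)) stop("f0 and f1 length mismatch")
  as.integer(c_expect * f0 < (1 - c_expect) * f1)
}

#' Exact true error of a bin classifier
#'
#' `P(psi(X) != Y)` under the true feature-label distribution: an exact sum
#' over bins, never a test-set estimate.
#'
#' @param psi Integer 0/1 decision vector over bins.
#' @param problem A [classification_problem()].
#' @return Error probability.
#' @export
classifier_true_error <- function(psi, problem) {
  if (length(psi) != problem$b) stop("classifier/problem length mismatch")
  problem$c * sum(problem$p0[psi == 1L]) +
    (1 - problem$c) * sum(problem$p1[psi == 0L])
}

#' Bayes error of a discrete problem
#'
#' The minimum achievable error over all classifiers:
#' `sum_j min(c * p0_j, (1 - c) * p1_j)`.
#'
#' @param problem A [classification_problem()].
#' @return Error probability.
#' @export
bayes_error <- function(problem) {
  sum(pmin(problem$c * problem$p0, (1 - problem$c) * problem$p1))
}

#' Bayes classifier of a discrete problem
#'
#' @param problem A [classification_problem()].
#' @return Integer 0/1 decision vector attaining [bayes_error()].
#' @export
bayes_classifier <- function(problem) {
  as.integer(problem$c * problem$p0 < (1 - problem$c) * problem$p1)
}

#' Histogram (plug-in) classification rule
#'
#' Labels bin `j` as class 1 iff its class-1 count strictly exceeds its
#' class-0 count; ties — including empty bins — go to class 0, mirroring
#' the `>=` tie convention of the OBC.
#'
#' @param counts0,counts1 Bin-count vectors of equal length.
#' @return Integer 0/1 decision vector.
#' @export
histogram_rule <- function(counts0, counts1) {
  if (length(counts0) != length(counts1)) stop("length mismatch")
  as.integer(counts1 > counts0)
}

#' Squared distance of posterior means from the true parameters
#'
#' `sum_y || alpha*_y / alpha0*_y - p_y ||^2`, the evaluation metric for
#' prior-construction quality.
#'
#' @param post0,post1 Posterior [dirichlet_hyper()]s for the two classes.
#' @param problem A [classification_problem()].
#' @return Non-negative real.
#' @export
posterior_distance <- function(post0, post1, problem) {
  sum((effective_density(post0) - problem$p0)^2) +
    sum((effective_density(post1) - problem$p1)^2)
}
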