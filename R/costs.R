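#' Information-theoretic cost functions for prior construction
#'
#' The prior-construction optimization minimises the expectation, under the
#' candidate Dirichlet prior, of an information-theoretic cost.  Three
#' choices are supported, each available in closed form through log-Beta
#' and digamma terms:
#'
#' * **Maximum entropy** (`cost_maxent`): the negative differential entropy
#'   of the prior itself, `-H[Dir(alpha)]`.  Minimising it yields the least
#'   informative prior compatible with the constraints.
#' * **Maximal data information** (`cost_mdip`): Zellner's criterion
#'   `E[ln pi(theta)] + E[H[P(x | theta)]]`, keeping the prior maximally
#'   committed to the data.
#' * **Expected mean log-likelihood** (`cost_remlp`): minus the expected
#'   mean log-likelihood of a small prior-construction sample `D`,
#'   `-(1/n_D) sum_j U_j (psi(alpha_j) - psi(alpha0))`.
#'
#' @param alpha A [dirichlet_hyper()] or positive numeric vector.
#' @return A single numeric cost value.
#' @name mkdip_costs
NULL

as_alpha <- function(alpha) {
  if (inherits(alpha, "dirichlet_hyper")) alpha$alpha else as.numeric(alpha)
}

# differential entropy of Dirichlet(alpha)
dirichlet_entropy <- function(alpha) {
  a0 <- sum(alpha); b <- length(alpha)
  sum(lgamma(alpha)) - lgamma(a0) + (a0 - b) * digamma(a0) -
    sum((alpha - 1) * digamma(alpha))
}

#' @rdname mkdip_costs
#' @export
cost_maxent <- function(alpha) {
  alpha <- as_alpha(alpha)
  -dirichlet_entropy(alpha)
}

#' @rdname mkdip_costs
#' @export
cost_mdip <- function(alpha) {
  alpha <- as_alpha(alpha)
  if (length(alpha) == 1L) return(0)   # single bin: all terms vanish
  a0 <- sum(alpha)
  # E[sum_i theta_i log theta_i] = sum_i (a_i/a0)(psi(a_i + 1) - psi(a0 + 1))
  -dirichlet_entropy(alpha) -
    sum((alpha / a0) * (digamma(alpha + 1) - digamma(a0 + 1)))
}

#' @rdname mkdip_costs
#' @param prior_data Non-negative integer bin counts of the
#'   prior-construction sample `D` (must be non-empty).
#' @export
cost_remlp <- function(alpha, prior_data) {
  alpha <- as_alpha(alpha)
  n <- sum(prior_data)
  if (n == 0) stop("prior-construction sample D is empty")
  if (length(prior_data) != length(alpha)) stop("length mismatch")
  a0 <- sum(alpha)
  -sum(prior_data * (digamma(alpha) - digamma(a0))) / n
}

# --- analytic gradients with respect to alpha (internal) -----------------

grad_maxent <- function(alpha) {
  a0 <- sum(alpha); b <- length(alpha)
  (alpha - 1) * trigamma(alpha) - (a0 - b) * trigamma(a0)
}

grad_mdip <- function(alpha) {
  a0 <- sum(alpha)
  t_i <- digamma(alpha + 1) - digamma(a0 + 1)
  Tm <- sum(alpha * t_i) / a0
  dT <- (t_i + alpha * trigamma(alpha + 1)) / a0 - Tm / a0 -
    trigamma(a0 + 1)
  grad_maxent(alpha) - dT
}

grad_remlp <- function(alpha, prior_data) {
  n <- sum(prior_data)
  a0 <- sum(alpha)
  -(prior_data * trigamma(alpha) - n * trigamma(a0)) / n
}
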