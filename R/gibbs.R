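#' Multinomial mixture model with Dirichlet priors
#'
#' Observations arise from `M` multinomial components with unknown weights;
#' the weight vector carries a Dirichlet prior with parameter `phi` and each
#' component's bin-probability vector carries its own Dirichlet prior.
#' Component-specific informative priors (e.g. one centred on the normal
#' steady state, one on the mutated) break label-switching symmetry by
#' construction.
#'
#' @param phi Positive numeric vector of length `M`.
#' @param component_priors List of `M` [dirichlet_hyper()]s over the same
#'   number of bins.
#' @return An object of class `mixture_model`.
#' @export
mixture_model <- function(phi, component_priors) {
  if (any(phi <= 0)) stop("phi must be positive")
  M <- length(phi)
  if (length(component_priors) != M)
    stop("one component prior per mixture component")
  b <- length(component_priors[[1]]$alpha)
  for (pr in component_priors)
    if (length(pr$alpha) != b) stop("component priors must share b")
  structure(list(M = M, phi = as.numeric(phi),
                 component_priors = component_priors, b = b),
            class = "mixture_model")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  # guard against all-zero draws for tiny alphas
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' One sweep of the Gibbs sampler for the multinomial mixture
#'
#' Implements the three conditional updates: each latent label is drawn
#' with probability proportional to `c_j * theta_{j, x_i}`; the weights are
#' drawn from `Dirichlet(phi + label counts)`; each `theta_j` is drawn from
#' `Dirichlet(alpha_j + bin counts of the observations assigned to j)`.
#'
#' @param state List with elements `weights` (length `M`), `thetas` (list
#'   of `M` probability vectors) and `labels` (integer vector in `1..M`).
#' @param observations Integer bin indices in `1..b`.
#' @param model A [mixture_model()].
#' @return The next state, same structure.
#' @export
gibbs_step <- function(state, observations, model) {
  M <- model$M; b <- model$b
  n <- length(observations)
  # labels | weights, thetas
  logw <- log(pmax(state$weights, 1e-300))
  scores <- matrix(0, n, M)
  for (j in seq_len(M))
    scores[, j] <- logw[j] + log(pmax(state$thetas[[j]][observations],
                                      1e-300))
  scores <- exp(scores - apply(scores, 1, max))
  cs <- matrix(t(apply(scores, 1, cumsum)), n, M)
  u <- stats::runif(n) * cs[, M]
  labels <- max.col(cs >= u, ties.method = "first")
  # weights | labels
  counts_m <- tabulate(labels, nbins = M)
  weights <- rdirichlet1(model$phi + counts_m)
  # thetas | labels, data
  thetas <- vector("list", M)
  for (j in seq_len(M)) {
    bc <- tabulate(observations[labels == j], nbins = b)
    thetas[[j]] <- rdirichlet1(model$component_priors[[j]]$alpha + bc)
  }
  list(weights = weights, thetas = thetas, labels = labels)
}

#' Run the Gibbs chain
#'
#' Initial labels are drawn from the prior predictive (weights from
#' `Dirichlet(phi)`, then component memberships), so the chain is unbiased
#' and fully reproducible given `seed`.
#'
#' @param observations Integer bin indices in `1..b`.
#' @param model A [mixture_model()].
#' @param iterations Total sweeps (must exceed `burn_in`).
#' @param burn_in Discarded initial sweeps.
#' @param thinning Keep every `thinning`-th post-burn-in state.
#' @param seed Integer seed.
#' @return List of retained states (see [gibbs_step()]), length
#'   `floor((iterations - burn_in) / thinning)`.
#' @export
run_chain <- function(observations, model, iterations = 2000,
                      burn_in = 500, thinning = 2, seed = 1L) {
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  if (any(observations < 1 | observations > model$b))
    stop("observations outside 1..b")
  set.seed(seed)
  M <- model$M
  w0 <- rdirichlet1(model$phi)
  labels <- sample.int(M, length(observations), replace = TRUE, prob = w0)
  thetas <- lapply(model$component_priors, function(pr) rdirichlet1(pr$alpha))
  state <- list(weights = w0, thetas = thetas, labels = labels)
  kept <- vector("list", (iterations - burn_in) %/% thinning)
  ki <- 0L
  for (t in seq_len(iterations)) {
    state <- gibbs_step(state, observations, model)
    if (t > burn_in && (t - burn_in) %% thinning == 0L &&
        ki < length(kept)) {
      ki <- ki + 1L
      kept[[ki]] <- state
    }
  }
  kept[seq_len(ki)]
}

#' Monte-Carlo OBC decision rule from a Gibbs chain
#'
#' Classifies bin `k` to the component maximising
#' `sum_t c_y^(t) * theta_{y,k}^(t)` over the retained chain states; ties
#' break toward the lower component index.
#'
#' @param chain Non-empty list of Gibbs states.
#' @param bins Integer bin indices to classify (default: all bins).
#' @return Integer component labels (in `1..M`), one per requested bin.
#' @export
obc_mixture_classify <- function(chain, bins = NULL) {
  if (length(chain) == 0) stop("empty chain")
  M <- length(chain[[1]]$weights)
  b <- length(chain[[1]]$thetas[[1]])
  if (is.null(bins)) bins <- seq_len(b)
  score <- matrix(0, length(bins), M)
  for (st in chain)
    for (j in seq_len(M))
      score[, j] <- score[, j] + st$weights[j] * st$thetas[[j]][bins]
  max.col(score, ties.method = "first")
}
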