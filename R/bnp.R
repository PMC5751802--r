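#' Boolean network with perturbation (BNp)
#'
#' At each synchronous step a Bernoulli decision with success probability
#' `p_pert` determines whether the state is updated by perturbation or by
#' the regulating logic.  Two perturbation semantics are supported:
#'
#' * `"single"` (default): with probability `p_pert` one uniformly chosen
#'   free node flips its value and all others hold; otherwise every node
#'   takes the value of its regulating function.  This is the convention
#'   under which the package's case-study problems are calibrated.
#' * `"node"`: every free node independently either flips its current
#'   value (with probability `p_pert`) or takes its logic value, so the
#'   transition kernel factorises over nodes.
#'
#' With `p_pert > 0` either chain is irreducible over the free-node states
#' and possesses a unique steady-state distribution.
#'
#' Fixed assignments (stuck-at mutations, fixed extracellular scenarios) are
#' substituted into all regulating functions and the corresponding nodes are
#' removed from the state space; perturbation never acts on them.  Input
#' nodes left free hold their previous value under the logic update, making
#' them symmetric Bernoulli sources in steady state.
#'
#' @param network A [boolean_network()].
#' @param p_pert Perturbation probability, in \[0, 1).  `p_pert = 0` is
#'   allowed for constructing the deterministic transition matrix but not
#'   for steady-state analysis.
#' @param fixed Named 0/1 vector of stuck-at assignments (may be empty).
#' @param perturbation `"single"` or `"node"`; see Details.
#' @return An object of class `bnp_model` with elements `network` (the
#'   reduced network over free nodes), `p_pert`, `fixed` and
#'   `perturbation`.
#' @export
bnp_model <- function(network, p_pert, fixed = NULL,
                      perturbation = c("single", "node")) {
  if (!inherits(network, "boolean_network")) stop("not a boolean_network")
  if (!is.numeric(p_pert) || length(p_pert) != 1L || p_pert < 0 || p_pert >= 1)
    stop("p_pert must be a single number in [0, 1)")
  perturbation <- match.arg(perturbation)
  reduced <- fix_nodes(network, fixed)
  if (length(reduced$nodes) == 0L) stop("all nodes fixed; empty state space")
  structure(list(network = reduced, p_pert = p_pert,
                 fixed = if (is.null(fixed)) numeric(0) else unlist(fixed),
                 perturbation = perturbation),
            class = "bnp_model")
}

#' @export
print.bnp_model <- function(x, ...) {
  cat("BNp model: ", length(x$network$nodes), " free nodes, p_pert = ",
      x$p_pert, "\n", sep = "")
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), x$fixed, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Categorical distribution over network-state bins
#'
#' A probability vector over the `2^k` joint states of an ordered node
#' subset.  `bin_order` records the subset and its ordering; the bin index of
#' a state follows [state_to_bin()].
#'
#' @param probs Non-negative numeric vector summing to 1 (within 1e-12).
#' @param bin_order Character vector of node names, `2^length(bin_order)`
#'   must equal `length(probs)`; may be `NULL` for a distribution over
#'   unlabelled states (such distributions cannot be marginalized).
#' @return An object of class `categorical_distribution`.
#' @export
categorical_distribution <- function(probs, bin_order = NULL) {
  if (any(probs < -1e-15)) stop("negative probabilities")
  if (abs(sum(probs) - 1) > 1e-12) stop("probabilities must sum to 1")
  if (!is.null(bin_order) && length(probs) != 2^length(bin_order))
    stop("length(probs) must be 2^length(bin_order)")
  structure(list(probs = pmax(probs, 0), bin_order = bin_order),
            class = "categorical_distribution")
}

#' @export
print.categorical_distribution <- function(x, ...) {
  cat("Categorical distribution over", length(x$probs), "bins")
  if (!is.null(x$bin_order))
    cat(" of [", paste(x$bin_order, collapse = ","), "]")
  cat("\n")
  invisible(x)
}

#' Bin index of a binary state
#'
#' For ordered nodes `(g1, ..., gk)` with values `x`, the 1-based bin index
#' is `1 + sum(x_i * 2^(k - i))`: the first listed node is the most
#' significant bit.  All distributions, counts and constraints in the
#' package share this convention.
#'
#' @param state 0/1 vector (or matrix with one state per row).
#' @return Integer bin index (or vector of indices).
#' @examples
#' state_to_bin(c(1, 0, 1))  # 6
#' @export
state_to_bin <- function(state) {
  if (is.matrix(state)) {
    k <- ncol(state)
    as.integer(1 + state %*% 2^((k - 1):0))
  } else {
    k <- length(state)
    as.integer(1 + sum(state * 2^((k - 1):0)))
  }
}

#' Decode bin indices back to binary states
#'
#' Inverse of [state_to_bin()].
#'
#' @param bin Integer bin indices (1-based).
#' @param k Number of nodes.
#' @return 0/1 matrix with one state per row.
#' @export
bin_to_state <- function(bin, k) {
  s <- as.integer(bin) - 1L
  mat <- vapply(seq_len(k),
                function(i) bitwAnd(bitwShiftR(s, k - i), 1L),
                integer(length(s)))
  matrix(mat, nrow = length(s), ncol = k)
}

#' Exact transition probability matrix of a BNp
#'
#' Row-stochastic matrix over the `2^m` free-node states.  Under the
#' `"single"` semantics,
#' `P(x -> y) = (p / m) * 1(|y - x| = 1) + (1 - p) * 1(y = f(x))`.
#' Under the `"node"` semantics the node perturbations are independent, so
#' `P(x -> y) = prod_i [ p * 1(y_i = 1 - x_i) + (1 - p) * 1(y_i = f_i(x)) ]`,
#' which factorises into per-node Bernoulli probabilities
#' `P(y_i = 1) = p * (1 - x_i) + (1 - p) * f_i(x)`.
#'
#' @param model A [bnp_model()] with at most ~14 free nodes (exact
#'   enumeration).
#' @return A `2^m x 2^m` row-stochastic matrix; rows and columns are indexed
#'   by bin (see [state_to_bin()]).
#' @export
build_transition_matrix <- function(model) {
  if (!inherits(model, "bnp_model")) stop("not a bnp_model")
  net <- model$network
  m <- length(net$nodes)
  if (m > 14L) stop("exact enumeration limited to 14 free nodes")
  p <- model$p_pert
  S <- state_matrix(m)
  Fm <- logic_table(net)
  n <- 2^m
  if (identical(model$perturbation, "node")) {
    # per-row probability that each node is 1 next step
    Q <- p * (1 - S) + (1 - p) * Fm        # n x m
    P <- matrix(1, n, n)
    for (i in seq_len(m)) {
      qi <- Q[, i]                          # P(y_i = 1 | x) per row
      yi <- S[, i]                          # y_i per column
      P <- P * (outer(qi, yi) + outer(1 - qi, 1 - yi))
    }
    return(P)
  }
  # "single": one uniformly chosen node flips w.p. p, else synchronous logic
  P <- matrix(0, n, n)
  Fidx <- 1L + as.integer(Fm %*% 2^((m - 1):0))
  bit <- 2^((m - 1):0)
  for (x in seq_len(n)) {
    nb <- x + ifelse(S[x, ] == 1L, -bit, bit)   # single-flip neighbours
    P[x, nb] <- p / m
    P[x, Fidx[x]] <- P[x, Fidx[x]] + (1 - p)
  }
  P
}

#' Stationary distribution of an ergodic transition matrix
#'
#' Solves `t(P) %*% pi = pi`, `sum(pi) = 1` exactly by a dense linear solve.
#' The chain must be irreducible and aperiodic (guaranteed for a BNp with
#' `p_pert` in (0, 1)); reducible chains are rejected rather than silently
#' returning an arbitrary eigenvector.
#'
#' @param tpm Row-stochastic square matrix.
#' @param bin_order Optional node names defining the state bits; defaults to
#'   `b1, b2, ...`.
#' @return A [categorical_distribution()] with residual
#'   `max |t(P) pi - pi| <= 1e-12`.
#' @export
steady_state <- function(tpm, bin_order = NULL) {
  n <- nrow(tpm)
  if (ncol(tpm) != n) stop("tpm must be square")
  if (max(abs(rowSums(tpm) - 1)) > 1e-10) stop("tpm rows must sum to 1")
  if (!is_irreducible(tpm))
    stop("transition matrix is not irreducible; no unique steady state ",
         "(is p_pert = 0?)")
  A <- t(tpm) - diag(n)
  A[n, ] <- 1
  pi <- solve(A, c(rep(0, n - 1L), 1))
  resid <- max(abs(crossprod(tpm, pi) - pi))
  if (resid > 1e-10 || any(pi < -1e-10))
    stop("stationary solve failed (residual ", format(resid), ")")
  pi <- pmax(pi, 0); pi <- pi / sum(pi)
  if (is.null(bin_order)) {
    k <- round(log2(n))
    if (2^k == n) bin_order <- paste0("b", seq_len(k))
  }
  categorical_distribution(pi, bin_order)
}

# strong connectivity of the directed support graph via boolean matrix
# squaring; cheap for the <= 2^12 states handled here
is_irreducible <- function(tpm) {
  R <- (tpm > 0) | diag(nrow(tpm)) > 0
  steps <- ceiling(log2(nrow(tpm))) + 1L
  for (i in seq_len(steps)) {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  all(R) || all(R & t(R))
}

#' Steady-state distribution of a BNp model
#'
#' Convenience wrapper: transition matrix plus stationary solve, labelled by
#' the model's free nodes.
#'
#' @param model A [bnp_model()] with `p_pert` in (0, 1).
#' @return A [categorical_distribution()] over the free-node states.
#' @export
bnp_steady_state <- function(model) {
  if (model$p_pert <= 0)
    stop("steady state requires p_pert > 0 (ergodicity)")
  steady_state(build_transition_matrix(model), model$network$nodes)
}

#' Marginalize a state distribution onto a node subset
#'
#' Bin `j` of the output accumulates all input bins whose values on the kept
#' nodes decode to `j`.
#'
#' @param dist A [categorical_distribution()].
#' @param keep Ordered subset of `dist$bin_order`.
#' @return A [categorical_distribution()] over `2^length(keep)` bins.
#' @export
marginalize <- function(dist, keep) {
  if (is.null(dist$bin_order)) stop("distribution has no bin_order")
  if (!all(keep %in% dist$bin_order))
    stop("keep must be a subset of bin_order")
  m <- length(dist$bin_order)
  S <- state_matrix(m)
  colnames(S) <- dist$bin_order
  idx <- state_to_bin(S[, keep, drop = FALSE])
  out <- numeric(2^length(keep))
  for (i in seq_along(idx)) out[idx[i]] <- out[idx[i]] + dist$probs[i]
  categorical_distribution(out / sum(out), keep)
}

#' Convex mixture of distributions over the same bins
#'
#' Used for scenario averaging, e.g. weighting an extracellular signal's
#' off/on steady states.
#'
#' @param dists List of [categorical_distribution()] sharing one
#'   `bin_order`.
#' @param weights Non-negative weights summing to 1.
#' @return A [categorical_distribution()].
#' @export
scenario_mixture <- function(dists, weights) {
  if (length(dists) != length(weights)) stop("one weight per distribution")
  if (abs(sum(weights) - 1) > 1e-12 || any(weights < 0))
    stop("weights must be a probability vector")
  ref <- dists[[1]]$bin_order
  for (d in dists)
    if (!identical(d$bin_order, ref)) stop("mismatched bin_order")
  p <- Reduce(`+`, Map(function(d, w) w * d$probs, dists, weights))
  categorical_distribution(p / sum(p), ref)
}

#' Two-class discrete classification problem
#'
#' Ground truth for sampling and exact error evaluation: class-0 prior `c`
#' and the two true bin-probability vectors.
#'
#' @param c Class-0 prior probability, in (0, 1).
#' @param p0,p1 [categorical_distribution()]s over the same `bin_order`.
#' @return An object of class `classification_problem` with elements `c`,
#'   `p0`, `p1`, `bin_order` and `b` (number of bins).
#' @export
classification_problem <- function(c, p0, p1) {
  if (c <= 0 || c >= 1) stop("c must be in (0, 1)")
  if (!identical(p0$bin_order, p1$bin_order))
    stop("p0 and p1 must share bin_order")
  structure(list(c = c, p0 = p0$probs, p1 = p1$probs,
                 bin_order = p0$bin_order, b = length(p0$probs)),
            class = "classification_problem")
}

#' @export
print.classification_problem <- function(x, ...) {
  cat("Two-class problem over", x$b, "bins of [",
      paste(x$bin_order, collapse = ","), "], c =", x$c, "\n")
  cat("Bayes error:", format(bayes_error(x), digits = 4), "\n")
  invisible(x)
}
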