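#' Conditional-probability knowledge constraint
#'
#' One knowledge statement about the feature-label distribution: the
#' probability that gene `target_node` takes value `target_value`, given
#' that the conditioning genes take the values in `conditioning`, is
#' (approximately) `a`.  In the regulatory reading, `a = 1 - delta` under
#' conditioning (the regulators force the target up to context effects) and
#' `a = eta` under crosstalk.  A slackness variable with range `slack_range`
#' relaxes the constraint in the prior-construction optimization, absorbing
#' inconsistencies in archived knowledge.
#'
#' @param target_node Gene name.
#' @param target_value 0 or 1.
#' @param conditioning Named 0/1 vector over observed genes (may be empty
#'   for a marginal statement).
#' @param a Target probability in \[0, 1\].
#' @param direction One of `">="`, `"<="`, `"="`.
#' @param slack_range Allowed interval for the slackness variable, a subset
#'   of \[0, 1).
#' @return An object of class `conditional_constraint`.
#' @export
conditional_constraint <- function(target_node, target_value, conditioning =
                                     numeric(0), a = 1, direction = ">=",
                                   slack_range = c(0, 1 - 1e-9)) {
  conditioning <- unlist(conditioning)
  if (length(conditioning) && is.null(names(conditioning)))
    stop("conditioning must be a named vector")
  if (target_node %in% names(conditioning))
    stop("target node cannot appear in its own conditioning set")
  if (!target_value %in% c(0, 1)) stop("target_value must be 0 or 1")
  if (a < 0 || a > 1) stop("a must be in [0, 1]")
  direction <- match.arg(direction, c(">=", "<=", "="))
  if (slack_range[1] < 0 || slack_range[2] >= 1 ||
      slack_range[1] > slack_range[2])
    stop("slack_range must be within [0, 1)")
  structure(list(target_node = target_node,
                 target_value = as.integer(target_value),
                 conditioning = conditioning, a = a, direction = direction,
                 slack_range = slack_range),
            class = "conditional_constraint")
}

#' @export
print.conditional_constraint <- function(x, ...) {
  cond <- if (length(x$conditioning))
    paste(names(x$conditioning), x$conditioning, sep = "=", collapse = ", ")
  else "(none)"
  cat(sprintf("E[P(%s=%d | %s)] %s %g  (slack in [%g, %g])\n",
              x$target_node, x$target_value, cond, x$direction, x$a,
              x$slack_range[1], x$slack_range[2]))
  invisible(x)
}

#' Constraint set for prior construction
#'
#' Bundles the conditional-probability constraints for one class with the
#' optional population-statistic bracket on the most probable bin: when the
#' largest true bin probability is known within +/- 5%, the prior mean of
#' that bin is constrained to `[0.95, 1.05] * max_j p_j`.
#'
#' @param constraints List of [conditional_constraint()].
#' @param bin_order Character vector of observed genes defining the bins.
#' @param max_bin Optional list with elements `bin` (index of the true
#'   argmax bin), `lo`, `hi` (bounds on the prior-mean probability of that
#'   bin).
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(constraints, bin_order, max_bin = NULL) {
  for (ct in constraints) {
    if (!inherits(ct, "conditional_constraint"))
      stop("constraints must be conditional_constraint objects")
    nodes <- c(ct$target_node, names(ct$conditioning))
    if (!all(nodes %in% bin_order))
      stop("constraint references unobserved node(s): ",
           paste(setdiff(nodes, bin_order), collapse = ", "))
  }
  structure(list(constraints = constraints, bin_order = bin_order,
                 max_bin = max_bin),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("Constraint set over [", paste(x$bin_order, collapse = ","), "]:\n")
  for (ct in x$constraints) { cat("  "); print(ct) }
  if (!is.null(x$max_bin))
    cat(sprintf("  max-bin bracket: %g <= E[p_%d] <= %g\n",
                x$max_bin$lo, x$max_bin$bin, x$max_bin$hi))
  invisible(x)
}

#' Max-bin population-statistic bracket from the ground truth
#'
#' Implements the assumption that the largest true bin probability is known
#' within a +/- `tol` relative interval.
#'
#' @param p True bin-probability vector for the class.
#' @param tol Relative half-width (default 0.05).
#' @return A `max_bin` list for [constraint_set()].
#' @export
max_bin_bracket <- function(p, tol = 0.05) {
  j <- which.max(p)
  list(bin = j, lo = (1 - tol) * p[j], hi = min(1, (1 + tol) * p[j]))
}

#' Derive conditional-probability constraints from regulating functions
#'
#' For each observed gene, enumerates the minimal assignments of its
#' observed regulators that force the output of its Boolean regulating
#' function for every value of the unobserved variables (and of the gene
#' itself, for self-referential functions).  Each such forcing assignment
#' `R = r  =>  X_i = k` yields the constraint
#' `E[P(X_i = k | R = r)] >= 1 - eps` with `a = 1` and a free slackness
#' variable, matching the treatment of regulating-function knowledge when
#' the context effect is not quantified.
#'
#' Genes whose functions cannot be forced by observed variables alone
#' contribute no constraints.  Stuck-at mutations are substituted before
#' derivation, so the constraint sets differ between the normal and mutated
#' classes.
#'
#' @param network A [boolean_network()].
#' @param observed Ordered character vector of observed genes (the
#'   `bin_order`).
#' @param fixed Named 0/1 vector of stuck-at assignments (optional).
#' @param slack_range Slack range for every derived constraint.
#' @return A [constraint_set()] (without a max-bin bracket).
#' @export
derive_constraints <- function(network, observed, fixed = NULL,
                               slack_range = c(0, 1 - 1e-9)) {
  net <- fix_nodes(network, fixed)
  if (!all(observed %in% net$nodes))
    stop("observed nodes must be free nodes of the (reduced) network")
  out <- list()
  for (target in observed) {
    f <- net$functions[[target]]
    if (is.null(f)) next
    vars <- all.vars(f)
    cond_vars <- intersect(observed, setdiff(vars, target))
    compl_vars <- setdiff(vars, cond_vars)
    accepted <- list()   # minimal forcing assignments found so far
    for (size in 0:length(cond_vars)) {
      combs <- if (size == 0) list(character(0))
               else utils::combn(cond_vars, size, simplify = FALSE)
      for (S in combs) {
        n_assign <- 2^length(S)
        for (ai in seq_len(n_assign) - 1L) {
          r <- as.integer(bin_to_state(ai + 1L, max(length(S), 1L)))[
            seq_len(length(S))]
          names(r) <- S
          if (is_dominated(r, accepted)) next
          k <- forced_value(f, r, setdiff(c(cond_vars, compl_vars), S))
          if (!is.null(k)) {
            accepted[[length(accepted) + 1L]] <- r
            out[[length(out) + 1L]] <- conditional_constraint(
              target, k, r, a = 1, direction = ">=",
              slack_range = slack_range)
          }
        }
      }
    }
  }
  constraint_set(out, observed)
}

# does any accepted assignment coincide with a sub-assignment of r?
is_dominated <- function(r, accepted) {
  for (a in accepted) {
    if (all(names(a) %in% names(r)) &&
        identical(unname(r[names(a)]), unname(a))) return(TRUE)
  }
  FALSE
}

# value of f forced by assignment r over all completions of `free`, or NULL
forced_value <- function(f, r, free) {
  m <- length(free)
  env <- new.env(parent = baseenv())
  for (nm in names(r)) assign(nm, r[[nm]] == 1L, envir = env)
  if (m == 0) return(as.integer(eval(f, env)))
  S <- state_matrix(m)
  for (i in seq_len(m)) assign(free[i], S[, i] == 1L, envir = env)
  vals <- as.integer(rep_len(eval(f, env), 2^m))
  if (all(vals == vals[1])) vals[1] else NULL
}

# indices of bins consistent with a named assignment over bin_order
bins_matching <- function(assignment, bin_order) {
  b <- 2^length(bin_order)
  S <- state_matrix(length(bin_order))
  colnames(S) <- bin_order
  keep <- rep(TRUE, b)
  for (nm in names(assignment))
    keep <- keep & (S[, nm] == assignment[[nm]])
  which(keep)
}

#' Expected conditional probability under a Dirichlet prior
#'
#' For the Dirichlet-multinomial model the expectation of a conditional
#' probability is an exact ratio of sums of hyperparameters:
#' `E[P(X_i = k | R = r)] = abar(k, r) / (abar(k, r) + abar(k^c, r))`,
#' where `abar(.)` sums `alpha` over all bins consistent with the assignment
#' (unconditioned genes summed out).
#'
#' @param alpha A [dirichlet_hyper()] or positive numeric vector indexed by
#'   `bin_order`.
#' @param constraint A [conditional_constraint()].
#' @param bin_order Character vector of observed genes.
#' @return The exact expectation (no Monte Carlo).
#' @export
expected_conditional_prob <- function(alpha, constraint, bin_order) {
  if (inherits(alpha, "dirichlet_hyper")) alpha <- alpha$alpha
  if (length(alpha) != 2^length(bin_order))
    stop("alpha length must be 2^length(bin_order)")
  num <- bins_matching(c(stats::setNames(constraint$target_value,
                                         constraint$target_node),
                         constraint$conditioning), bin_order)
  den <- bins_matching(c(stats::setNames(1L - constraint$target_value,
                                         constraint$target_node),
                         constraint$conditioning), bin_order)
  A <- sum(alpha[num]); B <- sum(alpha[den])
  A / (A + B)
}

#' Feasibility margins of a constraint set
#'
#' For each constraint with slack `eps_i`: direction `>=` gives margin
#' `E - (a - eps_i)`; `<=` gives `(a + eps_i) - E`; `=` gives the pair
#' `min(E - (a - eps_i), (a + eps_i) - E)` collapsed to its minimum.  The
#' point is feasible iff all margins are non-negative.
#'
#' @param alpha Hyperparameter vector (or [dirichlet_hyper()]).
#' @param cset A [constraint_set()].
#' @param slacks Numeric vector of slackness values, one per constraint,
#'   each within its `slack_range`.
#' @return Numeric vector of margins.
#' @export
constraint_residuals <- function(alpha, cset, slacks) {
  cts <- cset$constraints
  if (length(slacks) != length(cts))
    stop("one slack per constraint required")
  vapply(seq_along(cts), function(i) {
    ct <- cts[[i]]; eps <- slacks[i]
    if (eps < ct$slack_range[1] - 1e-12 || eps > ct$slack_range[2] + 1e-12)
      stop("slack ", i, " outside its range")
    E <- expected_conditional_prob(alpha, ct, cset$bin_order)
    switch(ct$direction,
           ">=" = E - (ct$a - eps),
           "<=" = (ct$a + eps) - E,
           "="  = min(E - (ct$a - eps), (ct$a + eps) - E))
  }, numeric(1))
}

#' Read / write constraint files
#'
#' Tab-separated with columns `target_node`, `target_value`,
#' `conditioning` (semicolon-separated `node=value`, or `.` for none), `a`,
#' `direction`, `slack_lo`, `slack_hi`.
#'
#' @param path File path.
#' @param bin_order Observed genes defining the bins.
#' @return `read_constraints()` returns a [constraint_set()].
#' @export
read_constraints <- function(path, bin_order) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  cts <- lapply(seq_len(nrow(df)), function(i) {
    cond <- numeric(0)
    if (df$conditioning[i] != ".") {
      parts <- strsplit(df$conditioning[i], ";", fixed = TRUE)[[1]]
      kv <- strsplit(parts, "=", fixed = TRUE)
      cond <- stats::setNames(as.integer(vapply(kv, `[`, "", 2L)),
                              vapply(kv, `[`, "", 1L))
    }
    conditional_constraint(df$target_node[i],
                           as.integer(df$target_value[i]), cond,
                           a = as.numeric(df$a[i]),
                           direction = df$direction[i],
                           slack_range = c(as.numeric(df$slack_lo[i]),
                                           as.numeric(df$slack_hi[i])))
  })
  constraint_set(cts, bin_order)
}

#' @rdname read_constraints
#' @param cset A [constraint_set()].
#' @export
write_constraints <- function(cset, path) {
  rows <- lapply(cset$constraints, function(ct) {
    cond <- if (length(ct$conditioning))
      paste(names(ct$conditioning), ct$conditioning, sep = "=",
            collapse = ";")
    else "."
    data.frame(target_node = ct$target_node,
               target_value = ct$target_value, conditioning = cond,
               a = ct$a, direction = ct$direction,
               slack_lo = ct$slack_range[1], slack_hi = ct$slack_range[2])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
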