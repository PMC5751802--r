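#' Boolean gene regulatory networks
#'
#' A Boolean network is an ordered set of named nodes, each carrying a Boolean
#' regulating function over the node names, written with the operators `&`
#' (AND), `|` (OR), `!` (NOT) and parentheses.  Input nodes (extracellular
#' signals such as a growth factor or a DNA-damage event) carry no function
#' and are flagged as inputs; their dynamics are decided by the model that
#' embeds the network (see [bnp_model()]).
#'
#' The node order is fixed at construction and defines the bit ordering of
#' network states throughout the package: the first listed node is the most
#' significant bit of the state index (see [state_to_bin()]).
#'
#' @param nodes Character vector of node names (at least one, unique).
#' @param functions Named list mapping node names to unevaluated R
#'   expressions (as produced by [str2lang()]) over node names.  Nodes absent
#'   from the list are input nodes.
#' @return An object of class `boolean_network` with elements `nodes`,
#'   `functions` and `inputs`.
#' @examples
#' net <- boolean_network(c("a", "b"), list(b = str2lang("!a")))
#' net$inputs
#' @seealso [read_bnet()] for the plain-text file format.
#' @export
boolean_network <- function(nodes, functions = list()) {
  if (length(nodes) < 1L) stop("a Boolean network needs at least one node")
  if (anyDuplicated(nodes)) stop("duplicated node names")
  if (!all(names(functions) %in% nodes))
    stop("functions given for undeclared nodes: ",
         paste(setdiff(names(functions), nodes), collapse = ", "))
  for (nm in names(functions)) {
    refs <- all.vars(functions[[nm]])
    bad <- setdiff(refs, nodes)
    if (length(bad))
      stop("function for '", nm, "' references undeclared node(s): ",
           paste(bad, collapse = ", "))
  }
  structure(
    list(nodes = nodes, functions = functions,
         inputs = setdiff(nodes, names(functions))),
    class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network with", length(x$nodes), "nodes\n")
  for (nm in x$nodes) {
    rhs <- if (nm %in% x$inputs) "INPUT" else deparse1(x$functions[[nm]])
    cat(" ", nm, "=", rhs, "\n")
  }
  invisible(x)
}

#' Read a Boolean network from a plain-text file
#'
#' One line per node, `name = expression`, with `&`, `|`, `!` and
#' parentheses; input nodes are declared as `name = INPUT`.  Blank lines and
#' `#` comments are ignored.  Node order in the file defines the state bit
#' order.
#'
#' @param path Path to the network definition file.
#' @return A [boolean_network()].
#' @examples
#' net <- read_bnet(system.file("extdata", "tp53.bnet", package = "mkdipobc"))
#' net$nodes
#' @export
read_bnet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  nodes <- character(0)
  funs <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed line (no '='): ", ln)
    nm <- trimws(substr(ln, 1L, eq - 1L))
    rhs <- trimws(substr(ln, eq + 1L, nchar(ln)))
    if (!grepl("^[A-Za-z][A-Za-z0-9_.]*$", nm))
      stop("invalid node name: '", nm, "'")
    nodes <- c(nodes, nm)
    if (!identical(rhs, "INPUT")) {
      if (grepl("[^A-Za-z0-9_.!&|()[:space:]]", rhs))
        stop("invalid character in expression for '", nm, "'")
      funs[[nm]] <- str2lang(rhs)
    }
  }
  boolean_network(nodes, funs)
}

#' Substitute permanently fixed node values into a network
#'
#' Stuck-at mutations (and fixed extracellular scenarios) remove a node from
#' the state space: its value is substituted as a constant into every other
#' regulating function and the node itself is dropped.  Perturbation never
#' acts on a fixed node.
#'
#' @param network A [boolean_network()].
#' @param fixed Named numeric/integer vector or list of 0/1 values.
#' @return A smaller `boolean_network` over the remaining nodes.
#' @export
fix_nodes <- function(network, fixed) {
  fixed <- unlist(fixed)
  if (length(fixed) == 0L) return(network)
  if (!all(names(fixed) %in% network$nodes))
    stop("fixed nodes not in network: ",
         paste(setdiff(names(fixed), network$nodes), collapse = ", "))
  if (!all(fixed %in% c(0, 1))) stop("fixed values must be 0 or 1")
  env <- list()
  for (nm in names(fixed)) env[[nm]] <- fixed[[nm]] == 1
  keep <- setdiff(network$nodes, names(fixed))
  funs <- list()
  for (nm in intersect(keep, names(network$functions)))
    funs[[nm]] <- substitute_constants(network$functions[[nm]], env)
  boolean_network(keep, funs)
}

# recursive constant substitution into a Boolean expression
substitute_constants <- function(expr, env) {
  if (is.name(expr)) {
    nm <- as.character(expr)
    if (nm %in% names(env)) return(env[[nm]])
    return(expr)
  }
  if (is.call(expr)) {
    for (i in seq_along(expr)[-1L])
      expr[[i]] <- substitute_constants(expr[[i]], env)
    return(expr)
  }
  expr
}

#' Synchronous logic update of a network state
#'
#' Applies every regulating function to the current state simultaneously.
#' Input nodes (no function) hold their current value; fixed nodes must have
#' been substituted away beforehand (see [fix_nodes()] / [bnp_model()]).
#'
#' @param model A [bnp_model()] (or a bare [boolean_network()], in which case
#'   no nodes are fixed).
#' @param state Integer 0/1 vector over the model's free nodes, in node
#'   order.
#' @return Integer 0/1 vector: the deterministic synchronous successor.
#' @examples
#' net <- read_bnet(system.file("extdata", "tp53.bnet", package = "mkdipobc"))
#' m <- bnp_model(net, p_pert = 0.01, fixed = c(dna_dsb = 0))
#' evaluate_logic(m, c(1, 0, 0, 0))  # ATM on -> P53 on next step
#' @export
evaluate_logic <- function(model, state) {
  net <- if (inherits(model, "bnp_model")) model$network else model
  if (!inherits(net, "boolean_network")) stop("not a boolean_network")
  m <- length(net$nodes)
  if (length(state) != m)
    stop("state length ", length(state), " but network has ", m, " free nodes")
  env <- new.env(parent = baseenv())
  for (i in seq_len(m)) assign(net$nodes[i], state[i] == 1, envir = env)
  out <- integer(m)
  for (i in seq_len(m)) {
    nm <- net$nodes[i]
    f <- net$functions[[nm]]
    out[i] <- if (is.null(f)) state[i] else as.integer(eval(f, env))
  }
  out
}

# all 2^m states as a 0/1 matrix, row s+1 = state with index s,
# column i = node i, first node most significant bit
state_matrix <- function(m) {
  s <- 0:(2^m - 1)
  mat <- vapply(seq_len(m),
                function(i) bitwAnd(bitwShiftR(s, m - i), 1L),
                integer(2^m))
  matrix(mat, nrow = 2^m, ncol = m)
}

# next-state table: row s+1 = f(state s) for every state, as a 0/1 matrix
logic_table <- function(net) {
  m <- length(net$nodes)
  S <- state_matrix(m)
  env <- new.env(parent = baseenv())
  for (i in seq_len(m)) assign(net$nodes[i], S[, i] == 1, envir = env)
  Fm <- matrix(0L, nrow = 2^m, ncol = m)
  for (i in seq_len(m)) {
    f <- net$functions[[net$nodes[i]]]
    Fm[, i] <- if (is.null(f)) S[, i]
               else as.integer(rep_len(eval(f, env), 2^m))
  }
  Fm
}
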