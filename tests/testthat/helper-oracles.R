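# shared fixtures and independent oracles used across test files

toy2 <- boolean_network(c("a", "b"),
                        list(a = str2lang("a | b"), b = str2lang("!a")))

toy3 <- boolean_network(c("x", "y", "z"),
                        list(x = str2lang("y & !z"),
                             y = str2lang("x | z"),
                             z = str2lang("!x")))

load_cellcycle <- function()
  read_bnet(system.file("extdata", "cellcycle.bnet", package = "mkdipobc"))
load_tp53 <- function()
  read_bnet(system.file("extdata", "tp53.bnet", package = "mkdipobc"))

cc_features <- c("E2F", "CycE", "CycA", "Cdc20", "Cdh1", "UbcH10", "CycB")
tp_features <- c("ATM", "Wip1", "Mdm2")

# independent per-node-perturbation TPM: enumerate all flip/logic decision
# vectors explicitly instead of factorising
tpm_oracle_node <- function(model) {
  net <- model$network
  m <- length(net$nodes)
  p <- model$p_pert
  n <- 2^m
  P <- matrix(0, n, n)
  for (xi in seq_len(n)) {
    x <- as.integer(bin_to_state(xi, m))
    f <- evaluate_logic(model, x)
    for (di in seq_len(2^m)) {
      d <- as.integer(bin_to_state(di, m))   # 1 = flip, 0 = logic
      y <- ifelse(d == 1L, 1L - x, f)
      w <- prod(ifelse(d == 1L, p, 1 - p))
      yi <- state_to_bin(y)
      P[xi, yi] <- P[xi, yi] + w
    }
  }
  P
}

# empirical distribution of a simulated trajectory of the chain
trajectory_ssd <- function(tpm, steps, seed = 1) {
  set.seed(seed)
  n <- nrow(tpm)
  counts <- numeric(n)
  s <- 1L
  # transition by inverse-cdf sampling on precomputed row cdfs
  cdf <- t(apply(tpm, 1, cumsum))
  u <- stats::runif(steps)
  for (t in seq_len(steps)) {
    s <- which(cdf[s, ] >= u[t])[1]
    counts[s] <- counts[s] + 1
  }
  counts / steps
}

rdirichlet_mat <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha,
                                                           each = n)),
              nrow = n)
  g / rowSums(g)
}

# brute-force OBC: enumerate all 2^b labelings, minimise posterior
# expected error
obc_oracle <- function(c_expect, f0, f1) {
  b <- length(f0)
  best <- NULL; best_err <- Inf
  for (code in 0:(2^b - 1)) {
    psi <- as.integer(bin_to_state(code + 1, b))
    err <- c_expect * sum(f0[psi == 1L]) +
      (1 - c_expect) * sum(f1[psi == 0L])
    if (err < best_err - 1e-15) { best_err <- err; best <- psi }
  }
  list(psi = best, err = best_err)
}
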