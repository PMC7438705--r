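# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closure by boolean matrix powers, profile
# enumeration by brute-force filtering, likelihood by exhaustive trajectory
# enumeration.

# reflexive transitive closure via repeated boolean matrix multiplication
oracle_closure <- function(K, edges) {
  A <- diag(1, K)
  if (length(edges)) for (e in edges) A[e[1], e[2]] <- 1
  repeat {
    B <- (A %*% A > 0) * 1
    if (identical(B, A)) return(A)
    A <- B
  }
}

# all binary K-vectors (rows), in no particular order
oracle_all_profiles <- function(K) {
  as.matrix(expand.grid(rep(list(0:1), K)))[, K:1, drop = FALSE]
}

# brute-force permissible profiles: keep alpha iff every mastered attribute
# has all its closure-prerequisites mastered
oracle_permissible <- function(K, edges) {
  R <- oracle_closure(K, edges)
  all_p <- oracle_all_profiles(K)
  keep <- apply(all_p, 1, function(a)
    all(sapply(seq_len(K), function(k)
      a[k] == 0 || all(a[R[, k] == 1] == 1))))
  all_p[keep, , drop = FALSE]
}

# exhaustive-path marginal log-likelihood: sums the structural x measurement
# product over all C^T latent trajectories; p is the I x C probability matrix
oracle_loglik <- function(delta, tau_list, p, responses) {
  d <- dim(responses)
  N <- d[1]; I <- d[2]; Tt <- d[3]; C <- length(delta)
  paths <- as.matrix(expand.grid(rep(list(seq_len(C)), Tt)))
  total <- 0
  for (n in seq_len(N)) {
    lik <- 0
    for (j in seq_len(nrow(paths))) {
      path <- paths[j, ]
      pr <- delta[path[1]]
      if (Tt > 1) for (t in 2:Tt) pr <- pr * tau_list[[t - 1]][path[t - 1], path[t]]
      for (t in seq_len(Tt)) {
        y <- responses[n, , t]
        pc <- p[, path[t]]
        pr <- pr * prod(ifelse(y == 1, pc, 1 - pc))
      }
      lik <- lik + pr
    }
    total <- total + log(lik)
  }
  total
}

# a random DAG on K attributes: random topological order, each forward pair
# becomes an edge with probability p_edge
random_dag <- function(K, p_edge = 0.4) {
  ord <- sample(K)
  edges <- list()
  for (i in seq_len(K - 1)) for (j in (i + 1):K)
    if (stats::runif(1) < p_edge)
      edges <- c(edges, list(c(ord[i], ord[j])))
  edges
}

# random row-stochastic matrix
random_stochastic <- function(C) {
  m <- matrix(stats::rgamma(C * C, 1), C, C)
  m / rowSums(m)
}

# a small simulated data set plus its generating design, shared by tests
make_small_sim <- function(hierarchy = "linear", design = "Q2", N = 200,
                           seed = 42) {
  d <- study_design(hierarchy, design, n_examinees = N)
  c(simulate_study(d, seed = seed), list(hierarchy = d$hierarchy))
}
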