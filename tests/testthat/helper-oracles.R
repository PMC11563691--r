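# Shared fixtures and independent oracles used across the suite.

# random positive-definite correlation matrix
rand_corr <- function(k) {
  A <- matrix(rnorm(k * k), k)
  cov_to_corr(crossprod(A) + diag(k))
}

# random rooted binary tree with strictly positive branch lengths
rand_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

# zero-mean MVN log density computed by an independent route
# (explicit inverse and determinant rather than Cholesky backsolves)
naive_mvn_loglik <- function(x, V) {
  k <- length(x)
  logdet <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -(k / 2) * log(2 * pi) - 0.5 * logdet -
    0.5 * drop(t(x) %*% solve(V) %*% x)
}

# weighted squared-change objective for BM ancestral states, and its direct
# numerical minimisation (the brute-force reconstruction oracle)
ssq_objective <- function(tree, x_tips, internal) {
  s <- c(x_tips[tree$tip.label], internal)
  sum((s[tree$edge[, 2]] - s[tree$edge[, 1]])^2 / tree$edge.length)
}
numeric_asr <- function(tree, x_tips) {
  o <- stats::optim(rep(mean(x_tips), tree$Nnode), ssq_objective,
                    tree = tree, x_tips = x_tips, method = "BFGS",
                    control = list(reltol = 1e-16, maxit = 5000))
  o$par
}

# exhaustive Fitch oracle: minimum changes over all internal labelings
brute_fitch <- function(tree, states) {
  n <- ape::Ntip(tree)
  n_int <- tree$Nnode
  s_tip <- states[tree$tip.label]
  grid <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    s <- c(s_tip, grid[i, ])
    best <- min(best, sum(s[child] != s[parent]))
  }
  best
}
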