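#' Brownian-motion ancestral state reconstruction
#'
#' Joint maximum-likelihood reconstruction of internal node states under
#' Brownian motion, computed independently per trait.  Equivalent to
#' weighted squared-change parsimony: the internal states minimise
#' `sum over branches of (change along branch)^2 / branch length`.
#' Implemented as a two-pass message-passing scheme — a tipward (postorder)
#' pass accumulates, for each node, the conditional mean and an effective
#' variance of its subtree; a rootward (preorder) pass then resolves each
#' internal state as the precision-weighted average of its subtree message
#' and its parent's resolved state.
#'
#' Zero-length branches are replaced by `1e-8` times the tree height so the
#' inverse-length weights stay finite.
#'
#' @param tree a rooted binary `phylo` with branch lengths.
#' @param X species-by-trait matrix whose rownames cover all tips of `tree`.
#' @return numeric matrix of node states, `(2n - 1)` rows named by node id
#'   (tips `1..n` carry the observed values exactly), one column per trait.
#' @examples
#' tr <- parse_newick("(A:1,B:1);")
#' asr_bm(tr, matrix(c(0, 2), 2, 1, dimnames = list(c("A", "B"), "t")))
#' @export
asr_bm <- function(tree, X) {
  X <- as.matrix(X)
  n <- ape::Ntip(tree)
  missing <- setdiff(tree$tip.label, rownames(X))
  if (length(missing))
    stop("tips absent from trait matrix: ", paste(missing, collapse = ", "))
  X <- X[tree$tip.label, , drop = FALSE]
  if (anyNA(X)) stop("trait matrix contains missing values")
  k <- ncol(X)
  n_nodes <- n + tree$Nnode
  bl <- .branch_lengths(tree)

  m <- matrix(0, n_nodes, k)          # subtree conditional means
  v <- numeric(n_nodes)               # subtree effective variances
  m[seq_len(n), ] <- X
  wsum <- numeric(n_nodes)

  # postorder guarantees a child's own accumulation is complete before its
  # edge is visited, so its message can be finalised at that moment
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; c_ <- po$edge[i, 2]
    if (c_ > n) {
      m[c_, ] <- m[c_, ] / wsum[c_]
      v[c_] <- 1 / wsum[c_]
    }
    w <- 1 / (bl[c_] + v[c_])
    m[p, ] <- m[p, ] + w * m[c_, ]
    wsum[p] <- wsum[p] + w
  }
  root <- .root_node(tree)
  m[root, ] <- m[root, ] / wsum[root]
  v[root] <- 1 / wsum[root]

  states <- matrix(NA_real_, n_nodes, k,
                   dimnames = list(seq_len(n_nodes), colnames(X)))
  states[seq_len(n), ] <- X
  states[root, ] <- m[root, ]
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pre$edge))) {
    p <- pre$edge[i, 1]; c_ <- pre$edge[i, 2]
    if (c_ <= n) next
    wd <- 1 / v[c_]; wp <- 1 / bl[c_]
    states[c_, ] <- (wd * m[c_, ] + wp * states[p, ]) / (wd + wp)
  }
  states
}

#' Branch-wise divergence vectors
#'
#' One row per branch: the reconstructed change along that branch, computed
#' as child state minus parent state (the change accumulated moving tipward;
#' the global sign convention leaves correlation matrices unchanged).  A
#' rooted binary tree with n tips yields exactly `2n - 2` rows, and along
#' any root-to-tip path the rows telescope to tip value minus root value.
#'
#' @param tree a rooted binary `phylo`.
#' @param states node-state matrix from [asr_bm()] (must cover all nodes).
#' @param scale_by_time divide each row by the square root of its branch
#'   length, standardising changes to unit expected variance under
#'   time-scaled Brownian motion.  Off by default: the mixture model applies
#'   one covariance matrix per branch with no time factor.
#' @return `(2n - 2)`-by-k matrix, rows named by child node id, with a
#'   `branch_lengths` attribute (epsilon-adjusted, same order).
#' @export
branch_divergences <- function(tree, states, scale_by_time = FALSE) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  if (nrow(states) != n_nodes)
    stop("states must cover all ", n_nodes, " nodes")
  child <- tree$edge[, 2]
  D <- states[child, , drop = FALSE] - states[tree$edge[, 1], , drop = FALSE]
  rownames(D) <- child
  bl <- .branch_lengths(tree)[child]
  if (scale_by_time) D <- D / sqrt(bl)
  attr(D, "branch_lengths") <- stats::setNames(bl, child)
  D
}
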