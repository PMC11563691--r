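# Internal tree helpers shared by the reconstruction, search and simulation
# code.  All of them use ape's node numbering: tips 1..n, root n+1.

# parent pointer for every node (0 for the root)
.parents <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  par <- integer(n_nodes)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

.root_node <- function(tree) ape::Ntip(tree) + 1L

# number of tips descended from every node (tips count themselves)
.tip_counts <- function(tree) {
  n <- ape::Ntip(tree)
  cnt <- integer(n + tree$Nnode)
  cnt[seq_len(n)] <- 1L
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    e <- po$edge[i, ]
    cnt[e[1]] <- cnt[e[1]] + cnt[e[2]]
  }
  cnt
}

# strict descendants (node ids, tips and internals) of `node`
.descendants <- function(tree, node) {
  children <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- children[[as.character(node)]]
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, v)
    kids <- children[[as.character(v)]]
    if (!is.null(kids)) stack <- c(stack, kids)
  }
  out
}

# preorder sequence of node ids (root first)
.preorder_nodes <- function(tree) {
  ro <- ape::reorder.phylo(tree, "cladewise")
  c(.root_node(tree), ro$edge[, 2])
}

# branch lengths indexed by child node id, zero-length branches bumped to a
# small epsilon relative to tree height so inverse-length weights stay finite
.branch_lengths <- function(tree, eps_scale = 1e-8) {
  bl <- numeric(ape::Ntip(tree) + tree$Nnode)
  bl[tree$edge[, 2]] <- tree$edge.length
  height <- max(ape::node.depth.edgelength(tree))
  if (height <= 0) height <- 1
  child <- tree$edge[, 2]
  bl[child][bl[child] <= 0] <- eps_scale * height
  bl
}

#' Assign every branch to a covariation regime
#'
#' Each branch belongs to the regime of the most recent shift node on its
#' rootward path, with the root regime numbered 0.  A shift is placed *at* a
#' clade root: the clade's stem branch stays in the parent regime, and only
#' branches strictly inside the clade take the new regime (so a shift node's
#' own subtending branch is not reassigned).
#'
#' @param tree a `phylo` object.
#' @param shift_nodes integer vector of internal node ids; the i-th entry
#'   defines regime `i`.  May be empty.
#' @return integer vector of regime ids, one per branch, named by the
#'   branch's child node id.
#' @export
regime_assignment <- function(tree, shift_nodes = integer(0)) {
  shift_nodes <- as.integer(shift_nodes)
  par <- .parents(tree)
  regime_of_node <- integer(0)
  if (length(shift_nodes))
    regime_of_node <- stats::setNames(seq_along(shift_nodes), shift_nodes)
  child <- tree$edge[, 2]
  out <- integer(length(child))
  for (i in seq_along(child)) {
    v <- par[child[i]]           # start at the parent: the stem is excluded
    reg <- 0L
    while (v != 0L) {
      hit <- regime_of_node[as.character(v)]
      if (!is.na(hit)) { reg <- unname(hit); break }
      v <- par[v]
    }
    out[i] <- reg
  }
  stats::setNames(out, child)
}
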