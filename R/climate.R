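# Freezing-tolerance classification from per-species minimum coldest-month
# temperatures (BIO6) and Fitch parsimony mapping of the binary habit.

#' Classify one species as freezing tolerant or not
#'
#' A species is called freezing tolerant when at least 2.5% of its cleaned
#' occurrences experience a minimum coldest-month temperature at or below
#' 0 degrees C; species with fewer than `min_occurrences` values are
#' excluded as undersampled.  Both boundaries are inclusive: a fraction of
#' exactly 0.025 and a temperature of exactly 0 both count.
#'
#' @param bio6 numeric vector of BIO6 values (degrees C), one per
#'   occurrence.
#' @param min_occurrences minimum number of occurrences (default 10).
#' @param freezing_fraction fraction threshold (default 0.025).
#' @param freezing_temp temperature cutoff in degrees C (default 0).
#' @return `"freezing"`, `"nonfreezing"` or `"excluded"`.
#' @examples
#' classify_freezing(c(rep(5, 39), 0))   # 1/40 = 0.025 -> freezing
#' @export
classify_freezing <- function(bio6, min_occurrences = 10,
                              freezing_fraction = 0.025,
                              freezing_temp = 0) {
  bio6 <- bio6[!is.na(bio6)]
  if (length(bio6) && any(!is.finite(bio6)))
    stop("non-finite BIO6 values")
  if (length(bio6) < min_occurrences) return("excluded")
  frac <- mean(bio6 <= freezing_temp)
  if (frac >= freezing_fraction) "freezing" else "nonfreezing"
}

#' Classify every species in a long-format occurrence table
#'
#' @param occurrences data frame with columns `species` and `bio6` (one row
#'   per occurrence), as read by [read_bio6()].
#' @inheritParams classify_freezing
#' @return data frame with columns `species`, `n_occurrences`, `state`
#'   (`"freezing"`/`"nonfreezing"`/`"excluded"`), and `state01` (1 =
#'   freezing, 0 = nonfreezing, NA = excluded).
#' @export
classify_freezing_table <- function(occurrences, min_occurrences = 10,
                                    freezing_fraction = 0.025,
                                    freezing_temp = 0) {
  if (!all(c("species", "bio6") %in% names(occurrences)))
    stop("`occurrences` must have columns species and bio6")
  by_sp <- split(occurrences$bio6, occurrences$species)
  state <- vapply(by_sp, classify_freezing, character(1),
                  min_occurrences = min_occurrences,
                  freezing_fraction = freezing_fraction,
                  freezing_temp = freezing_temp)
  data.frame(
    species = names(by_sp),
    n_occurrences = vapply(by_sp, function(v) sum(!is.na(v)), integer(1)),
    state = unname(state),
    state01 = unname(c(freezing = 1L, nonfreezing = 0L,
                       excluded = NA_integer_)[state]),
    row.names = NULL
  )
}

#' Read a long-format BIO6 occurrence table
#'
#' @param file CSV with columns `species,bio6`, one row per occurrence.
#' @return data frame with those two columns.
#' @export
read_bio6 <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("species", "bio6") %in% names(df)))
    stop("expected columns species,bio6 in ", file)
  df$bio6 <- as.numeric(df$bio6)
  df
}

#' Fitch parsimony mapping of a binary character
#'
#' Minimum number of state changes for a binary (0/1) character on a rooted
#' tree, together with the full MPR (most parsimonious reconstruction)
#' state set for every node: state s belongs to a node's set exactly when
#' some globally optimal labelling assigns s to that node.  Computed by
#' unit-cost dynamic programming down- and up-passes, so the sets are exact
#' rather than the (narrower) plain Fitch downpass sets.  Ambiguous nodes
#' are reported as two-state sets, not resolved.
#'
#' Tips lacking a state (e.g. species excluded by the occurrence filter)
#' must be pruned from the tree first, e.g. with [ape::drop.tip()].
#'
#' @param tree rooted `phylo` (binary or not).
#' @param states integer/numeric vector of 0/1 states named by tip label,
#'   covering every tip.
#' @return list with `score` (minimum changes), `node_sets` (2n-1 by 2
#'   logical matrix, columns `state0`/`state1`, rows = node ids), and
#'   `downpass` (the Fitch downpass sets, same shape).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' fitch_map(tr, c(A = 1, B = 1, C = 0, D = 0))$score   # 1
#' @export
fitch_map <- function(tree, states) {
  n <- ape::Ntip(tree)
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("tips without a state: ", paste(miss, collapse = ", "))
  s <- states[tree$tip.label]
  if (anyNA(s) || !all(s %in% c(0, 1)))
    stop("states must be 0 or 1 for every tip (prune excluded tips first)")
  n_nodes <- n + tree$Nnode
  big <- n_nodes + 1  # exceeds any attainable change count

  # downpass: minimal changes in the subtree with the node fixed to a state
  down <- matrix(0, n_nodes, 2)
  down[cbind(seq_len(n), 2 - s)] <- big   # tip fixed: other state forbidden
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    contrib <- pmin(down[ch, ], c(down[ch, 2] + 1, down[ch, 1] + 1))
    down[p, ] <- down[p, ] + contrib
  }
  root <- n + 1L
  score <- min(down[root, ])

  # uppass: minimal changes outside the subtree with the node fixed
  up <- matrix(0, n_nodes, 2)
  children <- split(po$edge[, 2], po$edge[, 1])
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pre$edge))) {
    p <- pre$edge[i, 1]; ch <- pre$edge[i, 2]
    sibs <- setdiff(children[[as.character(p)]], ch)
    sib_cost <- rep(0, 2)   # indexed by parent state
    for (b in sibs)
      sib_cost <- sib_cost + pmin(down[b, ], c(down[b, 2] + 1, down[b, 1] + 1))
    parent_cost <- up[p, ] + sib_cost
    up[ch, ] <- pmin(parent_cost, parent_cost[2:1] + 1)
  }

  total <- down + up
  node_sets <- total == score
  colnames(node_sets) <- c("state0", "state1")
  rownames(node_sets) <- seq_len(n_nodes)
  dp_sets <- down < big & sweep(down, 1, apply(down, 1, min), "==")
  colnames(dp_sets) <- c("state0", "state1")
  rownames(dp_sets) <- seq_len(n_nodes)
  list(score = score, node_sets = node_sets, downpass = dp_sets)
}
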