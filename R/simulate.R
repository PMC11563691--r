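# Simulation of regime-structured multivariate trait evolution, used for
# null calibration and shift-recovery experiments.

#' Simulate a Yule (pure-birth) tree
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per Myr (> 0).
#' @param seed integer seed; all randomness flows from it.
#' @return rooted binary ultrametric `phylo` with tips `t1..tn`.
#' @export
sim_yule <- function(n_tips, birth_rate = 1, seed = 1) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  set.seed(as.integer(seed))
  ape::rphylo(n_tips, birth = birth_rate, death = 0)
}

#' Pick the clade whose size is closest to a target
#'
#' Deterministic helper for planting shifts: among internal non-root nodes,
#' returns the one whose tip count is nearest `size` (ties: larger clade,
#' then preorder position).
#'
#' @param tree rooted `phylo`.
#' @param size target number of tips.
#' @return internal node id.
#' @export
choose_clade <- function(tree, size) {
  cnt <- .tip_counts(tree)
  pre <- .preorder_nodes(tree)
  cand <- pre[pre > ape::Ntip(tree) & pre != .root_node(tree)]
  if (!length(cand)) stop("tree has no internal non-root nodes")
  d <- abs(cnt[cand] - size)
  cand[order(d, -cnt[cand])][1]
}

#' Simulate branch-wise divergences under regime-specific correlations
#'
#' Draws, for every branch, a k-variate normal increment with mean zero and
#' covariance the matrix of the branch's regime (optionally scaled by
#' branch length), then accumulates increments root-to-tip to produce tip
#' trait values.  The root state is fixed at zero; regime membership
#' follows [regime_assignment()] (a shift's stem branch draws from the
#' parent regime).
#'
#' @param tree rooted binary `phylo`.
#' @param shift_nodes integer vector of shift node ids (regime i is
#'   `matrices[[i + 1]]`); empty for a homogeneous tree.
#' @param matrices list of positive-definite k-by-k matrices, one per
#'   regime (`length(shift_nodes) + 1`, ancestral regime first), or a
#'   single matrix for the homogeneous case.
#' @param seed integer seed.
#' @param scale_by_time multiply each increment's covariance by the branch
#'   length (time-scaled Brownian motion); off by default to match the
#'   mixture model's unscaled branches.
#' @return list with `traits` (tip-by-trait matrix, rownames = tip
#'   labels), `divergences` (true increments, rows named by child node
#'   id, same layout as [branch_divergences()]), and `assignment`.
#' @export
sim_divergences <- function(tree, shift_nodes = integer(0), matrices,
                            seed = 1, scale_by_time = FALSE) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (length(matrices) != length(shift_nodes) + 1L)
    stop("need one matrix per regime (length(shift_nodes) + 1)")
  k <- ncol(matrices[[1]])
  chols <- lapply(matrices, function(V) {
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) stop("regime matrix is not positive definite")
    ch
  })
  set.seed(as.integer(seed))
  assignment <- regime_assignment(tree, shift_nodes)
  n <- ape::Ntip(tree)
  n_nodes <- n + tree$Nnode
  child <- tree$edge[, 2]
  Z <- matrix(stats::rnorm(length(child) * k), length(child), k)
  D <- matrix(0, length(child), k, dimnames = list(child, colnames(matrices[[1]])))
  for (i in seq_along(child)) {
    inc <- Z[i, ] %*% chols[[assignment[[as.character(child[i])]] + 1L]]
    if (scale_by_time) inc <- inc * sqrt(tree$edge.length[i])
    D[i, ] <- inc
  }
  states <- matrix(0, n_nodes, k)
  pre <- ape::reorder.phylo(tree, "cladewise")
  row_of <- stats::setNames(seq_along(child), child)
  for (i in seq_len(nrow(pre$edge))) {
    p <- pre$edge[i, 1]; c_ <- pre$edge[i, 2]
    states[c_, ] <- states[p, ] + D[row_of[[as.character(c_)]], ]
  }
  traits <- states[seq_len(n), , drop = FALSE]
  rownames(traits) <- tree$tip.label
  list(traits = traits, divergences = D, assignment = assignment)
}

#' Simulation experiment: does the search recover planted shifts?
#'
#' Runs `replicates` independent rounds of: simulate a Yule tree, plant the
#' configured shifts (clades chosen by [choose_clade()] at the requested
#' sizes), simulate trait divergences, run [greedy_search()] on the true
#' divergence matrix, and record what the search found.  With a single
#' matrix and no `shift_sizes` this measures the false-positive rate under
#' the homogeneous null.  Set `use_asr = TRUE` to run the full empirical
#' chain instead ([shift_search()] on the simulated tip traits, so
#' reconstruction error is included in the experiment).
#'
#' @param n_tips tips per simulated tree.
#' @param matrices list of regime correlation matrices (ancestral first);
#'   a single matrix simulates the homogeneous null.
#' @param shift_sizes integer vector of planted clade sizes (one per
#'   non-ancestral regime); `NULL` for the null configuration.
#' @param replicates number of rounds (0 gives an empty table).
#' @param seed master seed; replicate r uses `seed + r`.
#' @param birth_rate Yule speciation rate.
#' @param alpha,min_size,min_delta_aic search settings, see
#'   [greedy_search()].
#' @param scale_by_time simulate (and analyse) time-scaled increments.
#' @param use_asr analyse reconstructed divergences from the simulated tip
#'   traits instead of the true increments.
#' @return data frame with one row per replicate: `replicate`,
#'   `planted_nodes` and `shift_nodes` (comma-joined ids), `n_shifts`
#'   (number retained), `recovered` (retained set exactly equals the
#'   planted set), `contains_planted` (every planted node retained, extras
#'   allowed), and `delta_aic` (base AIC minus final AIC).
#' @export
recovery_experiment <- function(n_tips, matrices, shift_sizes = NULL,
                                replicates = 20, seed = 1, birth_rate = 1,
                                alpha = 0.1, min_size = NULL,
                                min_delta_aic = 0, scale_by_time = FALSE,
                                use_asr = FALSE) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (length(matrices) != length(shift_sizes) + 1L)
    stop("need one matrix per regime (length(shift_sizes) + 1)")
  empty <- data.frame(replicate = integer(0), planted_nodes = character(0),
                      shift_nodes = character(0), n_shifts = integer(0),
                      recovered = logical(0), contains_planted = logical(0),
                      delta_aic = numeric(0))
  if (!replicates) return(empty)
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rep_seed <- as.integer(seed) + r
    tree <- sim_yule(n_tips, birth_rate, seed = rep_seed)
    planted <- integer(0)
    for (sz in shift_sizes) planted <- c(planted, choose_clade(tree, sz))
    sim <- sim_divergences(tree, planted, matrices, seed = rep_seed + 10000L,
                           scale_by_time = scale_by_time)
    model <- if (use_asr)
      shift_search(tree, sim$traits, min_size = min_size, alpha = alpha,
                   scale_by_time = scale_by_time,
                   min_delta_aic = min_delta_aic)
    else
      greedy_search(tree, sim$divergences, min_size = min_size,
                    alpha = alpha, min_delta_aic = min_delta_aic)
    out[[r]] <- data.frame(
      replicate = r,
      planted_nodes = paste(planted, collapse = ","),
      shift_nodes = paste(model$shift_nodes, collapse = ","),
      n_shifts = length(model$shift_nodes),
      recovered = setequal(model$shift_nodes, planted),
      contains_planted = all(planted %in% model$shift_nodes),
      delta_aic = model$base_aic - model$aic
    )
  }
  do.call(rbind, out)
}

#' Correlation matrices used in the validation experiments
#'
#' `equicorr(k, rho)` is the exchangeable correlation matrix; requiring
#' `rho > -1/(k-1)` keeps it positive definite.  `flip_sign(R, i)` negates
#' variable i's correlations (a similarity transform, so positive
#' definiteness is preserved); applied to a strong equicorrelation matrix
#' it yields a matrix with the same mean absolute correlation but a
#' maximally different sign structure.
#'
#' @param k dimension.
#' @param rho common correlation.
#' @return k-by-k correlation matrix.
#' @export
equicorr <- function(k, rho) {
  if (rho <= -1 / (k - 1) || rho >= 1)
    stop("equicorrelation matrix not positive definite for this rho")
  M <- matrix(rho, k, k)
  diag(M) <- 1
  M
}

#' @rdname equicorr
#' @param R correlation matrix.
#' @param i variable whose correlations are negated.
#' @export
flip_sign <- function(R, i = 1) {
  s <- rep(1, ncol(R))
  s[i] <- -1
  diag(s) %*% R %*% diag(s)
}
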