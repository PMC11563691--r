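# Ranked greedy AIC search for clade-level shifts in the divergence
# correlation structure.

# shrunk correlation estimate from a block of divergence rows; NULL when the
# block is too small or the result cannot be factorised
.regime_matrix <- function(rows, alpha, assume_zero_mean = FALSE) {
  if (nrow(rows) < 2L) return(NULL)
  R <- cov_to_corr(shrunk_covariance(rows, alpha,
                                     assume_zero_mean = assume_zero_mean))
  ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
  if (!ok) return(NULL)
  R
}

#' Internal nodes eligible as shift points
#'
#' All internal non-root nodes whose clade holds at least `min_size` tips,
#' in preorder (root-to-tip, left-to-right) order.  Restricting candidate
#' clades keeps the search fast and avoids estimating covariance matrices
#' from clades too small to determine them; a `min_size` at or below the
#' trait count triggers a warning because the clade covariance would then
#' be rank deficient before shrinkage.
#'
#' @param tree a rooted binary `phylo`.
#' @param min_size minimum clade tip count (>= 2).
#' @param k optional trait count used only for the small-clade warning.
#' @return integer vector of node ids (possibly empty).
#' @export
candidate_clades <- function(tree, min_size, k = NULL) {
  if (min_size < 2L) stop("min_size must be >= 2")
  if (!is.null(k) && min_size <= k)
    warning("min_size <= number of traits: clade covariance matrices will ",
            "be poorly determined")
  cnt <- .tip_counts(tree)
  root <- .root_node(tree)
  pre <- .preorder_nodes(tree)
  cand <- pre[pre > ape::Ntip(tree) & pre != root]
  cand[cnt[cand] >= min_size]
}

#' Evaluate a single candidate shift
#'
#' Fits the two-regime model for one candidate clade: the clade matrix is
#' estimated from the branches strictly inside the clade (the stem stays
#' with the background), the background matrix from all remaining branches,
#' and the combined log-likelihood and AIC are compared with the
#' single-regime base model.  `delta_aic > 0` means the shift improves fit.
#'
#' @param node internal node id (clade root).
#' @param D divergence matrix from [branch_divergences()].
#' @param tree the tree `D` was computed on.
#' @param alpha shrinkage coefficient.
#' @param background `"reestimate"` (default) re-fits the background matrix
#'   from the non-clade branches for each candidate; `"global"` reuses the
#'   base-model matrix.
#' @param base optional precomputed base model list (`loglik`, `aic`,
#'   `matrix`) to avoid re-fitting.
#' @param param_count passed to [aic_score()].
#' @param assume_zero_mean passed to [shrunk_covariance()].
#' @return list with `node`, `size` (clade tips), `clade_matrix`,
#'   `background_matrix`, `loglik`, `aic`, `delta_aic`; or `NULL` with a
#'   message when the clade matrix is singular.
#' @export
evaluate_candidate <- function(node, D, tree, alpha = 0.1,
                               background = c("reestimate", "global"),
                               base = NULL,
                               param_count = "correlation",
                               assume_zero_mean = FALSE) {
  background <- match.arg(background)
  k <- ncol(D)
  if (is.null(base)) base <- .base_model(D, alpha, k, param_count, assume_zero_mean)
  inside <- as.character(.descendants(tree, node))
  in_idx <- rownames(D) %in% inside
  R_in <- .regime_matrix(D[in_idx, , drop = FALSE], alpha, assume_zero_mean)
  if (is.null(R_in)) {
    message("candidate node ", node,
            " discarded: clade matrix singular or too few branches")
    return(NULL)
  }
  R_out <- if (background == "reestimate")
    .regime_matrix(D[!in_idx, , drop = FALSE], alpha, assume_zero_mean) else base$matrix
  if (is.null(R_out)) {
    message("candidate node ", node, " discarded: background matrix singular")
    return(NULL)
  }
  ll <- .mvn0_rows_loglik(D[in_idx, , drop = FALSE], R_in) +
    .mvn0_rows_loglik(D[!in_idx, , drop = FALSE], R_out)
  aic <- aic_score(ll, 2L, k, param_count)
  list(node = as.integer(node), size = .tip_counts(tree)[node],
       clade_matrix = R_in, background_matrix = R_out,
       loglik = ll, aic = aic, delta_aic = base$aic - aic)
}

.base_model <- function(D, alpha, k, param_count, assume_zero_mean = FALSE) {
  R0 <- .regime_matrix(D, alpha, assume_zero_mean)
  if (is.null(R0)) stop("base covariance matrix is singular; ",
                        "increase the shrinkage coefficient")
  ll <- .mvn0_rows_loglik(D, R0)
  list(matrix = R0, loglik = ll, aic = aic_score(ll, 1L, k, param_count))
}

# combined model for a given ordered set of shift nodes; shift regimes use
# the precomputed per-clade matrices, the root regime is re-estimated from
# (or, with background = "global", keeps) the base matrix
.combined_model <- function(tree, D, shift_nodes, clade_matrices, base,
                            alpha, background, param_count,
                            assume_zero_mean = FALSE) {
  k <- ncol(D)
  assignment <- regime_assignment(tree, shift_nodes)
  matrices <- c(list(`0` = base$matrix),
                stats::setNames(clade_matrices, seq_along(shift_nodes)))
  if (background == "reestimate") {
    rows0 <- D[assignment[rownames(D)] == 0L, , drop = FALSE]
    R0 <- .regime_matrix(rows0, alpha, assume_zero_mean)
    if (!is.null(R0)) matrices[["0"]] <- R0
  }
  ll <- tree_loglik(D, assignment, matrices)
  list(assignment = assignment, matrices = matrices, loglik = ll,
       aic = aic_score(ll, 1L + length(shift_nodes), k, param_count))
}

#' Greedy AIC search for covariation-regime shifts
#'
#' The automated shift search.  Every clade with at least `min_size` tips
#' is evaluated independently as a two-regime model against the
#' single-regime base model ([evaluate_candidate()]); candidates that
#' improve the AIC are ranked by their improvement, and the ranked list is
#' walked, retaining each shift that still lowers the AIC of the combined
#' model built from the previously retained shifts.  Ranking first means
#' that where several nested nodes mark the same signal, the best-placed
#' one is added first and the others are retained only if they add
#' explanatory power of their own.  After the walk, regimes left with fewer
#' than `k + 1` branches (possible once nested shifts carve up a clade) are
#' dissolved into their parent regime, and all matrices are re-estimated
#' once from the final branch assignment.
#'
#' The search is fully deterministic: ties in AIC improvement are broken by
#' larger clade, then preorder position.
#'
#' @param tree rooted binary `phylo`.
#' @param D divergence matrix from [branch_divergences()] on `tree`.
#' @param min_size minimum clade tip count; default `max(10, k + 1)` so
#'   clade size always exceeds the trait count.
#' @param alpha shrinkage coefficient (default 0.1).
#' @param min_delta_aic retention threshold: a shift must improve the AIC
#'   by more than this (default 0, i.e. any strict improvement).
#' @param background `"reestimate"` or `"global"`, see
#'   [evaluate_candidate()].
#' @param param_count passed to [aic_score()].
#' @param assume_zero_mean estimate regime covariances about zero instead
#'   of the sample mean (see [shrunk_covariance()]).
#' @return object of class `"regime_model"`: shift nodes (regime ids
#'   1..m in retention order; regime 0 is ancestral), per-branch
#'   `assignment`, per-regime correlation `matrices`, `loglik`, `aic`,
#'   `n_params`, the base-model fit, and the per-candidate table.
#' @export
greedy_search <- function(tree, D, min_size = NULL, alpha = 0.1,
                          min_delta_aic = 0,
                          background = c("reestimate", "global"),
                          param_count = "correlation",
                          assume_zero_mean = FALSE) {
  background <- match.arg(background)
  D <- as.matrix(D)
  k <- ncol(D)
  if (nrow(D) != 2L * ape::Ntip(tree) - 2L)
    stop("D must have one row per branch (2n - 2 rows)")
  if (is.null(min_size)) min_size <- max(10L, k + 1L)
  base <- .base_model(D, alpha, k, param_count, assume_zero_mean)

  cand_nodes <- candidate_clades(tree, min_size, k = k)
  cands <- list()
  for (nd in cand_nodes) {
    ev <- evaluate_candidate(nd, D, tree, alpha, background, base, param_count,
                             assume_zero_mean)
    if (!is.null(ev)) cands[[length(cands) + 1L]] <- ev
  }
  cand_table <- if (length(cands)) data.frame(
    node = vapply(cands, `[[`, integer(1), "node"),
    size = vapply(cands, function(x) as.integer(x$size), integer(1)),
    delta_aic = vapply(cands, `[[`, numeric(1), "delta_aic"),
    retained = FALSE
  ) else data.frame(node = integer(0), size = integer(0),
                    delta_aic = numeric(0), retained = logical(0))

  improving <- which(cand_table$delta_aic > min_delta_aic)
  pre_pos <- match(cand_table$node, .preorder_nodes(tree))
  ord <- improving[order(-cand_table$delta_aic[improving],
                         -cand_table$size[improving],
                         pre_pos[improving])]

  retained_idx <- integer(0)
  current_aic <- base$aic
  for (i in ord) {
    trial_idx <- c(retained_idx, i)
    trial <- .combined_model(tree, D,
                             cand_table$node[trial_idx],
                             lapply(cands[trial_idx], `[[`, "clade_matrix"),
                             base, alpha, background, param_count,
                             assume_zero_mean)
    if (trial$aic < current_aic - min_delta_aic) {
      retained_idx <- trial_idx
      current_aic <- trial$aic
    }
  }
  cand_table$retained[retained_idx] <- TRUE
  shift_nodes <- cand_table$node[retained_idx]

  # dissolve regimes carved below k + 1 branches by nested shifts
  repeat {
    if (!length(shift_nodes)) break
    assignment <- regime_assignment(tree, shift_nodes)
    counts <- table(factor(assignment, levels = 0:length(shift_nodes)))
    small <- which(counts[-1] < k + 1)
    if (!length(small)) break
    drop <- small[1]
    cand_table$retained[cand_table$node == shift_nodes[drop]] <- FALSE
    shift_nodes <- shift_nodes[-drop]
  }

  # final re-estimation from the final branch assignment
  assignment <- regime_assignment(tree, shift_nodes)
  matrices <- list()
  ok <- TRUE
  for (r in 0:length(shift_nodes)) {
    rows <- D[assignment[rownames(D)] == r, , drop = FALSE]
    M <- .regime_matrix(rows, alpha, assume_zero_mean)
    if (is.null(M)) { ok <- FALSE; break }
    matrices[[as.character(r)]] <- M
  }
  if (!ok || !length(shift_nodes)) {
    shift_nodes <- integer(0)
    assignment <- regime_assignment(tree, shift_nodes)
    matrices <- list(`0` = base$matrix)
  }
  ll <- tree_loglik(D, assignment, matrices)
  aic <- aic_score(ll, 1L + length(shift_nodes), k, param_count)
  if (length(shift_nodes) && aic > base$aic) {
    # retention guarantees improvement with the search matrices; if the
    # final re-estimation ever loses that, fall back to the base model
    shift_nodes <- integer(0)
    assignment <- regime_assignment(tree, shift_nodes)
    matrices <- list(`0` = base$matrix)
    ll <- base$loglik
    aic <- base$aic
  }

  structure(list(
    shift_nodes = shift_nodes,
    n_regimes = 1L + length(shift_nodes),
    assignment = assignment,
    matrices = matrices,
    loglik = ll,
    aic = aic,
    n_params = (1L + length(shift_nodes)) *
      if (param_count == "correlation") k * (k - 1) / 2 else k * (k + 1) / 2,
    base_loglik = base$loglik,
    base_aic = base$aic,
    candidates = cand_table,
    k = k,
    settings = list(min_size = min_size, alpha = alpha,
                    min_delta_aic = min_delta_aic, background = background,
                    param_count = param_count,
                    assume_zero_mean = assume_zero_mean)
  ), class = "regime_model")
}

#' Full shift analysis from tree and trait matrix
#'
#' Convenience wrapper running the whole chain: align traits to tips,
#' reconstruct ancestral states under Brownian motion, form branch
#' divergences, and run the greedy shift search.
#'
#' @param tree rooted binary `phylo`.
#' @param X species-by-trait matrix (log scale) with species rownames.
#' @param scale_by_time standardise divergences by the square root of
#'   branch length (see [branch_divergences()]).
#' @inheritParams greedy_search
#' @param ... further arguments to [greedy_search()].
#' @return a `regime_model` with the tree, trait names and divergence
#'   matrix attached.
#' @export
shift_search <- function(tree, X, min_size = NULL, alpha = 0.1,
                         scale_by_time = FALSE, ...) {
  states <- asr_bm(tree, X)
  D <- branch_divergences(tree, states, scale_by_time = scale_by_time)
  model <- greedy_search(tree, D, min_size = min_size, alpha = alpha, ...)
  model$tree <- tree
  model$trait_names <- colnames(X)
  model$divergences <- D
  model
}

#' @export
print.regime_model <- function(x, ...) {
  cat("Covariation regime model\n")
  cat(sprintf("  regimes: %d (shift nodes: %s)\n", x$n_regimes,
              if (length(x$shift_nodes))
                paste(x$shift_nodes, collapse = ", ") else "none"))
  cat(sprintf("  log-likelihood: %.4f   AIC: %.4f (base AIC: %.4f)\n",
              x$loglik, x$aic, x$base_aic))
  cat(sprintf("  free parameters: %d   traits: %d\n", x$n_params, x$k))
  for (id in names(x$matrices))
    cat(sprintf("  regime %s: %d branches, mean |r| = %.3f\n", id,
                sum(x$assignment == as.integer(id)),
                mean_abs_correlation(x$matrices[[id]])))
  invisible(x)
}

#' Write a machine-readable fit report
#'
#' JSON report with the final model summary (shift nodes, per-regime mean
#' absolute correlations and matrices, log-likelihood, AIC, parameter
#' count), the base model, the per-candidate AIC-improvement table, and the
#' search settings.
#'
#' @param model a `regime_model`.
#' @param file output path.
#' @export
write_fit_report <- function(model, file) {
  rep <- list(
    n_regimes = model$n_regimes,
    shift_nodes = model$shift_nodes,
    loglik = model$loglik,
    aic = model$aic,
    n_params = model$n_params,
    base = list(loglik = model$base_loglik, aic = model$base_aic),
    mean_abs_correlation = lapply(model$matrices, mean_abs_correlation),
    matrices = lapply(model$matrices, function(M) unname(as.matrix(M))),
    regime_branch_counts = as.list(table(model$assignment)),
    candidates = model$candidates,
    settings = model$settings
  )
  jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}
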