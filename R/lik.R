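# Multivariate-normal mixture likelihood over branches.
#
# Under Brownian motion the expected net change along any branch is zero,
# so each divergence vector x is modelled as k-variate normal with mean 0
# and covariance the regime's (correlation) matrix V; the tree likelihood
# is the product over the 2n - 2 branches.  All computation is in log space
# via Cholesky factors; a factorisation failure signals singularity rather
# than silently regularising.

.chol_or_stop <- function(V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch))
    stop("covariance matrix is singular or not positive definite; ",
         "consider a larger shrinkage coefficient")
  ch
}

# log-likelihood of a block of rows under one zero-mean MVN, via one Cholesky
.mvn0_rows_loglik <- function(rows, V) {
  rows <- as.matrix(rows)
  k <- ncol(rows)
  ch <- .chol_or_stop(V)
  logdet <- 2 * sum(log(diag(ch)))
  z <- backsolve(ch, t(rows), transpose = TRUE)   # V = R'R, quad = |R'^-1 x|^2
  quad <- colSums(z^2)
  sum(-(k / 2) * log(2 * pi) - logdet / 2 - quad / 2)
}

#' Log-likelihood of one branch divergence vector
#'
#' Log density of the zero-mean k-variate normal with covariance `V` at
#' `x`: `-(k/2) log(2 pi) - log(det V)/2 - x' V^{-1} x / 2`.
#'
#' @param x length-k divergence vector.
#' @param V positive-definite k-by-k (correlation) matrix.
#' @return scalar log-likelihood.
#' @examples
#' branch_loglik(0, matrix(1))       # -log(2*pi)/2
#' @export
branch_loglik <- function(x, V) {
  x <- as.numeric(x)
  V <- as.matrix(V)
  if (length(x) != ncol(V)) stop("length(x) must match dim(V)")
  .mvn0_rows_loglik(matrix(x, 1), V)
}

#' Log-likelihood of a divergence matrix under a set of regimes
#'
#' Sum over branches of [branch_loglik()] with each row evaluated under the
#' matrix of its assigned regime.
#'
#' @param D divergence matrix from [branch_divergences()] (rows named by
#'   child node id).
#' @param assignment integer vector of regime ids named by child node id,
#'   covering every row of `D` (see [regime_assignment()]).
#' @param matrices named list of regime matrices; names are regime ids as
#'   character.
#' @return scalar log-likelihood.
#' @export
tree_loglik <- function(D, assignment, matrices) {
  D <- as.matrix(D)
  ids <- rownames(D)
  if (is.null(ids)) stop("D must have branch (child node id) rownames")
  miss <- setdiff(ids, names(assignment))
  if (length(miss))
    stop("branches without a regime assignment: ", paste(miss, collapse = ", "))
  reg <- assignment[ids]
  total <- 0
  for (r in unique(reg)) {
    V <- matrices[[as.character(r)]]
    if (is.null(V)) stop("no matrix supplied for regime ", r)
    total <- total + .mvn0_rows_loglik(D[reg == r, , drop = FALSE], V)
  }
  total
}

#' Akaike information criterion for a regime model
#'
#' `AIC = 2 m - 2 loglik` with `m` free parameters.  Each regime's
#' correlation matrix contributes its `k(k-1)/2` free off-diagonal entries;
#' `param_count = "covariance"` instead counts `k(k+1)/2` per regime for
#' sensitivity analysis, and `small_sample = TRUE` applies the AICc
#' correction with `n_obs` observations.
#'
#' @param loglik model log-likelihood.
#' @param n_regimes number of regimes (>= 1).
#' @param k number of traits (>= 2).
#' @param param_count `"correlation"` (default) or `"covariance"`.
#' @param small_sample use AICc.
#' @param n_obs number of observations (branches), required for AICc.
#' @return scalar AIC.
#' @export
aic_score <- function(loglik, n_regimes, k,
                      param_count = c("correlation", "covariance"),
                      small_sample = FALSE, n_obs = NULL) {
  param_count <- match.arg(param_count)
  if (n_regimes < 1L) stop("n_regimes must be >= 1")
  if (k < 2L) stop("k must be >= 2")
  per <- if (param_count == "correlation") k * (k - 1) / 2 else k * (k + 1) / 2
  m <- n_regimes * per
  out <- 2 * m - 2 * loglik
  if (small_sample) {
    if (is.null(n_obs)) stop("n_obs required for the small-sample correction")
    if (n_obs - m - 1 <= 0)
      stop("too few observations for the small-sample correction")
    out <- out + 2 * m * (m + 1) / (n_obs - m - 1)
  }
  out
}
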