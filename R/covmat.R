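#' Shrinkage-regularised covariance of divergence rows
#'
#' Empirical covariance of the rows shrunk toward an isotropic target:
#' `(1 - alpha) * S + alpha * (tr(S)/k) * I`, where `S` is the
#' maximum-likelihood covariance (divisor = number of rows).  Shrinkage
#' tempers the erratically high and low covariances that small clades
#' produce, which would otherwise masquerade as structural shifts.
#'
#' By default `S` is taken about the sample mean of the rows; with
#' `assume_zero_mean = TRUE` raw second moments are used instead, matching
#' the Brownian-motion expectation that divergences have mean zero.
#'
#' @param rows numeric matrix, one divergence vector per row (at least 2).
#' @param alpha shrinkage coefficient in `[0, 1]`; the default 0.1 is a
#'   mild regularisation suited to clades only slightly larger than the
#'   trait count.
#' @param assume_zero_mean compute second moments about zero instead of the
#'   sample mean.
#' @return k-by-k symmetric matrix; positive definite whenever `alpha > 0`
#'   and the rows are not all zero.
#' @examples
#' shrunk_covariance(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), 0.3)
#' @export
shrunk_covariance <- function(rows, alpha = 0.1, assume_zero_mean = FALSE) {
  rows <- as.matrix(rows)
  if (nrow(rows) < 2L) stop("need at least 2 rows to estimate a covariance")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  N <- nrow(rows)
  k <- ncol(rows)
  centred <- if (assume_zero_mean) rows else
    sweep(rows, 2, colMeans(rows), "-")
  S <- crossprod(centred) / N
  out <- (1 - alpha) * S + alpha * (sum(diag(S)) / k) * diag(k)
  if (!is.null(colnames(rows)))
    dimnames(out) <- list(colnames(rows), colnames(rows))
  out
}

#' Rescale a covariance matrix to a correlation matrix
#'
#' @param M symmetric matrix with strictly positive diagonal.
#' @return matrix with unit diagonal and entries `m_ij / sqrt(m_ii m_jj)`.
#' @export
cov_to_corr <- function(M) {
  M <- as.matrix(M)
  d <- diag(M)
  if (any(d <= 0)) stop("nonpositive diagonal entry: cannot rescale")
  R <- M / sqrt(outer(d, d))
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Mean absolute off-diagonal correlation
#'
#' Overall integration strength of a regime: the mean of `|r_ij|` over the
#' `k(k-1)/2` upper-triangle entries.  The unit diagonal is excluded.
#'
#' @param R a correlation matrix, `k >= 2`.
#' @return scalar in `[0, 1]`.
#' @export
mean_abs_correlation <- function(R) {
  R <- as.matrix(R)
  if (ncol(R) < 2L) stop("need at least 2 traits")
  mean(abs(R[upper.tri(R)]))
}

#' Write trait-labelled regime matrices to CSV
#'
#' Stacks the per-regime correlation matrices into one long table with
#' columns `regime,trait,<trait columns>`.
#'
#' @param matrices named list of k-by-k matrices (names = regime ids).
#' @param file output path.
#' @param trait_names optional column labels when matrices are unnamed.
#' @export
write_matrices_csv <- function(matrices, file, trait_names = NULL) {
  rows <- lapply(names(matrices), function(id) {
    M <- matrices[[id]]
    tn <- colnames(M)
    if (is.null(tn)) tn <- trait_names
    if (is.null(tn)) tn <- paste0("trait", seq_len(ncol(M)))
    data.frame(regime = id, trait = tn, M, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
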