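## Deterministic matrix kernels shared by all models.

#' VanRaden-style genomic relationship matrix
#'
#' Computes the genomic relationship matrix G = W W' / p from a J x p marker
#' dosage matrix W, where p is the number of markers. No centering or
#' scaling of W is performed here; apply any centering before calling if
#' desired. The result is symmetric and positive semi-definite for any real
#' W (and typically rank-deficient when J > p).
#'
#' @param W numeric matrix of marker dosages, lines in rows (rownames used
#'   as line identifiers), markers in columns. Must contain no missing
#'   values; run \code{\link{filterMarkers}} first.
#' @return J x J numeric matrix with line identifiers as dimnames.
#' @examples
#' W <- matrix(c(1, 0, 2, 0, 1, 1, 2, 2, 0), 3, 3, byrow = TRUE,
#'             dimnames = list(c("L1", "L2", "L3"), NULL))
#' grmVanRaden(W)
#' @export
grmVanRaden <- function(W) {
  if (!is.matrix(W) || !is.numeric(W)) stopData("W must be a numeric matrix")
  p <- ncol(W)
  if (p < 1L) stopData("W must contain at least one marker (p >= 1)")
  if (anyNA(W)) {
    idx <- which(is.na(W), arr.ind = TRUE)[1L, ]
    ln <- if (!is.null(rownames(W))) rownames(W)[idx[1L]] else idx[1L]
    mk <- if (!is.null(colnames(W))) colnames(W)[idx[2L]] else idx[2L]
    stopData("W contains missing entries (first at line ", ln, ", marker ",
             mk, "); apply marker QC/imputation first")
  }
  G <- tcrossprod(W) / p
  G <- (G + t(G)) / 2
  ids <- rownames(W)
  if (!is.null(ids)) dimnames(G) <- list(ids, ids)
  G
}

#' Positive-semidefinite-safe Cholesky factor
#'
#' Returns a lower-triangular L with L L' equal to M when M is positive
#' definite (standard Cholesky, non-negative diagonal), and otherwise equal
#' to a spectrally clipped copy of M: eigenvalues below
#' eps = 1e-10 * (largest eigenvalue) are raised to eps before
#' reconstruction and factorization. This makes the factorization
#' well-defined for rank-deficient genomic relationship matrices (e.g. built
#' from fewer markers than lines). The clipping threshold is deterministic;
#' no random jitter is added.
#'
#' @param M square symmetric numeric matrix (symmetry checked to a relative
#'   tolerance of 1e-8).
#' @return lower-triangular matrix of the same dimension as \code{M}.
#' @export
safeCholesky <- function(M) {
  M <- checkSymmetric(M, what = "cholesky input")
  dn <- dimnames(M)
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) {
    ee <- eigen(M, symmetric = TRUE)
    lmax <- max(ee$values, 0)
    if (lmax <= 0) {
      ## zero / negative-semidefinite input clips to the zero matrix
      L <- matrix(0, nrow(M), ncol(M))
      dimnames(L) <- dn
      return(L)
    }
    lam <- pmax(ee$values, 1e-10 * lmax)
    Mc <- ee$vectors %*% (lam * t(ee$vectors))
    Mc <- (Mc + t(Mc)) / 2
    R <- chol(Mc)
  }
  L <- t(R)
  dimnames(L) <- dn
  L
}

#' Convert a covariance matrix to a correlation matrix
#'
#' Thin validating wrapper around \code{stats::cov2cor}:
#' R[i,j] = S[i,j] / sqrt(S[i,i] S[j,j]). The result has a unit diagonal and
#' is exactly symmetric.
#'
#' @param S square covariance matrix with strictly positive diagonal.
#' @return correlation matrix of the same dimension.
#' @export
covToCor <- function(S) {
  S <- checkSymmetric(S, what = "covariance matrix")
  d <- diag(S)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    nm <- if (!is.null(rownames(S))) rownames(S)[i] else i
    stopData("covariance diagonal must be strictly positive (trait ", nm, ")")
  }
  R <- stats::cov2cor(S)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R
}

## Kronecker product (env-major block layout); base kronecker does the work.
kronProd <- function(A, B) kronecker(A, B)
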