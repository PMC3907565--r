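#' Amari distance between two mixing matrices
#'
#' Permutation- and scale-invariant discrepancy between a true mixing
#' matrix and an estimate, computed from `P = pinv(A_est) A_true`:
#' \deqn{d = \frac{1}{2L(L-1)} \left[ \sum_i \left(\sum_j \frac{|P_{ij}|}{\max_k |P_{ik}|} - 1\right) + \sum_j \left(\sum_i \frac{|P_{ij}|}{\max_k |P_{kj}|} - 1\right) \right]}
#' which is 0 iff `P` is a scaled permutation and at most 1.
#'
#' @param A_true,A_est D x L matrices with the same column count.
#' @return A number in \[0, 1\].
#' @export
amari_distance <- function(A_true, A_est) {
  stopifnot(ncol(A_true) == ncol(A_est), nrow(A_true) == nrow(A_est))
  L <- ncol(A_true)
  if (L == 1L) return(0)
  P <- abs(MASS_ginv(A_est) %*% A_true)
  rowpart <- sum(rowSums(P / apply(P, 1L, max)) - 1)
  colpart <- sum(colSums(sweep(P, 2L, apply(P, 2L, max), "/")) - 1)
  (rowpart + colpart) / (2 * L * (L - 1))
}

## Moore-Penrose pseudoinverse via SVD (avoids a MASS dependency for one
## call site)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  keep <- s$d > tol * s$d[1L]
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Principal angles between two subspaces
#'
#' @param U,V Matrices whose columns span the subspaces (need not be
#'   orthonormal).
#' @return Angles in degrees, increasing; length `min(ncol(U), ncol(V))`.
#' @export
principal_angles <- function(U, V) {
  qu <- qr.Q(qr(U))
  qv <- qr.Q(qr(V))
  sv <- svd(crossprod(qu, qv))$d
  sort(acos(pmin(pmax(sv, -1), 1)) * 180 / pi)
}
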