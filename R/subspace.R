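#' Linear temporal subspace baseline
#'
#' Estimates a rank-`r` temporal basis (the top right singular vectors of the
#' training block), the classical linear-subspace model that the
#' deep-learning reconstruction is compared against.
#'
#' @param S_train training transient block (rows x time).
#' @param r subspace rank (default 32; must satisfy
#'   `r <= min(nrow, ncol)`).
#' @return Object of class `subspace_basis`: list with `basis` (r x N_T,
#'   orthonormal rows), `singular_values` and `rank`.
#' @export
fit_subspace <- function(S_train, r = 32) {
  S_train <- .check_block(S_train)
  if (r <= 0) stop("`r` must be positive", call. = FALSE)
  if (r > min(dim(S_train)))
    stop("`r` exceeds min(n_rows, n_time)", call. = FALSE)
  sv <- svd(S_train, nu = 0, nv = r)
  structure(list(basis = t(sv$v[, seq_len(r), drop = FALSE]),
                 singular_values = sv$d[seq_len(r)], rank = r),
            class = "subspace_basis")
}

#' @export
print.subspace_basis <- function(x, ...) {
  cat(sprintf("Temporal subspace basis: rank %d, %d time points\n",
              x$rank, ncol(x$basis)))
  invisible(x)
}

#' Subspace reconstruction from short transients
#'
#' Fits, for every row, the least-squares coefficients of the basis
#' restricted to the first `N_T'` time samples, then expands the
#' coefficients over the full-length basis. When `N_T' < r` the system is
#' underdetermined; the minimum-norm solution is returned with a warning.
#'
#' @param S_short short transient block (`N_T'` columns).
#' @param basis a [fit_subspace()] result.
#' @return Reconstructed block, rows x full length.
#' @export
subspace_reconstruct <- function(S_short, basis) {
  stopifnot(inherits(basis, "subspace_basis"))
  S_short <- .check_block(S_short)
  ntp <- ncol(S_short); r <- basis$rank
  if (ntp > ncol(basis$basis))
    stop("short block longer than the basis", call. = FALSE)
  Bs <- basis$basis[, seq_len(ntp), drop = FALSE]    # r x N_T'
  if (ntp < r) {
    warning("underdetermined fit (N_T' < rank); returning minimum-norm solution")
    coef <- S_short %*% .pinv(Bs)
  } else {
    coef <- t(solve(tcrossprod(Bs), Bs %*% t(S_short)))
  }
  coef %*% basis$basis
}

# Moore-Penrose pseudoinverse of the (r x m) restricted basis, returning the
# m x r right-pseudoinverse so that coef = S_short %*% pinv.
.pinv <- function(A, tol = 1e-12) {
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * tol
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}
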