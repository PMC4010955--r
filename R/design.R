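#' Moore-Penrose pseudo-inverse
#'
#' Computes the pseudo-inverse of a matrix by singular value decomposition.
#' Singular values below \code{max(dim(A)) * eps * sigma_max} are treated as
#' zero, so the result is well defined for rank-deficient and zero-width
#' matrices.
#'
#' @param A Numeric matrix (may have zero columns).
#' @return The pseudo-inverse of \code{A}, a \code{ncol(A) x nrow(A)} matrix.
#' @export
pseudoinverse <- function(A) {
  A <- as.matrix(A)
  if (ncol(A) == 0L) return(matrix(0, 0L, nrow(A)))
  if (!all(is.finite(A))) stop("matrix contains non-finite entries")
  s <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

matrix_rank <- function(A, tol = NULL) {
  A <- as.matrix(A)
  if (ncol(A) == 0L || nrow(A) == 0L) return(0L)
  d <- svd(A, nu = 0L, nv = 0L)$d
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(d, 0)
  sum(d > tol)
}

#' Validate a design matrix
#'
#' Checks that the design is a finite, full column rank matrix with more
#' observations than regressors, and returns it with attributes \code{N}
#' (observations) and \code{r} (regressors).
#'
#' @param M Numeric matrix, \code{N x r}.
#' @return The validated design matrix.
#' @export
design_matrix <- function(M) {
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  if (!all(is.finite(M))) stop("design matrix contains non-finite entries")
  N <- nrow(M); r <- ncol(M)
  if (N <= r) stop("design must have more observations than regressors (N > r)")
  if (matrix_rank(M) < r) stop("design matrix is rank deficient")
  structure(M, N = N, r = r)
}

#' Validate a contrast matrix
#'
#' A contrast is an \code{r x s} full column rank matrix, \code{1 <= s <= r};
#' the null hypothesis tested is \code{C' psi = 0}. A vector is treated as a
#' single (rank-1) contrast.
#'
#' @param C Numeric matrix \code{r x s} or length-\code{r} vector.
#' @param r Number of regressors in the design the contrast applies to.
#' @return The validated contrast matrix.
#' @export
contrast_matrix <- function(C, r) {
  if (is.vector(C)) C <- matrix(C, ncol = 1L)
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  if (!all(is.finite(C))) stop("contrast contains non-finite entries")
  if (nrow(C) != r) stop("contrast has ", nrow(C), " rows but design has ", r, " regressors")
  s <- ncol(C)
  if (s < 1L || s > r) stop("contrast rank must satisfy 1 <= s <= r")
  if (matrix_rank(C) < s) stop("contrast matrix is rank deficient")
  C
}

#' Hat and residual-forming matrices
#'
#' For a matrix \code{A} with \code{N} rows, returns the projection ("hat")
#' matrix \code{H = A A^+} and the residual-forming matrix \code{R = I - H}.
#' A zero-width \code{A} gives \code{H = 0} and \code{R = I}.
#'
#' @param A Numeric matrix with \code{N} rows (possibly zero columns).
#' @return List with elements \code{H} and \code{R}, both \code{N x N}.
#' @export
residual_forming <- function(A) {
  A <- as.matrix(A)
  N <- nrow(A)
  if (ncol(A) > 0L && !all(is.finite(A))) stop("matrix contains non-finite entries")
  if (ncol(A) == 0L) {
    H <- matrix(0, N, N)
  } else {
    H <- A %*% pseudoinverse(A)
    H <- (H + t(H)) / 2 # enforce exact symmetry
  }
  list(H = H, R = diag(N) - H)
}

#' Partition a design matrix by a contrast
#'
#' Splits the full design \code{M} into regressors of interest \code{X}
#' (\code{s} columns) and nuisance regressors \code{Z} (\code{r - s} columns)
#' for the contrast \code{C}, such that testing \code{beta = 0} in
#' \code{Y = X beta + Z gamma + e} is equivalent to testing
#' \code{C' psi = 0} in \code{Y = M psi + e}: the F statistic of the
#' partitioned model equals the F statistic of the contrast on the
#' unpartitioned model, for any data vector.
#'
#' Two schemes are available. The default \code{"contrast"} scheme builds
#' \code{X = M D C (C' D C)^-1} with \code{D = (M'M)^-1} and a nuisance basis
#' adjusted so that \code{X} and \code{Z} are orthogonal; it works for any
#' full-rank contrast. The \code{"selection"} scheme is available when each
#' contrast column selects a single regressor (rows of \code{C} are 0/1 with
#' one 1 per column): \code{X} is then the selected columns of \code{M}
#' untouched and \code{Z} the remaining ones, i.e. the model is kept
#' unpartitioned in the usual sense.
#'
#' @param M Design matrix (\code{N x r}), full rank.
#' @param C Contrast (\code{r x s}), full rank.
#' @param scheme Partitioning scheme, \code{"contrast"} or \code{"selection"}.
#' @return An object of class \code{"partitioned_model"}: a list with
#'   \code{X}, \code{Z}, the hat/residual-forming matrices \code{H_M},
#'   \code{R_M}, \code{H_Z}, \code{R_Z}, and bookkeeping fields \code{N},
#'   \code{r}, \code{s}.
#' @export
partition_model <- function(M, C, scheme = c("contrast", "selection")) {
  scheme <- match.arg(scheme)
  M <- design_matrix(M)
  r <- ncol(M)
  C <- contrast_matrix(C, r)
  s <- ncol(C)
  if (scheme == "selection") {
    sel <- apply(C != 0, 2L, which)
    ok <- colSums(C != 0) == 1L && all(C[cbind(unlist(sel), seq_len(s))] == 1)
    if (!isTRUE(ok))
      stop("selection scheme requires a contrast whose columns each select one regressor")
    idx <- unlist(sel)
    X <- M[, idx, drop = FALSE]
    Z <- M[, setdiff(seq_len(r), idx), drop = FALSE]
  } else {
    D <- solve(crossprod(M))
    CDCi <- solve(t(C) %*% D %*% C)
    X <- M %*% D %*% C %*% CDCi
    if (s == r) {
      Z <- matrix(0, nrow(M), 0L)
    } else {
      # orthonormal basis of the null space of C', then adjusted so that
      # the spans of X and Z are orthogonal under the (M'M)^-1 metric
      Cu <- qr.Q(qr(diag(r) - C %*% pseudoinverse(C)))[, seq_len(r - s), drop = FALSE]
      Cv <- Cu - C %*% CDCi %*% (t(C) %*% D %*% Cu)
      Z <- M %*% D %*% Cv %*% solve(t(Cv) %*% D %*% Cv)
    }
  }
  fz <- residual_forming(Z)
  fm <- residual_forming(cbind(X, Z))
  structure(list(X = X, Z = Z,
                 H_M = fm$H, R_M = fm$R, H_Z = fz$H, R_Z = fz$R,
                 N = nrow(M), r = r, s = s, scheme = scheme),
            class = "partitioned_model")
}

#' Fit a general linear model by least squares
#'
#' Fits \code{Y = M psi + e} column-wise by the pseudo-inverse,
#' \code{psi_hat = M^+ Y}, with residuals \code{R_M Y}.
#'
#' @param Y Data, an \code{N x V} matrix (or a vector, treated as one column).
#' @param M Design matrix.
#' @return List with \code{psi_hat} (\code{r x V}), \code{residuals}
#'   (\code{N x V}), \code{rank_M}, and \code{dof} (\code{N - rank_M}).
#' @export
fit_glm <- function(Y, M) {
  Y <- as.matrix(Y)
  M <- design_matrix(M)
  if (!all(is.finite(Y))) stop("data contain non-finite values")
  if (nrow(Y) != nrow(M))
    stop("data have ", nrow(Y), " rows but design has ", nrow(M))
  Mp <- pseudoinverse(M)
  psi <- Mp %*% Y
  res <- Y - M %*% psi
  rk <- matrix_rank(M)
  list(psi_hat = psi, residuals = res, rank_M = rk, dof = nrow(M) - rk)
}
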