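#' Variance groups
#'
#' A variance group (VG) is a set of observations assumed to share the same
#' error variance. The group variances are pooled within group to build the
#' diagonal weighting matrix of the heteroscedasticity-robust statistic
#' \code{\link{compute_G}}. With a single VG covering all observations the
#' weights are constant and \code{G} reduces to the usual \code{F}.
#'
#' @param g Vector of group labels, one per observation (integer, factor or
#'   character).
#' @return Object of class \code{"variance_groups"}: list with integer
#'   \code{id} (1-based group index per observation), \code{levels},
#'   \code{k} (number of groups) and \code{sizes}.
#' @export
variance_groups <- function(g) {
  if (anyNA(g)) stop("variance group labels contain NA")
  f <- factor(g, levels = unique(g))
  id <- as.integer(f)
  sizes <- tabulate(id)
  if (any(sizes == 1L))
    warning("variance group(s) of size 1: the group variance is estimated from a single residual")
  structure(list(id = id, levels = levels(f), k = nlevels(f), sizes = sizes),
            class = "variance_groups")
}

as_variance_groups <- function(vg, N) {
  if (is.null(vg)) vg <- rep(1L, N)
  if (!inherits(vg, "variance_groups")) vg <- variance_groups(vg)
  if (length(vg$id) != N) stop("variance group vector has wrong length")
  vg
}

#' F statistic for a contrast
#'
#' Computes \code{F = [psi' C (C'(M'M)^-1 C)^-1 C' psi / s] /
#' [e'e / (N - rank(M))]} from a fitted model. A zero residual sum of squares
#' with a nonzero numerator yields \code{+Inf} with a warning; such values are
#' ranked as the largest during p-value counting.
#'
#' @param psi_hat Coefficients, \code{r x V} (from \code{\link{fit_glm}}).
#' @param M Design matrix.
#' @param C Contrast matrix \code{r x s}.
#' @param residuals Residual matrix \code{N x V}.
#' @param rank_M Rank of \code{M} (defaults to \code{ncol(M)}).
#' @return Numeric vector of \code{V} F values.
#' @export
compute_F <- function(psi_hat, M, C, residuals, rank_M = ncol(M)) {
  M <- as.matrix(M)
  psi_hat <- as.matrix(psi_hat)
  residuals <- as.matrix(residuals)
  C <- contrast_matrix(C, nrow(psi_hat))
  s <- ncol(C)
  dof <- nrow(M) - rank_M
  if (dof <= 0) stop("zero residual degrees of freedom")
  B <- solve(t(C) %*% solve(crossprod(M)) %*% C)
  q <- crossprod(C, psi_hat) # s x V
  num <- colSums((chol(B) %*% q)^2) / s
  den <- colSums(residuals^2) / dof
  f <- num / den
  bad <- num > 0 & den < num * 1e-12 # residual variance zero to working precision
  if (any(bad)) {
    warning("zero residual variance with nonzero effect: statistic set to +Inf")
    f[bad] <- Inf
  }
  f[den == 0 & num == 0] <- 0
  f
}

#' t statistic from F for a rank-1 contrast
#'
#' For a single contrast (\code{s = 1}) the signed square root of \code{F}
#' is Student's t: \code{t = sign(beta_hat) * sqrt(F)}. Applied to \code{G}
#' instead of \code{F} with more than one variance group the same relation
#' yields the Aspin-Welch \code{v}.
#'
#' @param F_value Numeric vector of F (or G) values.
#' @param beta_hat Estimated contrast effect(s), same length.
#' @return Numeric vector of signed statistics.
#' @export
compute_t <- function(F_value, beta_hat) {
  if (length(F_value) != length(beta_hat))
    stop("F values and effect estimates have different lengths")
  sign(beta_hat) * sqrt(F_value)
}

#' Per-observation weights from variance groups
#'
#' Builds the diagonal of the weighting matrix \code{W} used by
#' \code{\link{compute_G}}: for observation \code{n} in variance group
#' \code{g}, \code{W_nn = sum of R_M diagonal over g / residual sum of
#' squares of g}, i.e. the reciprocal of the estimated group variance
#' (group effective degrees of freedom over group RSS).
#'
#' @param residuals Residual vector (single test).
#' @param vg Variance groups (see \code{\link{variance_groups}}).
#' @param R_M_diag Diagonal of the residual-forming matrix of the model.
#' @return List with \code{W_diag} (length N) and \code{trace_W}.
#' @export
compute_weights <- function(residuals, vg, R_M_diag) {
  residuals <- as.numeric(residuals)
  vg <- as_variance_groups(vg, length(residuals))
  if (length(R_M_diag) != length(residuals))
    stop("R_M_diag has wrong length")
  rssg <- as.numeric(rowsum(residuals^2, vg$id))
  dfg <- as.numeric(rowsum(R_M_diag, vg$id))
  if (any(rssg == 0))
    stop("variance group(s) with zero residual sum of squares: ",
         paste(vg$levels[rssg == 0], collapse = ", "))
  wg <- dfg / rssg
  W <- wg[vg$id]
  list(W_diag = W, trace_W = sum(W), group_weights = wg, group_dof = dfg)
}

#' Welch-type correction factor
#'
#' Computes \code{Lambda = 1 + (2(s-1)/(s(s+2))) * sum_g (1/df_g) *
#' (1 - sum_{n in g} W_nn / trace(W))^2}. It equals 1 when there is a single
#' variance group or when \code{s = 1}.
#'
#' @param W Weights as returned by \code{\link{compute_weights}}.
#' @param vg Variance groups.
#' @param R_M_diag Diagonal of the residual-forming matrix.
#' @param s Contrast rank.
#' @return Scalar \code{Lambda >= 1}.
#' @export
compute_lambda <- function(W, vg, R_M_diag, s) {
  vg <- as_variance_groups(vg, length(W$W_diag))
  dfg <- as.numeric(rowsum(R_M_diag, vg$id))
  sumWg <- as.numeric(rowsum(W$W_diag, vg$id))
  1 + 2 * (s - 1) / (s * (s + 2)) *
    sum((1 / dfg) * (1 - sumWg / W$trace_W)^2)
}

#' Heteroscedasticity-robust generalised statistic
#'
#' Computes \code{G = psi' C (C'(M'WM)^-1 C)^-1 C' psi / (Lambda * s)}, a
#' generalisation of the F statistic in which the residual variance is
#' estimated separately within each variance group (diagonal weighting
#' matrix \code{W}) and a Welch-type correction \code{Lambda} is applied.
#' With one variance group \code{G = F} exactly; with two or more groups and
#' a rank-1 contrast, \code{sign(beta_hat) * sqrt(G)} is the Aspin-Welch
#' \code{v} statistic for the Behrens-Fisher problem; for group-mean designs
#' with more groups it equals Welch's \code{v^2} (the Welch ANOVA statistic).
#'
#' This is the single-test reference implementation; the permutation engine
#' uses an equivalent compiled path vectorised over tests.
#'
#' @param psi_hat Coefficient vector (length r).
#' @param M Design matrix.
#' @param C Contrast matrix \code{r x s}.
#' @param W Weights from \code{\link{compute_weights}}.
#' @param lambda Correction factor from \code{\link{compute_lambda}}.
#' @return Scalar G value.
#' @export
compute_G <- function(psi_hat, M, C, W, lambda) {
  M <- as.matrix(M)
  psi_hat <- as.numeric(psi_hat)
  C <- contrast_matrix(C, length(psi_hat))
  s <- ncol(C)
  MtWM <- crossprod(M, W$W_diag * M)
  K <- tryCatch(solve(MtWM), error = function(e) stop("singular M'WM"))
  q <- crossprod(C, psi_hat)
  num <- as.numeric(t(q) %*% solve(t(C) %*% K %*% C, q))
  num / (lambda * s)
}

# Vectorised statistic evaluation used by the permutation engine.
#
# D       : design matrix actually fitted (N x p)
# Cp      : contrast in the fitted design's coefficient space (p x s)
# psi     : p x V coefficients, res : N x V residuals
# vg      : variance_groups or NULL (NULL/single group -> F/t path)
# kind    : "F", "t", "G", "v"
# dof     : residual degrees of freedom to use for F/t
# Rdiag   : diagonal of the residual-forming matrix of D (for G weights)
# Returns numeric V-vector.
stat_columns <- function(D, Cp, psi, res, vg, kind, dof, Rdiag = NULL,
                         precomp = NULL) {
  s <- ncol(Cp)
  q <- crossprod(Cp, psi) # s x V
  if (kind %in% c("F", "t")) {
    B <- if (!is.null(precomp$cholB)) precomp$cholB else
      chol(solve(t(Cp) %*% solve(crossprod(D)) %*% Cp))
    num <- colSums((B %*% q)^2) / s
    den <- colSums(res^2) / dof
    f <- num / den
    f[num > 0 & den < num * 1e-12] <- Inf
    f[den == 0 & num == 0] <- 0
    if (kind == "t") sign(q[1L, ]) * sqrt(f) else f
  } else {
    if (is.null(Rdiag)) Rdiag <- 1 - rowSums(D * t(pseudoinverse(D)))
    id <- vg$id
    dfg <- if (!is.null(precomp$dfg)) precomp$dfg else
      as.numeric(rowsum(Rdiag, id))
    ng <- vg$sizes
    rssg <- rowsum_sq(res, id, vg$k)
    Astack <- if (!is.null(precomp$Astack)) precomp$Astack else
      vg_crossprods(D, id, vg$k)
    g <- as.numeric(gstat_columns(q, rssg, dfg, ng, Astack, Cp))
    if (kind == "v") sign(q[1L, ]) * sqrt(g) else g
  }
}

# k x V matrix of per-group residual sums of squares
rowsum_sq <- function(res, id, k) {
  out <- rowsum(res * res, id)
  if (nrow(out) != k) stop("empty variance group")
  out
}

# r x r x k array of per-group design cross-products
vg_crossprods <- function(D, id, k) {
  r <- ncol(D)
  A <- array(0, c(r, r, k))
  for (g in seq_len(k)) A[, , g] <- crossprod(D[id == g, , drop = FALSE])
  A
}
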