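STRATEGIES <- c("draper_stoneman", "still_white", "freedman_lane", "manly",
                "ter_braak", "kennedy", "huh_jhun", "smith", "parametric")

# short aliases accepted on the command line and in strategy arguments
normalize_method <- function(method) {
  alias <- c(ds = "draper_stoneman", sw = "still_white", fl = "freedman_lane",
             tb = "ter_braak", hj = "huh_jhun", param = "parametric",
             k = "kennedy", m = "manly", s = "smith")
  m <- tolower(method)
  if (m %in% names(alias)) m <- alias[[m]]
  match.arg(m, STRATEGIES)
}

# deterministic orthonormal basis of the column space of R_Z:
# eigenvectors with eigenvalue ~1, sign fixed so the largest-magnitude
# entry of each column is positive
hj_basis <- function(R_Z, rank_Z) {
  N <- nrow(R_Z)
  e <- eigen(R_Z, symmetric = TRUE)
  Q <- e$vectors[, seq_len(N - rank_Z), drop = FALSE]
  for (j in seq_len(ncol(Q))) {
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) Q[, j] <- -Q[, j]
  }
  Q
}

#' Transform a regression problem for one shuffling under a given strategy
#'
#' Returns the shuffled regression problem for the nine nuisance-handling
#' strategies. Writing \code{B} for the shuffling (sign flips followed by
#' permutation), \code{R_Z}, \code{H_Z}, \code{R_M}, \code{H_M} for the
#' residual-forming/hat matrices of the nuisance and full models:
#' Draper-Stoneman fits \code{Y} on \code{[BX, Z]}; Still-White fits
#' \code{B R_Z Y} on \code{X} alone; Freedman-Lane fits
#' \code{(B R_Z + H_Z) Y} on \code{[X, Z]}; Manly fits \code{BY} on
#' \code{[X, Z]}; ter Braak fits \code{(B R_M + H_M) Y} on \code{[X, Z]};
#' Kennedy fits \code{B R_Z Y} on \code{R_Z X}; Huh-Jhun fits
#' \code{B~ Q' R_Z Y} on \code{Q' R_Z X} in the reduced space of dimension
#' \code{N - rank(Z)} (no exchangeability blocks allowed); Smith fits
#' \code{Y} on \code{[B R_Z X, Z]}; parametric performs no shuffling.
#'
#' @param method Strategy name (or alias such as \code{"fl"}).
#' @param sh Shuffling (list with \code{perm}, \code{signs}); for Huh-Jhun
#'   its length must equal the reduced dimension.
#' @param Y Data matrix \code{N x V}.
#' @param part Partitioned model from \code{\link{partition_model}}.
#' @return List with \code{Y}, \code{X}, \code{Z} of the transformed problem
#'   and \code{dof} (residual degrees of freedom for the statistic).
#' @export
transform_model <- function(method, sh, Y, part) {
  method <- normalize_method(method)
  Y <- as.matrix(Y)
  X <- part$X; Z <- part$Z
  N <- part$N
  rank_Z <- matrix_rank(Z)
  rank_M <- matrix_rank(cbind(X, Z))
  dof_full <- N - rank_M
  switch(method,
    draper_stoneman = list(Y = Y, X = apply_shuffling(sh, X), Z = Z, dof = dof_full),
    still_white = list(Y = apply_shuffling(sh, part$R_Z %*% Y),
                       X = X, Z = matrix(0, N, 0L), dof = N - matrix_rank(X)),
    freedman_lane = list(Y = apply_shuffling(sh, part$R_Z %*% Y) + part$H_Z %*% Y,
                         X = X, Z = Z, dof = dof_full),
    manly = list(Y = apply_shuffling(sh, Y), X = X, Z = Z, dof = dof_full),
    ter_braak = list(Y = apply_shuffling(sh, part$R_M %*% Y) + part$H_M %*% Y,
                     X = X, Z = Z, dof = dof_full),
    kennedy = list(Y = apply_shuffling(sh, part$R_Z %*% Y),
                   X = part$R_Z %*% X, Z = matrix(0, N, 0L), dof = dof_full),
    huh_jhun = {
      Q <- hj_basis(part$R_Z, rank_Z)
      Yt <- crossprod(Q, part$R_Z %*% Y)
      Xt <- crossprod(Q, part$R_Z %*% X)
      if (length(sh$perm) != nrow(Yt))
        stop("Huh-Jhun shufflings must act in the reduced space of dimension N - rank(Z)")
      list(Y = apply_shuffling(sh, Yt), X = Xt, Z = matrix(0, nrow(Yt), 0L),
           dof = nrow(Yt) - part$s)
    },
    smith = list(Y = Y, X = apply_shuffling(sh, part$R_Z %*% X), Z = Z, dof = dof_full),
    parametric = list(Y = Y, X = X, Z = Z, dof = dof_full))
}

round_stat <- function(x) {
  out <- signif(x, 12L)
  out[!is.finite(x)] <- x[!is.finite(x)]
  out
}

#' Run a permutation test over simultaneous tests
#'
#' Computes the observed statistic \code{T0} for every column of \code{Y}
#' and, for each shuffling in \code{shuffles}, the statistic of the
#' transformed model under \code{method}, accumulating the counts
#' \code{T* >= T0} per test and the per-shuffle maximum across tests.
#' Shuffling-constant matrices (e.g. the nuisance residual projection of the
#' data) are formed once and reused across the \code{V} columns.
#'
#' @param Y Data matrix \code{N x V} (each column one test).
#' @param M Design matrix \code{N x r}.
#' @param C Contrast \code{r x s}.
#' @param blocks Exchangeability blocks or \code{NULL}. Huh-Jhun cannot be
#'   combined with blocks.
#' @param vg Variance groups or \code{NULL}. When supplied (more than one
#'   group), the default statistic is the robust \code{G}/\code{v}.
#' @param method Nuisance-handling strategy (default Freedman-Lane).
#' @param stat \code{"auto"}, \code{"F"}, \code{"t"}, \code{"G"} or
#'   \code{"v"}. \code{"auto"} picks \code{t}/\code{v} for rank-1 contrasts
#'   and \code{F}/\code{G} otherwise, robust variants when more than one
#'   variance group is present.
#' @param shuffles Shuffling set from \code{\link{enumerate_shufflings}}
#'   (identity first). For \code{method = "parametric"} it is ignored.
#' @param scheme Partitioning scheme passed to \code{\link{partition_model}}.
#' @param keep_null Retain the full \code{J x V} matrix of shuffled
#'   statistics (memory permitting) in the result.
#' @param sw_full_dof Use full-model residual degrees of freedom for
#'   Still-White instead of the X-only default.
#' @return Object of class \code{"perm_dist"}: list with \code{T0},
#'   \code{count_ge} (counts of \code{T* >= T0} including the identity),
#'   \code{Tmax}, \code{J}, \code{stat}, \code{method}, \code{parametric}
#'   p-value ingredients (\code{param_p}) when applicable, and optionally
#'   \code{Tstar}.
#' @export
run_permutation_test <- function(Y, M, C, blocks = NULL, vg = NULL,
                                 method = "freedman_lane", stat = "auto",
                                 shuffles = NULL,
                                 scheme = c("contrast", "selection"),
                                 keep_null = FALSE, sw_full_dof = FALSE) {
  method <- normalize_method(method)
  scheme <- match.arg(scheme)
  Y <- as.matrix(Y)
  part <- partition_model(M, C, scheme = scheme)
  N <- part$N; s <- part$s; V <- ncol(Y)
  if (nrow(Y) != N) stop("data and design have different numbers of rows")
  vg <- as_variance_groups(vg, N)
  if (method == "huh_jhun" && !is.null(blocks) && blocks$mode != "unrestricted")
    stop("Huh-Jhun cannot be used with exchangeability blocks")

  kind <- resolve_stat(stat, s, vg)
  if (kind %in% c("G", "v") && method == "huh_jhun" && vg$k > 1L)
    stop("variance groups are not supported for the reduced-space Huh-Jhun method; use F or t")

  X <- part$X; Z <- part$Z
  Dfull <- cbind(X, Z)
  Cp <- rbind(diag(s), matrix(0, ncol(Z), s))

  if (method == "parametric") {
    fit <- fit_glm(Y, Dfull)
    dof <- fit$dof
    pre <- stat_precompute(Dfull, Cp, vg, kind)
    T0 <- stat_columns(Dfull, Cp, fit$psi_hat, fit$residuals, vg, kind, dof,
                       Rdiag = pre$Rdiag, precomp = pre)
    pp <- if (kind %in% c("t", "v")) stats::pt(T0, dof, lower.tail = FALSE)
          else stats::pf(T0, s, dof, lower.tail = FALSE)
    return(structure(list(T0 = T0, count_ge = NULL, Tmax = NULL, J = 1L,
                          V = V, stat = kind, method = method, dof = dof,
                          parametric = TRUE, param_p = pp, Tstar = NULL),
                     class = "perm_dist"))
  }

  if (is.null(shuffles)) stop("a shuffling set is required (see enumerate_shufflings)")
  J <- shuffles$J

  # method-specific precomputation: for data-shuffling strategies the fitted
  # design is fixed, and the shuffled data are row rearrangements of a
  # precomputed matrix (plus a fixed offset), so each shuffle costs O(NV)
  fixed_design <- !(method %in% c("draper_stoneman", "smith"))
  if (method == "huh_jhun") {
    tm <- transform_model(method, list(perm = seq_len(N - matrix_rank(Z)),
                                       signs = rep(1L, N - matrix_rank(Z))), Y, part)
    E <- tm$Y; offset <- NULL
    D <- tm$X; dof <- tm$dof
    if (shuffles$N != nrow(E))
      stop("Huh-Jhun shufflings must be generated for the reduced dimension N - rank(Z) = ",
           nrow(E))
  } else {
    if (shuffles$N != N) stop("shuffling set has wrong dimension")
    E <- switch(method,
      freedman_lane = part$R_Z %*% Y,
      still_white = part$R_Z %*% Y,
      kennedy = part$R_Z %*% Y,
      ter_braak = part$R_M %*% Y,
      manly = Y,
      Y) # draper_stoneman, smith: data not shuffled
    offset <- switch(method,
      freedman_lane = part$H_Z %*% Y,
      ter_braak = part$H_M %*% Y,
      NULL)
    D <- switch(method,
      still_white = X,
      kennedy = part$R_Z %*% X,
      Dfull)
    dof <- switch(method,
      still_white = if (sw_full_dof) N - matrix_rank(Dfull) else N - matrix_rank(X),
      N - matrix_rank(Dfull))
  }
  Cp_use <- if (ncol(D) == s) diag(s) else Cp

  pre <- if (fixed_design) stat_precompute(D, Cp_use, vg, kind) else NULL
  PD <- if (fixed_design) pseudoinverse(D) else NULL

  T0 <- NULL
  count_ge <- numeric(V)
  Tmax <- numeric(J)
  Tstar <- if (keep_null) matrix(NA_real_, J, V) else NULL
  nonfinite <- integer(0)

  RzX <- if (method %in% c("smith")) part$R_Z %*% X else NULL

  for (j in seq_len(J)) {
    sh <- get_shuffling(shuffles, j)
    if (fixed_design) {
      Ystar <- (sh$signs * E)[sh$perm, , drop = FALSE]
      if (!is.null(offset)) Ystar <- Ystar + offset
      psi <- PD %*% Ystar
      res <- Ystar - D %*% psi
      Tj <- stat_columns(D, Cp_use, psi, res, vg, kind, dof,
                         Rdiag = pre$Rdiag, precomp = pre)
    } else {
      Xj <- if (method == "smith") (sh$signs * RzX)[sh$perm, , drop = FALSE]
            else (sh$signs * X)[sh$perm, , drop = FALSE]
      Dj <- cbind(Xj, Z)
      PDj <- pseudoinverse(Dj)
      psi <- PDj %*% Y
      res <- Y - Dj %*% psi
      prej <- stat_precompute(Dj, Cp, vg, kind, PDj = PDj)
      Tj <- stat_columns(Dj, Cp, psi, res, vg, kind, dof,
                         Rdiag = prej$Rdiag, precomp = prej)
    }
    if (j == 1L) T0 <- Tj
    if (any(!is.finite(Tj))) nonfinite <- c(nonfinite, j)
    Tjr <- round_stat(Tj)
    count_ge <- count_ge + (Tjr >= round_stat(T0))
    Tmax[j] <- max(Tj)
    if (keep_null) Tstar[j, ] <- Tj
  }
  if (length(nonfinite))
    message("non-finite statistics at shuffle(s): ",
            paste(utils::head(nonfinite, 10L), collapse = ", "))

  structure(list(T0 = T0, count_ge = count_ge, Tmax = Tmax, J = J, V = V,
                 stat = kind, method = method, dof = dof,
                 parametric = FALSE, Tstar = Tstar,
                 n_possible = shuffles$n_possible,
                 generation = shuffles$method_of_generation),
            class = "perm_dist")
}

resolve_stat <- function(stat, s, vg) {
  stat <- match.arg(tolower(stat), c("auto", "f", "t", "g", "v"))
  het <- vg$k > 1L
  kind <- switch(stat,
    auto = if (s == 1L) (if (het) "v" else "t") else (if (het) "G" else "F"),
    f = "F", t = "t", g = "G", v = "v")
  if (kind == "t" && s > 1L) stop("t statistic requires a rank-1 contrast")
  if (kind == "v" && s > 1L) stop("v statistic requires a rank-1 contrast")
  kind
}

# per-design precomputation shared across shuffles (and columns)
stat_precompute <- function(D, Cp, vg, kind, PDj = NULL) {
  if (kind %in% c("F", "t")) {
    list(cholB = chol(solve(t(Cp) %*% solve(crossprod(D)) %*% Cp)),
         Rdiag = NULL)
  } else {
    PD <- if (is.null(PDj)) pseudoinverse(D) else PDj
    Rdiag <- 1 - rowSums(D * t(PD))
    list(Rdiag = Rdiag,
         dfg = as.numeric(rowsum(Rdiag, vg$id)),
         Astack = vg_crossprods(D, vg$id, vg$k))
  }
}

#' @export
print.perm_dist <- function(x, ...) {
  cat("Permutation distribution: V =", x$V, "tests, J =", x$J,
      "shufflings, statistic", x$stat, ", method", x$method, "\n")
  invisible(x)
}
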