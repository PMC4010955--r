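#' Uncorrected permutation p-values
#'
#' \code{p_v = (1/J) * sum_j I(T*_jv >= T0_v)}. The identity shuffling is
#' part of the distribution, so the smallest attainable p-value is
#' \code{1/J}, never zero. Statistics are compared after rounding to 12
#' significant digits so that genuine ties are not split by floating-point
#' noise.
#'
#' @param dist A \code{perm_dist} from \code{\link{run_permutation_test}}.
#' @return Numeric vector of V p-values, each a multiple of \code{1/J}.
#' @export
pvalues_uncorrected <- function(dist) {
  if (isTRUE(dist$parametric)) return(dist$param_p)
  cnt <- if (!is.null(dist$Tstar)) {
    T0r <- round_stat(dist$T0)
    colSums(round_stat(dist$Tstar) >= matrix(T0r, dist$J, dist$V, byrow = TRUE))
  } else dist$count_ge
  cnt / dist$J
}

#' FWER-corrected p-values from the maximum statistic
#'
#' \code{p^fwer_v = (1/J) * sum_j I(Tmax_j >= T0_v)}, where \code{Tmax_j} is
#' the maximum statistic across the V tests at shuffle \code{j}. For the
#' parametric strategy a Bonferroni correction is returned instead.
#'
#' @param dist A \code{perm_dist}.
#' @return Numeric vector of V FWER-corrected p-values (elementwise at least
#'   the uncorrected ones).
#' @export
fwer_pvalues <- function(dist) {
  if (isTRUE(dist$parametric)) return(pmin(1, dist$param_p * dist$V))
  Tmaxr <- round_stat(dist$Tmax)
  T0r <- round_stat(dist$T0)
  vapply(T0r, function(t0) sum(Tmaxr >= t0), 0) / dist$J
}

#' FWER threshold for the statistic map
#'
#' The \code{(1 - alpha)} quantile of the per-shuffle maximum statistic:
#' tests whose observed statistic reaches this value are significant at
#' familywise level \code{alpha}.
#'
#' @param dist A \code{perm_dist}.
#' @param alpha Familywise error level.
#' @return Scalar threshold.
#' @export
fwer_threshold <- function(dist, alpha = 0.05) {
  if (isTRUE(dist$parametric)) stop("no permutation distribution for the parametric strategy")
  st <- sort(dist$Tmax)
  k <- floor(alpha * dist$J)
  if (k < 1L) return(Inf)
  st[dist$J - k + 1L]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment of the uncorrected p-values
#' (monotone-enforced), via \code{stats::p.adjust}.
#'
#' @param p_unc Vector of uncorrected p-values in (0, 1].
#' @return Adjusted p-values in (0, 1].
#' @export
fdr_adjust <- function(p_unc) {
  if (any(p_unc <= 0 | p_unc > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_unc, method = "BH")
}

#' Full inference from a permutation distribution
#'
#' @param dist A \code{perm_dist}.
#' @return Object of class \code{"inference_result"}: data frame with
#'   columns \code{T0}, \code{p_unc}, \code{p_fwer}, \code{p_fdr} plus
#'   attribute \code{J}.
#' @export
inference_result <- function(dist) {
  p_unc <- pvalues_uncorrected(dist)
  p_fwer <- fwer_pvalues(dist)
  p_fdr <- fdr_adjust(p_unc)
  out <- data.frame(index = seq_along(p_unc), T0 = dist$T0,
                    p_unc = p_unc, p_fwer = p_fwer, p_fdr = p_fdr)
  attr(out, "J") <- dist$J
  class(out) <- c("inference_result", "data.frame")
  out
}
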