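#' Permutation inference for a GLM contrast
#'
#' One-stop interface: partitions the design for the contrast, builds the
#' shuffling set (exhaustive when the number of unique shufflings does not
#' exceed \code{nperm}, conditional Monte Carlo otherwise), runs the
#' permutation test under the chosen nuisance-handling strategy and
#' statistic, and returns uncorrected, FWER-corrected (maximum statistic)
#' and FDR-adjusted p-values for the \code{V} simultaneous tests.
#'
#' Variance-group defaults follow the block structure when \code{vg} is not
#' given: one group per block under within-block shuffling; under
#' whole-block shuffling one group per within-block position (the k-th
#' observation of every block); a single group otherwise.
#'
#' @param Y Data: \code{N x V} matrix or length-N vector.
#' @param design Design matrix \code{N x r}.
#' @param contrast Contrast \code{r x s} (vector for a single contrast).
#' @param blocks Optional exchangeability blocks
#'   (\code{\link{exchangeability_blocks}} object, or a label vector used
#'   with \code{block_mode}).
#' @param block_mode \code{"within_block"} or \code{"whole_block"}; used when
#'   \code{blocks} is a plain label vector.
#' @param vg Optional variance-group labels.
#' @param method Nuisance-handling strategy (default \code{"freedman_lane"}).
#' @param stat Statistic: \code{"auto"}, \code{"F"}, \code{"t"}, \code{"G"},
#'   \code{"v"}.
#' @param regime \code{"ee"} (permutation), \code{"ise"} (sign flipping) or
#'   \code{"both"}.
#' @param nperm Maximum number of shufflings J (identity included).
#' @param seed Integer seed for shuffling generation.
#' @param scheme Partitioning scheme (see \code{\link{partition_model}}).
#' @param keep_null Keep the J x V matrix of shuffled statistics.
#' @param alpha Level used for the reported FWER threshold.
#' @return Object of class \code{"permglm"}: list with \code{table} (the
#'   \code{\link{inference_result}} data frame), \code{dist}, \code{J},
#'   \code{n_possible}, \code{generation}, \code{stat}, \code{method},
#'   \code{fwer_threshold}.
#' @examples
#' set.seed(7)
#' N <- 24
#' age <- scale(rnorm(N))
#' group <- rep(c(1, 0), each = N / 2)
#' Y <- cbind(0.8 * group + rnorm(N), rnorm(N))
#' M <- cbind(group, age, 1)
#' fit <- perm_glm(Y, M, c(1, 0, 0), nperm = 500, seed = 1)
#' fit$table
#' @export
perm_glm <- function(Y, design, contrast, blocks = NULL,
                     block_mode = c("within_block", "whole_block"),
                     vg = NULL, method = "freedman_lane", stat = "auto",
                     regime = c("ee", "ise", "both"), nperm = 1000L,
                     seed = NULL, scheme = c("contrast", "selection"),
                     keep_null = FALSE, alpha = 0.05) {
  regime <- match.arg(regime)
  scheme <- match.arg(scheme)
  method <- normalize_method(method)
  Y <- as.matrix(Y)
  N <- nrow(Y)
  if (!is.null(blocks) && !inherits(blocks, "exchangeability_blocks"))
    blocks <- exchangeability_blocks(blocks, mode = match.arg(block_mode))
  eb <- as_blocks(blocks, N)
  if (is.null(vg)) {
    vg <- switch(eb$mode,
      unrestricted = rep(1L, N),
      within_block = eb$block_of,
      whole_block = stats::ave(seq_len(N), eb$block_of, FUN = seq_along))
  }
  vg <- as_variance_groups(vg, N)

  part <- partition_model(design, contrast, scheme = scheme)
  # repeated-row detection on the shuffled partition: X for residual-based
  # methods, the full design for Manly and ter Braak
  Xdet <- if (method %in% c("manly", "ter_braak")) cbind(part$X, part$Z) else part$X

  dist <- if (method == "parametric") {
    run_permutation_test(Y, design, contrast, blocks = blocks, vg = vg,
                         method = method, stat = stat, scheme = scheme)
  } else {
    if (method == "huh_jhun") {
      ntil <- N - matrix_rank(part$Z)
      shuffles <- enumerate_shufflings(NULL, regime = regime, J_max = nperm,
                                       seed = seed, N = ntil)
    } else {
      shuffles <- enumerate_shufflings(blocks, regime = regime, J_max = nperm,
                                       seed = seed, X_rows = Xdet, N = N)
    }
    run_permutation_test(Y, design, contrast, blocks = blocks, vg = vg,
                         method = method, stat = stat, shuffles = shuffles,
                         scheme = scheme, keep_null = keep_null)
  }
  tab <- inference_result(dist)
  thr <- if (!dist$parametric) fwer_threshold(dist, alpha) else NA_real_
  structure(list(table = tab, dist = dist, J = dist$J,
                 n_possible = dist$n_possible, generation = dist$generation,
                 stat = dist$stat, method = method, alpha = alpha,
                 fwer_threshold = thr, seed = seed),
            class = "permglm")
}

#' @export
print.permglm <- function(x, ...) {
  cat("Permutation GLM inference\n")
  cat("  method: ", x$method, ",  statistic: ", x$stat, "\n", sep = "")
  if (!is.null(x$generation))
    cat("  shufflings: J = ", x$J, " (", x$generation,
        "; unique possible = ", format(x$n_possible, big.mark = ","), ")\n", sep = "")
  cat("  tests: V =", nrow(x$table), "\n")
  if (!is.na(x$fwer_threshold))
    cat("  FWER ", format(100 * (1 - x$alpha)), "% threshold on the statistic: ",
        format(x$fwer_threshold, digits = 6), "\n", sep = "")
  print(utils::head(x$table, 10L))
  if (nrow(x$table) > 10L) cat("  ...", nrow(x$table) - 10L, "more tests\n")
  invisible(x)
}

#' @useDynLib permglm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pf pt qnorm rnorm runif rexp rweibull ks.test p.adjust ave quantile
#' @importFrom utils head read.table write.table
NULL
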