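#' Simulation scenario specification
#'
#' Describes one synthetic-data condition. Two families are supported.
#' Group scenarios (\code{group_sizes} given) use a cell-means design with
#' one variance group per cell and normal errors with per-group variances;
#' under signal the true group means are \code{c(0, -1)} for two groups and
#' \code{c(0, -0.33, -0.67, -1)} for four, and the contrast tests equality of
#' all group means. Regression scenarios (\code{group_sizes = NULL}) use a
#' regressor of interest \code{x1}, one nuisance regressor \code{z1} and an
#' intercept, with \code{Y = beta1*x1 + 0.5*z1 + 1 + e}; \code{x1} is a
#' linear trend on [-1, 1] (continuous) or a half/half +1/-1 indicator
#' (discrete), \code{z1} the mean-centred squared trend (continuous) or the
#' -1/+1/-1 quarter pattern (discrete), orthogonal to \code{x1} by
#' construction; correlation \code{rho} can be induced between them and the
#' errors can follow a normal, uniform, exponential or Weibull law,
#' standardised to zero mean and unit variance.
#'
#' @param group_sizes Integer vector of group sizes, or NULL for a
#'   regression scenario.
#' @param group_variances Positive variances, one per group.
#' @param signal For group scenarios: add the true group-mean signal.
#' @param N Observations for regression scenarios (divisible by 4 when a
#'   discrete regressor is used).
#' @param x1_kind,z1_kind \code{"continuous"} or \code{"discrete"}.
#' @param rho Correlation induced between \code{x1} and \code{z1}, in [0, 1).
#' @param beta1 Effect size of \code{x1} (0 for null scenarios).
#' @param error_law \code{"normal"}, \code{"uniform"}, \code{"exponential"}
#'   or \code{"weibull"}.
#' @param include_partitioning Use the contrast-driven partitioning scheme
#'   (TRUE) or the plain column split (FALSE) in regression studies.
#' @param regime Shuffling regime for the study.
#' @return Object of class \code{"scenario_spec"}.
#' @export
scenario_spec <- function(group_sizes = NULL, group_variances = NULL,
                          signal = FALSE, N = NULL,
                          x1_kind = c("continuous", "discrete"),
                          z1_kind = c("continuous", "discrete"),
                          rho = 0, beta1 = 0,
                          error_law = c("normal", "uniform", "exponential", "weibull"),
                          include_partitioning = FALSE,
                          regime = c("ee", "ise", "both")) {
  x1_kind <- match.arg(x1_kind); z1_kind <- match.arg(z1_kind)
  error_law <- match.arg(error_law); regime <- match.arg(regime)
  if (!is.null(group_sizes)) {
    if (is.null(group_variances)) group_variances <- rep(1, length(group_sizes))
    if (length(group_sizes) != length(group_variances))
      stop("group sizes and variances must have the same length")
    if (any(group_variances <= 0)) stop("variances must be positive")
    kind <- "group"
    N <- sum(group_sizes)
  } else {
    if (is.null(N)) stop("N required for regression scenarios")
    kind <- "regression"
  }
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  structure(list(kind = kind, group_sizes = group_sizes,
                 group_variances = group_variances, signal = signal,
                 N = N, x1_kind = x1_kind, z1_kind = z1_kind, rho = rho,
                 beta1 = beta1, error_law = error_law,
                 include_partitioning = include_partitioning,
                 regime = regime),
            class = "scenario_spec")
}

#' Regressors for a regression scenario
#'
#' Builds the regressor of interest \code{x1}, the nuisance \code{z1} and
#' the intercept. Continuous: \code{x1} is a linear trend from -1 to +1 and
#' \code{z1} its mean-centred square. Discrete: \code{x1} is +1 for the
#' first N/2 observations and -1 for the rest; \code{z1} is -1 on the first
#' and last N/4 and +1 on the middle N/2. Both constructions make \code{x1}
#' and \code{z1} orthogonal.
#'
#' @param spec A \code{scenario_spec} (regression kind), or NULL to use the
#'   kinds given explicitly.
#' @param N Number of observations.
#' @param x1_kind,z1_kind Used when \code{spec} is NULL.
#' @return List with \code{x1}, \code{z1}, \code{intercept}.
#' @export
make_scenario_design <- function(spec = NULL, N = spec$N,
                                 x1_kind = spec$x1_kind, z1_kind = spec$z1_kind) {
  trend <- seq(-1, 1, length.out = N)
  if (x1_kind == "discrete" || z1_kind == "discrete") {
    if (N %% 4L != 0L) stop("N must be divisible by 4 for discrete regressors")
  }
  x1 <- if (x1_kind == "continuous") trend else rep(c(1, -1), each = N / 2)
  z1 <- if (z1_kind == "continuous") {
    q <- trend^2; q - mean(q)
  } else {
    c(rep(-1, N / 4), rep(1, N / 2), rep(-1, N / 4))
  }
  list(x1 = x1, z1 = z1, intercept = rep(1, N))
}

#' Induce correlation between two regressors
#'
#' Post-multiplies \code{[x1 z1]} by the Cholesky factor \code{L} of the
#' target 2x2 correlation matrix \code{K = L'L} with off-diagonal
#' \code{rho}. With \code{rho = 0} the inputs are returned unchanged. When
#' the input columns are orthonormal the output columns have exactly the
#' requested correlation.
#'
#' @param x1,z1 Regressor vectors.
#' @param rho Target correlation, |rho| < 1.
#' @return List with \code{x1}, \code{z1}.
#' @export
induce_correlation <- function(x1, z1, rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (rho == 0) return(list(x1 = x1, z1 = z1))
  K <- matrix(c(1, rho, rho, 1), 2L)
  L <- chol(K) # upper-triangular U with K = U'U
  out <- cbind(x1, z1) %*% L
  list(x1 = out[, 1L], z1 = out[, 2L])
}

#' Draw standardised errors
#'
#' Draws \code{n} errors from the requested law, shifted/scaled to have
#' expected zero mean and unit variance: normal(0,1);
#' uniform(-sqrt(3), sqrt(3)); exponential(rate 1) minus 1; Weibull with
#' shape 1/3 and scale 1, centred at Gamma(4) = 6 and scaled by
#' sqrt(Gamma(7) - Gamma(4)^2) (a strongly skewed law).
#'
#' @param law Error law.
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return Numeric vector of length n.
#' @export
draw_errors <- function(law = c("normal", "uniform", "exponential", "weibull"),
                        n, seed = NULL) {
  law <- match.arg(law)
  if (!is.null(seed)) set.seed(seed)
  switch(law,
    normal = rnorm(n),
    uniform = runif(n, -sqrt(3), sqrt(3)),
    exponential = rexp(n, rate = 1) - 1,
    weibull = (rweibull(n, shape = 1 / 3, scale = 1) - gamma(4)) /
      sqrt(gamma(7) - gamma(4)^2))
}

#' Simulate a group-design dataset collection
#'
#' Builds the cell-means design, the all-means-equal contrast, the variance
#' groups, and \code{n_tests} independent data columns with per-group normal
#' error variances (plus the true group means when the scenario carries
#' signal).
#'
#' @param spec Group-kind \code{scenario_spec}.
#' @param n_tests Number of independent data columns.
#' @param seed Optional seed.
#' @return List with \code{Y} (N x n_tests), \code{M}, \code{C}, \code{vg},
#'   \code{psi} (true group means).
#' @export
simulate_group_dataset <- function(spec, n_tests = 1L, seed = NULL) {
  if (spec$kind != "group") stop("not a group scenario")
  if (!is.null(seed)) set.seed(seed)
  sizes <- spec$group_sizes
  k <- length(sizes)
  N <- sum(sizes)
  g <- rep(seq_len(k), sizes)
  M <- outer(g, seq_len(k), "==") + 0
  # successive-difference contrast columns testing all means equal
  C <- matrix(0, k, k - 1L)
  for (j in seq_len(k - 1L)) C[c(j, j + 1L), j] <- c(1, -1)
  psi <- if (spec$signal) {
    if (k == 2L) c(0, -1) else if (k == 4L) c(0, -0.33, -0.67, -1) else
      seq(0, -1, length.out = k)
  } else rep(0, k)
  sds <- sqrt(spec$group_variances)[g]
  Y <- matrix(rnorm(N * n_tests, mean = psi[g], sd = sds), N, n_tests)
  list(Y = Y, M = M, C = C, vg = g, psi = psi)
}

#' Simulate a regression-scenario dataset collection
#'
#' Builds the design \code{[x1 z1 1]} (after inducing correlation
#' \code{rho}), the contrast testing \code{beta1 = 0}, and \code{n_tests}
#' data columns \code{Y = beta1*x1 + 0.5*z1 + 1 + e} with errors from the
#' scenario's law.
#'
#' @param spec Regression-kind \code{scenario_spec}.
#' @param n_tests Number of independent data columns.
#' @param seed Optional seed.
#' @return List with \code{Y}, \code{M}, \code{C}.
#' @export
simulate_regression_dataset <- function(spec, n_tests = 1L, seed = NULL) {
  if (spec$kind != "regression") stop("not a regression scenario")
  if (!is.null(seed)) set.seed(seed)
  d <- make_scenario_design(spec)
  dc <- induce_correlation(d$x1, d$z1, spec$rho)
  M <- cbind(dc$x1, dc$z1, d$intercept)
  mu <- spec$beta1 * dc$x1 + 0.5 * dc$z1 + 1
  E <- matrix(draw_errors(spec$error_law, spec$N * n_tests), spec$N, n_tests)
  list(Y = mu + E, M = M, C = matrix(c(1, 0, 0), 3L))
}

#' Wilson score confidence interval
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param level Confidence level (default 0.95).
#' @return Named vector \code{c(lo, hi)} of proportions.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  c(lo = max(0, (centre - half) / denom), hi = min(1, (centre + half) / denom))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around \code{stats::ks.test} returning the statistic D and
#' the (asymptotic when samples are large) p-value.
#'
#' @param a,b Numeric samples (nonempty).
#' @return List with \code{D} and \code{p}.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Type-I error / power study for one scenario
#'
#' Simulates \code{n_reps} independent datasets under the scenario, runs the
#' permutation test on each (all datasets share one design, so they are run
#' as the V columns of a single vectorised call, each column receiving its
#' own p-value), and reports the percentage with \code{p <= alpha} together
#' with its 95% Wilson interval. Scenarios without signal measure the type-I
#' error; scenarios with signal (or nonzero \code{beta1}) measure power.
#'
#' @param spec A \code{scenario_spec}.
#' @param n_reps Number of simulated datasets.
#' @param J Maximum number of shufflings (exhaustive sets are used whenever
#'   the number of unique shufflings does not exceed J).
#' @param alpha Significance level.
#' @param seed Integer seed. A per-repetition seed ladder is derived from it,
#'   so any single repetition can be reproduced in isolation.
#' @param method Nuisance-handling strategy.
#' @param stat Statistic.
#' @param perms \code{"shared"} runs all datasets as the columns of one
#'   vectorised call with a single random shuffling set (the imaging
#'   situation: every voxel sees the same shufflings; cheap, but the Monte
#'   Carlo error of the reported proportion is slightly overdispersed
#'   relative to binomial because rejections share the shuffling draw);
#'   \code{"fresh"} draws an independent shuffling set per dataset (each
#'   dataset is a fully independent test, binomial Monte Carlo error).
#' @return Data frame (one row) with \code{proportion}, \code{ci_lo},
#'   \code{ci_hi} in percent, \code{n_reps}, \code{J}, \code{method},
#'   \code{stat}.
#' @export
run_error_power_study <- function(spec, n_reps = 1000L, J = 1000L,
                                  alpha = 0.05, seed = NULL,
                                  method = "freedman_lane", stat = "auto",
                                  perms = c("shared", "fresh")) {
  perms <- match.arg(perms)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps + 1L)
  if (spec$kind == "group") {
    sim <- simulate_group_dataset(spec, n_tests = n_reps)
    vg <- sim$vg
  } else {
    sim <- simulate_regression_dataset(spec, n_tests = n_reps)
    vg <- NULL
  }
  scheme <- if (spec$kind == "regression" && !spec$include_partitioning)
    "selection" else "contrast"
  if (perms == "shared") {
    fit <- perm_glm(sim$Y, sim$M, sim$C, vg = vg, method = method, stat = stat,
                    regime = spec$regime, nperm = J, seed = rep_seeds[1L],
                    scheme = scheme)
    p <- fit$table$p_unc
    Jused <- fit$J
    statused <- fit$stat
  } else {
    p <- numeric(n_reps)
    Jused <- NA_integer_
    statused <- NA_character_
    for (i in seq_len(n_reps)) {
      fit <- perm_glm(sim$Y[, i, drop = FALSE], sim$M, sim$C, vg = vg,
                      method = method, stat = stat, regime = spec$regime,
                      nperm = J, seed = rep_seeds[i + 1L], scheme = scheme)
      p[i] <- fit$table$p_unc
      Jused <- fit$J
      statused <- fit$stat
    }
  }
  k <- sum(p <= alpha)
  ci <- wilson_ci(k, n_reps)
  data.frame(proportion = 100 * k / n_reps,
             ci_lo = 100 * ci[["lo"]], ci_hi = 100 * ci[["hi"]],
             n_reps = n_reps, J = Jused, method = method, stat = statused,
             stringsAsFactors = FALSE)
}

#' Distribution-robustness comparison across variance configurations
#'
#' For each repeat and each variance configuration of a group scenario,
#' pools the observed statistic over \code{n_voxels} simulated null tests
#' and compares all configuration pairs with the two-sample KS test,
#' Bonferroni-corrected within the scenario. A pivotal statistic keeps the
#' same null distribution across configurations, so its rejection fraction
#' stays near \code{alpha}; a non-pivotal one is rejected far more often.
#'
#' @param sizes Group sizes (shared by all configurations).
#' @param variance_configs List of variance vectors, one per configuration.
#' @param n_voxels Null tests pooled per configuration and repeat.
#' @param n_reps Number of repeats.
#' @param alpha Level before Bonferroni correction.
#' @param stat \code{"F"} or \code{"G"}.
#' @param seed Integer seed.
#' @return Data frame with one row per configuration pair: indices,
#'   \code{rejection_fraction}, \code{n_reps}.
#' @export
run_distribution_comparison <- function(sizes, variance_configs,
                                        n_voxels = 1000L, n_reps = 100L,
                                        alpha = 0.05, stat = c("G", "F"),
                                        seed = NULL) {
  stat <- match.arg(stat)
  if (n_voxels <= 1L) warning("n_voxels <= 1 gives a degenerate KS comparison")
  if (!is.null(seed)) set.seed(seed)
  nc <- length(variance_configs)
  pairs <- utils::combn(nc, 2L)
  alpha_corr <- alpha / ncol(pairs)
  rej <- matrix(0L, n_reps, ncol(pairs))
  specs <- lapply(variance_configs, function(v)
    scenario_spec(group_sizes = sizes, group_variances = v))
  for (rep_i in seq_len(n_reps)) {
    stats_by_config <- lapply(specs, function(sp) {
      sim <- simulate_group_dataset(sp, n_tests = n_voxels)
      glm_statistic(sim$Y, sim$M, sim$C,
                    vg = if (stat == "G") sim$vg else NULL, stat = stat)
    })
    for (pi in seq_len(ncol(pairs))) {
      ks <- ks_two_sample(stats_by_config[[pairs[1L, pi]]],
                          stats_by_config[[pairs[2L, pi]]])
      rej[rep_i, pi] <- as.integer(ks$p < alpha_corr)
    }
  }
  data.frame(config_a = pairs[1L, ], config_b = pairs[2L, ],
             rejection_fraction = colMeans(rej), n_reps = n_reps)
}

#' Observed statistic for each test column
#'
#' Computes the observed F, t, G or v statistic of a contrast for every
#' column of \code{Y}, without permutation.
#'
#' @param Y Data matrix \code{N x V}.
#' @param M Design matrix.
#' @param C Contrast.
#' @param vg Optional variance-group labels.
#' @param stat Statistic (\code{"auto"} resolves as in \code{\link{perm_glm}}).
#' @return Numeric vector of V statistics.
#' @export
glm_statistic <- function(Y, M, C, vg = NULL, stat = "auto") {
  Y <- as.matrix(Y)
  part <- partition_model(M, C)
  vg <- as_variance_groups(vg, part$N)
  kind <- resolve_stat(stat, part$s, vg)
  D <- cbind(part$X, part$Z)
  Cp <- rbind(diag(part$s), matrix(0, ncol(part$Z), part$s))
  fit <- fit_glm(Y, D)
  pre <- stat_precompute(D, Cp, vg, kind)
  stat_columns(D, Cp, fit$psi_hat, fit$residuals, vg, kind, fit$dof,
               Rdiag = pre$Rdiag, precomp = pre)
}
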