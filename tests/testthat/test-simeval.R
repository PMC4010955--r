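test_that("scenario regressors follow the trend/quadratic and block constructions", {
  d <- make_scenario_design(N = 12, x1_kind = "continuous", z1_kind = "continuous")
  expect_equal(d$x1[1], -1)
  expect_equal(d$x1[12], 1)
  expect_equal(diff(d$x1), rep(2 / 11, 11))
  expect_lt(abs(sum(d$x1 * d$z1)), 1e-12)
  expect_lt(abs(mean(d$z1)), 1e-14)
  dd <- make_scenario_design(N = 8, x1_kind = "discrete", z1_kind = "discrete")
  expect_equal(dd$x1, c(1, 1, 1, 1, -1, -1, -1, -1))
  expect_equal(dd$z1, c(-1, -1, 1, 1, 1, 1, -1, -1))
  expect_equal(sum(dd$x1 * dd$z1), 0)
  expect_error(make_scenario_design(N = 10, x1_kind = "discrete",
                                    z1_kind = "continuous"), "divisible by 4")
})

test_that("correlation induction hits the target and is invertible", {
  expect_identical(induce_correlation(1:4, 4:1, 0), list(x1 = 1:4, z1 = 4:1))
  set.seed(71)
  X0 <- scale(matrix(rnorm(200 * 2), 200, 2), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(X0)) # mean-zero orthonormal columns
  out <- induce_correlation(Q[, 1], Q[, 2], 0.8)
  expect_equal(stats::cor(out$x1, out$z1), 0.8, tolerance = 1e-10)
  # invert through L^-1
  L <- chol(matrix(c(1, .8, .8, 1), 2))
  back <- cbind(out$x1, out$z1) %*% solve(L)
  expect_equal(back[, 1], Q[, 1], tolerance = 1e-12)
  expect_equal(back[, 2], Q[, 2], tolerance = 1e-12)
  expect_error(induce_correlation(1:3, 3:1, 1), "rho")
})

test_that("error laws are standardised to zero mean and unit variance", {
  n <- 2e5
  for (law in c("uniform", "exponential", "weibull")) {
    e <- draw_errors(law, n, seed = 72)
    expect_lt(abs(mean(e)), 0.02, label = law)
    tol <- if (law == "weibull") 0.2 else 0.02 # heavy-tailed variance estimate
    expect_lt(abs(var(e) - 1), tol, label = law)
  }
  expect_identical(draw_errors("normal", 10, seed = 1),
                   draw_errors("normal", 10, seed = 1))
  # uniform support is exactly +/- sqrt(3)
  e <- draw_errors("uniform", 1e4, seed = 73)
  expect_lt(max(abs(e)), sqrt(3))
})

test_that("group datasets carry the scenario sizes, variances and signal", {
  spec <- scenario_spec(group_sizes = c(8, 4), group_variances = c(5, 1))
  sim <- simulate_group_dataset(spec, n_tests = 4000, seed = 74)
  expect_equal(dim(sim$Y), c(12L, 4000L))
  expect_equal(sim$vg, rep(1:2, c(8, 4)))
  v1 <- mean(apply(sim$Y[1:8, ], 1, var))
  v2 <- mean(apply(sim$Y[9:12, ], 1, var))
  expect_equal(v1, 5, tolerance = 0.2)
  expect_equal(v2, 1, tolerance = 0.1)
  expect_lt(max(abs(rowMeans(sim$Y))), 0.2) # null spec: zero expectation
  spec4 <- scenario_spec(group_sizes = c(4, 4, 4, 4), signal = TRUE)
  sim4 <- simulate_group_dataset(spec4, n_tests = 2000, seed = 75)
  gm <- rowsum(rowMeans(sim4$Y), sim4$vg) / 4
  expect_equal(as.numeric(gm), c(0, -0.33, -0.67, -1), tolerance = 0.1)
  # contrast columns test all-means-equal
  expect_equal(colSums(sim4$C), rep(0, 3))
  expect_equal(qr(sim4$C)$rank, 3L)
})

test_that("regression datasets implement Y = b1 x1 + 0.5 z1 + 1 + e", {
  spec <- scenario_spec(N = 48, beta1 = 0.5, rho = 0, error_law = "normal")
  sim <- simulate_regression_dataset(spec, n_tests = 3000, seed = 76)
  coefs <- pseudoinverse(sim$M) %*% rowMeans(sim$Y)
  expect_equal(as.numeric(coefs), c(0.5, 0.5, 1), tolerance = 0.05)
})

test_that("Wilson intervals match printed reference values", {
  expect_equal(round(100 * wilson_ci(49, 1000), 1), c(lo = 3.7, hi = 6.4))
  expect_equal(round(100 * wilson_ci(729, 1000), 1), c(lo = 70.1, hi = 75.6))
  expect_equal(wilson_ci(0, 10)[["lo"]], 0)
  # prop.test (score interval without continuity correction) as oracle
  pt <- stats::prop.test(49, 1000, correct = FALSE)
  expect_equal(unname(wilson_ci(49, 1000)), unname(pt$conf.int[1:2]),
               tolerance = 1e-10)
  expect_error(wilson_ci(5, 0), "positive")
})

test_that("KS comparison behaves at the edges and near nominal level", {
  expect_equal(ks_two_sample(1:10, 1:10)$D, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
  set.seed(77)
  rej <- replicate(200, ks_two_sample(rnorm(300), rnorm(300))$p < 0.05)
  expect_lt(abs(mean(rej) - 0.05), 0.05)
})

test_that("an exhaustive null study is calibrated and a huge effect gives full power", {
  spec <- scenario_spec(group_sizes = c(4, 4))
  r <- run_error_power_study(spec, n_reps = 400, J = 100, seed = 78)
  # true level of the one-sided exhaustive test is 3/70
  expect_gt(r$proportion, 1)
  expect_lt(r$proportion, 8)
  expect_true(r$ci_lo <= r$proportion && r$proportion <= r$ci_hi)
  spec_big <- scenario_spec(group_sizes = c(10, 10), group_variances = c(1, 1))
  sim <- simulate_group_dataset(spec_big, n_tests = 50, seed = 79)
  sim$Y[11:20, ] <- sim$Y[11:20, ] - 20 # enormous group difference
  fit <- perm_glm(sim$Y, sim$M, sim$C, vg = sim$vg, nperm = 500, seed = 80)
  expect_true(all(fit$table$p_unc == 1 / fit$J))
})

test_that("distribution comparison flags F but not G under strong heteroscedasticity", {
  res <- run_distribution_comparison(
    sizes = c(40, 30, 20, 10),
    variance_configs = list(c(15, 10, 5, 1), c(1, 1, 1, 1)),
    n_voxels = 150, n_reps = 12, stat = "F", seed = 81)
  resG <- run_distribution_comparison(
    sizes = c(40, 30, 20, 10),
    variance_configs = list(c(15, 10, 5, 1), c(1, 1, 1, 1)),
    n_voxels = 150, n_reps = 12, stat = "G", seed = 81)
  expect_gt(res$rejection_fraction, 0.8)
  expect_lt(resG$rejection_fraction, 0.3)
  expect_warning(
    run_distribution_comparison(c(4, 4), list(c(1, 1), c(1, 2)),
                                n_voxels = 1, n_reps = 2, seed = 1),
    "degenerate")
})

test_that("scenario specification rejects invalid settings", {
  expect_error(scenario_spec(group_sizes = c(4, 4), group_variances = c(1, -1)),
               "positive")
  expect_error(scenario_spec(group_sizes = c(4, 4), group_variances = 1),
               "same length")
  expect_error(scenario_spec(N = 12, rho = 1), "rho")
  expect_error(scenario_spec(), "N required")
})
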