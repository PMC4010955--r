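# shared regression fixture: N = 16, interest + nuisance + intercept
engine_fixture <- function(seed = 41, V = 3, rho_xz = 0) {
  set.seed(seed)
  N <- 16
  x <- scale(rnorm(N))[, 1]
  z <- scale(rnorm(N))[, 1]
  if (rho_xz == 0) z <- stats::residuals(stats::lm(z ~ x)) # exactly orthogonal
  M <- cbind(x, z, 1)
  Y <- matrix(rnorm(N * V), N, V)
  list(Y = Y, M = M, C = c(1, 0, 0), N = N)
}

test_that("identity shuffling reproduces the observed statistic for every method", {
  fx <- engine_fixture()
  part <- partition_model(fx$M, fx$C)
  idsh <- list(perm = 1:fx$N, signs = rep(1L, fx$N))
  for (m in c("draper_stoneman", "still_white", "freedman_lane", "manly",
              "ter_braak", "kennedy", "smith")) {
    tm <- transform_model(m, idsh, fx$Y, part)
    Dm <- cbind(tm$X, tm$Z)
    fitm <- fit_glm(tm$Y, Dm)
    T_id <- compute_F(fitm$psi_hat, Dm,
                      rbind(diag(1), matrix(0, ncol(tm$Z), 1)),
                      fitm$residuals, rank_M = nrow(Dm) - tm$dof)
    sh <- enumerate_shufflings(NULL, "ee", J_max = 50, seed = 1, N = fx$N)
    d <- run_permutation_test(fx$Y, fx$M, fx$C, method = m, stat = "F",
                              shuffles = sh, keep_null = TRUE)
    expect_equal(d$Tstar[1, ], d$T0, info = m)
    expect_equal(d$T0, T_id, tolerance = 1e-9, info = m)
  }
  # Huh-Jhun works in the reduced space
  ntil <- fx$N - 2L
  shr <- enumerate_shufflings(NULL, "ee", J_max = 50, seed = 2, N = ntil)
  d <- run_permutation_test(fx$Y, fx$M, fx$C, method = "huh_jhun", stat = "F",
                            shuffles = shr, keep_null = TRUE)
  expect_equal(d$Tstar[1, ], d$T0)
  # and its observed statistic equals the full-model F
  expect_equal(d$T0, glm_statistic(fx$Y, fx$M, fx$C, stat = "F"),
               tolerance = 1e-9)
})

test_that("Freedman-Lane reduces to Manly when there is no nuisance", {
  set.seed(42)
  N <- 10
  M <- matrix(rnorm(N), N, 1)
  Y <- matrix(rnorm(N * 2), N, 2)
  part <- partition_model(M, matrix(1, 1, 1))
  sh <- list(perm = sample(N), signs = rep(1L, N))
  fl <- transform_model("freedman_lane", sh, Y, part)
  ml <- transform_model("manly", sh, Y, part)
  expect_equal(fl$Y, ml$Y, tolerance = 1e-12)
})

test_that("Draper-Stoneman and Smith coincide when X and Z are orthogonal", {
  fx <- engine_fixture(seed = 43, rho_xz = 0)
  sh <- enumerate_shufflings(NULL, "ee", J_max = 40, seed = 3, N = fx$N)
  # selection scheme keeps the raw columns, whose orthogonality we control
  dds <- run_permutation_test(fx$Y, fx$M, fx$C, method = "draper_stoneman",
                              stat = "t", shuffles = sh, keep_null = TRUE,
                              scheme = "selection")
  dsm <- run_permutation_test(fx$Y, fx$M, fx$C, method = "smith",
                              stat = "t", shuffles = sh, keep_null = TRUE,
                              scheme = "selection")
  expect_equal(dds$Tstar, dsm$Tstar, tolerance = 1e-9)
})

test_that("the Freedman-Lane fast form equals the literal six-step procedure", {
  fx <- engine_fixture(seed = 44, V = 2, rho_xz = 0.5)
  part <- partition_model(fx$M, fx$C)
  X <- part$X; Z <- part$Z
  D <- cbind(X, Z)
  Cp <- rbind(diag(1), matrix(0, ncol(Z), 1))
  sh <- enumerate_shufflings(NULL, "ee", J_max = 30, seed = 4, N = fx$N)
  d <- run_permutation_test(fx$Y, fx$M, fx$C, method = "freedman_lane",
                            stat = "F", shuffles = sh, keep_null = TRUE)
  # literal steps: fit reduced model, permute its residuals, add back the
  # nuisance fit, refit the full model, compute the statistic
  gam <- pseudoinverse(Z) %*% fx$Y
  ez <- fx$Y - Z %*% gam
  for (j in seq_len(sh$J)) {
    perm <- sh$perm[j, ]
    Ystar <- ez[perm, , drop = FALSE] + Z %*% gam
    Tj <- glm_statistic(Ystar, D, Cp, stat = "F")
    expect_equal(d$Tstar[j, ], Tj, tolerance = 1e-10)
  }
})

test_that("parametric strategy returns F/t tail areas", {
  fx <- engine_fixture(seed = 45, V = 4)
  d <- run_permutation_test(fx$Y, fx$M, fx$C, method = "parametric", stat = "F")
  expect_equal(pvalues_uncorrected(d),
               pf(d$T0, 1, 16 - 3, lower.tail = FALSE))
  dt <- run_permutation_test(fx$Y, fx$M, fx$C, method = "parametric", stat = "t")
  expect_equal(pvalues_uncorrected(dt),
               pt(dt$T0, 16 - 3, lower.tail = FALSE))
})

test_that("exhaustive permutation p-values are uniform on the 1/J grid under the null", {
  set.seed(46)
  n_rep <- 150
  ps <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    fx <- two_group_fixture(n1 = 3, n2 = 3, seed = 1000 + i)
    fit <- perm_glm(fx$y, fx$M, fx$C, nperm = 100, stat = "F", seed = i)
    expect_equal(fit$J, 20L)
    ps[i] <- fit$table$p_unc
  }
  expect_true(all(abs(ps * 20 - round(ps * 20)) < 1e-9)) # multiples of 1/J
  # P(p <= 0.25) should be close to 0.25 (binomial 99% band)
  frac <- mean(ps <= 0.25)
  expect_lt(abs(frac - 0.25), 2.58 * sqrt(0.25 * 0.75 / n_rep) + 1e-9)
})

test_that("a strong signal yields the smallest attainable p-value 1/J", {
  set.seed(47)
  fx <- two_group_fixture(n1 = 4, n2 = 4, seed = 48, means = c(50, 0))
  fit <- perm_glm(fx$y, fx$M, fx$C, nperm = 1000, stat = "t", seed = 5)
  expect_equal(fit$table$p_unc, 1 / fit$J)
})

test_that("Huh-Jhun refuses exchangeability blocks and sign-flip sets are honoured", {
  fx <- engine_fixture(seed = 49)
  eb <- exchangeability_blocks(rep(1:2, each = 8), "within_block")
  expect_error(
    run_permutation_test(fx$Y, fx$M, fx$C, blocks = eb, method = "huh_jhun",
                         stat = "F",
                         shuffles = enumerate_shufflings(NULL, "ee", 10, N = 14)),
    "Huh-Jhun")
  # ISE regime: sign flips change the statistic but identity reproduces T0
  sh <- enumerate_shufflings(NULL, "ise", J_max = 64, seed = 6, N = fx$N)
  d <- run_permutation_test(fx$Y, fx$M, fx$C, method = "freedman_lane",
                            stat = "t", shuffles = sh, keep_null = TRUE)
  expect_equal(d$Tstar[1, ], d$T0)
  expect_gt(stats::sd(d$Tstar[, 1]), 0)
})

test_that("engine runs are reproducible from the seed", {
  fx <- engine_fixture(seed = 50, V = 2)
  f1 <- perm_glm(fx$Y, fx$M, fx$C, nperm = 200, seed = 7)
  f2 <- perm_glm(fx$Y, fx$M, fx$C, nperm = 200, seed = 7)
  expect_identical(f1$table, f2$table)
})
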