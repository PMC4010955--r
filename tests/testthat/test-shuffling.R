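test_that("maximum shuffling counts follow the block formulas", {
  # unrestricted, distinct rows: N!
  X <- matrix(rnorm(5), 5, 1)
  expect_equal(count_max_shufflings(NULL, X, "ee"), 120)
  expect_equal(count_max_shufflings(NULL, X, "ise"), 32)
  # repeated rows: multinomial
  Xr <- matrix(c(1, 1, 2, 2), 4, 1)
  expect_equal(count_max_shufflings(NULL, Xr, "ee"), 6)
  # within-block sizes {2,3}
  eb <- exchangeability_blocks(rep(1:2, c(2, 3)), "within_block")
  X5 <- matrix(rnorm(5), 5, 1)
  expect_equal(count_max_shufflings(eb, X5, "ee"), 2 * 6)
  expect_equal(count_max_shufflings(eb, X5, "ise"), 2^5)
  expect_equal(count_max_shufflings(eb, X5, "both"), 12 * 32)
  # whole-block, three equal blocks with distinct content
  eb3 <- exchangeability_blocks(rep(1:3, each = 2), "whole_block")
  X6 <- matrix(1:6, 6, 1)
  expect_equal(count_max_shufflings(eb3, X6, "ee"), 6)
  expect_equal(count_max_shufflings(eb3, X6, "ise"), 8)
  # repeated whole blocks
  Xrep <- matrix(c(1, 2, 1, 2, 3, 4), 6, 1)
  expect_equal(count_max_shufflings(eb3, Xrep, "ee"), 3) # 3!/2!
  expect_error(exchangeability_blocks(rep(1:2, c(2, 3)), "whole_block"),
               "equal size")
})

test_that("exhaustive enumeration is complete, unique, identity first", {
  # sign flips, N = 3: exactly 8 patterns
  sh <- enumerate_shufflings(NULL, "ise", J_max = 8, seed = 1, N = 3)
  expect_equal(sh$J, 8L)
  expect_true(all(sh$signs[1, ] == 1))
  expect_true(all(sh$perm[1, ] == 1:3))
  expect_equal(nrow(unique(sh$signs)), 8L)
  expect_equal(sh$method_of_generation, "exhaustive")
  # within-block {1,2},{3,4}: the four block-respecting permutations
  eb <- exchangeability_blocks(rep(1:2, each = 2), "within_block")
  sh2 <- enumerate_shufflings(eb, "ee", J_max = 100, seed = 2,
                              X_rows = matrix(1:4, 4, 1))
  expect_equal(sh2$J, 4L)
  want <- rbind(c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3))
  got <- sh2$perm[order(apply(sh2$perm, 1, paste, collapse = ",")), ]
  expect_equal(got, want[order(apply(want, 1, paste, collapse = ",")), ])
  # whole-block, two blocks of three: identity and the block swap
  eb2 <- exchangeability_blocks(rep(1:2, each = 3), "whole_block")
  sh3 <- enumerate_shufflings(eb2, "ee", J_max = 10, X_rows = matrix(1:6, 6, 1))
  expect_equal(sh3$J, 2L)
  expect_equal(sh3$perm[1, ], 1:6)
  expect_equal(sh3$perm[2, ], c(4:6, 1:3))
})

test_that("exhaustive cardinality equals the count for random block configurations", {
  set.seed(33)
  for (i in 1:12) {
    mode <- sample(c("unrestricted", "within_block", "whole_block"), 1)
    if (mode == "whole_block") {
      B <- sample(2:3, 1); sz <- sample(1:2, 1)
      labels <- rep(seq_len(B), each = sz)
    } else if (mode == "within_block") {
      nb <- sample(2:3, 1)
      labels <- rep(seq_len(nb), times = sample(1:3, nb, replace = TRUE))
    } else labels <- rep(1L, sample(3:5, 1))
    eb <- exchangeability_blocks(labels, mode)
    X <- matrix(sample(1:3, eb$N, replace = TRUE), eb$N, 1)
    regime <- sample(c("ee", "ise", "both"), 1)
    cnt <- count_max_shufflings(eb, X, regime)
    if (cnt <= 600) {
      sh <- enumerate_shufflings(eb, regime, J_max = 600, seed = i, X_rows = X)
      expect_equal(sh$J, cnt)
      key <- apply(cbind(sh$perm, sh$signs), 1, paste, collapse = ",")
      expect_equal(anyDuplicated(key), 0L)
    }
  }
})

test_that("random draws respect block constraints and are reproducible", {
  eb <- exchangeability_blocks(rep(1:3, c(3, 3, 2)), "within_block")
  sh <- enumerate_shufflings(eb, "both", J_max = 200, seed = 9,
                             N = 8)
  expect_equal(sh$method_of_generation, "cmc")
  for (j in seq_len(sh$J)) {
    p <- sh$perm[j, ]
    expect_true(all(eb$block_of[p] == eb$block_of)) # never crosses blocks
    expect_true(all(sort(p) == 1:8))
  }
  sh_again <- enumerate_shufflings(eb, "both", J_max = 200, seed = 9, N = 8)
  expect_identical(sh, sh_again)
  # whole-block CMC: blocks move intact, block-constant flips
  ebw <- exchangeability_blocks(rep(1:3, each = 2), "whole_block")
  shw <- enumerate_shufflings(ebw, "both", J_max = 50, seed = 10, N = 6)
  for (j in seq_len(shw$J)) {
    p <- shw$perm[j, ]
    expect_true(all(p[c(2, 4, 6)] - p[c(1, 3, 5)] == 1L))
    s <- shw$signs[j, ]
    expect_true(all(s[c(1, 3, 5)] == s[c(2, 4, 6)]))
  }
})

test_that("applying a shuffling and its inverse restores the input", {
  set.seed(34)
  A <- matrix(rnorm(24), 8, 3)
  sh <- list(perm = sample(8), signs = sample(c(-1L, 1L), 8, TRUE))
  expect_equal(apply_shuffling(list(perm = 1:8, signs = rep(1L, 8)), A), A)
  expect_equal(apply_shuffling(list(perm = 1:8, signs = rep(-1L, 8)), A), -A)
  B <- apply_shuffling(sh, A)
  expect_equal(apply_shuffling(invert_shuffling(sh), B), A)
  expect_error(apply_shuffling(sh, A[1:5, ]), "dimension")
})

test_that("dedup re-draws duplicated CMC shufflings", {
  sh <- enumerate_shufflings(NULL, "ee", J_max = 20, seed = 5, N = 60,
                             dedup = TRUE)
  key <- apply(sh$perm, 1, paste, collapse = ",")
  expect_equal(anyDuplicated(key), 0L)
})
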