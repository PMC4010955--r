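# deterministic small fixtures built in code

random_design <- function(N, r, seed = 1) {
  set.seed(seed)
  repeat {
    M <- matrix(rnorm(N * r), N, r)
    if (qr(M)$rank == r) return(M)
  }
}

# two-group cell-means fixture
two_group_fixture <- function(n1 = 4, n2 = 4, seed = 1, means = c(0, 0),
                              sds = c(1, 1)) {
  set.seed(seed)
  g <- rep(1:2, c(n1, n2))
  list(y = rnorm(n1 + n2, means[g], sds[g]),
       g = g,
       M = cbind(g == 1, g == 2) + 0,
       C = matrix(c(1, -1), 2))
}

# classical one-way ANOVA F for a grouped vector (independent oracle)
anova_F <- function(y, g) {
  unname(summary(stats::aov(y ~ factor(g)))[[1]]$`F value`[1])
}

# one-sided Welch v for subset idx as group 1 (independent oracle)
welch_v <- function(y, idx) {
  a <- y[idx]; b <- y[-idx]
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}
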