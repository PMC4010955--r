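---
title: "Permutation inference for GLM contrasts: model, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation inference for GLM contrasts: model, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permglm)
```

## The problem

Given data $Y$ ($N$ observations, possibly $V$ simultaneous tests such as
image voxels), a full-rank design $M$ ($N \times r$) and a full-rank
contrast $C$ ($r \times s$), we test $H_0 : C'\psi = 0$ in the general
linear model $Y = M\psi + \epsilon$ without assuming normal errors.
Permutation inference replaces the theoretical null distribution of a test
statistic by its empirical distribution over data shufflings that leave the
joint error distribution unchanged under $H_0$: row permutations when the
errors are exchangeable (EE), sign flips when they are independent and
symmetric (ISE), or both. The p-value is
$\frac{1}{J}\sum_j I(T^*_j \ge T_0)$, with the unshuffled statistic always
included, so the smallest attainable p-value is $1/J$.

The complication addressed by this package is the presence of *nuisance*
regressors: under $H_0$ the data still contain nuisance effects and are not
directly exchangeable. The model is therefore re-expressed as
$Y = X\beta + Z\gamma + \epsilon$, where $X$ carries the effects under test
and $Z$ the nuisance, and the nuisance is handled by one of nine classical
strategies (`method` argument): Draper–Stoneman, Still–White, Freedman–Lane,
Manly, ter Braak, Kennedy, Huh–Jhun, Smith, and a parametric reference.
Freedman–Lane — the default — permutes the residuals of the nuisance-only
model and refits the full model; it is implemented through the one-matrix
form $(P_j R_Z + H_Z)Y$, where $H_Z = ZZ^+$ and $R_Z = I - H_Z$, so the
shuffling matrix is built once per permutation and applied to all $V$
columns. A test verifies that this equals the literal six-step procedure to
$10^{-10}$.

## Partitioning the design

The split of $M$ into $[X\ Z]$ for a given contrast is not unique. The
default scheme sets $X = M D C (C' D C)^{-1}$ with $D = (M'M)^{-1}$ and
builds $Z$ from a basis $C_v$ of the null space of $C'$ adjusted so that
$X'Z = 0$. The contract — enforced by tests rather than by any particular
algebra — is that the $F$ statistic for $\beta$ in the partitioned model
equals the $F$ statistic for $C'\psi$ in the unpartitioned one, for any
data. A `"selection"` scheme is also provided for contrasts that merely
pick columns of $M$; it keeps the designated columns untouched (the
"unpartitioned" variant used in the regression simulations below). When
several contrasts are tested, the partition is rebuilt per contrast.

## Statistics

With homoscedastic errors the usual $F$ (and $t = \mathrm{sign}(\hat\beta)
\sqrt F$ for $s = 1$) is used. When observations fall into *variance
groups* (VGs) with unequal variances, pooling the residual variance breaks
pivotality: the null distribution of $F$ then depends on the variance
configuration, which invalidates comparisons across tests (and hence
max-statistic FWER correction). The generalised statistic

$$G = \frac{\hat\psi' C (C'(M'WM)^{-1}C)^{-1} C'\hat\psi}{\Lambda\, s}$$

uses a diagonal weighting matrix with $W_{nn}$ the reciprocal of the
estimated variance of the group of observation $n$ (group effective degrees
of freedom over group residual sum of squares), and a Welch-type correction

$$\Lambda = 1 + \frac{2(s-1)}{s(s+2)} \sum_g \frac{1}{\sum_{n \in g} R_{nn}}
\left(1 - \frac{\sum_{n \in g} W_{nn}}{\mathrm{tr}(W)}\right)^2 .$$

Special cases, each covered by a test against an independent implementation:
one VG gives $\Lambda = 1$ and $G = F$ exactly; for two VGs and a rank-1
contrast, $\mathrm{sign}(\hat\beta)\sqrt G$ is the Aspin–Welch $v$
(equal to `t.test`'s Welch statistic); for more groups, $G$ equals Welch's
$v^2$ (`oneway.test`). With two groups of equal size $G = F$ for any
variances. The `stat = "auto"` default resolves to $t$/$v$ for rank-1
contrasts and $F$/$G$ otherwise, with the robust variant whenever more than
one VG is present. Note the one-sided convention throughout: evidence
against $H_0$ corresponds to large statistics, and for signed statistics
($t$, $v$) the direction is the one given by the contrast; use the squared
statistics ($F$, $G$) for direction-free tests.

The statistic of every shuffle is computed from solves, never explicit
inverses; the per-column $G$ loop (an $r \times r$ solve per test per
shuffle) is compiled (RcppArmadillo), with the per-group design
cross-products precomputed once whenever the fitted design does not change
across shufflings. A pure-R single-test implementation (`compute_G`) serves
as the reference in tests. Degenerate cases: a zero group residual sum of
squares makes the weight infinite and the statistic is reported as `+Inf`,
which simply ranks largest during p-value counting; VGs of size 1 are
permitted with a warning (their variance is estimated from one residual).

## Shufflings, blocks, and counting

Exchangeability blocks (EBs) restrict the permutations: within-block
shuffling permutes observations only inside their block (sign flips remain
unrestricted), whole-block shuffling exchanges entire equal-sized blocks
(sign flips act per block; matrices are block-level shufflings expanded by
a Kronecker product with an identity). Variance groups default to one per
block under within-block shuffling and to one per within-block position
under whole-block shuffling, and can be overridden.

Permutations that do not change the shuffled partition are counted once:
two permutations are synonymous when, for every set of identical rows of
the shuffled matrix ($X$ for residual-shuffling strategies, $M$ for Manly
and ter Braak), the same set of observations lands on that row class. The
number of distinct shufflings is the multinomial coefficient
$N!/\prod_m N_m!$ (unrestricted), its per-block product (within-block), or
$B!/\prod_{\tilde m} N_{\tilde m}!$ over blocks (whole-block), times $2^N$
(or $2^B$) sign flips when applicable. When this count is at most the
requested $J$, the complete unique set is enumerated (the enumeration order
is randomised to avoid the bias of lexicographic subsets, identity kept
first); otherwise $J - 1$ shufflings are drawn by conditional Monte Carlo.
Plain CMC may repeat a shuffling; a `dedup` flag re-draws duplicates. Sign
flips are indexed in radix-2, digit 1 meaning $+1$.

Two limitations are deliberate. First, nested mixtures of whole- and
within-block exchange in one file are not supported — one level only.
Second, when rows of $X$ repeat but the corresponding rows of $Z$ differ,
the synonym detection (based on $X$ alone, as is conventional) can merge
permutations whose statistics differ slightly through $Z$; in the designs
used here ($Z$ constant within each repeated-row class, or all rows
distinct) the enumeration is exact.

## Strategy-specific details

* **Still–White** fits the interest-only model after residualising the
  data, with $N - \mathrm{rank}(X)$ degrees of freedom (the common use when
  the nuisance is no longer available); `sw_full_dof = TRUE` restores
  full-model degrees of freedom.
* **Kennedy** fits $P R_Z Y$ on $R_Z X$; its statistic at the identity
  equals the full-model one when full-model degrees of freedom are used, so
  they are.
* **Huh–Jhun** works in the reduced space $Q' R_Z$, where $Q$ is an
  orthonormal basis of the column space of $R_Z$ (dimension
  $N - \mathrm{rank}(Z)$) computed by a symmetric eigendecomposition with a
  deterministic sign convention (largest-magnitude entry positive);
  shufflings are generated in that reduced dimension. It cannot be combined
  with exchangeability blocks, and multiple variance groups are not
  meaningful in the rotated space, so both are refused.
* **Parametric** performs no shuffling; p-values are $F$/$t$ tail areas,
  FWER by Bonferroni.

Identity shufflings reproduce the observed statistic exactly for every
strategy (tested). Statistics are compared for $T^* \ge T_0$ after rounding
both to 12 significant digits, so genuine ties are not split by
floating-point noise.

## Multiple testing

Across the $V$ tests the per-shuffle maximum $T^{\max}_j$ is recorded;
FWER-corrected p-values count $T^{\max}_j \ge T_0$, and the
$(1-\alpha)$-quantile of $T^{\max}$ is reported as a single map threshold.
FDR uses Benjamini–Hochberg adjusted p-values (`stats::p.adjust`), the more
informative alternative to a single FDR threshold. The minimum-p variant of
FWER correction is intentionally not implemented: with discrete permutation
p-values it can lose considerable power compared to the max-statistic.

## The synthetic-data module

`scenario_spec` describes the two families of simulation used to evaluate
the machinery, and every evaluation below is constructible from it alone —
no external data.

*Group scenarios*: cell-means designs with given group sizes and error
variances; normal errors; under signal the true group means are
$(0, -1)$ for two groups and $(0, -0.33, -0.67, -1)$ for four; the contrast
tests equality of all group means; one VG per group. These emulate the
situation where each test (voxel) carries its own variance configuration.

*Regression scenarios*: one regressor of interest $x_1$ (linear trend on
$[-1, 1]$, or a half/half $\pm 1$ indicator), one nuisance $z_1$ (the
mean-centred squared trend, or a $-1/+1/-1$ quarter pattern), and an
intercept; the constructions make $x_1 \perp z_1$, and correlation $\rho$
can be induced via the Cholesky factor of the target correlation matrix.
Data are $Y = \beta_1 x_1 + 0.5\, z_1 + 1 + \epsilon$ with errors drawn
from a normal, uniform $(-\sqrt3, \sqrt3)$, exponential (rate 1, shifted) or
Weibull (shape $1/3$, strongly skewed) law, each standardised to zero mean
and unit variance; the Weibull constants come from $\Gamma$-function
moments rather than hard-coded numbers.

What the generator does *not* emulate: spatial correlation between tests,
non-Gaussian group errors in the group family, temporal autocorrelation,
or outliers. Passing simulations therefore speak to calibration and power
under independent tests with the stated error laws, not to robustness
against structured noise.

`run_error_power_study` simulates `n_reps` datasets and reports the
percentage with $p \le \alpha$ plus a 95% Wilson interval. Repetitions are
run either as the $V$ columns of a single vectorised call sharing one
shuffling set (`perms = "shared"`, the imaging situation, and the cheap
default) or with an independent shuffling set per dataset
(`perms = "fresh"`). The two have the same expectation; the shared variant
is slightly overdispersed relative to binomial sampling because all
repetitions share the shuffling draw, which is worth remembering when
comparing a shared-permutation estimate against its nominal Wilson
interval. `run_distribution_comparison` pools null statistics per variance
configuration and compares configurations pairwise with the two-sample
Kolmogorov–Smirnov test (Bonferroni-corrected within scenario): a pivotal
statistic keeps a near-$\alpha$ rejection fraction while a non-pivotal one
is rejected nearly always under strong heteroscedasticity.

## Numerical and design choices

* Pseudo-inverse rank tolerance: singular values below
  $\max(N, r)\,\varepsilon\,\sigma_{\max}$ are treated as zero.
* Exhaustive sets are used whenever the unique count does not exceed the
  requested $J$; $J$ is capped at the unique count (drawing more would only
  duplicate).
* The seed governs every random element (order randomisation, CMC draws,
  scenario simulation); studies derive a per-repetition seed ladder so any
  single repetition is reproducible in isolation.
* Problem sizes in the test suite are scaled down (e.g. 250 repetitions for
  the calibration reproductions, 50 repeats for the KS study, a
  16-scenario stratified grid for the strategy comparison); the package
  functions run the full-size studies unchanged.
* Default statistic `auto` and default method `freedman_lane` reflect the
  combination with the best observed calibration/power trade-off;
  Freedman–Lane and Smith stay within the nominal band far more reliably
  than Kennedy (anticonservative) or Still–White (mis-calibrated,
  especially with correlated nuisance), which the suite checks on the
  stratified grid.

## Known limitations

Rank-deficient designs are rejected rather than handled; weighted
least-squares fitting is out of scope (the weights enter only through the
statistic); spatial statistics (cluster extent/mass, TFCE) and
non-stationarity corrections are not implemented; variance-smoothed
pseudo-$t$ is not provided. For very small exhaustive sets the discreteness
of p-values makes the attainable test level coarser than $\alpha$ (e.g. 70
unique permutations give an effective one-sided level of $3/70 \approx
4.3\%$ at $\alpha = 0.05$), which is a property of the method, not an
implementation artefact.
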