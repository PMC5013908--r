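---
title: "Estimating Z-score noncentralities: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Z-score noncentralities: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wincurse)
```

## The estimation problem

A genome scan reports, for each of $k$ variants, a statistic
$X_i \sim N(\mu_i, 1)$ and its two-sided p-value $p_i = 2\Phi(-|X_i|)$.
The target of inference here is the *noncentrality* $\mu_i$ — the true mean
of each statistic — for **all** variants, not only the significant ones.
The naive estimate $\hat\mu_i = X_i$ is marginally unbiased but disastrous
for the variants one actually looks at: conditioning on being extreme,
$|X_i|$ overestimates $|\mu_i|$, sometimes badly. That selection bias is
the winner's curse.

All methods in this package shrink the observed statistics toward zero;
they differ in how the amount of shrinkage is chosen.

## FIQT

Multiple-testing adjustment of p-values and winner's curse adjustment of
Z-scores are the same operation viewed on two scales: both move the
evidence toward the null (p toward 1, Z toward 0). FIQT exploits this
by performing the adjustment on the scale where it is easy — the p-value
scale, via the Benjamini–Hochberg step-up — and transporting the result
back to the Z scale:

$$\hat\mu_i = \mathrm{sign}(X_i)\,\Phi^{-1}\!\left(1 - \frac{p_i^*}{2}\right),
\qquad p_i^* = \text{BH}(p_1,\dots,p_k)_i .$$

Properties that follow directly, and that the test suite asserts:

* **shrinkage**: $q_i \ge p_i$ implies $|\hat\mu_i| \le |X_i|$ always;
* **identity at $k=1$**: a single test has $q = p$ and the transform is
  exactly the identity (the implementation special-cases $q_i = p_i$ so
  this holds bit-exactly, not merely to rounding);
* **rank preservation**: BH is monotone on sorted p-values, so the
  ordering of $|\hat\mu|$ follows the ordering of $|X|$;
* $q_i = 1$ maps to exactly 0 — no epsilon fudging at the null point.

Numerical note: both directions of the transform run through R's
log-probability paths (`pnorm(..., log.p = TRUE)` and its inverse), so
p-values as small as $10^{-308}$ ($|Z| \approx 37.5$) survive the round
trip; the two-sided p-value is floored at the smallest positive double so
no q-value is ever exactly zero. Input statistics are assumed to have unit
sampling variance; the package applies no genomic-control rescaling — that
is the caller's responsibility. Missing statistics are excluded from the
FDR pool (so they do not distort $k$) and receive missing estimates.
Bonferroni and Holm variants of the back-transform are exposed
(`fiqt_with_mta`); they shrink at least as hard as FDR and are provided
for completeness, not benchmarked.

## Empirical Bayes via Tweedie's formula

With unit Gaussian noise, the posterior mean of $\mu$ given $z$ depends on
the data only through the *marginal* density $f$ of the observed
statistics:

$$E[\mu \mid z] = z + \frac{d}{dz}\ln f(z).$$

`fit_log_density()` estimates $\ln f$ by binning the statistics into 120
equal-width bins and fitting a Poisson log-linear regression of bin counts
on a natural cubic spline basis of the bin midpoints. The derivative is
the analytic derivative of the fitted spline expansion (the B-spline
design matrix differentiated before the natural-spline constraint
projection), never a finite difference of raw counts.

Tunable parameters, with defaults and rationale:

* `n_bins = 120` — enough resolution for genome-scale inputs while keeping
  dozens of counts per bulk bin; below $10 \times$ `n_bins` statistics the
  fit warns, below `n_bins` it refuses (the density is unidentifiable).
* `spline_df = 7` — chosen once against the Gaussian-prior closed form:
  with $\mu \sim N(0, \tau^2)$ the estimator must reproduce
  $E[\mu\mid z] = z\,\tau^2/(1+\tau^2)$; 7 df achieves mean absolute error
  $< 0.01$ at $k = 2\times10^5$ for $\tau^2 \in \{0.5, 1, 2\}$ while
  staying smooth in the tails. Exposed as a knob.
* Outside the fitted range the derivative clamps to its boundary value
  (with a warning): a natural spline is linear beyond its boundary knots,
  so the boundary derivative is the correct continuation, and unclamped
  extrapolation of the *density* would be meaningless anyway.

The printed form of the estimator in parts of the literature drops the
leading $z$ and keeps only the derivative term. We implement the full
formula: the derivative-only form estimates $-z$ on a pure null scan
(where $d\ln f/dz \approx -z$) instead of $0$, failing the most basic
calibration check.

**EB-n.** Scan statistics are locally correlated through linkage
disequilibrium (LD), which the pooled density fit ignores. `eb_n()` splits
the statistics, in genomic order, into $n$ interleaved sets (indices
congruent mod $n$), so members of one set sit $\sim n$ lags apart and are
quasi-independent. Each set gets its own density fit; each set density
scores *all* $k$ statistics; the final estimate is the arithmetic mean of
the $n$ set-specific vectors (assertable via `debug = TRUE`, which
attaches the per-set matrix). `eb_n(z, 1)` is bit-identical to
`tweedie_estimate(z)` — same code path.

## Tail adjustment

The classical correction adjusts only statistics that exceeded a selection
threshold $|Z| > c$. The literature defers the exact estimator to its
citations; we adopt the common core of those methods, the conditional MLE
of the truncated-normal likelihood:

$$\hat\mu(z) = \arg\max_\mu \;\ln\phi(z-\mu)
  - \ln\!\big(\Phi(\mu - c) + \Phi(-\mu - c)\big),$$

solved by bounded 1-D optimization on $[-|z|-1, |z|+1]$ to $10^{-6}$, on
$|z|$ with the sign restored (the likelihood is symmetric, so
$\hat\mu(-z) = -\hat\mu(z)$ exactly). The selection event is two-sided,
consistent with the two-sided p-value convention everywhere else. A
mean-bias-subtraction variant ($\hat\mu$ solving
$\mu = z - E[Z-\mu \mid |Z|>c]$, iterated to a fixed point) is exposed
behind `variant = "bias_sub"` but not benchmarked; the two differ
numerically only near the threshold. For large scans `approx_grid` solves
the MLE on a grid of $|z|$ nodes and interpolates monotonically — the
estimate is a smooth monotone function of $|z|$ for fixed $c$, so a few
hundred nodes reproduce the exact solution to $\sim 10^{-4}$.

Sub-threshold statistics pass through unchanged by default (the
alternative: return them as missing). In the cumulative evaluation
protocol the harness deliberately applies TA at *every* grid threshold,
including wildly non-significant ones — outside the method's intended use,
but required for a like-for-like comparison with estimators that adjust
the whole scan.

## The scan simulator

Simulating from genotypes is laborious; the simulator instead generates
the statistics directly with the two features that matter for evaluating
these estimators: realistic local correlation, and realistic effect sizes.

* **Residuals**: a stationary ARMA(3,4) process with
  AR = (0.8716, 0.9782, −0.851), MA = (−0.665, −0.998, 0.659, 0.025),
  a parameterization calibrated in the literature to scan statistics at
  ~1 SNP per kbp. The AR polynomial is near unit root (it evaluates to
  0.0012 at 1), giving lag-1 autocorrelation ≈ 0.52 with a slow decay —
  LD-like. Innovation variance is set from the theoretical stationary
  variance (via the MA(∞) weights), so the marginal variance is exactly 1
  by construction rather than by empirical rescaling; the near-unit root
  is why the default burn-in is 10,000 steps.
* **Effects**: `m1 = round(gamma_c * 180)` causal loci, patterned on the
  ~180 genome-wide-significant loci of the large human-height
  mega-analysis (~180,000 subjects). The actual published effect sizes
  live in supplementary material we do not redistribute; the packaged
  profile is synthetic — drawn once, under a fixed internal seed, from
  $5.45 + \mathrm{Exp}(\text{mean}=1.5)$, i.e. every locus genome-wide
  significant at the reference sample size with a realistically decaying
  tail. This is the largest interpretive choice in the package; the
  profile is pluggable (`build_true_means(..., profile = )`) so real
  reported values can be substituted.
* **Scaling**: noncentralities grow with the square root of the sample
  size, so a relative sample size $\gamma_s$ multiplies each peak by
  $\sqrt{\gamma_s}$ (quadrupling the cohort exactly doubles every
  noncentrality — asserted as an exact identity).
* **LD decay of means**: each causal locus spreads mean into its
  neighbors with the theoretical ARMA autocorrelation as the kernel,
  truncated where $\rho < 0.01$ (±822 SNPs for the default process) —
  the same correlation structure stands in for LD in both the noise and
  the signal. Causal loci are placed uniformly at random with a 1 Mb
  minimum spacing so ground-truth peaks do not confound each other.
* Positions are one synthetic chromosome at 1 SNP/kbp (stored as doubles:
  at the full 2,866,105-SNP scale base-pair positions exceed $2^{31}$).

What the simulator does **not** emulate: allele-frequency-dependent power,
non-Gaussian residuals from case–control imbalance, long-range LD blocks
(MHC-like), population stratification. Passing the benchmarks here shows
the estimators behave correctly under calibrated local correlation and
realistic effect magnitudes — not that real-data MSE curves are
reproduced numerically.

## Evaluation protocol

Metrics are cumulative over a $-\log_{10} p$ grid (default 0, 0.5, …, 8):
at threshold $t$ the SNP set is $S(t) = \{i : p_i \le 10^{-t}\}$ — all
statistics at least as significant as the threshold. (The alternative
reading, "less significant than", would make the TA comparison vacuous.)
Over $S(t)$: MSE, bias, the *population* variance of the errors (so
MSE = bias² + variance to machine precision), and R² as the squared
Pearson correlation between estimates and truth (the 1 − SS_res/SS_tot
variant is behind a flag). Replicate-level averaging with Monte-Carlo
standard errors is the default; it gives clean uncertainty estimates,
whereas pooling SNPs across replicates would hide between-replicate
variation.

Problem sizes used by the test suite and the acceptance script: null
benchmark $k = 10^5$ with 25 replicates; alternative benchmark
$k = 2\times10^5$, $\gamma_s = 2$, $\gamma_c = 1/4$, 25 replicates;
simulator fidelity at $k = 10^6$. These are desk-scale study conditions
chosen once for the package's own benchmarks; the full-scale design
($k = 2{,}866{,}105$, 250 replicates, the full $\gamma$ grids) is what the
defaults of `simulation_config()` describe.

**A scale-dependence worth knowing about.** With $\gamma_c = 1/4$ the
simulator plants 45 causal loci regardless of $k$, and the ±822-SNP decay
kernel then covers ~37% of a $2\times10^5$-SNP scan versus ~2.6% of the
full-scale scan. On such signal-dense scans the EB-1 marginal density
carries a lot of signal mass and EB-1 attains a lower *full-scan* MSE than
FIQT — the opposite of the full-scale ordering, where EB-1 never
outperforms FIQT under the alternative. The FIQT-versus-MLE dominance (in
both MSE and R², at every threshold) is stable across scales; the
FIQT-versus-EB-1 full-scan comparison is not, and the corresponding
benchmark test in the suite documents this by failing at desk scale. We
report this rather than re-scaling the causal count with $k$, because the
causal count is a study condition, not a free parameter.

## Future-cohort prediction

`scale_noncentrality()` multiplies estimates by $\sqrt{n_{\text{ratio}}}$;
`predict_significant()` converts to predicted p-values and applies a
*strict* $p < 5\times10^{-8}$ threshold (a predicted p exactly at the
boundary is not called); `cluster_regions()` merges flagged variants
within 250 kb by single linkage per chromosome, the standard clumping
reading of "within 250 kb". The inference is a point prediction — no
standard errors are attached to the estimates (a known limitation of the
transform in its present form), hence none to the regions. The extended
MHC (chr6:25–33 Mb) is handled as a user-supplied special interval in
`overlap_regions()`, not hard-coded.

## Degenerate inputs and numerical choices

* p-values outside $(0, 1]$, non-positive standard errors and non-finite
  statistics are domain errors (or dropped-and-counted rows when reading
  files); zero usable rows is an input error.
* A z/p pair disagreeing by more than $10^{-3}$ relative is reported,
  never silently repaired.
* Ties in p receive identical q-values; sorting is stable with original
  index as tie-break, so output is deterministic across platforms.
* `optimize()` non-convergence and Poisson-fit non-convergence surface as
  classed numerical errors with the offending values, distinguishable
  from configuration and input errors (the CLI maps the classes to exit
  codes 2/3/4).
* One master seed drives everything: `compare_methods()` draws one
  sub-seed per replicate, `simulate_scan()` splits its seed into a
  mean-structure seed and a residual seed (the former can be pinned to
  share a truth vector across replicates).

## Known limitations

* The synthetic effect profile approximates the shape, not the exact
  values, of the published height effects; region counts from real
  summary statistics will not match published counts exactly.
* FIQT is conservative (negatively biased) at very small p-values; it
  wins on variance, not bias.
* No standard errors on noncentrality estimates.
* FDR assumes correlations are local and not predominantly negative —
  reasonable for LD, wrong for systematically anti-correlated designs.
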