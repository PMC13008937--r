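---
title: "Methods: two-sample MR, screening and two-step mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, screening and two-step mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instruments
for an exposure $X$: if a variant affects the outcome $D$ only through $X$
(no horizontal pleiotropy), is associated with $X$, and is independent of
confounders, then the per-variant *Wald ratio*
$\hat\theta_j = \hat\beta_{Dj} / \hat\beta_{Xj}$ estimates the causal effect
of $X$ on $D$, with first-order standard error
$se_j = se_{Dj} / |\hat\beta_{Xj}|$. The package's primary estimator is the
inverse-variance weighted (IVW) average of the Wald ratios,

$$\hat\beta_{IVW} = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},
  \qquad w_j = se_j^{-2},$$

algebraically a weighted regression of $\hat\beta_{Dj}$ on $\hat\beta_{Xj}$
through the origin with weights $se_{Dj}^{-2}$. Four robust companions guard
against instrument invalidity under different assumptions: MR-Egger
regression (adds an intercept; its slope is consistent under the InSIDE
assumption and the intercept estimates the mean directional pleiotropic
effect), the weighted median (consistent when instruments carrying at least
half the weight are valid) and the simple and weighted mode estimators
(consistent when the largest group of instruments sharing one ratio is
valid). For a binary outcome all effects are log-odds, reported as
$OR = e^\beta$ with 95% bounds $e^{\beta \pm 1.96\,se}$; the geometric mean
of the bounds equals the point estimate by construction, which is the
structure of the conventional `OR(lower-upper)` table format.

Two-step mediation decomposes the total effect of an exposure on the outcome
through a mediator $M$: with univariable IVW estimates
$\alpha_{total}$ ($X \to D$), $\alpha_1$ ($X \to M$) and $\alpha_2$
($M \to D$), the product-of-coefficients method gives
$\alpha_{mediated} = \alpha_1\alpha_2$,
$\alpha_{direct} = \alpha_{total} - \alpha_{mediated}$, and the mediated
proportion $100\,\alpha_{mediated}/\alpha_{total}$ percent.

## Estimator details and numerical choices

* **IVW model.** The default is multiplicative random effects: the
  fixed-effect standard error $(\sum_j w_j)^{-1/2}$ is inflated by
  $\max(1, \sqrt{Q/(n-1)})$, where $Q$ is Cochran's statistic. This is the
  common default in two-sample MR tooling; under-dispersion is never allowed
  to shrink the error below the fixed-effect value. A `fixed` model is
  available by flag. With a single instrument the estimate and error collapse
  exactly to the Wald ratio.
* **P-values** are two-sided standard normal, matching the asymptotic theory
  and common tooling, rather than $t$-based.
* **MR-Egger** orients every instrument so the exposure effect is
  non-negative before regression (the intercept is orientation-dependent;
  this is the conventional choice) and uses the same multiplicative
  random-effects inflation, $\max(1, \hat\sigma)$ with $\hat\sigma^2$ the
  weighted residual mean square on $n-2$ degrees of freedom.
* **Weighted median.** Ratios are ordered; the estimate is the value at
  which the cumulative normalized inverse-variance weights cross one half,
  linearly interpolated between bracketing ratios. The standard error is a
  seeded parametric bootstrap: each ratio is resampled from
  $N(\hat\theta_j, se_j^2)$ with the weights held fixed. Instruments are
  sorted by identifier before resampling, so bootstrap errors are invariant
  to input order given a fixed seed.
* **Mode estimators.** The estimate is the argmax of a normal-kernel density
  of the ratios on a fixed 512-point grid spanning the ratio range padded by
  three bandwidths; the bandwidth is $\phi \times 0.9\,\min(sd, mad)\,
  n^{-1/5}$ (modified Silverman rule, $\phi = 1$ by default), falling back to
  the standard deviation when the median absolute deviation degenerates to
  zero, and returning the common ratio directly when all ratios coincide.
  The fixed grid makes the argmax deterministic; ties resolve to the lowest
  grid point. Standard errors use the same parametric bootstrap as the
  median.
* **Confidence multiplier.** All reported 95% intervals use the literal
  1.96, not `qnorm(0.975)`, so that reconstructing $(\beta, se)$ from a
  printed `OR(95%CI)` row and re-applying the transform reproduces the row
  exactly.
* **Degenerate inputs.** Instruments with a zero exposure effect are
  excluded from ratio-based estimators with a warning; estimators below
  their instrument minimum (3 for Egger, median and modes; 2 for Q and
  leave-one-out) raise errors, which `mr_fit()` converts to per-method
  warnings so a partial fit is still returned.

## Instrument processing

Instruments are selected on the exposure only (no Steiger filtering), at a
strict `p < 1e-5`, the conventional threshold for molecular-trait exposures
whose GWAS rarely yield multiple genome-wide-significant loci. Greedy
clumping retains variants in p-ascending order (ties broken
lexicographically by rsid, for determinism) and removes candidates within
10,000 kb of a retained same-chromosome variant at $r^2 \ge 0.001$ —
the de facto standard for these analyses; with no LD provider the rule is
distance-only. Harmonization aligns outcome to exposure effect alleles with
at most one flip (betas negated, frequencies reflected); strand-ambiguous
A/T and C/G variants are resolved by allele frequency when both frequencies
lie outside the configurable (0.40, 0.60) window and dropped as ambiguous
otherwise — a conservative handling, since misresolved palindromes corrupt
effect signs silently. Multi-base (indel-style) alleles are accepted and are
never palindromic. Duplicate identifiers keep the smallest p-value record.

The reverse-MR filter re-runs the same machinery with the disease GWAS as
the instrument source; an exposure is retained when the reverse p-value
exceeds 0.05. When the disease GWAS has no variant at the instrument
threshold the reverse test is *untestable*, and the screening layer excludes
such exposures rather than passing them — the conservative choice where the
convention is unsettled. The leave-one-out influence flag is a sign change
or departure from the full fit's 95% interval; published analyses typically
show the forest plot without a numeric rule, so the package fixes one for
reproducibility. The mediator screen requires a mediator→outcome IVW
p-value below 0.05 (strict inequality — where a boundary p-value of exactly
0.050 falls is ambiguous in published tables; this package documents and
uses strict `<`), and an exposure→mediator leg with IVW p < 0.05 whose five
estimates agree in sign. No multiple-testing correction is applied at any
screening stage, mirroring the raw-p screening practice this pipeline
reproduces; the inflation risk is real and an optional BH-FDR column is
available by flag (off by default).

## What the synthetic generator emulates

`sim_config()` fixes a causal diagram: `m_snps` independent biallelic
instruments explain `h2_x` of a unit-variance exposure; the exposure affects
a unit-variance mediator (`theta_xm`, trait units) which carries `m_snps_m`
instruments of its own explaining `h2_m`; exposure and mediator affect a
binary outcome on the log-odds scale (`theta_xd`, `theta_md`). The implied
true total effect is `theta_xd + theta_xm*theta_md`. Default sample sizes
anchor the three layers to the study conditions the package targets: a large
plasma-proteomics exposure GWAS (35,559), a small immune-phenotype mediator
GWAS (3,757) and a rare outcome with extreme imbalance (126 cases, 412,055
controls). Trait variance scales are not published for such panels, so all
continuous traits are standardized to unit variance and effects are per
allele on that scale.

Summary statistics are drawn directly from their asymptotic sampling
distributions: $\hat\beta \sim N(\beta_{true}, se^2)$ with
$se = 1/\sqrt{2nf(1-f)}$ for standardized continuous traits and
$se = 1/\sqrt{2f(1-f)\,n_{cases}n_{controls}/n}$ for the binary outcome.
This is fast, desk-scale and analytically auditable — e.g. the expected mean
instrument F-statistic is $1 + n\,h^2/m$. The defaults `m_snps_m = 15`,
`h2_m = 0.25` encode the observation that phenotypes instrumentable in a
GWAS of ~3,800 people must carry few, large-effect loci; smaller per-SNP
effects would never reach `p < 1e-5` at that sample size and the
mediator→outcome leg could never run. The individual-level oracle
(`simulate_individual_oracle()`) draws binomial genotypes, builds the traits
through the same diagram (logistic outcome with intercept matched to the
configured case fraction) and computes per-variant regressions directly;
under one seed both generators share identical ground-truth effects, so
their agreement is testable. The test suite compares them at
`n_subsample = 20000`.

Pleiotropy modes add direct SNP→outcome effects to the exposure
instruments: `balanced` draws them from a zero-mean normal, `directional`
shifts the mean. Direct effects are defined per *exposure-increasing*
allele — the orientation MR-Egger regresses in — because a directional mean
attached to raw allele codings would cancel across sign-symmetric exposure
effects and no estimator could (or should) detect it.

What the generator does **not** emulate: realistic LD (instruments are
mutually independent; an optional block-copy mode duplicates instruments
with a declared $r^2$ of 0.99 purely to exercise the clumping stage),
population stratification, sample overlap between the two samples, winner's
curse beyond threshold selection, non-collapsibility of the odds ratio at
large effect sizes, and allele-frequency differences between studies.
Passing tests therefore demonstrate the correctness and calibration of the
statistical machinery under clean two-sample asymptotics, not robustness to
the biases real consortium data carry.

## Problem sizes used by the checks

The packaged checks run at deliberately desk-scale sizes chosen to keep
Monte Carlo error small relative to their tolerance bands: type-I
calibration with 50 instruments over 1,000 replicates (binomial 3-SD band
around 0.05); mediated-proportion recovery over 200 replicates of the
`(0.4, 0.5, 0.8)` effect mix at the anchored sample sizes (median within two
Monte Carlo standard errors of 20%); Egger-intercept recovery over 200
directional-pleiotropy replicates; delta-method interval coverage over 500
replicates; and an end-to-end screen of 51 exposures × 11 mediators over 50
seeded registries, requiring the planted pair to top the ranking in at least
45 runs. That last bar deserves a note: the reverse-causality filter retains
a truly causal exposure only when a null reverse test lands above p = 0.05,
which happens 95% of the time by construction — an irreducible ceiling on
per-run recovery that the 90% bar leaves room for.

## Design decisions on open points

* The screening registry plants a handful of large-effect
  disease-susceptibility variants (minor-allele frequency 0.2–0.5, log-OR
  1.5 per allele) in the outcome GWAS. With 126 cases, no variant would
  otherwise ever reach the reverse-instrument threshold, every reverse test
  would be untestable, and the (conservative) exclusion rule would empty the
  screen.
* The mediated effect's interval uses the first-order delta method; the
  second-order term (`se_1^2 se_2^2`) is available by flag and only widens
  the interval. No interval is propagated onto the mediated *proportion*:
  ratio intervals are unstable when the total effect is near zero.
* The mediator→outcome leg is univariable IVW, not multivariable MR
  adjusting for the exposure. This is faithful to the two-step screening
  design it reproduces, but means `alpha_2` includes any exposure-mediated
  path back into the outcome; with strong exposure→mediator effects the
  mediated proportion can be over-stated. Multivariable MR is out of scope.
* A published worked example of this pipeline reports a total log-odds
  effect of −2.4800 alongside a table OR of 0.138 (ln 0.138 ≈ −1.98) for the
  same exposure. The discrepancy is not resolvable from printed values;
  `mrmediate` always reports the log-scale beta and the OR side by side so
  its own outputs cannot be ambiguous in this way.

## Limitations

Single mediators only (no joint multi-mediator decomposition); no MR-PRESSO,
contamination-mixture or robust-regression estimators; no proxy-variant
lookup or reference-panel LD; no liftover; summary statistics only. The
screening thresholds are raw p-values by design — users scanning thousands
of exposures should expect false positives at the advertised rates and may
enable the FDR column for context.
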