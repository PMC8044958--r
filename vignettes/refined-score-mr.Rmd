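---
title: "Refined-score Mendelian randomization with correlated instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refined-score Mendelian randomization with correlated instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrriver)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure $X$ (say, a blood metabolite) on an outcome $Y$ (say, years of
schooling) using genetic variants $Z_1, \dots, Z_p$ as instruments, with the
instrument–exposure associations $b_{XZ_i}$ and instrument–outcome
associations $b_{YZ_i}$ taken from two independent GWAS. Public summary
statistics come from *single-locus* regressions: each $b_{XZ_i}$ is the
marginal effect of $Z_i$ alone. When instruments are in linkage
disequilibrium (LD), each marginal effect absorbs part of its correlated
neighbours' effects, so treating the $b_{XZ_i}$ as weights of a combined
genetic score double-counts shared signal. The usual escape — pruning until
instruments are nearly independent — discards information.

## The model

Assuming $(X, \mathbf{Z})$ is multivariate normal with a linear
exposure model, the marginal effect decomposes into a direct effect plus
LD leakage:

$$ b_{XZ_i} = \tilde b_{XZ_i} + \sum_{j \ne i} \tilde b_{XZ_j}\,
   \theta_{Z_j Z_i}, $$

where $\theta_{Z_j Z_i} = \rho_{ij} \sqrt{\operatorname{var}(Z_j) /
\operatorname{var}(Z_i)}$ is the simple-regression slope of $Z_j$ on $Z_i$.
In matrix form $\mathbf{b}_{XZ} = \boldsymbol\theta\, \tilde{\mathbf
b}_{XZ}$, so the *refined* (multivariable-equivalent, direct) coefficients
are recovered by solving

$$ \tilde{\mathbf b}_{XZ} = \boldsymbol\theta^{-1} \mathbf{b}_{XZ}, $$

with $\rho_{ij}$ and $\operatorname{var}(Z_i)$ taken from an external LD
reference panel — no individual-level data are needed. A useful identity:
when $\boldsymbol\theta$ is estimated from the *same* sample as the
single-locus fits, $\boldsymbol\theta^{-1}\mathbf{b}_{XZ}$ equals the
multivariable OLS coefficients exactly (both reduce to
$S_{ZZ}^{-1} S_{ZX}$); the package exploits this as an internal oracle in
its tests.

The refined coefficients weight a composite genetic score
$GS = \sum_i \tilde b_{XZ_i} Z_i$, whose Wald ratio gives the causal
estimate. Using $1/\operatorname{var}(b_{YZ_i})$ as a proxy for the
genotype variance yields the summary-data estimator

$$ \hat\beta_{XY} = \frac{\sum_i \tilde b_{XZ_i}\, b_{YZ_i} /
   \operatorname{var}(b_{YZ_i})}{\sum_i \tilde b_{XZ_i}\, b_{XZ_i} /
   \operatorname{var}(b_{YZ_i})}, \qquad
   \operatorname{se}(\hat\beta_{XY}) = \frac{\sqrt{\sum_i \sum_j \rho_{ij}
   \tilde b_{XZ_i} \tilde b_{XZ_j} / (s_i s_j)}}{\left|\sum_i \tilde
   b_{XZ_i} b_{XZ_i} / s_i^2\right|}, $$

with $s_i = \operatorname{se}(b_{YZ_i})$, and $u = \hat\beta_{XY} /
\operatorname{se}(\hat\beta_{XY})$ referred to the standard normal. The
denominator of the variance expression is the square of the estimator's own
denominator; with independent instruments and unrefined weights
($\tilde b = b$, $\rho = I$) both the estimate and the standard error
collapse to classical fixed-effect IVW, which the test suite asserts to
1e-10.

Two comparators are provided behind the same interface: `mr_ivw()`, the
generalized IVW estimator weighting by the full outcome covariance
$\Omega_{ij} = \rho_{ij} s_i s_j$, and `mr_gls()`, a GSMR-style generalized
least-squares combination of per-SNP Wald ratios with first-order
delta-method variances. The GLS comparator is deliberately simplified
(single-pass outlier filtering, first-order variances): it is a faithful
baseline for simulation comparisons, not a re-implementation of the
released GSMR software.

## Pipeline and tunable parameters

`run_mr()` chains the stages and logs instrument attrition at each:

1. **Harmonization** (`harmonize()`): restrict to shared SNPs, align the
   outcome to the exposure's effect allele (sign-flipping swapped records),
   drop palindromic A/T and C/G SNPs with effect-allele frequency in
   [0.4, 0.6] on either side (window configurable; the conservative
   community default — at those frequencies strand cannot be resolved from
   frequency), drop SNPs absent from the LD reference.
2. **Instrument selection**: exposure p-value below `p_threshold`
   (default 5e-8, genome-wide significance).
3. **LD pruning** (`ld_prune()`): greedy clumping — visit SNPs by ascending
   exposure p-value, keep a SNP iff its $r^2$ with everything already kept
   is at most `r2_prune` (default 0.5; the selection rule is the standard
   clumping convention). A looser threshold keeps more correlated
   instruments for the refinement step to exploit.
4. **Pleiotropy filtering** (`heidi_filter()`): each SNP's Wald ratio is
   tested against the top instrument's (smallest exposure p-value); the
   difference's delta-method variance includes the LD-induced covariance
   with the reference SNP, and SNPs with heterogeneity p below
   `heidi_alpha` (default 0.01, the conventional default for this filter)
   are removed in a single pass. Skipped with a warning below 3
   instruments.
5. **Refinement and estimation**: `build_theta()` + `refine_coefficients()`
   + the requested estimators; Bonferroni adjustment across the scan
   (`m_tests` lets a caller adjust within a larger family).

`refine_coefficients()` refuses to solve when the slope matrix's condition
number exceeds `max_condition` (default 1e6) and advises stricter pruning:
the inversion is exact, so conditioning is governed entirely by how
correlated the retained instruments are, and an explicit failure beats a
silently unstable pseudo-inverse. The solve is a linear system, never an
explicit inverse, and the reconstruction residual
$\|\boldsymbol\theta \tilde{\mathbf b} - \mathbf b\|_\infty$ is checked
against 1e-10.

By default `build_reference()` computes per-SNP variances as the
Hardy–Weinberg value $2\hat p(1-\hat p)$, matching the situation where only
allele frequencies are available from a public panel; `"empirical"` mode
(sample column variances) is used for Gaussian instruments in the
simulation studies. Missing dosages are handled pairwise-complete rather
than by dropping individuals panel-wide.

## What the simulators emulate

Two study designs are built in, and their defaults *are* the study
conditions; they are not tuned per run.

**Refinement study** (`simulate_refine_study()`): six instruments from an
equicorrelated multivariate normal (correlation 0–0.9), direct effects
drawn $N(\mu, 1)$ with $\mu \in \{-1, -0.5, 0.5, 1, 1.5, 2\}$, unit
exposure noise, analysis sample 1,000, external panel 5,000, 2,000
replicates. Each replicate returns the truth, the single-locus estimates,
the refinement through the external panel, the refinement through the
analysis sample's own correlation matrix, and the multivariable OLS oracle.

Calibration is summarized two ways by `summarize_refine_study()`. Because a
SNP's LD leakage ($\rho \sum_{j \ne i} \tilde b_j$) is *uncorrelated* with
its own true effect when effects are drawn independently, an ordinary
regression of estimate on truth has slope near 1 for every estimator and
hides the single-locus bias in its intercept ($\approx \rho (p-1) \mu$).
The proportional (through-origin) slope $\sum xy / \sum x^2$ is therefore
the calibration summary of record here: it is 1 in expectation for any
unbiased estimator and about $1 + \rho(p-1)\mu^2/(1+\mu^2)$ for the
single-locus estimates (about 3 at $\rho = 0.5$, $\mu = 2$). Both are
reported.

**Estimator study** (`simulate_mr_study()`): $J \in \{5, 10, 15, 20\}$
equicorrelated instruments, each explaining 0.005 of the exposure variance
(so $R^2_{ZX} = 0.005 J$), $R^2_{XY} \in \{0.05, 0.1, 0.15, 0.2\}$ under
the alternative, causal effect $b_{XY}$ (0 under the null, 1 for power),
exposure GWAS 1,000, outcome GWAS 1,500, LD panel 5,000, all three samples
independent, 2,000 replicates. Instrument coefficients are drawn
$U(0, 0.5)$ and then rescaled to a common magnitude: under equicorrelation
an equal-magnitude vector is the only one giving every instrument an
exactly equal share of the genetic variance, and the exposure-noise
construction fixes the total $R^2_{ZX}$ exactly regardless of the
coefficients' scale. Summary statistics are per-SNP simple regressions with
the usual OLS standard errors; every estimator sees identical inputs.

What these simulators do *not* emulate about real data: genotypes are
Gaussian rather than discrete (a separate generator,
`make_fixture_panel()`, produces 0/1/2 dosages by thresholding correlated
latent Gaussians at Hardy–Weinberg cutpoints, and feeds the I/O and
LD-estimation tests); LD is equicorrelated rather than block-structured; no
horizontal pleiotropy is generated, so passing tests show calibration and
efficiency under valid instruments, not robustness to invalid ones; allele
coding issues never arise. Results on real data also depend on the match
between the LD panel's population and the GWAS samples, which the
simulations idealize.

Two known behaviours worth naming. First, at the design's instrument
strength (per-instrument $R^2$ of 0.005 with an exposure GWAS of 1,000) the
instruments are individually weak, and all three estimators show the usual
two-sample attenuation toward the null under the alternative; the bias
shrinks as the exposure GWAS grows, which the test suite demonstrates at
larger $n_1$. Second, the refined-score and IVW point estimates track each
other closely — with unrefined weights they coincide exactly — and their
operating characteristics differ mainly through the standard errors.

## Mediation

`sobel_test()` implements the normal-approximation test of an indirect
effect $ab$ with $\operatorname{se} = \sqrt{a^2 se_b^2 + b^2 se_a^2}$, and
`two_step_network()` links two collections of MR estimates (upstream →
mediator, mediator → outcome), emitting a Sobel record for every pair
significant in both steps. Significance within each step uses
Bonferroni-adjusted p-values at `alpha` (default 0.05), mirroring the main
scan's correction; step-2 estimates are reused as-is rather than
re-estimated after removing mediator-associated SNPs.

## Numerical choices and degenerate inputs

- Ties in the pruning and reference-instrument orderings break
  lexicographically by SNP id, making every greedy pass deterministic.
- `mr_river()` errors when $\sum \tilde b_i b_{XZ_i} / s_i^2 = 0$
  (instruments collectively null for the exposure) rather than dividing by
  zero, and rejects a non-positive-semidefinite user-supplied correlation
  matrix via the sign of the variance quadratic form.
- `mr_gls()` requires every $b_{XZ_i} \ne 0$ (the Wald ratio is undefined
  otherwise).
- A monomorphic SNP in the reference panel is a hard error naming the SNP:
  zero variance breaks both the correlation and the slope matrix.
- Wald p-values use the standard normal, not a t distribution: the test
  statistic is asymptotically standard normal, and GWAS sample sizes make
  the distinction immaterial.
- `sobel_test(0, ., 0, .)` defines $z = 0$, $p = 1$.
- All generators are seed-deterministic; the seed is part of each study
  configuration.

## Problem sizes used in the shipped checks

The packaged test-suite runs reduced-replicate versions of both studies
(tens to low hundreds of replicates) for the structural and qualitative
checks, and the full 2,000-replicate study conditions for the operating
characteristics; the latter complete in a few minutes on a single core.
`scripts/acceptance.R` re-runs the full null study from scratch at a
user-supplied seed.

## Limitations

- Instruments must jointly satisfy the MR assumptions after the pleiotropy
  filter; nothing here tests the exclusion restriction directly.
- The refinement presumes the LD reference reflects the GWAS populations;
  a mismatched panel propagates directly into the refined weights.
- Binary outcomes, MR-Egger, weighted-median and multivariable-exposure
  designs are out of scope.
- Genome-build liftover and rsID/position resolution are not performed:
  inputs must share an identifier space.
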