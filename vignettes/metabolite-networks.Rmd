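---
title: "Case-control metabolomics: association scans and partial-correlation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control metabolomics: association scans and partial-correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabnet)
library(dplyr)
```

## The problem this package addresses

Untargeted serum metabolomics compares hundreds of semi-quantitative
metabolite intensities between disease cases and population controls. The
setting metabnet is built for is a three-group design — two dopaminergic
movement disorders, Parkinson's disease (PD) and restless legs syndrome
(RLS), against a large population control sample — where the scientific
questions are (i) which metabolites differ in each disease, (ii) which
differences are disease-specific rather than shared (shared unidirectional
changes are confounded with dopaminergic medication and pre-analytical
differences between case and control sampling), (iii) how the affected
metabolites sit inside the metabolite-metabolite dependence network, and
(iv) whether candidate disease SNPs shape metabolite levels in the healthy
population ("metabotypes").

The package implements the full analysis chain as composable, tested
functions: run-day normalization, missingness filtering, chained-equations
imputation, per-metabolite linear-model scans with Bonferroni control,
all-pairs ratio scans with the p-gain statistic, shrinkage-based Gaussian
graphical model (GGM) inference with a dual-significance edge rule, and a
candidate-SNP metabogenomic scan. A synthetic cohort generator with known
ground truth makes every stage testable end to end.

## Preprocessing model

**Run-day normalization.** MS intensities drift day by day with column and
instrument state. For each metabolite, every value is divided by the median
of that metabolite on its run day and multiplied by the metabolite's overall
median (both over observed values only):

$$x'_{sm} = \frac{x_{sm}}{\mathrm{med}_{d(s)m}} \cdot \mathrm{med}_m .$$

After the operation, every day's median equals the metabolite's overall
median, which makes the operation idempotent. One subtlety is worth stating
precisely: rescaling a single day's raw values by a constant cancels inside
the day-median ratio, but it can move the *overall* median, so the
normalized values change by one metabolite-wide factor. That factor carries
no information and vanishes after log transformation and standardization,
which is the scale all downstream inference uses. Medians are sample
medians with midpoint interpolation for even counts.

**Order of operations.** The chain is fixed as normalize → log → filter →
impute → standardize. Filtering and imputation sit on the log scale because
the chained regression imputation assumes approximately Gaussian
conditionals, which log-intensities satisfy far better than raw
intensities.

**Missingness filtering.** Metabolites with strictly more than 20% missing
values are removed first; then samples with strictly more than 10% missing
values over the retained metabolites. The strict inequality means a
metabolite missing in exactly 20% of samples stays in.

**Imputation.** Remaining missing cells are filled by chained equations:
each incomplete metabolite is regressed on all others (observed values plus
current imputations), starting from per-metabolite means, sweeping until
the largest change drops below 1e-4 or 20 sweeps. The default is
deterministic conditional-mean imputation so that downstream networks are
exactly reproducible; `draws = TRUE` switches to stochastic imputation with
residual-SD noise for uncertainty exploration. A numerically singular step
falls back to a small ridge penalty (1e-4 on the normal equations) with a
warning. Observed cells are never altered.

## Association scans

Each metabolite's log concentration is modelled by ordinary least squares
on a case indicator plus adjustment covariates — age and sex for all three
contrasts (PD vs control, RLS vs control, PD vs RLS). Samples missing the
response or a covariate are dropped listwise. Metabolome-wide significance
uses the Bonferroni level $\alpha/p$ with $p$ the number of metabolites
*profiled* (456-equivalent), not the post-filter count; with
$\alpha = 0.05$ and 456 metabolites the per-test threshold is
$1.0965 \times 10^{-4}$. The candidate-SNP scan corrects over the whole
grid, $0.05/(32 \cdot 456) = 3.43 \times 10^{-6}$.

Metabolites are then classified by where they reach significance:
`shared_unidirectional` (both diseases, same direction — treated as
suspect: drug effects or serum-tube artifacts), `pd_unique`, `rls_unique`,
`discordant` (both, opposite directions), and the direct `pd_vs_rls` set.

The scan is implemented as multi-response least squares (one QR per
contrast design, all metabolites at once); `fit_metabolite_model()` is the
single-metabolite `stats::lm()` reference path, and the test suite checks
the two agree to 1e-10.

## Ratio scans and the p-gain

For every unordered metabolite pair the same model is fitted to
$\log a - \log b$. Because least squares is linear in the response, the
ratio coefficient is the difference of the single-metabolite coefficients
and its standard error follows from residual cross-products, so the full
$p(p-1)/2$ scan (103,740 pairs at $p = 456$) needs only one fit and one
cross-product matrix. Each pair carries the p-gain
$\min(p_a, p_b) / p_{\mathrm{ratio}}$; a large value means the ratio is far
more strongly associated than either metabolite alone, the classical proxy
signature of a shared enzymatic conversion. Pairs are Bonferroni-controlled
over the pair count. A pair whose ratio response is essentially constant
(duplicated metabolite) is flagged `degenerate` and reported
non-significant rather than fitted.

## Gaussian graphical model

Partial correlations are estimated after residualizing age, sex, and the
two disease indicators out of the standardized matrix (regressing out and
then correlating is equivalent to augmenting the conditioning set for
linear effects, and simpler to test). The correlation matrix $R$ is shrunk
toward the identity with the analytic intensity

$$\lambda^\* = \frac{\sum_{i<j} \widehat{\mathrm{Var}}(r_{ij})}{\sum_{i<j} r_{ij}^2},
\qquad \hat R = (1-\lambda^\*) R + \lambda^\* I,$$

with $\widehat{\mathrm{Var}}(r_{ij})$ the unbiased empirical variance of
the standardized product terms. This keeps $\hat R$ positive definite even
with metabolite counts near the sample count, and $\lambda^\*$ shrinks to
zero as information grows. Partial correlations come from the inverse
$\Omega = \hat R^{-1}$ as
$\rho_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$.

**Edge rule.** An edge is called when *both* the Pearson correlation and
the partial correlation are significant at the Bonferroni-corrected level
$\alpha$ over the number of metabolite pairs (the most conservative
reading of "corrected over pairs"). Additionally, pairs with a near-zero
Pearson correlation ($|r| < 0.05$) but a negative partial correlation are
flagged as sign artifacts — the signature of conditioning on a common
effect (collider) — and excluded regardless of significance. The 0.05
"zero" cutoff is this package's operationalization; no numeric value is
standard.

**Edge significance.** The default test is the Fisher z-transform,
$z = \operatorname{atanh}(r)\sqrt{n - 3 - q}$ with $q = 0$ for marginal
and $q = p - 2$ for full-order partial correlations, referred two-sided to
the standard normal. A per-pair permutation test (B = 1000 by default,
add-one correction $p = (b+1)/(B+1)$, permuting one member's
covariate-residual) is available both as a validation route and as the
automatic fallback when $n - 3 - q < 1$. The software originally used in
this field estimates edge significance from an empirical-null mixture
fitted to the observed partial correlations; we chose Fisher-z and
permutation instead because both are reproducible from first principles
and make the null hypothesis explicit. For moderate p-values the routes
agree within a factor of two, which the test suite verifies.

## Metabogenomic scan

Within controls only, each (SNP, metabolite) pair is tested by OLS of the
log concentration on the additive allele dosage plus nine cofactors: BMI,
age, sex, HDL, LDL, total cholesterol, triglycerides, hypertension and
diabetes (the latter two as 0/1 indicators; missing cofactors are dropped
listwise). SNPs failing a Hardy-Weinberg chi-square test (p < 5e-6) or a
1% minor-allele-frequency floor are excluded before testing; fractional
(imputed) dosages skip the HWE test with a warning. Only the additive
genetic model is implemented — the field default for metabotype scans.

## The synthetic cohort generator

`simulate_cohort()` draws a full study with known truth. It emulates, in
order:

| feature | default | rationale |
|---|---|---|
| group sizes | 1272 / 82 / 95 | control, PD, RLS counts of the target design |
| ages | truncated normal (≥ 18): 64.1 ± 5.5, 70.0 ± 8.7, 60.6 ± 17.0 | group means/SDs of the target design |
| sex (% female) | 47.7 / 50.0 / 70.5 | idem |
| metabolites | 456, latent log-normal | platform size |
| dependence | sparse precision matrix, density 0.02, edge magnitudes U(0.3, 0.6) | implied partial correlations ≈ 0.15-0.45, the strength of biochemically adjacent pairs in real serum GGMs |
| run days | 20, multiplicative per-(day, metabolite) log-normal factors, SD 0.3 | day-dependent instrument drift |
| missingness | left-censoring below the 5% control quantile + 1% random | MS dropout is intensity-dependent |
| group effects | 30 metabolites per disease (disjoint), standardized shifts N(0, 0.5) | mean-shift alternative for the scans |
| genotypes | 32 SNPs, MAF U(0.1, 0.5), Hardy-Weinberg | candidate-SNP panel |
| SNP effects | 4 pairs, 0.3 latent-SD per allele | detectable metabotypes at n = 1272 |

The precision matrix starts from unit diagonal plus the random edge
entries, and the diagonal is raised uniformly only as far as needed to keep
the minimum eigenvalue at 0.1. This keeps the implied partial correlations
close to the drawn edge magnitudes for low-degree nodes, diluting them only
where hubs force it; a purely diagonally dominant construction would crush
all partial correlations at realistic dimensions. Draws are retried until
every edge implies $|\rho| \ge 0.05$.

The generator reproduces the *statistical* structure the pipeline assumes,
not the platform: there are no peak shapes, retention times, adduct or
identification errors, no biologically clustered metabolite classes, no
linkage disequilibrium between SNPs, and the missingness mechanism is a
sharp per-metabolite threshold rather than a probabilistic detection curve.
Passing recovery tests therefore demonstrates correctness of the
statistics under the assumed model, not performance on any real cohort.
Two observable consequences of the assumed model are worth knowing:
left-censoring plus listwise deletion biases the weakest injected effects
slightly toward the null (the tests assert 90% of injected effects inside
±3 SE rather than all of them), and shifts right at the 0.5 SD boundary sit
near 75% power at the default sample sizes, so only shifts ≥ 1 SD are
asserted to be found always.

## Numerical choices and degenerate inputs

* Medians: `stats::median()` midpoint interpolation; run-day cells with no
  observed values stay missing with a warning; a zero day median is an
  error (raw intensities must be positive).
* Scale discipline: the matrix container carries a scale tag
  (RAW → NORMALIZED → LOG → STANDARDIZED) and each stage refuses input on
  the wrong scale.
* Rank-deficient designs abort with the offending columns named; the
  imputation sweep alone degrades to ridge with a warning, since dropping a
  metabolite mid-sweep would silently change the model.
* Shrinkage with forced `lambda = 0` on a singular correlation matrix
  aborts and advises a floor; `lambda = 1` yields the identity and all-zero
  partials.
* Permutation p-values are never zero by construction (add-one).
* Sex is coded MALE = 0 / FEMALE = 1 in all designs; swapping case and
  reference groups exactly negates effect estimates.

## Problem sizes used by the test and acceptance runs

The suites exercise the full default cohort (1449 samples × 456
metabolites) for the association scans, where the fast multi-response path
makes a scan take about a second, and scale the network analyses to p = 50
metabolites at the full sample size (edge recovery: precision ≥ 0.9,
recall ≥ 0.6 against the generator truth) and p ≤ 20 for the specificity
and calibration checks. Permutation comparisons run at p = 5, n = 200 with
B = 2000. These sizes give stable verdicts for every property while the
whole suite stays interactive. At p = 50 the injected group-effect count is
reduced to 5 per contrast (the default 30 + 30 would exceed the metabolite
count).

## Known limitations

* Conditional-mean imputation underestimates the variance of imputed cells;
  for inference that must propagate imputation uncertainty, use
  `draws = TRUE` with multiple seeds.
* The Fisher-z test on *shrunk* partial correlations is conservative when
  $\lambda^\*$ is large (strong shrinkage attenuates the statistic); with
  very weak dependence structures, edge recall drops before specificity
  suffers.
* Bonferroni control over 103,740 ratio tests is extremely strict; the
  p-gain ordering of `top_ratios()` is usually the more informative output.
* The mGWAS applies only MAF and HWE filters; call-rate filtering, phasing
  and imputation quality are assumed handled upstream.
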