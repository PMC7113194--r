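---
title: "Estimating SNP heritability of trait averages and longitudinal changes"
author: "longherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating SNP heritability of trait averages and longitudinal changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longherit)
```

## The problem

Repeated biennial measurements of quantitative traits in a middle-aged
community cohort carry two distinct heritable signals: a subject's
*average* trait level, and the *rate at which the trait changes* over the
follow-up window. Cross-sectional SNP-heritability estimates blur the two
and are diluted by visit-to-visit measurement noise, which differs
markedly between examination waves. `longherit` implements a two-stage
procedure that separates the signals and estimates the SNP heritability
of each, with a per-SNP association scan on the same derived phenotypes.

## The model

**Stage 1 (period weights).** For each trait $k$ and visit period $j$,
the trait is regressed across subjects on sex, age and the top 10
principal components of the genetic relationship matrix. The residual
variance $w_{jk}$ of that cross-sectional regression measures how noisy
period $j$ is for trait $k$ after removing systematic covariate effects.
These variances differ clearly between waves (heteroscedasticity), which
is the motivation for weighting.

**Stage 2 (subject trajectories).** For each subject $i$, the observed
values are fit by weighted least squares to

$$y_{ij} = B_{0i} + B_{1i}\,(\mathrm{age}_{ij} - \overline{\mathrm{age}}_i) + \varepsilon_{ij},$$

where $\overline{\mathrm{age}}_i$ is the unweighted mean of the subject's
observed ages. $B_0$ is therefore the expected trait value at the
subject's own mean age and $B_1$ the average change per year. The default
observation weight is $1/w_{jk}$ — the standard heteroscedasticity
correction that down-weights noisy periods. The defining equation can
also be read literally as $\mathrm{Var}(\varepsilon_{ijk}) =
\sigma^2_{ik}/w_{jk}$ with $w_{jk}$ *called* a residual variance, which
would give noisy periods *more* weight; because the two readings
contradict each other we default to the statistically standard direction
and expose the literal one behind `weightScheme = "literal"` in
`fitSubjectTrajectories()`.

**Stage 3 (GREML).** $B_0$ and $B_1$ are analysed strictly separately.
For response $y \in \{B_0, B_1\}$ the variance-component model is

$$y = X\beta + \textstyle\sum_c g_c + e, \qquad
  \mathrm{Var}(g_c) = A_c\,\sigma^2_{g,c}, \quad \mathrm{Var}(e) = I\sigma^2_e,$$

with $X$ holding intercept, subject mean age and sex, and $A_c$ a genetic
relationship matrix — a single genome-wide GRM for overall
$h^2_{\mathrm{snp}} = \sum_c \sigma^2_{g,c} / (\sum_c \sigma^2_{g,c} +
\sigma^2_e)$, or 22 per-chromosome GRMs for the partitioned analysis.
The GRM uses the standardized-dosage estimator with the distinct diagonal
form (the GCTA estimator), in-sample allele frequencies, and pairwise
deletion of missing genotypes with per-pair SNP counts. Estimation is by
restricted maximum likelihood: one expectation-maximization burn-in step
followed by average-information updates. Because the null value of a
variance component lies on the boundary of its parameter space, the
likelihood-ratio statistic against the no-genetics null is referred to a
50:50 mixture of a point mass at zero and $\chi^2_1$; an observed
statistic of zero thus has $p = 0.5$.

**GWAS.** Each SNP is tested by ordinary least squares of the response on
intercept, dosage, mean age, sex and 10 PCs, with a two-sided t-test on
the dosage coefficient. Genome-wide significance is declared strictly
below $10^{-7}$ and suggestive significance strictly below $10^{-5}$;
Benjamini–Hochberg adjustment (via `stats::p.adjust`) is applied across
traits for the heritability tests and is available within trait for the
association scan, whose tables report raw p-values by default.

## Tunable parameters

* **QC thresholds** (`applySnpFilters()`, `applySampleFilters()`): HWE
  $p < 10^{-5}$, MAF $< 0.05$, SNP call rate $< 95\%$, sample missingness
  $> 5\%$ — all strict inequalities, so boundary values survive. A SNP
  failing several rules is counted once, under HWE → MAF → call-rate
  precedence; sample filtering runs before SNP filtering, and counts
  depend on that order. MAF and HWE use non-missing calls only. The HWE
  default is the 1-df chi-square goodness-of-fit test; the exact
  conditional test is available via `hweExact = TRUE`. The two disagree
  in ordering around extreme thresholds for sparse tables (the chi-square
  test is anticonservative at low minor-allele counts — e.g. counts
  (1, 0, 19) give chi-square $p \approx 8\times10^{-6}$ but exact
  $p \approx 0.026$), which is worth knowing when the panel contains rare
  variants.
* **Inclusion rules** (`filterMinMeasurements()`,
  `excludeSparseTraitPeriods()`): subjects need at least 3 non-missing
  visits per trait; a (trait, period) cell with missing rate strictly
  above 0.5 is dropped for that trait.
* **Transforms** (`traitConfig()`): right-skewed traits are analysed on
  the natural-log scale; non-positive values under a log flag become
  missing with a warning.
* **REML** (`fitGREML()`): convergence requires a restricted
  log-likelihood change below $10^{-4}$ and a relative change of the free
  components below $10^{-8}$; components are clamped at $10^{-6}\times$
  the phenotypic variance; the iteration cap is 100.
* **PCs** (`computePCs()`): 10 components by default, eigenvectors scaled
  by the square root of their eigenvalues, sign fixed by making the
  largest-magnitude loading positive so covariate files are reproducible.

## The synthetic cohort generator

`simConfig()` + `simulateGenotypes()` + `simulateLongitudinalPhenotypes()`
emulate the design the pipeline targets: six biennial visit periods,
baseline age uniform on 40–69 years, per-period visit noise, independent
visit missingness (10% by default) and an optional whole-period dropout
knob to exercise the sparse trait-period exclusion. Genotypes are
Binomial(2, p) at frequencies uniform in the configured MAF range —
Hardy–Weinberg proportions with **no linkage disequilibrium, no
population structure and no genotyping error**; passing tests therefore
validate the estimators under their own model assumptions, not robustness
to stratification or LD, which is exactly what parameter-recovery testing
requires.

Subject intercepts and slopes are polygenic-plus-environment:
`h2 * var` of each is a polygenic score from i.i.d. Gaussian effects on
standardized dosages, rescaled so the realized in-sample genetic variance
hits its target exactly (this makes recovery tests sharp at moderate
sample sizes); the environmental remainder is drawn with the
complementary variance, independent between intercept and slope by
default with a configurable correlation, since the two-stage model itself
takes no stance on their joint distribution.

Default magnitudes were chosen once to mimic a realistic epidemiological
design: intercept variance 1, slope variance 0.25, period noise variances
`c(1.0, 1.3, 0.9, 1.2, 0.8, 1.1)` — heteroscedastic around 1. Under this
design a subject observed at all six visits contributes
$\sum_j (\mathrm{age}_j - \bar{\mathrm{age}})^2 = 70$ years² of age
spread, so the sampling variance of a fitted slope is roughly
$\bar w / 70 \approx 0.015$ against a true slope variance of 0.25: slope
reliability $\approx 0.94$. Slope heritability estimates are therefore
attenuated by about 6% relative to the generating value — visible but
small, as in a well-designed 10-year follow-up. Severely noisy designs
(slope variance far below $\bar w/70$) would attenuate $B_1$ heritability
toward zero; that regime is a property of the design, not of the
estimator.

## Numerical choices

* **Active-set AI-REML on the log scale.** After the EM burn-in, Newton
  steps are taken in log-variance coordinates, which cannot overshoot
  past zero and stay conditioned when components differ by orders of
  magnitude; the largest per-component move is a factor e³, enforced by
  rescaling the whole step so it keeps the ascent property of the
  (positive semi-definite) average-information direction. Components
  hugging the non-negativity floor with a negative score are pinned
  there and the AI system is re-solved for the free components — their
  diverging log-steps would otherwise drown the free moves. Steps that
  decrease the restricted likelihood are halved in log space (up to 20
  times), then replaced by the monotone EM update. Floored components
  are excluded from the component-change convergence criterion, and
  convergence is only declared on an unhalved step.
* **Boundary-ridge polish.** The GCTA diagonal makes the GRM slightly
  indefinite, so fits approaching h² = 1 sit on a curved
  positive-definiteness boundary of V where the AI line search can jam,
  and where the average information grossly overstates the curvature
  along the ridge — the step-size criteria can then pass while the
  gradient is still visibly nonzero. The fit therefore checks the
  log-scale score at its final iterate and, when it is not numerically
  zero (or the iteration failed outright), re-maximizes the same
  restricted likelihood with restarted Nelder–Mead simplexes on the
  floored log scale, started from both the current iterate and the best
  point of a coarse grid. This optimizer cascade is standard practice in
  mixed-model software; it engages only for the small-sample boundary
  fits that need it.
* **Initialization** is equal shares of the phenotypic variance across
  all components.
* **Non-identifiability.** A GRM numerically equal to the identity makes
  $\sigma^2_g$ and $\sigma^2_e$ indistinguishable; the average-information
  matrix is singular and the fit reports status `"non-identifiable"`
  rather than an arbitrary interior estimate.
* **Non-positive-definite inputs.** If the covariance fails its Cholesky
  factorization at initialization, a ridge of $10^{-6}\times$ phenotypic
  variance is added with a warning.
* **Boundary LRT.** The full model's likelihood at a floored component
  sits a hair *below* the analytic null optimum; deficits smaller than
  $10^{-3}$ are clamped silently, larger ones warn.
* **Standard errors** come from the inverse average-information matrix,
  with the delta method for $h^2$.
* **Degenerate stage-2 subjects** (all visits at one age) are dropped
  with a warning; a subject with exactly two visits gets residual
  variance 0 by convention.
* **Stage-1 covariate age is raw age**, not centred age — the choice
  affects only the intercept of the stage-1 regression, not the residual
  variance that is actually used. The per-subject residual scale is
  carried in the trajectory table but unused downstream by default.

## Design choices that were genuinely open

* Whether per-chromosome estimates should come from one joint
  22-component fit or 22 separate fits is not dictated by the method;
  the default is the joint fit (`fitChromosomal(..., joint = TRUE)`),
  which attributes variance coherently, with separate fits behind a flag.
* HWE is tested on all subjects (no founder restriction), and PCs come
  from the post-QC GRM rather than a pruned SNP subset.
* The chromosome-partitioned analysis is run by default only for the
  trait with the highest significant $B_1$ heritability, mirroring the
  natural follow-up of a longitudinal-decline finding; any trait can be
  forced via the `chromosomal` config field.
* $B_0$ and $B_1$ are never modelled jointly (no bivariate REML, no
  one-stage mixed model); the two-stage route trades a small efficiency
  loss for transparency and speed, and the trajectory table makes the
  intermediate quantities auditable.

## What the test battery runs

The validation suite regenerates everything from seeds: oracle
equivalence of AI-REML against grid-plus-Nelder–Mead maximization of the
same restricted likelihood on 10 instances of 40 subjects × 200 SNPs;
intercept-heritability recovery (target 0.5) and slope-heritability
recovery through the full two-stage path (target 0.2) at 1000 subjects ×
5000 SNPs, 10 replicates each; null LRT calibration over 200 replicates
of 300 subjects; trajectory exactness against the weighted
normal-equations solution on 100 subjects; GRM diagonal, allele-flip and
chromosome-aggregation identities at 50 × 2000; chromosome localization
at 500 subjects with all causal variants on chromosome 1; GWAS
Frisch–Waugh equality, null calibration and power; QC boundary
enumeration; and PLINK/GCTA binary round trips. The same quantities are
recomputed end-to-end by `scripts/acceptance.R`. In the GWAS power check
the causal SNP is constructed to explain exactly 2% of the in-sample
response variance — the generator's exact-rescaling convention — so the
check validates the detection machinery at a known effect size rather
than compounding it with effect-size sampling noise.

## Known limitations

* No LD, relatedness, admixture or genotype imputation in the generator;
  the pipeline assumes unrelated subjects and a post-QC autosomal panel.
* The two-stage trajectory fit is less efficient than a joint mixed
  model when visit counts are very small; with the three-visit inclusion
  rule the loss is modest.
* Chromosome-length correlation uses SNP count as the default length
  proxy; physical base-pair lengths can be supplied instead.
* GWAS is fixed-effects OLS with PC adjustment, not a mixed-model
  association test; strong cryptic relatedness would inflate it.
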