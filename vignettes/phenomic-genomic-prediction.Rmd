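---
title: "Phenomic and genomic prediction for tetraploid breeding trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenomic and genomic prediction for tetraploid breeding trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psblup)
```

## The problem

Early potato breeding stages carry thousands of tetraploid clones with
too few tubers for replicated trials and budgets that rule out
genotyping every entry. Phenomic selection replaces the marker-derived
relationship matrix of genomic selection with one computed from cheap,
high-throughput reflectance measurements — here, plot-level
multispectral channels recorded by a drone on a few flight dates — on
the assumption that spectral similarity partially reflects genetic
similarity. `psblup` implements the full analysis chain for such a
study: mixed-model adjustment of augmented row-column trials, adjusted
entry means (AEMs) and broad-sense heritability, relationship matrices
from tetraploid allele dosages and from spectra, kernel BLUP prediction
under seven cross-validation scenarios, and weighted combinations of the
genomic and phenomic kernels. A synthetic-data module generates
populations and trials with the same statistical structure so that every
stage is testable without proprietary breeding data.

## Models

### Trial adjustment

Environments split into two maturity-group trials confound the test
clones with trials. The replicated checks, present once in every
incomplete block of both trials, identify the trial contrast through

`value ~ trial + (1 | check) + (1 | block) + (1 | row) + (1 | column)`

with the trial fixed and everything else random
(`estimateTrialEffects()`). The estimated contrast is subtracted from
every plot of the corresponding trial for all traits, significant or
not (`adjustForTrial()`).

### Entry means and heritability

The entry-mean model treats the clone as fixed (no intercept, so BLUEs
are the AEMs directly) and environment, clone-by-environment, and block,
row and column nested in environment as random (`computeAems()`).
Single-environment AEMs drop the environment terms; a
leave-one-environment-out scope supports predictions whose spectra come
from the excluded environment. Whether the column term enters can be
decided by a restricted likelihood-ratio test on its variance
(`rlrtColumnEffect()`), with a parametric bootstrap or the 50:50
chi-square(0)/chi-square(1) mixture as the null reference.

Broad-sense heritability on an entry-mean basis uses
`H2 = sigma2g / (sigma2g + vbar / 2)`, where `sigma2g` comes from a
refit with the clone random and `vbar` is the mean variance of a
difference between AEMs, computed exactly as the average of
`C_ii + C_jj - 2 C_ij` over all clone pairs from the BLUE covariance —
not the 2-times-mean-variance shortcut. Plot-basis heritability is
defined as `sigma2g` over the sum of all estimated variance components;
whether interaction variances belong in that denominator is a judgment
call, and this definition is recorded in the estimate objects.

Channel reflectances are treated as traits: per channel and flight date
with the entry-mean model, or per channel across dates with the flight
date and all its interactions (clone, environment, block, row, column)
added as random terms (`channelHeritability()`).

### Kernels

From a complete clones-by-markers dosage matrix (codes 0–4):

* additive: `G = Z Z' / m`, with `Z` column-centered by marker mean
  dosage by default. Centering is standard practice but the raw
  cross-product is retained behind `center = FALSE`; the marker count
  `m` is the default denominator, the tetraploid heterozygosity sum an
  option.
* dominance: per marker the digenic covariate `d (4 - d) / 6` — the
  fraction of heterozygous pairs among the C(4,2) = 6 pairings of four
  alleles — column-centered, cross-multiplied and rescaled to mean
  diagonal 1.
* epistatic: the Hadamard products `G∘G`, `G∘D`, `D∘D`, each rescaled
  to mean diagonal 1 so their variance components stay comparable.

From clone-level spectral features: `M = S S' / m_s`. Two environments
are combined either by column-joining the feature matrices (`cjM`; with
equal widths the kernel is exactly the average of the two
single-environment kernels) or by across-environment AEMs per feature
(`MAEM`). The weighted kernel is `C = x M + (1 - x) G`, a convex —
hence PSD-preserving — combination.

### Prediction

The BLUP model `Y = mu + U_1 + ... + U_k + eps`, `U_k ~ N(0, K_k
sigma2_k)`, is fitted by REML: a single kernel through a profiled
eigendecomposition (one 1-D optimization of the restricted likelihood
over the variance ratio), several kernels by direct quasi-Newton
maximization of the restricted likelihood over log-variances. The two
routes agree to numerical tolerance on one kernel; direct maximization
was chosen over an expectation-maximization/average-information
iteration because at clone scale (a few hundred rows) it is robust,
simple and fast, and its optimum is verifiable against a brute-force
variance grid. Factor-only models (everything before the kernel stage)
are fitted with `lme4`, which is built for exactly that structure; the
kernel engine is cross-checked against it where the structures coincide.

Held-out clones are predicted by the closed-form conditional
expectation `mu + sum_k sigma2_k K_k[v, t] V_tt^-1 (y_t - mu)`; an
independent route through Henderson's mixed-model equations with masked
responses (`predictMaskedMME()`) exists for verification and agrees to
1e-8 on small instances. Predictive ability is the Pearson correlation
between observed and predicted AEMs of a validation fold; five folds
times 25 replicates give 125 predictive abilities per case, and a case
fails the quality filter when the absolute coefficient of variation of
its PAs exceeds 150 or more than 100 predictions are missing.
Non-converged or degenerate folds (including a spectral variance
estimated at the zero boundary, which makes predictions constant)
propagate as missing PAs rather than errors, which is what the filter
is for.

### Scenarios

`enumerateScenarios()` lists the prediction cases: S1 same-environment
spectra, S2 cross-environment spectra (8 cases for 5 phenotype by 2
spectral environments), S3/S3b across-environment AEMs predicted from
single-environment spectra (S3b excluding the spectral environment from
the AEMs), S4/S5 combined spectra (cjM, MAEM) against single- or
across-environment AEMs, S6/S7 genomic prediction. `runScenario()`
assembles the named phenotype scope and kernel and cross-validates.

## The synthetic study

`simConfig()` defaults mirror the real design: 458 clones in 107
full-sib families plus 8 checks replicated once per block, 8 blocks and
at most 6 columns per block per environment, 5 environments of which
two carry spectra, two environments split into early (3 blocks) and
late (5 blocks) trials with families alternating between them, 3 flight
dates, 5 shared channels plus one year-specific channel per year, and
one shared channel missing in the second year — so each environment
reaches the full 7 x 3 = 21 features only after imputation.

Gametes assume bivalent pairing without double reduction: a parent of
dosage `d` transmits 2 of its 4 alleles drawn without replacement
(hypergeometric), the simplest autotetraploid model consistent with the
dosage coding. Offspring dosage is the sum of two parental gametes.
Trait values add marker-based additive effects, digenic dominance
deviations built from the same heterozygosity covariate the dominance
kernel uses (so G+D is the true model when the dominance fraction is
positive), i.i.d. clone-by-environment effects, exchangeable
environment/block/row/column effects (no spatial autocorrelation, to
match the exchangeable random-effect structure of the analysis models),
trial effects in split environments, and Gaussian noise. The residual
variance is solved per trait so the expected entry-mean heritability
`sigma2g / (sigma2g + (sigma2ge + sigma2e) / nEnvs)` hits the
configured target; targets of 0.3–0.9 are recovered within ±0.1 by the
estimation chain.

Spectra load a per-clone-date-environment latent genetic score onto
each channel. The latent score decomposes into a stable clone part and
clone-by-date, clone-by-environment and clone-by-date-by-environment
parts with shares (0.08, 0.42, 0.15, 0.35) and unit channel noise —
chosen so that per-date channel heritabilities land near 0.4 and
across-date heritabilities near 0.2, the regime reported for drone
reflectance data in potato, with the date-specific genetic part
dominating the stable part. Only the stable clone part is correlated
with the traits, through the configured spectral-overlap fractions: at
overlap 0 the spectra carry no information on the trait (the null
calibration the tests check), and the correlation grows as the square
root of the overlap. What the generator does **not** emulate: real
optics (values are abstract standardized reflectances, not radiometry),
spatially autocorrelated field trends, linkage between markers, or
double reduction — so passing tests demonstrate the statistical
machinery, not performance on real imagery.

For the split-signal experiment behind the weighted kernel, the
configuration puts 60% of the genetic variance into dominance (invisible
to the additive `G`) and gives the spectra a strong stable clone share
with high overlap, so the spectral and genomic kernels carry
complementary information of comparable strength; the interior optimum
of the weight grid then mirrors the benefit reported for combined
relationship matrices.

## Numerical choices

* Variance components are constrained non-negative (the kernel solvers
  optimize log-variances; boundary estimates are reported as 0).
* The single-kernel eigendecomposition profiles both the fixed effects
  and the residual variance, leaving a 1-D search over the variance
  ratio on the log scale in [-25, 25], with the boundary evaluated
  explicitly.
* Entry-mean models with 150 clones or more warm-start the clone-fixed
  optimizer from a clone-random fit of the same structure and relax the
  optimizer's stopping tolerance (absolute parameter tolerance 2e-3 on
  the relative-standard-deviation scale); this changes AEMs in the
  third decimal at most and can be disabled with `fast = FALSE`.
* The PCA outlier rule flags whole plot spectra whose score on any
  leading component exceeds 4 SD of that component; the threshold is
  configurable because the underlying criterion is a judgment call, and
  a corrupted flight frame argues for flagging the entire row rather
  than single cells.
* Predictive-mean-matching uses 5 donors and single imputation;
  imputed values always occur among observed donor values.
* Phenotype outliers are dropped once (no iteration) at |studentized
  residual| > 4, a deterministic stand-in for manual inspection of
  residual diagnostics that removes far less than 1% of Gaussian data.
* Fold assignment ignores family structure; seeds fully determine fold
  partitions, simulations and imputations.

## Problem sizes used in tests

The packaged tests run the full estimation chain at reduced sizes
chosen to keep each property informative: heritability recovery at the
full 400-clone, 5-environment dimensioning over 20 seeds; null/planted
phenomic calibration at 150 clones with a reduced channel set; the
weight-grid experiment at 120 clones; oracle equivalences at 8–25
clones where brute-force references are exact. These sizes are the
package's choices for routine verification; all of them scale up by
changing `simConfig()` fields.

## Known limitations

No spatial-correlation (AR1) structures, heterogeneous residual
variances, non-Gaussian responses or Bayesian whole-genome regressions;
flight dates are plain factors, not growth-stage covariates; marker
effects are unlinked. The restricted likelihood-ratio bootstrap refits
the full model per simulation and is therefore the slowest path in the
package — the chi-square-mixture approximation is the default where the
decision is only a model-selection convenience.
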