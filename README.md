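# psblup

Phenomic and genomic prediction for tetraploid potato breeding trials.

Early-stage potato breeding screens hundreds of tetraploid clones that
are too scarce to replicate and too numerous to genotype. *Phenomic
selection* sidesteps genotyping by building the relationship matrix of
a BLUP model from multispectral plot reflectances recorded by a drone,
instead of from SNP allele dosages. `psblup` implements the complete
analysis for such a study, for breeders and quantitative geneticists
who want to evaluate the approach on their own (or simulated) trials:

* **Trial adjustment** — in environments split into maturity-group
  trials, the trial contrast is estimated from the replicated checks
  with the mixed model `value ~ trial + (1|check) + (1|block) +
  (1|row) + (1|column)` and subtracted from every plot.
* **Adjusted entry means (AEMs)** — the clone enters as a fixed effect,
  environment, clone×environment and the row-column design factors as
  random effects; available across environments, per environment, and
  leave-one-environment-out.
* **Heritability** — broad-sense, on an entry-mean basis via
  H² = σ²g / (σ²g + v̄/2), where v̄ is the mean variance of a
  difference between AEMs computed exactly from the BLUE covariance;
  also per reflectance channel (per flight date, or across dates with
  the flight date and its interactions as random terms).
* **Relationship matrices** — additive G = ZZ′/m from tetraploid
  dosages 0–4, digenic dominance from the covariate d(4−d)/6,
  first-degree epistatic Hadamard products, multispectral M = SS′/m_s,
  column-joined (cjM) and AEM-combined (MAEM) two-environment spectra,
  and the weighted combination C = x·M + (1−x)·G.
* **Prediction** — kernel BLUP (Y = μ + U + ε, U ~ N(0, K σ²U)) fitted
  by REML, fivefold cross-validation with 25 replicates (125
  predictive abilities per case, Pearson r between observed and
  predicted AEMs), the quality filter (|CV| > 150 or > 100 missing
  predictions), seven prediction scenarios (S1–S7, including S3b and
  the cjM/MAEM variants of S4/S5), a grid search over the spectral
  weight x, and flight-date subset analysis.
* **Synthetic data** — a generator for tetraploid full-sib populations
  (hypergeometric gametes), augmented row-column trials with
  configurable trait architectures, and multichannel spectra with a
  tunable genetic overlap with the traits, emulating the study design
  (458 clones, 107 families, 8 checks × 8 blocks, 5 environments, 2
  with spectra, 3 flight dates, 7 channels, m_s = 21).

Marker QC (≥20% missingness and MAF < 5% filters with median
imputation), spectral preprocessing (scaling, PCA outlier flagging,
median imputation) and predictive-mean-matching imputation of
channel-year blocks are included.

## Worked example

```r
library(psblup)

cfg <- simConfig(nClones = 60, nFamilies = 15, nChecks = 4,
                 nFounders = 10, nMarkers = 80, nCausal = 40,
                 nBlocks = 4, seed = 11)
bundle <- simulateStudy(cfg)

# trial adjustment and entry means
plots <- adjustForTrial(bundle$plots, estimateTrialEffects(bundle$plots))
aems  <- computeAems(plots, "starch", scope = "across")
h2    <- heritability(fitCloneRandom(plots, "starch"), aems)
h2
#> H2[starch, entry-mean] = 0.886 (sigma2g = 1.09, vbar = 0.278)

# kernels: genomic and multispectral
proc <- processSpectra(bundle$spectra, seed = 5)
ks   <- buildKernels(qcMarkers(bundle$dosage), proc)
featureCount(proc$cloneSpectra$W20)
#> [1] 21

# genomic prediction of across-environment AEMs (scenario S7)
res <- runScenario(scenarioSpec("S7", "across", "G"),
                   aems = list(across = aemValues(aems)),
                   kernels = ks, nFolds = 5, nReps = 25, seed = 1)
res
#> PredictionResult: median PA = 0.649 over 125 folds; 0 missing; passed quality filter
```

The heritability line says that about 90% of the variance among entry
means is genotypic for this trait (it was simulated at H² = 0.90); the
21 spectral features per environment are the 7 channels × 3 flight
dates reconstructed by imputation; and the S7 result is the median
Pearson correlation between observed and GBLUP-predicted entry means
over 125 validation folds, with its quality-filter verdict.

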