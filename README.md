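# fluorQuant

Quantitative fluorescence analysis of membrane-protein oligomerization:
single-molecule photobleaching-step subunit counting, acceptor-photobleaching
FRET, and Mander's-coefficient colocalization with an exponential
dose–response — each validated end to end on truth-tagged synthetic data the
package generates itself.

## The problem

How many copies of a membrane protein sit in one complex? Regulatory
subunits of voltage-gated potassium channels (the KCNE family and their
partner channels such as Kv1.3) assemble in stoichiometries that decide
their trafficking and physiology, and three microscopy readouts are the
workhorses for answering this in cells:

1. **Photobleaching-step counting.** A GFP-tagged complex immobilised under
   TIRF bleaches in discrete steps, one per fluorescent tag. Because GFP
   matures with probability *p* < 1 and all-dark complexes are invisible,
   the observed step count *k* follows a **detection-conditional binomial**
   distribution:

   P(k | n, p) = C(n,k) p^k (1−p)^(n−k) / (1 − (1−p)^n),  k = 1…n.

   fluorQuant counts steps with a deterministic change-point fitter
   (binary segmentation under a BIC-type penalty, C++ core), applies
   explicit quality control, fits *p* by maximum likelihood, and selects
   the subunit count *n* by AIC — the computation behind calling a channel
   tetrameric, a KCNE4-like peptide dimeric, and a KCNE1-like peptide
   monomeric, with the familiar GFP maturation estimate p ≈ 0.67.

2. **Acceptor-photobleaching FRET.** Bleaching the acceptor dequenches the
   donor; the efficiency is computed from donor ROI means before and after,
   with the whole-scan fluorescence loss corrected from an unbleached
   control region, and an acceptor-bleach-depth QC gate (~80% depth).

3. **Colocalization dose–response.** Per cell, Mander's M1/M2 within a
   mask, and ER colocalization of a reporter against the regulator/reporter
   expression ratio, fitted with y = A·exp(−k·x) + C by bounded
   nonlinear least squares.

The synthetic-data module generates TIRF movies and traces (binomial spot
populations, exponential bleaching, Gaussian PSF rendering), FRET image
sets and colocalization panels with known ground truth, so every analysis
stage is tested as an inverse of its generative model.

## Worked example

Simulate a tetrameric channel population (1500 spots, p = 0.67, realistic
noise), count bleaching steps, and infer the stoichiometry:

```r
library(fluorQuant)

cfg <- simConfig(seed = 42, nSubunits = 4, pFluor = 0.67,
                 nSpots = 1500, noiseSd = 5)
sim <- simulateSpotPopulation(cfg)
sim$truth
#> SpotTruth: 1500 spots, 1480 visible; fluorophore counts ~ Binomial( 4 , 0.67 )

tab <- countDistribution(countSteps(sim$traces))
tab
#> StepCountTable: 1452 accepted spots
#>              1       2        3        4
#> count 149.0000 453.000 584.0000 266.0000
#> freq    0.1026   0.312   0.4022   0.1832

selectStoichiometry(tab)
#> Stoichiometry selection: n = 4 (AIC margin Inf )
#>  n      pHat    logLik      AIC
#>  1 1.0000000      -Inf      Inf
#>  2 0.8587678      -Inf      Inf
#>  3 0.7805937      -Inf      Inf
#>  4 0.6573018 -1850.674 3703.348
```

The observed frequencies peak at three steps, as the conditional binomial
predicts for a tetramer at p ≈ 0.67 (dark tags shift the mode below 4);
candidates with n < 4 cannot explain the 4-step spots and lose outright,
and the recovered maturation probability is 0.657 with 95% CI
[0.644, 0.670], covering the simulated 0.67.

One FRET cell with true efficiency 0.2, 80% acceptor bleach and 5% scan
loss:

```r
fs <- simulateFretPair(eTrue = 0.2, bleachDepthTrue = 0.8,
                       scanLossTrue = 0.05, noiseSd = 0.5, seed = 1)
computeFretEfficiency(fs)
#> FRET (acceptor photobleaching) cell1 : E = 20.09 % , beta = 0.8 [QC pass]
```

which matches the closed form 100·β·E/(1−E) = 20% expected under the
pre-bleach-normalised efficiency convention.

Pipelines (`runCountingPipeline()`, `runFretPipeline()`,
`runColocPipeline()`) chain the stages, consume simulated or TIFF/CSV
inputs, and write byte-reproducible CSV/JSON bundles with provenance; a
thin CLI lives at `inst/scripts/fluorquant.R`. The methods vignette
(`vignettes/fluorescence-stoichiometry.Rmd`) documents the models,
defaults and numerical choices.

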