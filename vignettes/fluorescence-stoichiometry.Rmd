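---
title: "Counting subunits, FRET and colocalization: the models behind fluorQuant"
author: "fluorQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting subunits, FRET and colocalization: the models behind fluorQuant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorQuant)
```

fluorQuant implements three quantitative fluorescence-microscopy analyses
used to establish the oligomeric state and trafficking behaviour of
membrane proteins — single-molecule photobleaching-step subunit counting,
acceptor-photobleaching FRET, and Mander's-coefficient colocalization with
an exponential dose–response — together with truth-tagged synthetic-data
generators that exercise every stage end to end. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not demonstrate about real data.

## 1. Subunit counting from photobleaching steps

### The detection-conditional binomial model

A GFP-tagged complex of $n$ subunits immobilised at the coverslip appears
in TIRF as one diffraction-limited spot. Under continuous illumination
each fluorophore bleaches once and irreversibly, so the spot's summed
intensity descends a staircase whose number of steps $k$ equals the
number of *fluorescent* tags. Not every tag is fluorescent: GFP folds and
matures with probability $p < 1$, so $k \sim \mathrm{Binomial}(n, p)$.
Spots with $k = 0$ are invisible and can never enter the data, so the
observable step-count distribution is conditioned on $k \geq 1$:

$$
P(k \mid n, p) \;=\;
\frac{\binom{n}{k} p^k (1-p)^{n-k}}{1 - (1-p)^n},
\qquad k = 1, \dots, n .
$$

This conditioning is not optional — ignoring it inflates the apparent
monomer fraction — and it is applied everywhere in the package
(`conditionalBinomialPmf()`). For $n = 1$ the conditional distribution is
a point mass at $k = 1$ regardless of $p$: a monomer data set carries no
information about $p$, which `fitBinomialP()` reports via a
flat-likelihood flag rather than a spurious estimate.

Fitting maximises the multinomial log-likelihood of the observed
step-count table over $p \in (0, 1]$ with a bounded one-dimensional
search (the objective is smooth and unimodal in all regimes we tested;
the suite cross-checks the optimum against a dense grid with step
$10^{-4}$). A 95% profile-likelihood interval and a Pearson chi-square
lack-of-fit statistic are attached, with sparse expected cells (below 1
count) pooled downward. Oligomeric state is chosen by AIC over candidate
$n \in \{1, 2, 3, 4\}$, counting one free parameter ($p$) for $n \geq 2$
and none for $n = 1$; ties break toward the smaller $n$ (parsimony).
Counts observed at $k > n$ are impossible under a candidate and drive its
likelihood to $-\infty$, which is exactly how a too-small $n$ loses.

`fitStoichiometryMixture()` fits a weighted mixture of states sharing one
$p$ by EM. An important structural caveat, printed on every mixture fit:
from step counts alone, a pure dimer with $p < 1$ is nearly
indistinguishable from a monomer/dimer mixture, because dark-tag dimers
produce one-step spots exactly where monomers would. We provide both
fits and document the confounding rather than pretending to resolve it.
For the same reason $p$ is best calibrated on a known oligomer (a
tetrameric channel control) and transferred to the construct of interest
— both per-construct and shared-$p$ fits are available.

### Step detection

Plateaus are found by recursive binary segmentation of each trace into
piecewise-constant segments (the split search is implemented in C++).
A candidate split is kept only when it lowers the residual sum of squares
by more than a BIC-type penalty
$\lambda \, \sigma^2 \log N$ (default $\lambda = 3$), with $\sigma$
estimated robustly as $\mathrm{mad}(\Delta y)/\sqrt{2}$. A post-pass
merges steps smaller than half the median step magnitude, and an optional
monotone mode removes upward steps (bleaching is monotone; upward blips
are artifacts, and the generator can inject them to stress this path).
The fit is deterministic and exactly invariant to adding a constant to
the trace (the segmentation centres the trace first, which also keeps the
cumulative sums well conditioned).

Quality control (`acceptTrace()`) rejects: zero-step fits; fits with more
than `kMax = 4` steps (the largest oligomer considered); traces that do
not return to background within twice the residual standard deviation
(incomplete bleaching — the trace ended before the last fluorophore
died); and fits containing a step larger than 2.5 times the median step
(two fluorophores bleaching within one frame produce a double-height
step that cannot be counted reliably, so the spot is discarded rather
than split heuristically). All thresholds are surfaced in
`stepFitParams()`. Real studies typically counted steps by eye and
reported no rejection rules; the explicit filter here is our
operationalisation, and its defaults are deliberately conservative
(noiseless simulated tetramer populations lose under 10% of spots).

Two uncountable situations deserve emphasis. Bleaches falling in the same
frame are aliased into one step *by construction*, at a rate set by the
frame interval over the mean bleach time (about 6% of tetramer spots at
the defaults); this slightly fattens low-$k$ cells and biases $\hat p$
down by roughly 0.01–0.015 at the defaults — visible in the validation
but far too small to disturb model selection. Second, plateaus shorter
than about two frames are only recoverable without noise; the staircase
benchmark (`simulateStepTraces()`) therefore draws plateau lengths of
5–15 frames, which we consider the resolvable regime for measuring
detector accuracy.

### Spot detection and trace extraction

Candidate spots are local maxima of a matched-filtered (Gaussian,
PSF-width) temporal mean of the early frames, thresholded at 5 robust
standard deviations of the filtered image plus a relative floor of 5% of
the brightest peak (which suppresses numerically tiny maxima in noise-free
renders). Overlapping candidate ROIs keep the brighter spot, with a
deterministic row/column tie-break. Each spot must then pass an
immobility test: the intensity-weighted centroid, tracked over the
frames in which the spot is visible, may wander at most 1 px from its
mean (the analysed spots in a neutravidin-fixed preparation are immobile;
a spot drifting 3 px across the movie is rejected). Traces are the sums
of 6 × 6-pixel ROI blocks per frame, minus the per-frame median of all
off-ROI pixels scaled to the ROI area; the 6 × 6 block is anchored so the
detected maximum sits at the upper-left of the central 2 × 2 (a
convention the original procedure leaves unstated — any fixed anchoring
works, it only must be deterministic). Extraction is exactly linear in
the movie. All coordinates in the package and its files are 1-based, R's
native convention.

## 2. The synthetic-data generators

`simulateSpotPopulation()` draws, per spot: a position (uniform, with a
minimum pairwise separation of 8 px — the low-density condition that
guarantees one complex per diffraction-limited spot; the constructor
refuses separations below twice the PSF sigma); a fluorescent-tag count
from $\mathrm{Binomial}(n, p)$; and independent exponential bleach times.
Traces are `unitIntensity × survivors(t) + background + noise`, emitted
background-subtracted for visible spots only (a flag exposes dark spots
for oracle tests). `renderMovie()` places each surviving fluorophore as a
pixel-integrated isotropic Gaussian of total mass `unitIntensity`, with
optional linear drift to exercise the immobility filter.

Defaults describe a plausible single-molecule TIRF acquisition and are
**our declared choices, not measured values from any particular
instrument**: 512 × 512 px field (a common EMCCD format), 100 ms frames,
500-frame movies, mean single-fluorophore bleach time 10 s (so a movie
spans five bleaching time constants and fewer than 1% of fluorophores
outlive it), 100 a.u. per fluorophore, Gaussian noise of 5 a.u.
(step-to-noise 20), background 10 a.u., PSF sigma 1.2 px (typical for a
high-NA TIRF objective at single-molecule magnification). Noise is
additive Gaussian by default for analytic tractability; a Poisson mode
exists. Blinking, EMCCD gain statistics, and stage drift are *not*
simulated — so passing the validation shows the analysis correctly
inverts its own generative model, not that it is robust to every
real-world artifact. Fields hosting very large populations (5000–10 000
spots in some validation runs) are enlarged proportionally
(1024–2048 px) at the same separation, since random sequential placement
saturates near 2850 spots on a 512 × 512 field; the spot density is
unchanged.

All stochastic stages draw from independent streams derived from one
master seed, so identical configurations are bit-identical and adding a
stage never perturbs another's draws.

## 3. Acceptor-photobleaching FRET

Destroying the acceptor abolishes transfer and dequenches the donor. With
unquenched donor intensity $D$, true efficiency $E$, acceptor bleach
depth $\beta$ and per-scan fluorescence loss $s$, the generative model is
$F_{\text{before}} = D(1-E)$ in the bleach ROI,
$F_{\text{after}} = D\,(1 - E(1-\beta))(1-s)$ inside it, and donor
changes outside the ROI by the scan factor only. The analysis measures
the scan factor $\rho$ as the donor post/pre ratio in an unbleached
control region, corrects $F_{\text{after}}$ by $1/\rho$, and reports

$$
E_{\text{app}} \;=\; 100 \cdot
\frac{F_{\text{after}}/\rho - F_{\text{before}}}{F_{\text{before}}} ,
$$

whose noiseless value is $100\,\beta E/(1-E)$ — confirmed by the suite to
0.1 percentage points over a grid of $E$ and $\beta$, with $E = 0$ giving
exactly 0 for any $\beta$ and scan loss. Note the normalisation: this
convention divides by the *pre-bleach* (quenched) donor, which reads out
$\beta E/(1-E)$ rather than the textbook $\beta E$. The conventional
estimator $100 (F_{\text{after}} - F_{\text{before}})/F_{\text{after}}$
is reported alongside in every result
(`efficiencyCanonicalPct`) so the two can be compared; the primary
output follows the pre-bleach convention because it is the formula whose
values the accompanying experiments report. ROI statistics use pixel
means (robust to ROI-size differences), and quality control requires an
acceptor bleach depth of at least 0.7 — our operationalisation of the
roughly 80% depth a good experiment reaches; it is configurable. No
crosstalk or direct-donor-bleach correction is applied beyond the
control-region scan factor.

## 4. Colocalization and the CaM dose–response

`mandersCoefficients()` computes the per-channel Mander's pair within the
cell mask: $M_1$ is the fraction of channel-A intensity on pixels where
channel B exceeds its threshold, $M_2$ the converse; the
intensity-product overlap coefficient is a secondary output, because
"Mander's overlap coefficient" is used ambiguously in the literature and
we read the per-channel fractions as the intended quantity. Thresholds
default to per-channel Otsu within the mask (a deterministic, reproducible
stand-in for the manual thresholds of interactive tools), with zero- and
fixed-threshold modes available. $M_1/M_2$ swap exactly under channel
exchange and are invariant to a positive gain change of the
non-thresholded channel.

The dose–response analysis plots, per cell, the ER colocalization of a
reporter against the regulator/reporter expression ratio (both as plain
means within the cell mask — intensities are used as acquired, which is
only meaningful at matched acquisition settings, so batches with
differing recorded settings are refused). The relationship is modelled as
$y = A e^{-kx} + C$ and fitted by bounded nonlinear least squares
(Levenberg–Marquardt, $A, k \ge 0$, $C \in [0,1]$) from five
deterministic data-derived starts, keeping the best SSE. The offset $C$
admits a residual ER fraction at saturating regulator; $C = 0$ is an
option (`fixC`). Constant-$y$ input returns a flagged flat fit with
$R^2 = 0$; degenerate $x$ errors. On noiseless model points the fit is
exact to $10^{-6}$ and its SSE never exceeds a $50^3$ grid-search floor.

One honest caveat about per-replicate accuracy. At 30 cells with
y-noise 0.05 the Fisher information of the three-parameter model bounds
the standard deviation of $\hat k$ at roughly 0.10–0.14 (design
dependent) for *any* unbiased estimator, so demanding $\hat k$ within 5%
of $k = 1.5$ (±0.075) in 90% of replicates is beyond what the data can
support at that noise level; the suite documents this: the fitter is
unbiased to well within sampling error at that design and matches the
SSE oracle, while the ±5% per-replicate band holds in only ~35% of
replicates, as the information bound dictates. Recovering $k$ that
tightly needs more cells, lower noise, or a fixed offset.

The panel generator builds, per cell, a circular footprint with a central
ER region and a peripheral membrane ring (disjoint); the reporter's total
intensity is split between ER and membrane according to the decay curve,
conserving total intensity exactly, while the regulator fills the
footprint uniformly at the requested ratio. This emulates the
*statistical* structure of the experiment — it does not attempt realistic
cell morphology, and segmentation is out of scope (masks are inputs).

## 5. Pipelines, provenance and problem sizes

`runCountingPipeline()`, `runFretPipeline()` and `runColocPipeline()`
bind the stages behind validated configuration lists (unknown keys are
rejected before any I/O), consume simulated or TIFF/CSV inputs, and write
CSV/JSON bundles with a provenance block (config echo, seed, package
version, input digests) that contains no timestamps: re-running a bundle
from its own provenance reproduces it byte for byte, which the suite
asserts with file digests. Movies travel as 32-bit-float grayscale TIFF
stacks with a JSON sidecar carrying the intensity scale and frame
interval; traces as long-format CSV. A thin command-line wrapper
(`inst/scripts/fluorquant.R`) exposes the three pipelines to shell users.

Validation problem sizes were chosen to estimate each property with
comfortable margins while keeping the default suite fast: 100 seeded
replicates of roughly 1000 visible spots per construct for stoichiometry
recovery, 5000 accepted spots for the dimer frequency signature, 1000
staircase traces for detector accuracy, a 45-point $(E, \beta)$ grid for
FRET, and 100 replicates of 30-cell panels for the decay fit.

## 6. Known limitations

* Step counting assumes monotone, well-separated bleaching; blinking and
  within-frame double bleaches are uncountable and handled by rejection,
  not modelling. No hidden-Markov or intensity-weighted step models.
* $p$ is assumed identical across constructs sharing a tag; violations
  bias transferred calibrations.
* The FRET module is ROI-level acceptor photobleaching only — no
  sensitized emission, spectral unmixing, or per-pixel maps.
* Colocalization offers Mander's coefficients only (no Pearson/Costes),
  and relies on caller-supplied or generator masks.
* The simulators omit camera gain statistics, blinking and drift (beyond
  the linear test mode); conclusions from synthetic validation transfer
  to real data only insofar as the generative assumptions hold.
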