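---
title: "Models and methods behind fret3wj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fret3wj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

The U4/U6 di-snRNP is a spliceosome assembly intermediate built around the
extensively base-paired U4 and U6 snRNAs. Where stems I and II of the
duplex meet the U4 5′ stem-loop, the RNA forms a three-way junction whose
global geometry — which two helices coaxially stack, and where the third
arm points — constrains how Snu13, Prp31 and the Prp3/4 dimer assemble onto
it. Two experimental readouts address this: single-molecule FRET (smFRET)
between dye pairs placed on different helical arms, and electrophoretic
mobility shift assays (EMSA) that titrate each protein against the RNA.

`fret3wj` implements the complete analysis chain for both readouts, plus a
synthetic-data generator so that every stage can be exercised and validated
without any experimental data.

# The smFRET measurement model

Each immobilized molecule is observed as a two-channel time series of donor
and acceptor intensities $I_D(t)$, $I_A(t)$. The pipeline works with the
*apparent* FRET efficiency

$$E = \frac{I_A}{I_A + I_D},$$

a proximity ratio with no gamma, crosstalk or background-trend correction.
This is deliberate: the downstream state means (0.2/0.3/0.4 FRET and so
on) are defined on the apparent scale, and corrections would silently move
them. `compute_fret()` flags frames whose total intensity falls below
$3\sigma_{bg}$ (estimated robustly from first differences) as undefined
rather than dropping them, so frame indexing survives.

## Photobleach detection and molecule QC

A genuine single molecule is identified by single-step photobleaching of
the total intensity. `detect_steps()` segments a signal into
piecewise-constant pieces by minimizing

$$\sum_{\text{segments}} \mathrm{RSS} + \beta \cdot \#\{\text{change points}\}$$

exactly, via optimal partitioning with PELT pruning (implemented in C++;
the exact solution matters because the QC criterion is a *count* of
steps). The default penalty is $\beta = 5\hat\sigma^2\log n$ with
$\hat\sigma = \mathrm{mad}(\Delta x)/\sqrt2$; for noiseless signals a
vanishing positive penalty is substituted so constants yield no change
points while exact steps are still found. The test suite checks the
segmenter against an exhaustive small-instance oracle.

`qc_select()` passes a molecule when its total intensity shows exactly one
downward step to background. Aggregates (two molecules in one spot) show
doubled intensity and two donor steps and are rejected; molecules that
never bleach are rejected because their single-molecule status cannot be
verified. Acceptor-first bleaching is recognized as an earlier
down-to-background step in the acceptor channel — *to background* is the
operative phrase, because FRET transitions of a dynamic molecule also step
$I_A$, and those must not be mistaken for bleaching. Traces are truncated
at the first bleach event; the per-molecule mean FRET uses strictly
pre-bleach frames.

`classify_static()` calls a trace dynamic when a change point in the
pre-bleach FRET series separates segments differing by at least
$\delta = 0.1$ FRET (the smallest spacing the ensemble histograms resolve)
with both dwell times at least 10 frames. Molecules whose pre-bleach
region is shorter than 2 × 10 frames are flagged indeterminate (`NA`)
rather than forced into either class.

## Histogramming and mixture fitting

`build_histogram()` pools all valid pre-bleach frames of all QC-passed
molecules over bins of width 0.02 on $[-0.2, 1.2]$ — wide enough that
channel noise pushing apparent FRET below 0 or above 1 stays on-support,
fine enough that peaks 0.1 apart keep five bins between their means. An
alternative `source = "means"` histogram uses one value per molecule.

Populations are extracted by fitting a sum of $k$ Gaussians to the binned
densities with bounded Levenberg–Marquardt (`minpack.lm`). This is done in
two stages, mirroring standard smFRET practice: molecules are first
grouped by their mean FRET (k-means seeded from the modes of the
per-molecule-means histogram, which are sharp because molecule means
scatter far less than frames), each group's pooled histogram is fit with a
single Gaussian, and those per-population means then *anchor* the overall
histogram fit, in which only widths and amplitudes remain free. The
anchoring is not a convenience: with peaks roughly $2\sigma$ apart a fully
free $k$-Gaussian least-squares fit on the histogram is ill-determined, and
we observed it migrating to tilted optima (one broad component swallowing
a neighbor) with *lower* residuals than the generative parameters. The
stage-one means are well-determined precisely because they are fit on
nearly pure sub-ensembles. `fit_mixture()` retains the fully free mode
(seeds, not constraints) for direct use, and flags degenerate outcomes
(coincident means, or a component weight under 0.05).

## Assignment, fractions, and comparisons

`assign_molecules()` assigns each static, QC-passed molecule to the
component with the highest Gaussian density at its mean FRET, breaking
ties toward the lower mean for determinism. A molecule more than 3
component widths from every mean lands in an explicit "unassigned" bucket
— this is where donor-only molecules (acceptor bleached before the movie
effectively began, apparent FRET near 0) end up. Fractions are computed
over assigned molecules, so they sum to 1; the unassigned count is
reported alongside. Uncertainties come from a molecule-level bootstrap
(1000 resamples, seeded).

`compare_conditions()` applies a two-sample Welch t-test to per-replicate
fractions of one component, with the usual 0.05/0.01/0.001 star
thresholds. The replicate unit is the pseudo-replicate ensemble (about
100 molecules, emulating movie-level subsets);
`compare_fixture_conditions()` builds such replicates with multinomial
state assignment, which at $n \approx 100$ naturally produces the ~5
percentage-point replicate scatter a real per-movie split shows. Two
identical constant replicate vectors return $t = 0$, $p = 1$ rather than
erroring.

# Junction geometry

Distances come from the Förster relation
$R = R_0\,((1-E)/E)^{1/6}$ with $R_0 = 60$ Å for the Cy3/Cy5 pair; the
orientation factor is not modelled and $R_0$ is taken as given. At
$E = 0.2$ this gives 75.6 Å. Helical arms are modelled as ideal A-form
duplexes with a rise of 2.8 Å/bp (configurable), so a 10 bp stem I is
28 Å and a 17 bp stem II is 47.6 Å. Fluorophore linkers and terminal
offsets are ignored — the coaxial-stacking argument compares bare contour
lengths, and 28 + 47.6 ≈ 76 Å is what makes the measured 0.2 FRET
distance diagnostic of stems I/II stacking.

`rank_stacking_models()` scores, for every unordered pair of arms, the
collinear (coaxially stacked) prediction — the sum of the two contour
lengths — against the measurements involving that pair, and optionally a
bent alternative whose inter-arm angle minimizes the same residual via the
law of cosines. Which stacked pair corresponds to junction family A, B or
C is supplied as a configurable mapping (`default_family_map()`): prior
modelling predicted a family-B junction (stem I stacked on the 5′
stem-loop) while the distance data support family A (stems I/II stacked),
so the package reports the stacked pair and leaves the family label to the
mapping rather than hard-coding either claim.

Component means convert to distances with first-order error propagation
through the Förster derivative; tests verify the propagated errors against
Monte-Carlo resampling.

# EMSA binding analysis

Fraction bound follows the Hill isotherm

$$\theta = \frac{a - b}{1 + (K_{d,app}/[\mathrm{protein}])^n} + b,$$

fit by bounded Levenberg–Marquardt with $K_{d,app}$ on a log scale and
five log-spaced multi-starts spanning the titrated range ($n \in (0.3,6)$,
$a \in (0.5,1.5)$, $b \in (-0.2,0.5)$). Reference affinity rows whose Hill
coefficient is reported as a bare 1 are refit with $n$ held at 1, matching
the asymmetric error reporting of the source table; rows with stated
uncertainties are refit with $n$ free. Replicates combine by
inverse-variance weighting of the fit standard errors, with the reported
spread being the weighted standard deviation of the replicate estimates; a
fit with a (near-)zero standard error triggers an unweighted fallback,
flagged. Fits whose $K_{d,app}$ falls more than 10× outside the titrated
range warn.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions, not tuning knobs:

* **States.** Each molecule occupies one static FRET state for its whole
  lifetime; interconversion is disallowed by construction (the
  configuration rejects `interconversion = TRUE`), because the modelled
  ensembles are static and non-interconverting.
* **Ensemble composition.** `simulate_ensemble()` assigns molecules to
  states by a multinomial draw on the configured weights by default. The
  bundled figure fixtures instead use largest-remainder proportional
  assignment: a fixture advertised as 44/45/11% at $n = 102$ should
  actually contain those proportions, and at that size a multinomial
  draw's realized composition deviates from the nominal weights by about
  5 percentage points (one standard deviation) — the fixture would not
  embody its own ground truth. Replicate-level simulations for the
  t-tests keep the multinomial default precisely because that scatter is
  the between-replicate variability being tested.
* **Noise.** Additive Gaussian noise per channel with constant
  $\sigma = 6$ photons/frame at a total intensity of 100, chosen so the
  per-frame apparent-FRET standard deviation,
  $\sigma_E \approx \sigma\sqrt{E^2 + (1-E)^2}/I_{tot}$, is about 0.05
  across the 0.2–0.5 range — peaks 0.1 apart remain separable, matching
  the resolution of the modelled histograms. An optional square-root
  intensity scaling exists but is off by default. Background after bleach
  has mean 0 with the same sigma, and negative samples are retained:
  clipping at zero would bias the FRET estimator.
* **Bleaching.** Independent exponential lifetimes per dye (donor 300
  frames, acceptor 500 frames by default). After acceptor-only bleach the
  donor recovers the full intensity (energy transfer lost); after donor
  bleach both channels sit at background.
* **Time base.** 0.1 s frames and 1000-frame movies. Frame rate and trace
  length are not constrained by the modelled experiments; these are
  explicit choices typical of TIRF recordings on the minutes time scale.
* **Titrations.** Fraction bound is drawn from the Hill function at 20
  log-spaced concentrations from 1 pM to 2.5 µM (the working range of a
  gel-shift titration) plus additive Gaussian noise, truncated to
  $[0, 1.2]$ to mimic gel-integration overshoot.
* **Blinking, spectral crosstalk, gamma, camera PSFs** are not simulated.

What passing tests on this generator do and do not show: they demonstrate
that the analysis correctly inverts the generative model it assumes —
static states, additive noise, exponential bleaching. Real traces carry
baseline drift, blinking, crosstalk and non-Gaussian camera noise that the
generator omits, so recovery here bounds algorithmic error, not total
experimental error.

# Numerical choices and degenerate inputs

* Change-point penalty $5\sigma^2\log n$, minimum segment length 2; the
  noiseless-signal fallback penalty is $10^{-8}\max(1, \mathrm{range}^2)$.
* Mixture fits parameterize $\log\sigma$ and $\log$ amplitude to keep both
  positive; $\sigma$ is bounded in $[5\times10^{-3}, 0.5]$ FRET.
* Assignment ties break toward the lower-mean component; hypothesis
  ranking breaks residual ties by pair name, making both order-invariant.
* All randomness flows from explicit integer seeds in the stage configs;
  a fixed seed yields byte-identical output tables.
* Degenerate cases error informatively rather than guessing: an empty
  QC-survivor set returns an annotated empty result with a reason tally, a
  both-zero band pair makes fraction bound undefined, Förster conversion
  rejects $E \in \{0, 1\}$.

# Problem sizes

The bundled fixtures use the modelled ensemble sizes (102–108 molecules,
1000 frames); the multi-seed recovery checks run 20 seeds per construct,
and noisy Hill recovery uses 100 seeds at one parameter set with a
30-seed spot check in the unit tests. Pseudo-replicate comparisons use 6
replicates of ~100 molecules per condition.

# Known limitations

* The apparent-FRET scale means distances inherit any gamma/crosstalk bias
  of the raw channels; the Förster conversion is only as calibrated as
  $R_0$.
* Histogram least-squares fitting (rather than frame-level EM) matches
  the modelled analysis but discards within-bin information; an EM
  cross-check mode is a natural extension.
* The bootstrap ± on population fractions quantifies sampling error of
  molecule assignment, not systematic error from model misfit.
* The collinear stacking model treats arms as rigid rods meeting at a
  point; junction linkers, dye linkers, and out-of-plane geometry are
  outside its vocabulary.
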