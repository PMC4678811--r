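# fret3wj

Single-molecule FRET and EMSA analysis of RNA three-way junction assembly.

## What this package is for

When a multi-helix RNA like the U4/U6 snRNA duplex assembles into a
ribonucleoprotein, the geometry of its three-way junction — which two
helices coaxially stack, and where the third arm points — controls how the
proteins (Snu13, Prp31, the Prp3/4 dimer, Sm and LSm rings) bind. Two
bench readouts probe this:

* **smFRET trajectories.** Dye pairs on different helical arms report the
  apparent FRET efficiency `E = I_A / (I_A + I_D)` per molecule per frame.
  An ensemble of such molecules separates into discrete conformer
  populations; protein binding shifts the population fractions.
* **EMSA titrations.** Native-gel band shifts give fraction bound versus
  protein concentration, fit by the Hill isotherm
  `θ = (a − b) / (1 + (K_d,app/[protein])^n) + b`.

`fret3wj` implements the full analysis chain for both, for researchers
analyzing TIRF smFRET movies of static RNA conformers or gel-shift
titrations:

1. **Trace QC** — penalized change-point detection (exact optimal
   partitioning, C++) finds photobleach steps; molecules pass only with
   single-step bleaching; traces truncate at the first bleach;
   static/dynamic classification.
2. **Populations** — time-binned FRET histograms, two-stage Gaussian
   mixture fitting (per-population means anchor the overall fit),
   per-molecule assignment with bootstrap uncertainties, Welch t-tests
   between conditions.
3. **Geometry** — Förster conversion `R = R0·((1−E)/E)^(1/6)` (R0 = 60 Å
   for Cy3/Cy5), A-form contour lengths (2.8 Å/bp), and ranking of
   coaxial-stacking hypotheses: at `E = 0.2` the inter-label distance is
   75.6 Å, matching the 28 + 47.6 ≈ 76 Å sum of a 10 bp and a 17 bp stem
   laid end to end — the signature of coaxial stacking.
4. **Binding** — bounded multi-start Hill fits, fixed or free Hill
   coefficient, inverse-variance replicate combination.
5. **Synthetic data** — a ground-truth-labelled generator for two-channel
   trajectories (static states, Gaussian channel noise, exponential
   per-dye bleaching) and noisy titrations, so the whole pipeline is
   testable offline.

See `vignettes/fret3wj-methods.Rmd` for the models, defaults and their
rationale.

## Worked example

Simulate the naked three-state junction ensemble (states 0.2/0.3/0.4
FRET, ground-truth proportions 44/45/11%, 102 molecules) and run it end
to end:

```r
library(fret3wj)
rr <- run_pipeline(list(
  trace_sim  = fixture_config("stemII-5SL", "naked", seed = 1),
  assignment = "proportional",
  condition  = "naked"))
print(rr)
#> <run_report v0.1.0: stages simulate -> trace_analysis -> population_analysis -> junction_geometry>
#> condition 'naked' (92 molecules):
#>   component 1  FRET 0.200   43.5% +/- 5.3%  (n=40)
#>   component 2  FRET 0.302   46.7% +/- 5.4%  (n=43)
#>   component 3  FRET 0.400    9.8% +/- 3.1%  (n=9)
```

92 of 102 molecules survive QC (the rest never bleach or bleach too fast
to measure); the three Gaussian components land on the true state means,
and the assigned fractions recover the ground truth within their bootstrap
errors. The stems I/II construct gives the geometry headline:

```r
rep2 <- repro("figure2", seed = 1)
rep2$comparison_table
#>                              quantity reference recovered
#> 1                           FRET peak       0.2      0.20
#> 2            inter-label distance (A)      76.0     75.49
#> 3 stem I + stem II contour length (A)      76.0     75.60
```

and a noiseless titration refits its generating affinity exactly:

```r
tt <- simulate_titration(titration_sim_config(hill_params(17e-9, 1),
                                              noise_sigma = 0, n_replicates = 1))
fit_hill(tt, fix_n = 1)
#> <hill_fit: K_d,app = 1.7e-08 M +/- 5.5e-21, n = 1.00 (fixed), a = 1.00, b = 0.00, rss = 2.53e-25>
```

`repro("figure3")`, `repro("figure4")` and `repro("table1")` run the
bundled protein-condition and affinity fixtures the same way and emit
reference-vs-recovered tables.

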