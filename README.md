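# ringkinetics

Quantitative analysis of cytokinesis from annotated time-lapse microscopy,
built around the way contractile ring closure is measured in dividing
epithelial cells such as the *C. elegans* vulval precursor cells (VPCs):
the cell outline and the contractile ring are each annotated with three
points per frame in a division-plane (z, x) view, summarized as best-fit
circles, and turned into closure and asymmetry kinetics.

## What it computes

For each frame, with cell circle radius `R`, ring circle radius `r`, and
center-to-center distance `D`:

- **Ring closure** `= 100 · (1 − r/R)` — 0% for an unclosed ring, 100% when
  fully constricted (the raw ratio `r/R` is kept alongside).
- **Furrow asymmetry** `= 100 · D/R` — 0% for concentric closure, approaching
  100% for fully unilateral ingression.
- **Apical displacement** — the signed projection of the ring-center
  displacement onto the apical axis (positive = apically-directed furrowing,
  the polarity seen in epithelia).

Per-trace kinetics follow: the midpoint (50% crossing) time used to align
traces, the 20–80% average speed (OLS slope of closure vs time over that
window), the peak speed and the closure at which it occurs (≈50% for
sigmoidal closure), and population mean ± SEM curves. A morphometrics layer
provides box-model cell volumes (length × height × z-step thickness), ring
breadth from intensity profiles (baseline mean + 2 SD threshold), Ramanujan
division-plane perimeters, and the scaling regressions (breadth vs length,
speed vs perimeter). Group comparisons use unpaired t-tests and one-way
ANOVA.

Because such studies rarely deposit raw movies, the package includes a
synthetic-data module that generates ground-truth logistic closure traces
(`c(t) = 100/(1 + e^{−k(t−t0)})`, peak speed `25k` %/min) with
apically-polarized center drift (`asymmetry = α · closure`), jittered
three-point annotations, size-halving cell populations, and annulus-like
division-plane image stacks with kymographs — so every stage of the
pipeline is verifiable against known truth.

## Worked example

Simulate a VPC-like division (radius 2.5 µm, peak speed 18 %/min, apical
drift fraction 0.5, 0.05 µm annotation jitter, 30 s frames), quantify it
through the full annotation → circle-fit → metrics chain, and summarize:

```r
library(ringkinetics)

m   <- closure_model(k = 0.72, t0 = 5, R0 = 2.5, alpha = 0.5, seed = 7)
sim <- simulate_trace(m, trace_id = "vpc1")
tr  <- quantify_trace(sim)
kinetics_summary(tr)
#>   trace_id cell_label t_mid_min avg_speed_20_80 endpoint_speed_20_80 peak_speed
#> 1     vpc1       <NA>     4.985           16.37                   16      17.94
#>   closure_at_peak duration_10_90_min
#> 1           48.05              6.426
asymmetry_at_closure(tr, 80)
#> [1] 37.5
```

The recovered midpoint (4.99 min vs true 5), peak speed (17.9 %/min vs the
generating 25k = 18) near 48% closure, and asymmetry at 80% closed
(37.5% vs the drift model's α · 80 = 40, within annotation noise) show the
measurement chain reproducing the generating parameters.

Size scaling across three halving division rounds, 20 cells per stage:

```r
pop <- simulate_population(n_per_stage = 20, seed = 7)
tapply(pop$dimensions$volume_um3, pop$dimensions$stage, mean)
#>  3 VPC  6 VPC 12 VPC
#>  170.4   81.6   41.3         # volume halves each round
linear_scaling_fit(pop$breadths$length_um, pop$breadths$apical_breadth_um)
#> <scaling_fit> y = 0.2075 x + 0.7372 (R2 = 0.889, n = 60)
#>   slope SE 0.00963, intercept SE 0.0801   # truth: slope 0.2
```

`run_pipeline(run_config(), out_dir)` chains simulate → quantify →
summarize → population averaging and writes the trace, summary and
population CSVs plus a kymograph TIFF, deterministically for a given seed.

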