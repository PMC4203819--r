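---
title: "Measuring contractile ring closure kinetics from point annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring contractile ring closure kinetics from point annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringkinetics)
```

## The measurement model

During cytokinesis an actomyosin contractile ring constricts the division
plane. In tissues this is typically imaged as a time-lapse z-stack, the
dividing cell cropped and rotated to give a division-plane (z, x) view in
which the cell outline and the ring both appear as circles. Full
segmentation of a dim, moving ring is unreliable, so the practical
measurement is manual three-point annotation: three points on the cell
outline and three on the ring per frame, each summarized by the circle
through them.

`circle_through_points()` computes that circumcircle by solving the linear
system equating squared distances to the three points; with exactly three
points the residual is zero up to round-off, and the residual field exists
so that a least-squares extension to more points would not change the
interface. Collinearity is tested scale-free: the annotation is rejected
when the triangle's cross product is below `1e-6` times the squared longest
side, so the test behaves identically in pixels or micrometres.

From the two circles per frame (cell radius $R$, ring radius $r$, center
distance $D$) the package derives:

* closure $= 100\,(1 - r/R)$. The ratio $r/R$ is the primitive measurement;
  closure is reported as its complement so that curves rise from 0% to 100%
  as constriction proceeds, matching how closure kinetics are plotted. The
  raw ratio is retained (`frame_metrics()$r_over_R`).
* asymmetry $= 100\,D/R$, the non-concentricity of closure.
* apical displacement, the projection of the ring-center displacement onto
  a per-trace apical unit vector. The axis is supplied explicitly (default
  $(0, 1)$ in image coordinates, i.e. apical at the bottom of the frame)
  because anatomical direction cannot be inferred from the image alone.

Annotation jitter near cytokinesis onset can make the fitted ring
marginally larger than the cell. Ratios $r/R \in (1, 1.02]$ are clamped to
0% closure; anything larger is treated as a data error rather than clamped,
since it indicates a mis-annotated frame.

## Kinetics

Times are converted to minutes at ingest (`quantify_trace()`); all speeds
are in percentage points of closure per minute.

* **Midpoint alignment.** Traces are aligned at their 50%-closure crossing
  (linear interpolation between bracketing frames, first upward crossing on
  noisy traces) before population averaging, so that cells that enter
  cytokinesis at different absolute times superimpose.
* **Speed.** The closure series is smoothed with a centered moving average
  (default window 3 frames, chosen to suppress 30-second annotation jitter
  without flattening the speed peak; the window shrinks symmetrically at
  the ends so linear series are preserved exactly) and differentiated by
  central differences, one-sided at the endpoints. Speeds are computed per
  trace and then averaged — this matches per-point SEM reporting — rather
  than differentiating the average curve.
* **20–80% average speed.** The OLS slope of closure against time over the
  frames inside $[20, 80]$, with the interpolated 20% and 80% crossings
  appended as virtual samples. The endpoint estimate
  $60/(t_{80} - t_{20})$ is reported alongside: for a logistic trace the
  OLS slope is slightly larger than the endpoint average (about 11.45 vs
  10.82 %/min at $k = 0.5$), so the two are not interchangeable.
* **Peak speed.** The maximum of the smoothed speed series and the
  (smoothed) closure at that frame. Exact ties — e.g. perfectly linear
  closure — resolve to the middle tied frame, so a linear trace reports its
  peak at 50% closure rather than at an arbitrary end.
* **Monotonicity guard.** A trace whose smoothed closure drops more than 5
  points below its running maximum is rejected with a diagnostic; silent
  truncation would bias speeds. The 10–90% duration is reported as `NA`
  (with a warning) when a trace does not span those levels, because real
  annotation typically starts after furrow initiation and stops before the
  optical limit; the 20–80% core remains a hard requirement.
* **Population curves.** Traces are resampled onto a fixed grid (0.5 min in
  time, 2 closure points for asymmetry-vs-closure curves) by linear
  interpolation without extrapolation; each grid point reports mean, SEM
  ($sd/\sqrt{n}$, sample sd) and $n$, with points supported by fewer than 3
  traces flagged. SEM uses the sample (n−1) standard deviation throughout
  the package.

## Morphometrics and scaling

Cell volume uses the box model: length × height × thickness, thickness
counted as occupied confocal z steps times the step size (default 0.6 µm).
Ring breadth operationalizes "myosin enrichment brighter than the adjacent
cortex" as intensity exceeding the baseline mean + 2 SD, the baseline taken
from the profile outside the central 50% of the cell; the breadth is the
widest contiguous run above threshold, and the per-cell summary averages
the first five timepoints with detectable enrichment. The maximal-run
estimator is deliberately simple; with heavy pixel noise *inside* the
enrichment band it is biased inward (a single dipping sample truncates the
run), so profiles should be modestly smoothed or projected before breadth
extraction — the tests characterize this by placing measurement noise in
the baseline that defines the threshold.

The division-plane perimeter is modelled as an ellipse with semi-axes
height/2 and thickness/2 via Ramanujan's approximation
$\pi[3(a+b) - \sqrt{(3a+b)(a+3b)}]$; nothing in the analysis depends on the
cross-section being exactly elliptical, only on a consistent monotone size
measure. Scaling relations (breadth vs length; furrowing speed vs
division-plane perimeter, optionally pooled with user-supplied reference
points from other cell types) use ordinary least squares with slope and
intercept standard errors and $R^2$.

Group comparisons use the unpaired t-test (Student's pooled-variance by
default — the common historical default of graphing software — with Welch
available by flag) and classical one-way ANOVA; no multiple-testing
correction is applied, mirroring the source analyses these tools
reproduce.

## The synthetic-data generators

The generators encode the structure the analysis assumes, with defaults
chosen once to describe a VPC-like division:

| parameter | default | rationale |
|---|---|---|
| $k$ | 0.72 /min | peak speed $25k = 18$ %/min, the magnitude reported for VPC furrowing |
| $t_0$ | 5 min | division completes within ~10 min |
| $R_0$ | 2.5 µm | division-plane radius for a cell ~4.5 µm high, ~3 µm thick |
| $\alpha$ | 0.5 | apical drift fraction giving asymmetry ≈ 40% at 80% closure |
| `dt` | 0.5 min | 30-second acquisition intervals |
| jitter | 0.05 µm | half a pixel at 0.1 µm pixel size |
| closure span | 5–92% | see below |

Closure follows the logistic law — the minimal symmetric sigmoid consistent
with acceleration to a mid-closure maximum and deceleration thereafter —
and the ring center drifts apically by $d = \alpha(R_0 - r)$, which makes
ground-truth asymmetry exactly $\alpha \times$ closure: a single parameter
reproduces monotone asymmetry-vs-closure curves. Annotation points sit at
fixed angles (cell 90°/210°/330°, ring 30°/150°/270°, well-conditioned
triangles) with isotropic Gaussian jitter.

Simulated annotation spans 5–92% closure. The lower bound reflects that a
furrow is only annotated once the ring is distinguishable from the cell
outline. The upper bound is an annotation-physics constraint: at 95%
closure the true ring radius (0.125 µm at default $R_0$) is only 2.5× the
jitter, and the circumcircle through three points of a near-degenerate
triangle produces occasional order-of-magnitude radius errors — exactly
why real annotation stops when the ring approaches the resolution limit
(~0.2 µm radius here). The frame grid is uniform in `dt` and extended one
frame so the span's upper end is actually reached.

Population generation halves stage mean lengths across rounds (12 → 6 → 3
µm) with constant mean height (4.5 µm) and thickness (5 × 0.6 µm steps),
lognormal length variation (CV 0.1) and small dimension noise (CV 0.05);
breadths follow planted lines (apical 0.2·length + 0.8 µm, basal
0.15·length + 0.5 µm, SD 0.3 µm) clamped to $[0, \text{length}]$. Movies
render the ring as an annulus with a Gaussian radial profile (SD 0.2 µm ≈
a confocal PSF width) on a uniform background at 0.1 µm pixels.

Every generator is a pure function of its model object including the seed,
and restores the caller's RNG state.

What the generators do *not* emulate: mechanical coupling to neighbours or
junctions, photobleaching, PSF anisotropy, out-of-focus light, or
non-circular ring geometry. Passing tests therefore demonstrate that the
measurement chain recovers parameters under the assumed noise structure,
not that the assumptions hold for any particular microscope or tissue.

## Kymographs

`make_kymograph()` collapses each frame by maximum projection along one
image axis and stacks the profiles over time; a closing ring yields two
bright edges converging at $\pm r(t)$ around the (drifting) center.
`kymograph_band_separation()` measures the edge separation per time column
as the full width at half maximum with subpixel interpolation. A Gaussian
radial profile of SD $\sigma_r$ pushes the half-maximum crossing
$\sigma_r\sqrt{2\ln 2}$ outside the true edge on each side; when
$\sigma_r$ is known (as for synthetic movies, or calibrated from a line
profile) the width is corrected by $2\sigma_r\sqrt{2\ln 2}$, after which
the measured separation tracks the true diameter $2r(t)$ to well within
one voxel. The correction is skipped when $\sigma_r$ is not supplied, and
becomes unreliable once $r \lesssim \sigma_r$ (the two edges merge).

## Numerical choices and degenerate inputs

* Interpolation is linear everywhere; crossings use the first upward
  crossing, so noisy non-monotone traces are handled deterministically.
* Duplicate and collinear annotation points, rings larger than the cell
  beyond tolerance, non-unit apical axes, non-monotone timestamps,
  windows longer than traces, degenerate (constant-$x$) regressions,
  zero-variance t-tests, out-of-bounds ROIs and zero backgrounds are all
  hard errors with messages naming the offending frame, row or trace.
* `run_pipeline()` skips and logs traces that fail quantification or
  summarization rather than aborting the run, and its CSV outputs embed
  the full configuration as `#` header lines, so reruns with the same
  config and seed are byte-identical.

## Problem sizes used in the test suite

The suite verifies the geometry against an independent barycentric
circumcenter oracle on 1000 random triples, runs end-to-end parameter
recovery on 20 simulated noisy traces, population coverage on 20 × 50
traces, type-I-error calibration on 2000 ANOVA replicates, and the imaging
chain on 64 × 64 × ~16 synthetic movies — sizes at which every check is
statistically meaningful while the whole suite completes in well under a
minute.

## Known limitations

Three-point circumcircle fitting is exact but not noise-optimal; a
least-squares fit over more annotation points would reduce radius variance
and is the natural extension of the `circle_fit` interface. Ring geometry
is assumed circular (no ellipse model). The asymmetry-vs-closure slope is
fitted by unconstrained OLS, so near-zero drift can yield slightly negative
slopes under noise. The breadth estimator's inward bias under in-band noise
is documented above. External reference points for speed-vs-perimeter
scaling are taken as supplied, not recomputed from images.
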