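---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaquant)
```

This vignette is the package's own account of what it measures, what its
synthetic-data generators emulate, and why the open design choices were
made the way they were.

## 1. Crawling kinematics

### The measurement

Larval crawling is a train of peristaltic contraction–elongation cycles.
With five tracked spine points per frame, the spine length
$L(t) = \sum_{i=1}^{4} \lVert p_{i+1}(t) - p_i(t) \rVert$ oscillates once
per cycle, so its time derivative oscillates smoothly around zero.
`segment_cycles()` defines a cycle boundary as a *positive-going* zero
crossing of the smoothed derivative — the start of elongation. Any
consistent crossing phase yields identical durations and net displacements
over full cycles; positive-going is simply the convention this package
fixes and documents. Crossing times are interpolated linearly between the
bracketing frames: at 5 frames/s a frame lasts 0.2 s, and without
interpolation stride durations would be quantised to 0.2 s steps —
useless against a ~1.1 s cycle.

Per cycle, stride duration is the inter-crossing interval and stride
length the *net* (straight-line) centroid displacement between the
interpolated boundaries. Net rather than path displacement is used because
the within-cycle path is already captured by the walking rate, which is
deliberately a different quantity: the mean frame-to-frame centroid
displacement rate across the whole recording, pauses and lateral motion
included.

### Tunable parameters

* **Smoothing window** (`window`, frames; default 3 = 0.6 s). The 5 fps
  sampling leaves only ~5.5 frames per cycle; a 5-frame window already
  attenuates the oscillation severely. Window 1 disables smoothing.
  Endpoints (and frames adjoining gaps) use one-sided means and
  differences.
* **Minimum cycle duration** (`min_cycle_duration`, s; default 0.4, i.e.
  under half a typical stride duration). Noise can produce double
  crossings; cycles shorter than this are merged into the following
  cycle.
* **Zero tolerance** (`zero_tol`, mm/s; default 1e-9). Derivative values
  below this magnitude count as exactly zero, so a numerically constant
  spine length yields no cycles instead of floating-point-jitter cycles.
* **Gap policy**: gaps are preserved at I/O level, never interpolated;
  cycles spanning a gap are discarded and gap-adjacent steps are skipped
  in the walking rate.

### The synthetic crawler

`simulate_larva()` inverts this measurement. Spine length follows
$L(t) = L_0 - a\cos(2\pi\phi_j(t))$ with the phase rising 0→1 over cycle
$j$, so the derivative crosses zero upward exactly at each boundary.
$L_0 = 4$ mm and $a = 0.15\,L_0$ (the contraction amplitude is not a
published number; 15% is of the order of larval segment-contraction
excursions and is configurable). The centroid advances $S_j$ mm linearly
over each cycle along a slowly meandering heading (default heading step
sd 0.15 rad/cycle — mild course drift during an escape crawl; heading
changes do not affect any of the three metrics).

Two design points deserve emphasis:

**Variance placement.** Published cohort values come as mean ± SEM over
larvae, each larva itself an average over ~18 cycles. The generator
therefore draws each *larva's* mean stride length and duration from
`Normal(mean, sd)` — the `sd` parameters are between-larva spreads, set in
the packaged configs to SEM·√n — and jitters individual cycles around the
larva's means with the same sd. Putting the whole sd at the cycle level
instead would shrink the cohort SEM by a further √18, producing cohorts
far more uniform than the published ones and making "recovery within
2 SEM" a test of sub-half-percent numerical bias rather than of the
measurement. Draws are truncated (durations at half the mean, lengths at
zero) for physical positivity; at these coefficients of variation the
truncation shifts means by well under 0.1%.

**Walking rate and wobble.** The published walking rate (1.15 mm/s,
control) exceeds stride length over stride duration (≈1.07 mm/s): real
larvae do not travel in straight lines, so the path rate exceeds the net
rate. The generator models the difference as a constant-amplitude lateral
wobble that alternates side every frame, giving per-frame steps
$\lvert\text{step}\rvert^2 = d_j^2 + w^2$ with $d_j = S_j/(T_j\,\text{fps})$
the cycle's net step. Two refinements over solving this with cohort means:
the per-larva target rate is $v_l = \bar v \,(S_l/T_l)\,/\,E[S_l/T_l]$,
with the expectation computed by quadrature over the truncated larva-level
distributions — so the cohort mean walking rate equals $\bar v$ without
the ~2% Jensen bias of $E[S/T] > \bar S/\bar T$, and $v_l$ never falls
below the larva's own net rate (which would make $w$ imaginary); and $w$
solves the time-weighted path-rate equation on the larva's realised cycle
draws, so each simulated larva's measured walking rate lands on its
target almost exactly. With all sds at zero both refinements reduce to
the plain closed form $w = \sqrt{(v/\text{fps})^2 - d^2}$.

Pauses (probability per cycle boundary, default 0) freeze the whole
larva — position and spine phase — for a fixed duration; the walking rate
averages over pause frames, matching a whole-recording average. Head
sweeps and reorientation kinematics are *not* modelled beyond this; the
generator's larvae never cast or curl, so passing recovery tests says
nothing about how the pipeline handles strongly bent postures in real
data.

## 2. FISH col/nau quantification

### The measurement

`quantify_stack()` chains three steps that mirror standard practice for
relative nascent-transcript quantification: a *sum-slices* projection over
z (sum, not maximum, so integrated intensity is preserved); a per-channel,
per-image background threshold with *soft subtraction* (pixels at or below
the threshold are zeroed, the threshold value is subtracted from the
rest — a hard clip would carry the full background pedestal into every
ROI integral); and the ratio of mask-integrated intensities
$R = I_{col}/I_{nau}$ per nucleus. The per-nucleus ratios are then
averaged per group — ratio-then-mean, not ratio of group sums, so each
nucleus contributes equally. Group comparisons use the unpaired
pooled-variance t-test.

The default threshold is the 50th percentile of the projected image:
transcription foci are sparse, so the median estimates the background
level. Both method and value are exposed in configuration and recorded in
the measurement metadata; they are declared conventions, not inferred
ones. Masks are consumed, never computed — nucleus segmentation is out of
scope, mirroring workflows where ROIs are drawn on an independent nuclear
marker.

### The synthetic stacks

`simulate_fish_stack()` places non-overlapping ellipsoidal nuclei
(semi-axes 3×6×6 px) in a 12×256×256 stack and renders one focus per
nucleus per channel as a unit-mass 3D Gaussian (σ = 1.5 px) at the
nucleus centre, scaled so the col/nau amplitude ratio of nucleus $i$ is
exactly $R_i \sim \text{Normal(ratio\_mean, ratio\_sd)}$. The packaged
configs transcribe the published group ratios with ratio_sd = SEM·√n, a
constant background of 50 counts/voxel, nau amplitude 5·10⁴ counts and
Poisson shot noise. Because both channels use the same focus kernel, the
noise-free measured ratio equals $R_i$ to machine precision regardless of
mask truncation of the Gaussian tails — the exactness property the test
suite asserts.

What the generator does *not* emulate: chromatic shift between channels,
nuclear autofluorescence, uneven illumination, out-of-focus haze from
neighbouring structures, or foci away from the nucleus centre. The
residual pipeline bias under the emulated noise (clipped-noise pickup in
the ROI, ~1% of the ratio, toward 1) is well inside one SEM at the
published group sizes.

16-bit TIFF round-trips are lossless exactly when stack values are
integers; Poisson-noise stacks are integer-valued by construction, while
noise-free stacks are continuous and are therefore compared in memory.

## 3. Phenotype tallies

`sample_phenotypes()` draws i.i.d. multinomial segment calls;
`tally_phenotypes()` reports per-genotype category proportions with
Wilson score 95% intervals. Wilson rather than Wald or Clopper–Pearson:
the published proportions sit near the extremes (85.2%, and categories
near 0%), where the Wald interval collapses and Clopper–Pearson
over-covers; Wilson behaves sensibly at both n ≈ 100–200 and p near 0
or 1. Because segments of one animal may not be independent, the tally
also reports per-animal-averaged proportions; the packaged configs fill
the categories the publication does not enumerate with small plausible
values, and only the published categories are used for validation.

## 4. Genotype statistics

`fit_genotype_model()` is ordinary least squares with treatment coding
and the control genotype as reference — each larva one unit, two-sided
tests, no multiple-testing correction (matching how raw pairwise p-values
are conventionally reported for these assays). With two groups the
contrast is exactly the difference of means and its t the pooled
two-sample t; the tests verify this identity numerically.
`summarize_cohort()` adds mean ± SEM and Tukey box descriptors; the
median notch uses the standard $1.57\,\text{IQR}/\sqrt{n}$ approximation
to the 95% interval of the median. Power check: at the published group
sizes and between-larva spreads, the closed-form power for the
stride-length contrast (0.09 mm effect) is ≈ 0.74 at α = 0.05; the test
suite verifies the Monte-Carlo rejection rate against that closed form
rather than against a round number.

## 5. Problem sizes and determinism

Validation runs use the published group sizes throughout: 118 and 108
larvae (20 s at 5 fps), nucleus groups of 28/18/24/25, and 190/103
segment draws. These are small enough that the whole suite runs in
seconds. Every generator takes an explicit integer seed; cohorts derive
per-larva sub-seeds as `(seed · 10007 + i) mod (2³¹−1)`, which makes
generation order-independent and keeps nearby base seeds from sharing
larvae. Identical (parameters, seed) give bit-identical outputs.

## 6. Known limitations

* The kinematics pipeline assumes an essentially straight, forward-crawling
  posture; it does not classify head casts, turns or backward waves, and
  recovery tests on synthetic data cannot certify behaviour on recordings
  dominated by reorientation.
* At 5 fps, cycles shorter than ~0.5 s approach the sampling limit;
  the generator's truncation at half the mean duration keeps simulated
  cycles above it, but real data faster than that would alias.
* The FISH quantifier measures relative, not absolute, transcription and
  inherits the usual caveats of intensity ratios under a shared threshold
  convention.
* Phenotype confidence intervals treat segments as independent trials;
  the per-animal view is descriptive, with no clustered-variance model.
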