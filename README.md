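# larvaquant

Quantification toolkit for three measurements used in studying how
muscle-identity defects affect *Drosophila* larvae: crawling kinematics from
spine-tracking tables, nascent-transcript levels from two-channel FISH
stacks, and muscle phenotype proportions — together with synthetic-data
generators that produce each input with known ground truth, so every
pipeline can be validated by parameter recovery.

## Who this is for

Labs quantifying larval locomotion from FIM/FIMTrack-style exports
(per-frame spine-point coordinates), measuring relative nascent
transcription by intronic-probe FISH, or scoring segmental muscle
phenotypes — and anyone who wants a tested, scriptable reimplementation of
these measurements rather than one-off analysis code.

## The measurements

**Crawling kinematics.** A tracked larva is five ordered spine points
p1..p5 per frame (head to tail, mm, 5 frames/s). The spine length
L(t) = Σᵢ |pᵢ₊₁(t) − pᵢ(t)| oscillates with the peristaltic wave; its
smoothed derivative dL/dt oscillates around zero, and each positive-going
zero crossing (start of elongation) marks a cycle boundary. Per cycle j:

* stride duration `T_j = t_{j+1} − t_j` (crossing times interpolated
  between frames);
* stride length `S_j = |p3(t_{j+1}) − p3(t_j)|`, the net centroid
  displacement across the cycle;
* walking rate `v = mean_t |p3(t+1) − p3(t)| · fps`, the centroid path
  rate over the whole recording.

Values are averaged per larva (the statistical unit), then compared across
genotypes with an ordinary linear model using genotype as fixed effect.

**FISH col/nau ratio.** For a two-channel z-stack (collier and nautilus
intronic probes; one nascent-transcription focus per active nucleus per
channel), the stack is sum-projected over z, a per-channel background
threshold is subtracted, and the ratio R = I_col / I_nau of the
mask-integrated intensities is computed per nucleus; groups are compared
with an unpaired t-test.

**Phenotype tallies.** Per-segment categorical calls (normal DA3, branched
DA3, DA3>DA2 transformed, absent) are tallied per genotype with Wilson 95%
confidence intervals, at segment level and per-animal-averaged.

## Worked example

Simulate three control larvae at the packaged control-genotype parameters
and run the full kinematics chain:

```r
library(larvaquant)
co <- simulate_cohort(3, packaged_config("kinematics", "control"), seed = 1)
m  <- analyze_cohort(co)
print(m, digits = 4)
#>      larva_id walking_rate stride_length_mean stride_duration_mean n_cycles
#> 1 control_001       1.5452              1.406               0.9504       20
#> 2 control_002       1.5545              1.400               0.9711       19
#> 3 control_003       0.8494              0.784               1.0648       17
```

Each row is one larva: its crawling speed (mm/s), mean stride length (mm),
mean stride duration (s) and the number of complete peristalsis cycles
found in the 20 s recording. Larva-to-larva spread is deliberate — the
generator draws each larva's own means from the cohort distribution. At
the published cohort size (n = 118) the cohort means recover the
generating values (1.15 mm/s, 1.17 mm, 1.09 s) within two standard errors.

The FISH pipeline on a synthetic wild-type founder-cell group:

```r
p   <- packaged_config("fish", "wt-fc")
sim <- simulate_fish_stack(p, seed = 7)
mq  <- quantify_stack(sim$stack, sim$masks, genotype = "wt-fc")
sprintf("col/nau = %.3f +/- %.3f (n = %d)",
        mean(mq$R), sd(mq$R) / sqrt(nrow(mq)), nrow(mq))
#> "col/nau = 2.269 +/- 0.038 (n = 28)"
```

i.e. the group mean ratio recovers the generative 2.20 within two SEM.

File-based workflows use `write_tracks()` / `read_tracks()` (CSV dialect:
`larva_id, frame, time_s, x1..x5, y1..y5`, mm, 0-based frames, y down),
`write_stack()` / `read_stack()` (16-bit multi-directory TIFF,
channel-major slices; integer-labelled mask TIFF) and `read_config()`
(YAML). A thin command-line front end with `analyze-tracks`,
`quantify-fish`, `tally` and `report` subcommands is installed at
`inst/cli/larvaquant`.

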