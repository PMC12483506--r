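---
title: "Mapping corticostriatal input with LSPS: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping corticostriatal input with LSPS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis

Laser-scanning photostimulation (LSPS) with glutamate uncaging maps the
presynaptic territory of a single recorded neuron: an ultraviolet beam
uncages glutamate at each site of a stimulation grid placed over cortex
(here 29 x 16 sites at 75 um, covering the barrel field), driving neurons
near the beam to fire, while a striatal projection neuron (SPN) is held in
whole-cell voltage clamp at -80 mV. A site whose stimulation evokes
excitatory postsynaptic currents (EPSCs) hosts at least one presynaptic
cell, to within the ~75 um excitation resolution of the method.

`lspsmap` implements the full analysis chain:

1. **Detection** (`detect_site_response()`, `build_maps()`): per-site,
   per-repetition EPSC detection with a 3-SD threshold and a >= 2-repetition
   consistency rule, yielding a synaptic *input map* (mean evoked amplitude
   in pA) and its binary support, the *connectivity map*.
2. **Pattern geometry** (`collapse_and_clusters()`, `column_count()`,
   `field_metrics()`, `layer_summary()`, `dominant_cluster_ratio()`):
   clusters on the vertically collapsed profile, cortical-column counts
   (`sum(ceiling(ConsSites/2))`, one barrel column ~ 150 um ~ 2 sites),
   input-field width and gap fraction, layer-wise EPSC sums.
3. **Topography** (`connectivity_cm()`, `synaptic_cm()`,
   `topography_summary()`, `projection_zone_width()`): lateral centers of
   mass referenced to the striatum/GPe/internal-capsule junction (Ref_hor)
   and cohort-level correlation with SPN position.
4. **Pairwise heterogeneity** (`pair_metrics()`, `cohort_pairs()`): field
   overlap, vertical alignment and exact site overlap for cells recorded in
   one slice.
5. **Excitation profiles** (`ap_metrics()`, `convert_site_count()`,
   `excitation_radius()`): AP counts on the fine 50-um calibration grid and
   their area-preserving conversion to the mapping grid.
6. **Truncation Monte-Carlo** (`estimate_truncation_loss()`): expected
   fraction of synaptic contacts removed by slicing, under a spherical
   dendritic-field model.

A synthetic-data generator (`generate_cohort_truth()`,
`simulate_sweepset()`, `simulate_excitation_profile()`) produces cohorts
with known ground truth so that every stage is testable without recordings.

## Detection: the operating point

Each sweep is 100 ms of baseline followed by the uncaging pulse and a 450 ms
post-stimulus segment; only the first 50 ms after the stimulus count as the
evoked-response window. Per sweep, the baseline mean and SD come from the
raw pre-stimulus segment; the response amplitude is the magnitude of the
most negative baseline-subtracted current in the window, retained when it
exceeds 3 baseline SDs. A site is connected when at least two repetitions
(of 2-4) carry a detection; the map value averages the detected peaks
(`mean_mode = "detected"`; the zero-including mean over all repetitions is
available as `"all"`, but it systematically understates the amplitude scale
whenever a site is detected in 2 of 3 repetitions).

Two numerical choices matter here:

* **Peak search runs on a 2 ms boxcar-smoothed copy of the trace, while the
  threshold stays tied to the raw baseline SD** (~9.2 pA at the ~3 pA noise
  the generator emulates). What the rule detects is an EPSC-shaped
  deflection, with a ~1 ms rise and ~10 ms decay, which passes the boxcar
  nearly intact. The raw single-sample minimum of a 50 ms window, by
  contrast, exceeds 3 SD in a large fraction of sweeps for broadband noise
  at any realistic sampling rate - an extreme-value property of Gaussian
  noise, not a property of the recordings - so a literal raw-minimum
  reading would flag sites everywhere. `boxcar_ms = 0` restores the raw
  minimum for sensitivity analyses.
* **Threshold scope.** The default estimates the SD per sweep
  (`sd_scope = "site"`); `sd_scope = "cell"` pools the median per-sweep SD
  over the whole map, which makes the threshold a stable per-cell quantity
  and resists single baselines contaminated by spontaneous events. A
  `sd_floor` of 1e-6 pA guards degenerate flat traces.

### The false-positive budget

A spontaneous EPSC falling inside the response window of a sweep is
indistinguishable from an evoked one; the >= 2-repetition rule is the only
defense. With window length $w$ = 50 ms and spontaneous rate $r$, a sweep is
hit with probability $p = 1 - e^{-rw}$, and a site with 3 repetitions is
spuriously connected with probability $3p^2(1-p) + p^3$. Keeping that below
1% of sites requires $p \lesssim 5.9\%$, i.e. $r \lesssim 1.2$ Hz once the
(near-zero) smoothed-noise contribution is added. The generator's default
`spont_rate_hz = 0.75` - a plausible sEPSC rate for SPNs at room
temperature - sits inside this budget with a factor ~2.5 margin; the rate is
a free parameter of the emulated preparation, and doubling it to 2 Hz
pushes the spurious-site rate to ~2.5%, which is visible in the null-control
test if you try it.

## The synthetic generator: what it emulates

* **Traces**: 100 ms baseline + 450 ms post-stimulus at a configurable
  sampling rate (the rate is stored with the data, never assumed), white
  Gaussian noise of SD 3.07 pA so that the 3-SD threshold lands at ~9.2 pA
  (an AR(1) `noise_corr_ms` option adds autocorrelation), Poisson
  spontaneous EPSCs of 10-20 pA, and difference-of-exponentials EPSC
  kinetics (rise 1 ms, decay 10 ms - standard AMPA-receptor-like values
  that keep events well under 50 ms).
* **Evoked responses**: each ground-truth source site carries 1-5
  presynaptic cells; the per-repetition amplitude is the sum of `n_presyn`
  log-normal per-synapse draws (trial-to-trial CV 0.2) around a per-site
  mean that is itself log-normal with population mean 40 pA. Latency is
  Gaussian (7 +/- 2 ms), clipped to stay inside the window.
* **Connectivity patterns**: per cell, a cluster count drawn with mean 1.9,
  cluster widths of mostly 1-2 columns, inter-cluster gaps of
  1 + Poisson(2.5) columns (mean spacing ~260 um), and connected rows
  weighted by a per-layer probability vector that concentrates input in
  L5a/L5b. The first cluster is centred on a topographic target
  `intercept + slope * position + N(0, jitter)`; later clusters alternate
  sides. Requested columns falling off the grid are clipped (flagged in the
  truth), and the stored `cluster_plan` is always the *realized* set of
  column runs, so downstream recovery can be checked exactly; clipping makes
  the realized mean cluster count (~1.7) slightly lower than the drawn mean.
* **Topographic scatter**: with cell positions uniform over
  `pos_range_um` (SD = range/sqrt(12) ~ 433 um for the default 300-1800 um)
  the expected cohort Pearson R between center of mass and position is
  `slope * sd(pos) / sqrt(slope^2 sd(pos)^2 + jitter^2 + s_place^2)`, where
  `s_place` ~ 150 um is the scatter contributed by discrete cluster
  placement. The default `jitter_sd_um = 550` targets R ~ 0.6. Setting
  `jitter_sd_um = 0` with `pos_on_lattice = TRUE` and single-column clusters
  makes the realized center of mass equal the cell position exactly
  (R = 1), the degenerate configuration used for exactness tests.
* **Excitation profiles**: on the 8 x 8, 50 um calibration grid every site
  within `excitation_radius_um` of the central (somatic) site fires one AP,
  or two with a small per-type probability (3-4%), matching mean
  spikes-per-site of ~1.03-1.04; all other sites are silent.

What it does **not** emulate: feedforward inhibition (prevented under LSPS
at -80 mV), direct somatic/dendritic activation artifacts, electrode series
resistance and drift, 1/f and line noise, the spatial blur of excitation
(evoked events appear exactly at truth sites, not at +/- 1 column), and
correlations between spontaneous activity and stimulation. Passing tests on
synthetic cohorts therefore validate the *analysis*, not the biology: they
show the chain recovers known ground truth under the stated noise model.

## The noise-free regime

Exact end-to-end recovery (detection equal to truth site-for-site, cluster
plans matched exactly) is only meaningful without stochastic corruption:
at any finite noise level a 3-SD rule has a nonzero false-positive floor,
which over tens of thousands of null sites guarantees a few spurious sites.
`noise_free()` switches off baseline noise, spontaneous events, amplitude
CV and latency jitter; the test suite uses it for the 200-cell
parameter-recovery check, and uses the full default noise model for the
statistical checks (null control < 1%, amplitude calibration within 5%,
single-source detection >= 95%).

## Centers of mass

The connectivity CM weights each column by its vertical count of connected
sites; the synaptic CM weights each column by the *mean* EPSC over its
connected sites (zeros excluded - including them would re-weight columns by
their depth coverage). The two coincide for maps with equal per-column
counts and equal amplitudes, but differ in general even for uniform
amplitudes, because one is count-weighted and the other count-normalized;
both are translation-equivariant in the grid offset and confined to the
field extent.

## Pairwise metrics

Both percentages pool the two maps (`100 * (aligned_A + aligned_B) /
(|A| + |B|)`): "aligned" means the site's column contains at least one
connected site of the other map (strict same-column matching; no +/- 1
column tolerance is applied for the excitation resolution), "overlap" means
exact (row, col) coincidence, so overlap never exceeds alignment. Field
overlap is the inclusive intersection of the two column spans. Distance
bins are half-open 100 um bins anchored at zero separation; empty bins are
reported as NA, never as zero.

## Excitation-profile conversion

`convert_site_count(sap, from, to)` rescales a firing-site count by
`(from/to)^2`: a site on a grid of spacing `s` stands for an area `s^2`, so
the excitable territory is conserved. Converting the 50 um calibration
grids to the 75 um mapping grid multiplies by (50/75)^2 = 4/9; with the
per-type spike statistics of the calibration recordings (total spikes
5.4 and 9.9, spikes-per-site 1.03 and 1.04, n = 30 and 10 for the two L5
populations) the n-weighted mean firing-site count converts to 2.8 sites of
the mapping grid. The reciprocal ratio sometimes quoted for this conversion
would inflate the excited area ~5-fold and is treated as a typo.

## Truncation Monte-Carlo

The SPN dendritic field is a sphere centred on the soma; 80% of synapses
are dendritic, placed at a radius drawn from a radial density table with an
isotropic direction, and the remaining 20% are somatic and never lost.
Slicing removes a spherical cap: a synapse is lost when its coordinate
toward the cut surface exceeds the soma depth (default 80 um, the
shallowest recording depth - a conservative fixed plane rather than a depth
distribution; the far slice face is 350 um away and ignored). For all mass
at one radius the loss has the closed form
`frac_dendritic * (r - d) / (2r)`, which the estimator must match within 3
Monte-Carlo SE.

The default radial density is a **triangular profile rising from the soma
to a peak at 80 um and vanishing at the 200 um dendritic radius**. This is
an explicit modelling assumption standing in for measured synapse
distributions along SPN dendrites: proximal density grows with the
expanding dendritic tree, distal synapses are proportionally rare. It is
fully user-overridable (`radial_density` takes any bin/weight table). Under
it, the expected loss is analytically
`0.8/24000 * integral_80^200 (r-80)(200-r)/r dr ~ 7.1%`, below the 10%
bound the model is meant to check; `scripts/acceptance.R` recomputes this
number by simulation.

## Reproducibility and problem sizes

All randomness flows through explicit `seed` arguments; sub-streams are
derived per stage by fixed labels, so toggling one pipeline stage never
changes another's draws, and `run_pipeline()` output is byte-identical
across runs with one seed. The test suite runs its sweep-level checks at
reduced acquisition settings (1-2.5 kHz, 160-200 ms traces) and its
statistical checks at 10-200 cells per cohort - sizes chosen so the whole
suite completes in a few minutes while keeping Monte-Carlo standard errors
well inside the asserted tolerances; the analysis itself is
rate-independent apart from the trivial discretization of the EPSC kernel.

## Known limitations

* Clusters are defined on the collapsed profile only; no 2-D clustering.
* Maps are aligned across slices by metadata (column offset relative to
  Ref_hor, L5a row) and never resampled; sub-spacing misalignment is not
  modelled.
* The dominant-cluster ratio divides the strongest cluster's EPSC sum by
  the *mean* of the others (`mode = "sum"` divides by their total); both
  readings are plausible and both are exposed.
* Inferential statistics (rank tests, ANCOVA) are out of scope; only
  descriptive Pearson/Spearman correlations and least-squares residuals are
  produced, to be fed into whatever testing framework the study design
  requires.
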