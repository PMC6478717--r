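---
title: "scramblekit: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scramblekit: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scramblekit)
```

scramblekit quantifies Ca^2+^-activated phospholipid scramblase (CaPLSase)
function from three kinds of data: time-lapse Annexin V (AnV) fluorescence
movies, patch-clamp current sweeps, and particle trajectories along the
membrane normal. Each analysis stage is paired with a seeded synthetic
generator that emulates the statistical structure the stage assumes, so
every estimator in the package can be validated against known ground truth.
This vignette explains the underlying models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
establish about real data.

## Scrambling kinetics from AnV movies

Scramblase activity exposes phosphatidylserine (PS) on the cell surface,
where fluorescent AnV conjugates accumulate. The per-cell readout is the
summed ROI intensity per frame,

$$I = \sum_{n=1}^{N} i_n,$$

over the $N$ pixels of a manually assigned region of interest, and the
kinetic score is $t_{1/2}(I_\mathrm{max})$: the earliest time at which the
baseline-subtracted trace reaches half of its in-window maximum. Using a
half-maximal time rather than the amplitude makes the score robust to
expression-level differences between cells.

Key parameters (all exposed as arguments, defaults in parentheses):

* `frame_interval_s` (5 s) and `window_s` (600 s) - acquisition interval
  and analysis window. The window is restricted to the first 10 minutes
  after ionophore application because apoptosis-driven scrambling begins to
  contaminate the AnV signal on longer timescales.
* `baseline_window_s` (15 s) - pre-stimulus frames averaged for the
  baseline. When a movie starts at the stimulus, the stimulus-frame
  intensity itself is the baseline. We deliberately avoid averaging
  early post-stimulus frames: for fast-scrambling cells they already carry
  signal, which would bias $t_{1/2}$ late, and it would make the
  half-max time of a noiseless linear ramp inexact.
* `fold_threshold` (2) - a cell is a scrambler when its in-window maximum
  reaches twice the baseline. The assay literature states no numeric
  rule ("did not exhibit activity"), so this is a configuration knob;
  non-scramblers receive an infinite-$t_{1/2}$ sentinel and are excluded
  from every mean, SEM and test.
* `median_filter` (off) - optional 3-frame running median. Endpoints are
  median-filtered too, because the first frame can anchor the baseline.

Numerical choices: half-max crossing is linearly interpolated between the
bracketing frames and the *first* crossing wins (ties broken earliest);
baseline subtraction is always applied, since the half-max of a raw summed
intensity is degenerate for nonzero baselines; intensities are summed, not
averaged, so ROIs of different sizes remain comparable through the
half-max normalization. $t_{1/2}$ is invariant to affine intensity
rescaling and equivariant under time shifts.

The movie generator renders disk-footprint cells whose summed intensity
follows a logistic onset
$b + (I_\mathrm{max} - b)\,\sigma((t - t_{1/2})/w)$. A logistic was chosen
because observed single-cell traces are sigmoidal and its midpoint equals
the true half-max time analytically, which gives exact oracles. Footprints
may not overlap - overlap would make the per-cell ground truth ambiguous,
and the assay this emulates used manually drawn, disjoint ROIs. Phenotypes:
`scrambler` (logistic onset), `non_scrambler` (baseline), `constitutive`
(maximal from frame 0), `apoptotic` (constitutive plus a flag standing in
for caspase 3/7 positivity; no morphology is modelled). Noise is Gaussian
read noise plus optionally variance-proportional shot noise. The generator
does not model point-spread functions, photobleaching, stage drift or
segmentation errors, so passing tests certify the estimators, not a
segmentation pipeline.

Constitutively scrambling mutants are scored differently: the fraction of
PS-positive expressing cells, pooled over 10-20 fields of view per
coverslip (`percent_ps_positive()`). The cohort generator draws per-cell
phenotypes binomially; its defaults (10-20 fields, ~15 expressing cells
per field) mirror typical counting experiments.

## Patch-clamp analysis

`build_iv()` takes the steady-state current per test step as the mean of
the last 10% of the step (the protocol literature says "steady-state"
without a window; the fraction is configurable). `build_gv()` takes the
peak tail current within 10 ms of repolarization onset, with the sign set
by the dominant tail polarity, and normalizes to the largest tail so the
G-V curve peaks at exactly 1. `measure_erev()` uses only the descending
phase of an inverted-V ramp and interpolates the zero-current crossing
linearly; on noisy ramps with several crossings it takes the one nearest a
supplied previous-condition value, or the median crossing otherwise, and
reports the multiplicity.

Ion selectivity uses the Goldman-Hodgkin-Katz voltage equation

$$V_m = \frac{RT}{F}\,\ln\frac{P_{Na}[\mathrm{Na}]_o + P_{Cl}[\mathrm{Cl}]_i}
{P_{Na}[\mathrm{Na}]_i + P_{Cl}[\mathrm{Cl}]_o},$$

with $F = 96485$ C mol^-1^, $R = 8.314$ J mol^-1^ K^-1^ and $T = 298.15$ K
($RT/F \approx 25.693$ mV). For the 140 mM to 14 mM NaCl internal dilution
design, the measured reversal shift inverts in closed form to
$P_{Cl}/P_{Na} = (\mathrm{Na}_o - e\,\mathrm{Na}_i)/(e\,\mathrm{Cl}_o -
\mathrm{Cl}_i)$ with $e = \exp(V_m F/RT)$. Shifts at or beyond the Nernst
limits ($\pm 59.16$ mV for the 10:1 dilution) correspond to pure
single-ion selectivity and are rejected as non-representable rather than
returned as infinities. The forward and inverse maps round-trip to
relative error below $10^{-9}$ across ratios from $10^{-3}$ to $10^{3}$.

### Free Ca^2+^ of EGTA-buffered solutions

`free_calcium()` solves the 1:1 Ca-EGTA equilibrium: with the apparent
dissociation constant $K_d' = \alpha_H / K_{CaL}$, where
$\alpha_H = 1 + 10^{pK_{a1}-pH} + 10^{pK_{a1}+pK_{a2}-2\,pH}$ accounts for
competition by protons, the free concentration is the positive root of

$$\mathrm{Ca}_{free}^2 + (\mathrm{EGTA}_{tot} - \mathrm{Ca}_{tot} + K_d')\,
\mathrm{Ca}_{free} - K_d'\,\mathrm{Ca}_{tot} = 0.$$

The constant set is pluggable and always echoed in the output, because
published Ca-EGTA constants genuinely disagree: association-constant
tables (`egta_constants("martell")`: $pK_a$ 9.47/8.85,
$\log K_{CaL} = 10.86$) predict roughly 2.5-fold less free Ca^2+^ than
direct measurements of Ca-EGTA buffers and the calculator family commonly
used to design physiological solutions. The default `"apparent"` set
($\log K_{CaL} = 10.49$ at 25 degC, ionic strength ~0.15 M) is that
measured-apparent calibration; it reproduces fluorimetrically verified
recipes such as the 2.26 uM internal solution (5 mM EGTA + 4.64 mM total
CaCl~2~ at pH 7.3) to within a few percent:

```{r}
free_calcium(solution(na_mM = 140, egta_mM = 5, ca_total_mM = 4.64,
                      ph = 7.3))$ca_free_uM
```

Limitations: the solver treats a single divalent species (no Mg^2+^
competition; at pH 7.3 proton competition dominates the correction by
three orders of magnitude, and Na^+^ binding to EGTA is negligible for the
same reason), and applies no explicit temperature or ionic-strength
transfer - the constant sets are stated at the conditions they are valid
for.

## Permeation profiling of trajectories

The permeation analyses operate on time-stamped particle positions with
species labels (`water`, `phosphate`) and replicate ids - the format the
Langevin generator writes and any trajectory source can be adapted to.
`select_frames()` applies the conventional equilibration discard (default:
keep 100-400 ns).

`density_profile()` histograms $z$ minus a reference coordinate (a marker
residue at the outer leaflet surface in the motivating application; a
static reference for synthetic data), per replicate, optionally inside a
lateral cylinder, normalized to particles per Angstrom per frame so that
$\sum_b \rho_b \Delta z$ equals the mean in-region particle count per
frame exactly. `pmf_from_density()` converts each replicate to an
effective free energy $W(z) = -kT\,\ln(\rho(z)/\rho_{max})$ - the
Boltzmann inversion implied whenever a "PMF from probability
distributions" is reported - averages bins across replicates, attaches
the standard error across replicates ($s/\sqrt{n}$), and re-anchors the
minimum to zero. Zero-density bins carry a $+\infty$ sentinel and drop
out of the SE; pseudocounts are off by default and available behind a
flag. Default bin width is 1 A. Conversion to kcal mol^-1^ uses
$kT = 0.592$ kcal mol^-1^ at 298 K.

A note on few-replicate error bars: with three replicates the per-bin
ratio (deviation)/(SE) is $t_2$-distributed, so a "within 3 SE" check
against the true potential would *falsely* fail roughly 40% of the time
even for a perfect sampler (the empirical SE of a triplicate is itself
very noisy). The validation tests therefore stabilize the comparison with
a per-bin floor: $SE^* = \max(\text{replicate SE}, \text{counting SE})$,
where the counting SE is the analytic multinomial error
$\sqrt{(1-p_b)/C_b}$ propagated through the log, and the reference is the
bin-averaged Boltzmann weight (eliminating discretization bias). The
tolerance itself stays at 3 SE.

`density_grid()` bins positions on a cubic grid (default 0.5 A). The
default `"occupancy"` mode reports the fraction of frames in which a
voxel holds at least one selected particle - a probability in [0, 1] -
because accessible-region thresholds of the form "probability > 0.005"
read most naturally as per-frame occupancy; a count-normalized mode is
available and the mode is recorded in the object and its OpenDX export.
`accessible_region()` applies a *strict* threshold (exactly-threshold
voxels are excluded).

`detect_permeation_events()` calls leaflet-to-leaflet transits with a
hysteresis band: a particle must commit below `inner_z_A` (default -15 A)
and then reach above `outer_z_A` (default +15 A), or the reverse; motion
inside the band never triggers an event, re-entering the starting zone
restarts the transit, and events per particle are non-overlapping. The
detector is reversal-symmetric: reversing frame order swaps directions
with identical counts. With a lateral groove cylinder supplied, each event
records whether the particle stayed inside it for the whole transit.

The Langevin generator integrates the overdamped update
$z \leftarrow z + (-U'(z))\,(D/kT)\,dt + \sqrt{2 D\,dt}\,\xi$ with
*reflecting* walls (a periodic wrap was rejected: the physical axis - a
membrane-spanning groove - is finite). A spec whose random step
$\sqrt{2 D dt}$ exceeds 10% of the z span is rejected as too coarse at
construction. Its stationary law is $\propto e^{-U/kT}$, giving closed-form
oracles: uniform for flat potentials, Gaussian with variance $kT/k$ for
harmonic wells, Boltzmann occupancy ratios across barriers. Three
replicates by default, mirroring triplicate-simulation designs. The
surrogate validates the *post-processing* only - it says nothing about
force fields, all-atom sampling, or lipid-specific kinetics.

## Group statistics and the pipeline

`summarize_groups()` reports mean +/- SEM over scrambling cells only;
a group whose cells all fail to scramble is flagged as having no assigned
mean/SEM rather than silently averaging sentinels. `compare_groups()`
uses an unpaired two-sided Student's t-test (equal variances) for two
groups and classical one-way ANOVA with Tukey's HSD for more; a
Welch-type correction was considered and not made the default because the
reporting convention this mirrors uses the classical test - the choice is
visible in the returned object. Significance stars (\*\*\*\*: p < 0.0001)
are display metadata at alpha = 0.05, never inputs to any computation.

`run_pipeline()` chains generate, quantify, summarize and compare for a
configured set of groups, writing per-cell, per-group and comparison CSVs
plus a JSON manifest with the seed, package version and every analysis
knob in effect. Unknown configuration keys are rejected by name. All
randomness derives from the single configured seed, so outputs are a pure
function of the configuration: reruns are byte-identical.

## Problem sizes used in validation

The shipped tests run the full stack at desk scale, chosen to keep the
suite fast while leaving comfortable statistical margins: 100-cell movies
(~112 x 112 px, 121 frames) at summed-trace SNR 10 for half-time recovery
(median error is required to stay within one 5-s frame); triplicate
Langevin runs of 20 walkers x 1e5 steps for PMF recovery; 250-cell trace
cohorts and 20-coverslip counting cohorts for fraction recovery, judged
against exact binomial confidence intervals. Generator defaults (noise
levels, half-time distributions) are fixed study conditions; per-cell
trace noise and expression-level distributions are free parameters of the
generator, not estimates of any particular dataset.
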