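---
title: "Dynamic phase synchrony in a social brain network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic phase synchrony in a social brain network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

`socialsync` implements a complete pipeline for asking how the coupling
between brain regions changes, second by second, while a subject watches
naturalistic video of conspecifics interacting. The motivating study design
is macaque fMRI: 16 regions of interest (ROIs) spanning the superior
temporal sulcus, cingulate gyrus and premotor cortex; videos built from
5--20-s clips of aggressive, affiliative or ambiguous social interactions
(plus single-actor, nonsocial and unclassifiable content) separated by 20-s
blanks; and sessions in which the same four 220-s sequences are viewed
several times. Because connectivity, not activation, is the question, the
pipeline is built around *relative phase synchrony* -- a coherence measure
that is deliberately blind to signal amplitude -- resolved in sliding
windows and then tested edge by edge against the behavioral content of the
videos.

# The synchrony model

## Instantaneous phase

Each ROI's residualized BOLD series is band-limited to 0.01--0.5 Hz and
converted to an analytic signal; its complex argument is the instantaneous
phase. Two numerical points deserve note.

* At TR = 2 s the sampling rate is 0.5 Hz and the Nyquist frequency is
  0.25 Hz, so the nominal 0.5 Hz upper band edge is not realizable as a
  low-pass corner. The filter therefore clamps the upper edge just below
  Nyquist; with the default band this reduces to a 4th-order zero-phase
  (forward--backward Butterworth) high-pass at 0.01 Hz, which is the
  faithful reading of "0.01 to 0.5 Hz" on this grid.
* Runs are filtered and phase-extracted independently, after mirror-padding
  each run by one window length (32 s). No phase estimate ever crosses a
  run boundary, and the pads are discarded.

## Windowed phase-locking value

For ROIs $i,j$ and a window $W$ of $N = 16$ volumes (32 s, advanced in 2-s
steps), the synchrony estimate is the phase-locking value

$$\mathrm{PLV}_{ij}(W) \;=\; \Bigl|\tfrac{1}{N}\sum_{t \in W}
  e^{\,\mathrm{i}\,(\varphi_i(t)-\varphi_j(t))}\Bigr| .$$

PLV is 1 under perfect locking and concentrates near
$\sqrt{\pi/(4N)} \approx 0.222$ for independent uniform phases. "Relative
phase synchrony" admits several estimators; PLV is the standard one matching
the description "coherence unbiased by the amplitude of the signals", and
the circular-variance variant ($1-\mathrm{PLV}$) is available behind the
`plv_estimator` flag. A caveat that matters for calibration: phases
estimated through the analytic signal are serially correlated within a
window, so the *measured* null for broadband noise sits above the
iid-phase closed form (about 0.28 rather than 0.222 at $N=16$). Tests that
check the closed form therefore feed iid phases directly into the
windowed estimator; tests on simulated BOLD allow the estimator's bias.

## Cleaning, transform, averaging

Window-level synchrony series are residualized per edge against luminance,
motion energy, gaze change and fixation (each sampled at the window-center
volume and mean-centered, with the fitted intercept added back so cleaned
values stay on the synchrony scale); arcsine-transformed
($r \mapsto \arcsin r$, with $\arcsin\sqrt r$ selectable -- the plain form
is the default because PLV is already a coherence in $[0,1]$, not a count
proportion); and averaged pointwise across repeated viewings onto the
880-s unique-content clock. Cleaning can push values marginally outside
$[0,1]$; they are clipped before the transform and the count is logged.

# Volume-level preprocessing

* **Motion outliers.** The per-volume statistic is the root-mean-square
  across ROIs of the volume-to-volume signal change (a DVARS analogue; the
  source tool's exact formula is not published). Volumes above
  mean + 2.5 SD of the session's statistic are flagged and modeled as
  indicator regressors -- never excised, so the window grid stays intact.
* **Nuisance regression.** Ordinary least squares per ROI on an intercept,
  the CSF series, a reward regressor (unit impulses at reward-pulse onsets,
  binned to volumes and convolved with the hemodynamic kernel -- the same
  transfer function applied to every other event series) and the outlier
  indicators. Collinear columns are dropped by pivoted QR with a warning.
* **Stimulus regressors.** Built at the volume rate from frame-level
  features: luminance averaged within each volume (a level), motion and
  gaze change summed (path-length-like quantities), exclusive actor-count
  indicators, per-behavior indicators and a video ON/OFF column. Volumes
  with fixation below 80% are zeroed in every unconvolved column *before*
  convolution with the hemodynamic kernel (the ordering is enforced; the
  boundary case of exactly 80% is retained, reading "failed to fixate for
  more than 80%" strictly). Whether continuous confound columns are masked
  too is switchable (`mask_confounds`, default on).
* **Hemodynamic kernel.** The gamma density with mean lag 3 s and SD 1.5 s
  -- the unique two-parameter gamma with those moments: shape 4, scale
  0.75 s, mode 2.25 s -- truncated at 30 s and renormalized to unit sum.

# Window-to-condition assignment

Edge-wise statistics require assigning each 32-s window to the stimulus
state it reflects. A majority rule ("more than half the window's volumes
carry the label") is structurally impossible for this design: most clips
last 5 or 10 s, so no aggressive or affiliative clip could ever dominate a
32-s window and those conditions would receive zero windows. The default
rule therefore labels a window by the event covering its center volume
after shifting events forward by the 2-s hemodynamic lag; the majority
rule remains available (`state_rule = "majority"`, with a configurable
overlap fraction) for designs with longer events.

# Edge statistics

Session-by-condition mean synchrony per edge feeds a split-plot
repeated-measures ANOVA, `value ~ subject + condition + Error(session)`:
sessions are the observational units, subject (monkey) is the
between-session factor, and social condition (aggressive / affiliative /
ambiguous) is the within-session factor. The subject-by-condition
interaction is pooled into the error by default -- the published degrees
of freedom (within-denominator 68 at 35 sessions) identify exactly this
model -- and an interaction flag plus the option of a
Greenhouse--Geisser-free classical table are the only deviations offered.
Sessions with missing condition cells are dropped with a warning; an edge
with fewer than two usable sessions per subject is untestable and reported
as $F = 0$, $p = 1$ rather than omitted, keeping the edge indexing stable.

Edge p values map to z statistics through the one-tailed upper
normal quantile ($z = \Phi^{-1}(1-p)$), matching the neuroimaging
convention in which $z > 2.05$ corresponds to a tail mass of about 0.0202
-- numerically the strongest 15% of 120 edges in the motivating data.
Both threshold modes are implemented: absolute ($z > 2.05$, the default)
and proportional (top $\lceil 0.15 \times 120\rceil = 18$ edges), with
boundary ties broken deterministically by canonical edge order and warned
about. Degree is a row sum of the binary adjacency; eigenvector
centrality is the nonnegative leading eigenvector (unit Euclidean norm) of
the largest connected component, computed by shifted power iteration (the
$+I$ shift prevents oscillation on bipartite components), zeros elsewhere.

# Clip-aligned time courses

Segments of the unique-clock synchrony series are aligned to social-clip
onsets: samples whose window centers fall from 4 s before to 6 s after the
onset plus the 2-s hemodynamic lag, interpolated by a natural cubic spline
onto a 0.5-s grid (21 points), with segments that straddle run boundaries
or fail to cover the full extent dropped and counted. Per anatomical edge
group (temporo-temporal, cingulate-temporal, cingulate-cingulate,
premotor-temporal, premotor-cingulate), restricted to suprathreshold
edges, each edge-by-clip segment is normalized by its own pre-onset mean,
then averaged over edges to a clip-level course.

Clips are the observational units for inference -- the source description
is silent on this, and clip-level units avoid pseudo-replication across
strongly correlated edges. Two families of tests run per group: one-sample
one-tailed t tests of each condition against its baseline, and per-timepoint
OLS contrasts reading each condition against the mean of the other two
(weights $(2,-1,-1)/3$, so the estimate is "condition minus mean of the
others"; any positive scaling leaves t and p unchanged). Bonferroni
correction uses the family "timepoints x tests within a group"
(21 x 3 = 63) -- the family definition is a documented choice, stated here
because the source states the correction but not the family.

# The synthetic-data generator

No imaging data accompany the motivating study, so the generator is a
first-class module that produces complete sessions -- coupled ROI BOLD,
schedules, confounds, behavior -- with known ground truth.

## Stimulus schedules

Four 220-s sequences, each opening with a 20-s blank and alternating clip
groups with the remaining blanks: 16 clips (ten 5-s, five 10-s, one 20-s;
120 s of clips, 100 s of blanks) per sequence, 880 s of unique content in
total. A fixed duration-by-category composition reproduces the emulated
content mix (aggressive 15%, affiliative 16%, ambiguous 14%, single-actor
14%, nonsocial 18%, unclassified 23%) to within about one percentage
point, and the shuffle retries until every ordered pair of social
behaviors occurs among consecutive social clips. Two deliberate
asymmetries:

* The ambiguous category carries three of the four 20-s exemplars.
  Responses are read out through 32-s windows, so the category whose
  condition-locked coupling the validation study must detect needs
  exposures on the window's own timescale; 5--10-s boosts are averaged
  away almost entirely.
* No 20-s clip may occupy a sequence's final slot: a clip flush against
  the run end contributes no aligned segments (there are no post-onset
  windows), the synthetic analogue of padding run ends for the
  hemodynamic lag.

## Phase-coupled BOLD

Each ROI sums two noisy oscillators at 0.02 and 0.04 Hz (amplitudes 1 and
0.9), plus an evoked response (the video-ON indicator convolved with the
hemodynamic kernel, amplitude 0.3) and white noise (SD 0.5). Oscillator
phases evolve by an *incremental circular-weighted blend*: each volume a
phase advances at its natural frequency with Brownian jitter, then moves
the fraction $\kappa_0$ of its remaining angular gap toward a
network-shared phase and the fraction $\Delta\kappa(t)$ toward its
community-shared phase. At weight 1 the phase lands on the shared
oscillator exactly (windowed synchrony 1 with zero noise); at weight 0 it
is private; expected synchrony is monotone in between. A one-shot convex
phasor blend was tried first and abandoned: with time-varying weights the
blended phasor can pass near the origin, and its argument then slews
chaotically, so clip-length boosts *lowered* synchrony. The incremental
form has the same steady-state semantics without the cancellation
pathology.

Condition-dependent coupling lives on 18 designated cingulate-temporal and
temporo-temporal edges arranged as four vertex-disjoint cliques (10 + 6 +
1 + 1 edges), so that boosting them leaves every non-designated edge
uncoupled beyond baseline. Each community's shared phase itself tracks the
network-shared phase at the baseline weight; without this hierarchy a
boost drains its members' baseline network-wide coherence and
*anti-modulates* every edge leaving the community. The boost weight
follows the ambiguous-clip indicator convolved with the hemodynamic
kernel, so simulated coupling lags clip onsets the way the analysis
expects. Phase jitter defaults to 0.45 rad/sqrt(s) at 0.02 Hz and 0.3 at
0.04 Hz: diffusion broadens each spectral line by roughly
$\mathrm{jitter}^2/4\pi$ Hz, and the narrower second line keeps both peaks
-- the generator's stated spectral signature -- resolvable in an averaged
periodogram.

## Confounds and behavior

Frame-rate (25 Hz) luminance and motion carry condition-specific means
whose separation from the grand clip mean scales with a single
`separation` parameter (0 gives an exact null); AR(1) noise rides on both.
Gaze is a reflected random walk inside the 13-degree screen bound;
fixation fraction is drawn per volume around a session mean, itself drawn
around subject-level means of 0.90, 0.89 and 0.62 (SDs 0.03, 0.07, 0.08),
matching the emulated subjects' reported compliance; CSF is slow AR(1)
noise; reward pulses occur about every 3 s during well-fixated video.

## What the generator does and does not emulate

It reproduces the statistical structure the pipeline *assumes*: spectral
peaks at 0.02/0.04 Hz, condition-dependent luminance/motion, subject-level
fixation differences, repeat structure, hemodynamically lagged coupling
changes. It does not emulate spatially structured scanner noise, eye
-movement physiology, cross-frequency (1:n) coupling, or amplitude-mediated
connectivity; passing tests therefore validate the pipeline's inferential
machinery, not the biological claims of any particular dataset.

# Validation-study problem sizes

The packaged validation studies (tests and the acceptance script) use
these sizes, chosen to give each check the factor structure it needs:

* default study: 3 subjects x 12 sessions, each session viewing the four
  sequences three times (the emulated design ran three to four viewings);
* null calibration of the edge-selection rule: 100 independent null
  studies (3 x 12 sessions) at one viewing per session -- calibration is
  unchanged by the repeat count, and single viewings keep the study of
  100 datasets desk-scale;
* coupling-recovery replicates: 50 studies of 3 subjects x 8 sessions for
  the clip-aligned contrast property.

# Known limitations

* The RM-ANOVA assumes compound symmetry across the three condition
  means; no sphericity correction is applied by default because the
  emulated analysis reported uncorrected degrees of freedom. This has a
  measurable cost under the windowing scheme: 32-s windows sliding at 2 s
  overlap across condition boundaries, so the three session-level
  condition means are correlated unevenly (Greenhouse--Geisser epsilon
  about 0.8 on null simulations), and the uncorrected within-condition F
  is mildly liberal -- the z > 2.05 selection admits roughly 2.1--2.6% of
  null edges rather than the nominal 2.02%. Users who prefer exact
  calibration over comparability with the emulated analysis can pass
  `gg = TRUE` to `rm_anova_edge()` for the Greenhouse--Geisser-corrected
  p; with the default they should treat the suprathreshold count as
  approximately, not exactly, rate-controlled.
* The aligned analysis resolves events only down to roughly the window
  length; condition effects carried entirely by sub-10-s events are
  attenuated below detectability by design, not by bug.
* Eigenvector centrality on a disconnected suprathreshold network scores
  only the largest component; competing equal-size components are broken
  by lowest node index.
* The pipeline models flagged outlier volumes as regressors and never
  excises them; designs needing scrubbing-style excision are out of scope.
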