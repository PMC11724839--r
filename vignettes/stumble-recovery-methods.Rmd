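---
title: "Analysing stumble recovery on a perturbation treadmill: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing stumble recovery on a perturbation treadmill}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stumblr)
```

## The problem

Lower-limb prosthesis users lack plantar sensation from the missing foot, and
their recovery from trips differs from that of able-bodied walkers.  A
sensory neuroprosthesis (SNP) — nerve-cuff stimulation whose intensity tracks
pressure under the prosthetic foot — may restore enough of that feedback to
change stumble-recovery behaviour.  The experimental paradigm this package
analyses delivers trip-like perturbations on a split-belt instrumented
treadmill: both belts accelerate at 3 m/s² for the first half of the
perturbation and decelerate at the same rate for the second half (800 ms or
600 ms total), triggered in early stance when the vertical ground reaction
force (GRF) on the perturbed side exceeds 100 N.  The analysis quantifies
the response over four steps — the perturbation step (`pert`) and three
recovery steps (`rec1`–`rec3`) — with three outcomes per step:

* **trunk angular sway**: the range of the trunk-to-vertical angle over the
  step (degrees);
* **peak trunk flexion angular velocity**: the largest forward rotation rate
  of the trunk within the step (deg/s);
* **peak ||GRF||**: the value of the *first* local maximum of the
  body-weight-normalised GRF magnitude on the step's stance plate (%BW).

Each perturbation trial is one analysis unit; trials are compared between
SNP-active and SNP-inactive walking blocks, separately for intact-side and
prosthetic-side perturbations.

## Pipeline

`run_analysis()` chains five stages, each exposed as ordinary functions:

1. **Preprocess** (`preprocess_trial`).  Marker gaps of at most
   `max_gap_frames` (default 10 frames, 0.1 s at 100 Hz) are filled by cubic
   splines fitted to the nearest valid neighbours; longer gaps and boundary
   gaps are left invalid — never extrapolated.  Markers are then low-pass
   filtered at 6 Hz and force channels at 10 Hz with fourth-order Butterworth
   filters applied forward and backward (zero phase, so event timing is not
   shifted; the two-pass amplitude response at the cutoff is 1/2), followed
   by a window-3 median filter against impulse noise.  Interpolation runs
   before filtering; the pre-interpolation validity mask is retained for the
   completeness screen.  The series is reflection-padded by ten times
   `rate/cutoff` samples before filtering so that end transients of the
   filter state die out outside the retained span.
2. **Gait events** (`detect_gait_events`).  A coordinate-based extremum
   method: heel strikes at per-cycle maxima of the heel marker's
   anterior–posterior (AP) position relative to the pelvis origin (centroid
   of SACR, LASI and RASI), toe-offs at per-cycle minima of the toe marker's
   relative AP position.  Candidate extrema must rise 10% of the half
   excursion above the neighbouring saddles; alternation within a side is
   enforced by discarding the weaker of two same-type events with no
   opposite event between them.
3. **Perturbations** (`detect_perturbations`).  The belt-speed channel is
   compared against the steady speed (trial median); an excursion beyond
   0.05 m/s marks a perturbation, and onset/end are refined to the samples
   where the speed actually departs from and rejoins the steady value, so
   the detected onset is accurate to a sample or two rather than lagging by
   the threshold crossing time.  The perturbed side is the limb whose most
   recent event is a heel strike without a subsequent toe-off (double
   support resolves to the later striker).  The onset's gait-cycle fraction
   is `(onset − previous strike) / (next strike − previous strike)`.
4. **Steps and metrics** (`segment_recovery_steps`, `step_*`).  A step runs
   from one heel strike to the next contralateral heel strike, so the four
   step windows tile the response contiguously: `pert` starts at the
   perturbed limb's strike preceding onset; `rec1` at the first
   contralateral strike after onset; `rec2` and `rec3` alternate onwards.
   The trunk angle is the 3-D angle between the pelvis-to-shoulder axis
   (pelvis centroid to the C7/CLAV midpoint) and the global vertical,
   signed by the sagittal tilt direction; a pure sagittal-projection
   variant is available (`trunk_projection = TRUE`).  Angular velocity is a
   central difference at the marker rate with no extra smoothing.  The
   first ||GRF|| peak requires the stance plate to load through 20 N and
   the candidate maximum to have at least 2 %BW prominence; windows with no
   interior maximum return the window maximum, flagged.
5. **Screening and statistics** (`screen_perturbations`, `mixed_anova`,
   `bonferroni_posthoc`, `welch_asymmetry_test`, `handrail_count_table`),
   described below.

## Screening rules

A perturbation contributes to the *kinematic* family (sway, velocity) iff it
is not warm-up, its onset lies within the first 20% of the gait cycle, no
handrail grab occurred, and every required marker is sufficiently complete;
the *kinetic* family (||GRF||) replaces completeness with belt separation.
Boundary comparators follow the literal reading of each rule: onset fraction
≤ 0.20 passes, a grab needs ≥ 50 ms below 5 cm/s, belt separation needs each
plate below 20 N for ≥ 15% of every gait cycle in the window, and *more
than* 5% missing marker data fails.  The completeness bound is applied per
required marker (the stricter reading; a pooled mode is available).  The
handrail search window runs from perturbation onset to the end of `rec3`.
The two inclusion families are tracked separately because the reported
sample sizes differ between the trunk and GRF analyses.  Warm-up removes
the first two perturbations per side of every walking block.

## Inference layer

`mixed_anova()` fits the split-plot (mixed-design) ANOVA with recovery step
as the repeated-measures factor and SNP condition as the between-group
factor, perturbation trials as subjects.  The within-subject part uses an
orthonormal contrast basis, giving the classical df identity: step and
step×SNP carry (3, 3·(N−2)).  Sphericity of the contrast covariance is
assessed with Mauchly's test (including the second-order term of the
chi-squared expansion, matching `stats::mauchly.test`); when its p-value
falls below 0.05 the step and interaction df are deflated by the
Greenhouse–Geisser ε before p-values are computed.  The between-group
effect is tested on subject means with df (1, N−2) — the conventional
split-plot between-subjects test; published reports sometimes print the
within-error df for this effect instead, which we deliberately do not
reproduce.  Unweighted (Type III) cell means are used for the within
effects, so the decomposition agrees with `car::Anova(type = 3)` to
machine precision; the test suite verifies 1e-8 relative agreement.

Post-hoc comparisons are Welch two-sample tests of SNP conditions within
each step, Bonferroni-adjusted with family size 4 (one comparison per step
label, the natural family here; the adjusted p is `min(1, 4p)`).  They are
computed whenever the ANOVA runs and flagged exploratory when neither the
interaction nor the SNP main effect reaches 0.05.

`welch_asymmetry_test()` asks whether the intact-vs-prosthetic difference
in a step's metric changes with the SNP: the contrast
`(m_I,off − m_P,off) − (m_I,on − m_P,on)` over the four side×condition
cells, with an unequal-variance standard error and Welch–Satterthwaite df
over the four-group linear combination.  This construction yields df close
to (but below) `n_total − 4`, consistent with the df magnitudes printed in
reports of this design; a plain two-group variant can be obtained by
passing only two cells' worth of data.  Normality is left to Q-Q
diagnostics and never gates inference.

## The synthetic-trial generator

`simulate_trial()` produces fully annotated walking blocks so that every
pipeline stage can be validated against ground truth without recorded data.
It is a statistical/geometric emulator, not a musculoskeletal simulation:

* **Kinematics** are smooth periodic templates.  The heel marker's relative
  AP position is a cosine peaking exactly at each heel strike; the toe's
  attains its minimum at each toe-off (stance occupies 62% of the stride).
  Pelvis and trunk markers are constructed so the trunk-angle formula
  recovers the designed angle exactly; finger markers swing on an
  elliptical path whose speed never falls below ~0.15 m/s, so the grab
  detector has no false positives.
* **Kinetics**: each stance's vertical GRF is two raised-cosine humps
  (support width 0.25 of stance, centres at 0.25 and 0.75), peaking near
  100–120 %BW and exactly zero in swing; AP/lateral shear components are
  proportional to `sin(4πs)` so they vanish at the first-peak instant and
  the ||GRF|| first peak equals the designed value analytically.
* **Perturbations** are scheduled by seeded permutation of sides with at
  least `min_spacing` strides between onsets; each onset is the first force
  sample of the chosen stance at which the (clean) vertical GRF exceeds
  100 N, so the trigger-rule invariant holds exactly on noiseless output.
* **Stumble response**: within each of the four step windows the baseline
  trunk oscillation is replaced by an asymmetric flexion excursion — a
  half-cosine rise whose duration sets the peak flexion velocity
  (`πA/(2·rise)`) followed by a slower half-cosine fall — so sway (= the
  excursion amplitude) and peak velocity are injectable independently and
  are analytically exact at zero noise.  The stance GRF first-hump peak of
  the step's stance side is re-targeted likewise.  Injected values are
  baseline + effect-profile offset + Gaussian noise, and the *realized*
  values (after feasibility clamping) are recorded in the ground truth.
* **Corruptions** emulate the screened failure modes: frozen finger markers
  (handrail grab), a contiguous invalid run on a trunk marker (dropout
  sized by `dropout_fraction` of the recovery window), and an extra 30 N on
  the contralateral plate for one gait cycle (mid-line crossing).
* **Determinism**: a single seed drives side permutation, metric noise,
  sensor noise and corruption draws through fixed derived seeds; identical
  configurations render bit-identical trials.

### Numerical calibration of the excursion shape

Because the pipeline's 6 Hz zero-phase filter is part of the measurement
definition, excursions that are too abrupt are eroded by it and excursions
that stop too abruptly ring into the sway range.  The generator therefore
constrains the rise duration to [0.23 s, step − 0.34 s] and uses a 0.26 s
fall with a 0.05 s post-strike onset delay; within that band the filtered,
median-smoothed trace reproduces the analytic sway and peak velocity to
well under 1%.  The baseline oscillation (1° at step frequency, zero at
every heel strike) is faded out over 0.3 s around each response region so
no oscillation energy leaks across step boundaries through the filter.
One consequence worth knowing: the feasible peak-velocity band at a given
sway is roughly [4.8·A, 6.8·A] deg/s per degree of sway, so wide velocity
noise or large velocity offsets saturate at the band edges.  Realized
values are always recorded in the ground truth, and the pipeline is
validated against those; but cohort-level *velocity* effect estimates can
be compressed relative to the nominal offset when the noise SD is a large
fraction of the band width.  Sway and GRF injection have no such coupling.

### What the generator does and does not emulate

It reproduces the statistical and mechanical structure the pipeline relies
on: periodic events, double-hump stance loading, the GRF trigger, step-wise
metric structure with injectable condition effects, realistic sensor noise
(1 mm marker jitter, 2 N force noise), and the screened corruption modes.
It does **not** vary step timing after a perturbation (the synthetic walker
keeps its cadence while the trunk and loading respond), model joint
kinetics, swing-limb trajectories beyond marker extrema, muscle activity or
visual flow, and its mid-stance GRF valley dips to zero, which is deeper
than physiological.  Passing tests therefore demonstrate the correctness of
the measurement and inference chain under the assumed signal structure, not
validity of the biomechanics on real recordings.

## Default parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| preferred speed | 1.0 | m/s | typical comfortable treadmill speed in this population |
| cadence | 90 | steps/min | typical self-selected rate near 1 m/s; steps comfortably contain the excursions |
| marker / force rate | 100 / 1000 | Hz | optical capture and force-plate standards |
| perturbation accel / duration | 3 / 0.8 | m/s², s | treadmill maximum; 0.6 s variant for the shorter protocol |
| perturbations per side | 12 | — | one walking block's dose |
| spacing | ≥ 10 | strides | return to steady state between perturbations |
| metric noise SD (sway, vel, GRF) | 1.6, 8, 10 | deg, deg/s, %BW | of the order implied by reported standard errors at n≈60; velocity bounded by the feasible band |
| marker / force noise | 0.001 / 2 | m, N | optical jitter and plate noise |
| filter cutoffs (markers/forces) | 6 / 10 | Hz | measurement definition |
| trigger force | 100 | N | early stance trigger |
| onset window | ≤ 20% | gait cycle | inclusion rule |
| grab rule | < 5 cm/s for ≥ 50 ms | — | hand-marker detector |
| completeness | ≤ 5% missing | per marker | inclusion rule |
| belt separation | < 20 N for ≥ 15% | of each cycle | mid-line rule |
| warm-up | first 2 per side per block | — | learning-effect exclusion |

## Problem sizes used in validation

The test suite and the acceptance script validate at the scales the methods
are meant for: 100 noiseless perturbations (five blocks) for exact metric
recovery; 200 noisy 20-s trials (≈11,000 events) for event detection; 1000
simulated metric tables at n = 60/60 for null calibration of the
interaction test plus 500 for power at a rec1-only offset of four
within-group SDs; 50 random small tables for oracle equivalence against an
independent multivariate decomposition; and an end-to-end cohort of twelve
blocks (n = 60 trials per condition, matching the reported group sizes)
for effect recovery.  These sizes make the whole suite run in a couple of
minutes while keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

* The generator's fixed step timing means perturbation side/onset never
  alters subsequent event times; analyses that depend on timing responses
  cannot be exercised synthetically.
* Velocity effect injection saturates at the feasible excursion band (see
  above).
* The Welch asymmetry contrast is one defensible construction of the
  "difference affected by the SNP" test; published df values are consistent
  with it but do not uniquely determine it.
* The between-subjects effect is reported with df (1, N−2); printed reports
  of this design sometimes show the within-error df for that row.
* C3D interchange is not provided; trial bundles are plain CSV/JSON.
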