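---
title: "Methods: neuromuscular and biomechanical assessment pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuromuscular and biomechanical assessment pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomechkit)
```

## What this package computes

Age-related loss of muscle strength has two distinguishable components:
loss of muscle mass (sarcopenia) and strength loss from other causes —
impaired neural activation, altered contractile properties — collectively
called dynapenia. Telling them apart requires combining several
measurements: imaging-based muscle morphometry, maximal voluntary isometric
contraction (MVIC) torque on a dynamometer, electrically evoked torque
superimposed on a maximal contraction, surface EMG, and gait analysis with
musculoskeletal simulation. `biomechkit` implements the computational side
of such an assessment as small, testable pipelines, plus seedable
synthetic-data generators so that every stage can be validated against
known ground truth without access to human recordings.

The package deliberately stops at the boundaries of the computational
problem: image segmentation, motion-capture pre-processing, and the
musculoskeletal simulations themselves (scaling, inverse kinematics /
dynamics, joint-reaction analysis, static optimization) are upstream tools
whose *outputs* — meshes, gait curves — this package consumes.

## Dynamometry and MVIC extraction

The dynamometer reports torque as a voltage. Processing follows the order:

1. zero-phase 4th-order Butterworth low-pass at 20 Hz;
2. conversion to newton-metres, $T = V \cdot f_{V\rightarrow ftlb} \cdot
   f_{ftlb\rightarrow Nm} = V \cdot 102.4 \cdot 1.3558 = 138.834\,V$;
3. segmentation of repetitions by the noise-derived threshold
   $\theta = \mu_{noise} + 3\,\sigma_{noise}$, where $\mu,\sigma$ are taken
   over a window known to contain no contraction. Supra-threshold runs
   separated by less than `min_gap_s` (default 0.5 s) are merged and runs
   shorter than `min_duration_s` (default 1 s) are discarded — contractions
   are held at least 3 s and pauses are 2 s or longer, so these defaults
   sit well inside the timing margins;
4. per-repetition peak extraction on a zero-phase 4th-order Butterworth
   2 Hz smoothing of the window, so transient bursts do not inflate the
   maximum. The MVIC is the maximum across repetitions.

Two details are worth making explicit. The 2 Hz smoother is applied *inside*
detected windows only: applying it before segmentation would smear
contraction onsets across the threshold. And a zero-phase Butterworth is
not a moving average — on the corner between the torque ramp and the
plateau it overshoots by roughly 0.8%, so a smoothed peak may slightly
exceed the plateau of a noiseless trapezoid. Under realistic sensor noise
the raw in-window maximum always dominates; the property tests assert the
"smoothing never amplifies" expectation in that regime.

The baseline (noise-window mean) is subtracted before peak extraction, so
a constant offset on the dynamometer channel does not bias the MVIC;
flexion trials are sign-inverted on input so "peak" is always a maximum.
If a third repetition exceeds both earlier ones by 5% or more a
`retest_flag` is raised (the protocol's cue to request a fourth trial);
whether the comparison is against both trials or their maximum is
configurable (`retest_rule`), with "both" the default.

## Central activation ratio

During a stimulated maximal contraction, a doublet delivered at the torque
plateau evokes an increment (the superimposed twitch) only if voluntary
drive is incomplete. With $MVC$ the plateau torque just before stimulation
and $\delta$ the twitch amplitude,

$$\mathrm{CAR} = \frac{MVC}{MVC + \delta},$$

equal to 1 at full voluntary activation (also reported ×100 in
`car_percent`; the fraction is the default because cohort tables use the
0–1 scale). Choices the definition leaves open, and how they are resolved
here:

- *plateau estimator*: mean over the 100 ms ending at the stimulation
  onset (configurable `plateau_window_s`). An instantaneous pre-stimulus
  sample would inherit full noise variance; averaging suppresses it
  without reaching back into the ramp.
- *twitch amplitude*: maximum of the 20 Hz-filtered, offset-removed torque
  within 300 ms after onset, minus the plateau. The mechanical response to
  a 10 ms-interpulse doublet is over well within 300 ms
  (`twitch_window_s`).
- *negative estimates* (noise dip instead of a twitch) are clamped to zero
  with a flag; CAR is then exactly 1.
- *onset*: read from the trigger channel when the stimulator is
  synchronized with acquisition (first rising edge inside the window).
  Without a trigger, the onset is the sample of maximal positive first
  difference within the plateau region, which is derived from the signal
  itself (samples at or above 95% of the window's 95th percentile, trimmed
  0.1 s per side) so that the rise and fall ramps do not contribute their
  large derivatives to the detection statistics. Detection requires the
  spike to exceed 5× the plateau-region derivative SD; trials without a
  detectable stimulus raise an error rather than being scored — only
  stimulated trials may enter a CAR summary. The derivative detector
  resolves twitches down to roughly 1–2% of the plateau at 1% noise;
  near-fully-activating subjects require the trigger channel.

Stimulation intensity adequacy uses the resting-twitch criterion: the
torque evoked at rest must reach at least 25% of the recorded peak
voluntary torque (`check_mvc25`, inclusive bound).

## EMG envelopes and co-contraction

The envelope chain (at the EMG system's 2000 Hz): zero-phase Chebyshev
type-I high-pass at 20 Hz (order 5) and low-pass at 300 Hz (order 8),
comb-notch removal of 50 Hz mains and all harmonics below Nyquist,
full-wave rectification, and a zero-phase 4th-order Butterworth low-pass
at 2 Hz. The Chebyshev passband ripple is not fixed by convention; 0.1 dB
is used and exposed (`ripple_db`) because reproducibility requires it to
be explicit. Each notch is a second-order IIR section with a 2 Hz −3 dB
bandwidth (configurable), applied zero-phase. Envelopes are normalized to
the maximum observed during the task; the scale factor is recorded.

Co-contraction of an antagonist pair uses the Rudolph index: with
$L = \min(a,b)$ and $H = \max(a,b)$ the lower and higher normalized
activations,

$$\mathrm{CCI}(t) = \frac{L(t)}{H(t)}\,\bigl(L(t) + H(t)\bigr),$$

which ranges from 0 to 2 for inputs in $[0,1]$, reaching 2 only when both
muscles are fully active; where both envelopes are zero the index is
defined as 0 (its limit value). Zero-phase filtering can leave normalized
envelopes marginally above 1; such samples are clipped to 1 with a
warning and count. For walking, the CCI series resampled on the cycle
grid is averaged separately over initial double support (0–10%), single
support (10–50%), pre-swing (50–60%) and swing (60–100%), the first three
half-open and swing closed at 100%.

## Mesh morphometry

Muscle surfaces arrive as STL (both dialects are read; vertices are
deduplicated so topology checks are meaningful; coordinates are assumed
mm, with a configurable unit scale). A mesh must be watertight and
consistently oriented — every directed edge matched by its reverse — or
volume computation refuses it, naming the number of open edges.
Degenerate faces are dropped with a count.

Volume is the divergence-theorem sum $\left|\sum \det(v_1,v_2,v_3)\right|/6$
over faces, orientation-independent through the absolute value, reported
in cm³. Maximal anatomical cross-sectional area slices the mesh with
planes perpendicular to a chosen axis every `slice_step_mm` (default 2 mm,
the MRI slice thickness; default axis the scanner z). Each straddling
triangle contributes one intersection segment oriented along
$\hat{a}\times\hat{n}_{face}$; because the surface is closed and
consistently oriented, the shoelace sum over those oriented segments *is*
the enclosed polygon area, holes subtracting automatically — no polygon
chaining step that could fail on tangent slices. Planes passing exactly
through vertices are nudged by a relative $10^{-9}$. After the coarse
scan, the neighbourhood of the best slice is re-scanned at 1/20th of the
step so the reported maximum is not quantized to the slice grid (a 2 mm
grid alone can understate a 10 mm-radius sphere's great circle by ~1%).
Anatomical, not physiological, CSA: no fiber directions are available.
Volume divided by body-mass index (`volume_per_bmi`) removes the
confounding effect of stature and mass in cohort comparisons.

## Gait post-processing

Simulation outputs are normalized — joint moments by body mass (Nm/kg),
joint contact forces by body weight with $g = 9.81$ m/s² (unit BW), angles
untouched — and resampled onto the 101-point percent grid (0–100%) of one
gait cycle by linear interpolation, which preserves endpoints exactly and
cannot overshoot on force curves (a spline can). Heel strikes, when a
vertical ground-reaction channel is available, are rising crossings of
20 N. Derived parameters:

- sagittal range of motion: max − min over the cycle;
- walking speed: displacement along the progression axis (the net
  displacement direction, so lateral sway is orthogonal and unbiased)
  divided by elapsed time over a window of at least 1 s;
- knee contact-force characteristic peaks: maxima over the early-stance
  window 0–50% and the push-off window 40–70% (configurable; the windows
  overlap deliberately so a late first peak is not missed). Curves
  without two local maxima are flagged unimodal rather than silently
  producing two identical "peaks". Peaks are extracted per trial and then
  averaged across a subject's trials.

Point-wise cohort comparison along the cycle is a cluster-mass
permutation test: a pooled-variance two-sample t statistic at each of the
101 points (zero, with a flag, where variance degenerates), clusters
formed where $|t|$ exceeds the pointwise critical value at $\alpha$,
cluster mass the sum of $|t|$, and the null distribution built from the
maximal cluster mass over label permutations (default 1000, seedable,
p-values with the +1 correction). Because both tails are examined, a
cluster is declared significant at $\alpha/2$ — the standard two-sided
correction in cluster-permutation practice — which guarantees a
family-wise error rate at or below $\alpha$ rather than exactly at it.
This is a permutation-based analogue of one-dimensional statistical
parametric mapping, not a random-field-theory implementation, and results
are labelled accordingly.

## Cohort summaries

Per-subject parameters pool into per-cohort arithmetic means and sample
(n−1) standard deviations, with missing values excluded pairwise and the
contributing n reported per cell; a single-subject cell reports SD 0 with
n = 1 visible. Demographic records are checked for internal consistency
(BMI vs mass/height², 0.5% tolerance). The hand-grip vs MVIC relationship
is an ordinary least-squares line plus Pearson r. No inferential
statistics are attached to scalar parameters: at five subjects per elderly
cohort they would be uninformative, and the point-wise gait comparison is
the only inference the package performs.

## Synthetic data: what it emulates and what it does not

Every generator is a pure function of its parameters and seed (bit-identical
regeneration, session RNG untouched) and returns its ground truth alongside
the data:

- `gen_mvic_trace`: trapezoidal contractions (1 s rise, 3 s hold, 1 s
  fall by default) with additive Gaussian sensor noise and compressed 2 s
  rests (the experimental 90 s rest carries no information); optional
  output in volts to exercise the conversion stage.
- `gen_snmes_trace`: one contraction with an alpha-function twitch
  $\delta\,(t/\tau)e^{1-t/\tau}$ ($\tau$ = 30 ms, ~150 ms transient) at a
  known onset, plus a 10 ms trigger pulse. Only the amplitude matters to
  CAR; the alpha shape is a modelling convenience.
- `gen_emg`: band-limited (20–300 Hz) Gaussian carrier amplitude-modulated
  by the activation profile, optional 50 Hz contamination. The carrier is
  scaled so the rectified mean of unit activation is 1.0, making the
  linear envelope read directly in activation units — the profile itself
  is the ground-truth envelope. No motor-unit structure is simulated.
- `gen_gait_curves`: smooth templates hitting the requested ROM exactly
  and a two-bump contact-force curve whose peak values and locations are
  imposed exactly (a 2×2 linear solve absorbs the bump overlap).
  Trial-to-trial deviations are *smooth* Gaussian processes (white noise
  convolved with a 3-percent-of-cycle Gaussian kernel, rescaled to 1% of
  the curve scale by default): inverse-kinematics and joint-reaction
  outputs are band-limited, and white per-grid-point noise would both
  misrepresent them and bias extremum readouts upward by its expected
  maximum.
- `gen_mesh`: icospheres, scaled ellipsoids, capped cylinders and a
  two-belly surface of revolution, all watertight and outward-oriented,
  with analytic (or, for the revolved profile, finely quadratured) volume
  and CSA stored as truth.

Passing recovery tests on these fixtures demonstrates that the pipelines
are correct and unbiased at realistic noise levels; it does not
demonstrate robustness to what the generators do not emulate — movement
artefacts and cable noise in EMG, fatigue-induced plateau drift,
electrode-placement variability, segmentation errors in the meshes, or
soft-tissue artefact in motion capture.

## Numerical choices

Zero-phase filtering is forward–backward application with odd (point-
symmetric) reflective edge padding. The pad length adapts to the filter:
at least three filter lengths, and enough to cover about four cycles of
the lowest corner frequency (for the notches, of the notch bandwidth),
because a 2 Hz corner at 2000 Hz has transients of hundreds of samples. A
signal too short for its pad raises an explicit error rather than being
truncated. Each directional pass routes the input's leading value around
the recursion (the response to a constant is exactly the constant times
the DC gain), so constants pass bit-clean and start-up transients vanish;
filtering remains exactly linear. Trace endpoints still retain raw-noise
amplitude — a property of all reflective-padding zero-phase filters — so
the threshold stage's activity check ignores a 5% margin at the window
edges, and noise windows should not abut the trace start. Filters are
designed in normalized frequency at the signal's own rate (`signal::butter`,
`signal::cheby1`); resampling is never implicit, and cutoffs at or above
Nyquist are refused.

Degenerate inputs are handled explicitly throughout: zero-variance noise
windows degrade the threshold to the window mean with a message; empty
segmentations return zero windows (an error only where a contraction is
required); all-zero envelopes refuse normalization; flat contact-force
curves are flagged unimodal; zero-variance grid points get a zero t
statistic with a flag.

Test and acceptance problem sizes — chosen so the full suite exercises
100-seed recovery sweeps while remaining quick on one core — are 3-trial
(≈22 s) MVIC traces and single-contraction (≈9 s) stimulation trials at
2000 Hz, 8–30 s EMG, subdivision-4 icospheres (5120 faces), 0.5 mm voxel
oracles, 10-trial gait sets on the 101-point grid, and 1000-permutation
comparisons of 10-curve groups.

## Known limitations

- The dynamometer channel's sampling rate is taken to be the EMG system's
  2000 Hz unless stated otherwise; all rates are configurable.
- CCI on real antagonist pairs depends on each muscle being normalized to
  its own maximal task; the generators sidestep MVIC-transfer error by
  calibrating envelopes in activation units.
- The envelope low-pass ripples an antagonist's small activation around
  its true level, so task-level CCI estimates carry a small negative bias
  at low activation (visible in the workflow's step-4 output).
- Anatomical CSA from surface slicing matches per-slice image CSA only up
  to segmentation/discretization differences.
- The permutation comparison assumes exchangeability of subjects between
  cohorts under the null; it is not a random-field SPM and reports
  cluster-level inference only.
- C3D input is not supported; tabular (delimited, MOT/STO) interfaces
  only.
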