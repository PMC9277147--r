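---
title: "Predictive beam's-eye-view cine simulation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive beam's-eye-view cine simulation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem bevcine simulates

During MR-guided radiotherapy of a mobile thoracic tumor, a 2D cine
image acquired in the beam's-eye-view (BEV) — the plane perpendicular to
the radiation beam — shows the tumor as the beam sees it. A thin cine
slice, however, only shows the in-plane tumor cross-section: motion
perpendicular to the plane changes that cross-section without the tumor
actually shrinking. Overlaying the *projection of the full tumor volume*
restores the missing information, but retrieving the right volume from a
library of previously acquired time-resolved 4D MRI (TR-4DMRI) takes
computation time, which shows up as latency between acquisition and
guidance.

`bevcine` implements the predictive strategy that hides this latency:
while the next cine frame is being acquired, the diaphragm position for
that frame is *forecast* from the breathing signal, the forecast selects
a motion-matched volumetric image from direction-resolved
(inhalation/exhalation) libraries, and the selected tumor volume is
projected onto the BEV — so the overlay is ready the moment the frame
arrives. Respiratory hysteresis — inhale and exhale paths differing at
equal superior–inferior (SI) displacement — is handled by the library
split: the predicted moving direction picks the library before the
predicted amplitude picks the entry.

Because no public TR-4DMRI data exist, the package is built around a
synthetic 4D breathing-thorax phantom whose ground truth is known
analytically; every accuracy claim in the test suite is a comparison
against that ground truth.

## The breathing phantom

### Waveform kernel

The diaphragm SI position follows, within breathing cycle $k$,

$$ p(t) = b - A_k \cos^{2n}\!\big(\pi\, s(t) + \tfrac{\pi}{2}\big), $$

where $b$ is the end-exhale baseline, $A_k$ the cycle amplitude, $n$ the
shape exponent, and $s(t)$ the normalized cycle phase. The even cosine
power concentrates time near the baseline, producing the characteristic
long end-exhale dwell. Two forms of irregularity are modeled: per-cycle
uniform jitter of amplitude and period (defaults 5%), and per-sample
Gaussian noise (`noise_sd`, default 0.2 mm) representing within-cycle
trajectory irregularity at the scale of sub-voxel navigator extraction
noise.

The phase map $s(t)$ is piecewise linear so that a fraction
`inhale_fraction` (default 0.45) of each cycle is spent on the
descending (inhale) limb. This departs from a pure
$\cos^{2n}(\pi t/\tau)$ kernel deliberately: that kernel is
time-symmetric within a cycle, so classifying frames by moving direction
would split them 50/50 and the exhalation library could never be larger
than the inhalation one — contrary to what direction-classified
free-breathing images show. An inspiration:expiration time ratio of
roughly 0.45 : 0.55 is the textbook asymmetry of quiet breathing and
yields the expected exhale excess, which the library tests assert.

Inhalation moves the diaphragm *inferior*: the SI coordinate decreases
from the baseline by up to $A_k$. All modules inherit the axis
convention (LR, AP, SI), SI increasing toward superior.

### Volumes, hysteresis and ground truth

Each frame is a 64×64×64 grid of 5-mm isotropic voxels (the
free-breathing acquisition resolution; a 2-mm variant is a pure
configuration change): a dark lung compartment above a bright
sub-diaphragmatic compartment, separated by a gently curved dome whose
apex follows the waveform. The interface voxel is filled by its
partial-volume fraction, which is what makes sub-voxel navigator
extraction meaningful. An ellipsoidal tumor (default semi-axes
15×12×18 mm, volume ≈ 14 cc) sits in the lung; its SI center moves with
`tumor_si_coupling` (default 0.9) times the diaphragm displacement.

Hysteresis is realized as an AP phase loop. With normalized displacement
$u \in [0,1]$ ($u = \cos^{2n}$, 0 at end-exhale, 1 at full inhale), the
tumor AP center is offset by $\pm h\,\sqrt{u(1-u)}$ — positive on
exhale, negative on inhale — so the branch separation at equal SI
displacement is $2h\sqrt{u(1-u)}$, peaking at the configured
`hysteresis_width` $h$ (default 3 mm) at mid-displacement and vanishing
at the turning points, an elliptical SI–AP loop. An optional
`shape_modulation` scales the ellipsoid isotropically along the same
loop for direction-dependent shape change; it is off by default.

Masks are voxelized by the ellipsoid-inequality test at voxel centers,
with no anti-aliasing: ground truth is exact and reproducible. The
generating phase direction is *recorded* with each frame, never
re-derived from finite differences, so tests can distinguish
classification errors from generator ambiguity.

### The eight-phantom cohort

`cohort_config()` fixes the study conditions used by the evaluation
runs: eight phantoms with diaphragm amplitudes 15.8, 12.9, 20.7, 14.4,
9.6, 15.8, 11.6 and 29.1 mm (the free-breathing excursions the phantom
cohort emulates), periods between 2 and 4 s — subject 2 at 2.0 s and
subject 7 at 40/17 s, matching their observed 20 and 17 cycles per 40-s
scan — 5–10% cycle jitter, and hysteresis widths spanning 2–4 mm. Each
phantom contributes three 40-s series at 2 Hz (3 × 80 volumes). These
values are the generator's definition of the cohort, chosen once; they
are not tuning knobs.

## Waveform extraction and resampling

`extract_diaphragm()` averages intensity over the LR×AP extent of a
navigator box (default 30×30×60 mm on the dome apex) at each SI level
and returns the SI location of the largest absolute centered-difference
gradient. Magnitude rather than signed gradient makes the method
agnostic to bright-below vs bright-above contrast; equal maxima break
toward the most inferior location, deterministically. A three-point
parabolic fit through the gradient peak refines the estimate to
sub-voxel accuracy — without it, 5-mm voxels would quantize the waveform
far above the sub-millimeter regime the forecaster operates in; the
refinement is on by default and switchable off. On noise-free phantoms
the extraction error is bounded by half a voxel, and a small constant
bias (from dome curvature inside the box) cancels between library keys
and predictions because both live in extracted coordinates.

`interpolate_waveform()` fits a cubic spline (Forsythe–Malcolm–Moler end
conditions) through the samples and resamples at an integer multiple of
the original rate, producing `duration * rate` points so a 40-s, 2-Hz
waveform yields exactly 160 points at 4 Hz and 320 at 8 Hz. Two
numerical consequences are documented rather than hidden: original
samples are reproduced exactly (knot property), and because
$n \cdot m$ uniform output points span slightly more than the knot range,
the final $m-1$ samples are filled by the end cubic. On a 0.25-Hz
sinusoid sampled at 2 Hz the interior error is below 1% of amplitude;
the first/last original sampling interval and the end extension carry
larger error (about 1–2% and up to tens of percent at the very last
extrapolated sample, respectively) — no standard cubic end condition
does better at this sampling density, and the sliding forecaster only
ever consumes the affected points as the last few ground-truth samples.

`add_waveform_noise()` implements the robustness variant: zero-mean
uniform noise with half-width `percent` × (waveform range), e.g. 2%
of a 16-mm range bounds every perturbation by 0.32 mm. Uniform,
range-scaled noise is a choice; nothing in the problem pins the
distribution.

## Just-in-time forecasting

The treatment-time loop is a sliding window: 30 s of waveform
(`30 * f` points) trains a model, the next frame is predicted, the
window advances one timepoint. The first held-out point seeds the first
window advance, so a 40-s waveform yields `10 * f − 1` first-step
predictions (39 at 4 Hz, 79 at 8 Hz) — the off-by-one is a documented
convention, with truth taken from the held-out 10-s tail.

*AR(10)* is fitted per window by ordinary least squares on the lag
matrix with an intercept; a rank-deficient window (e.g. constant) falls
back to a ridge solution ($\lambda = 10^{-8}$, scaled) and flags the
result. Multi-step forecasts are recursive — predictions fed back as
inputs — not direct multi-output. AR forecasting is exactly
deterministic.

*LSTM*: a single recurrent layer of 20 units with a linear head,
trained from scratch on every window (the recurrent state is not carried
across windows) under squared-error loss with full-batch Adam
(learning rate 0.005, at most 150 epochs), on the z-score-normalized
window; a near-constant window skips training and returns the last
value. The backward pass is analytic truncated-nowhere BPTT, verified
against finite differences in the test suite to $10^{-6}$. Under a
fixed seed the training is bit-reproducible. The "20" is read as hidden
*units* (the usual toolbox convention), one recurrent layer.

Forecast quality ordering — errors growing with horizon, and 8-Hz
first-step errors below 4-Hz ones (more training points per window,
shorter lead time) — is asserted at cohort level by the tests, not
assumed.

## Motion libraries and matching

`build_libraries()` classifies every frame by the diaphragm moving
direction from the previous timepoint (decreasing SI = inhale), with two
deterministic conventions: a zero change inherits the previous label,
and the first frame of a series inherits the label of the second. The
displacement interval — the library granularity — is the motion range
divided by the mean entries per library; 30 mm over 120 entries per
library gives the worked value 0.25 mm.

`match_library()` selects the library by predicted direction, then the
entry with minimal |position − predicted|, ties toward the smaller
position (binary-search semantics over the sorted entries, verified
against exhaustive scans). The matched-displacement decomposition is
kept signed:

$$ \Delta D_\text{matched} = \Delta D_\text{prediction} +
   \Delta D_\text{matching}, $$

with $\Delta D_\text{prediction} = \text{truth} - \text{predicted}$ and
$\Delta D_\text{matching} = \text{predicted} - \text{entry}$, so the sum
telescopes to the net truth-to-entry displacement error and the identity
holds exactly on every match.

`inject_matching_error()` models imperfect matching: the matched
position is perturbed by uniform noise of half-width `fraction` ×
displacement interval and the nearest entry re-selected. The 10–20%
error is interpreted as a fraction of the displacement interval — the
granularity the error is physically tied to; the quantity it is a
percentage of is otherwise unspecified, and this is the documented
assumption. With a 0.25-mm interval, a 20% error moves the match at
most one neighbor away.

## BEV projection

`bev_basis()` builds the orthonormal triple for gantry angle θ (rotation
about the SI axis): beam axis $w = (\sin\theta, \cos\theta, 0)$ in
(LR, AP, SI), vertical BEV axis $v$ along SI, lateral axis
$u = v \times w$. At θ = 0 the BEV is coronal; $u$ then points along
−LR, a fixed in-plane mirror applied consistently everywhere, hence
invisible to every overlap and distance metric.

Projection is *orthographic* along $w$: the cine is a planar slice and
the volume overlay a parallel projection of contours; no source–axis
distance exists in the problem, so cone-beam divergence is deliberately
not modeled. The tumor mask is resampled by trilinear interpolation
(compiled code) on planes orthogonal to $w$ at 2-mm spacing — one plane
anchored at the isocenter, the stack spanning the occupied extent, a
sub-`step` extent collapsing to one midplane slice — thresholded at 0.5,
on a shared 2-mm BEV pixel grid centered on the isocenter. The
silhouette is the pixelwise union of the slice stack; the in-plane mask
is the single isocenter-plane sample (an infinitesimally thin plane —
the cine slice thickness is not modeled). Continuous resampling rather
than voxel walking keeps accuracy angle-independent with 5-mm voxels.
Centers of mass are computed over mask pixels in mm relative to the
isocenter.

Library masks default to automated threshold segmentation (midway
between the sub-diaphragm and tumor levels) followed by
largest-connected-component selection, mimicking an automatic
delineation step; on the phantom this reproduces the ground-truth mask
to Dice ≥ 0.99.

## Evaluation

Dice is $2|A \cap B| / (|A| + |B|)$ with two conventions for empty
masks: both empty = 1 (identical emptiness, e.g. two through-plane
misses), one empty = 0; such frames are flagged in the records. "3D
Dice" scores the projected-volume silhouettes, "2D Dice" the in-plane
slices, and ΔCOM is the Euclidean distance between silhouette centers
of mass in BEV millimeters.

IMRT uses the six fixed angles 0°–150° in 30° steps, and every
prediction frame is evaluated at all six angles (whether the original
analysis segmented time per beam is unknowable from the reported
per-patient equality of IMRT and VMAT columns, which is consistent with
either reading). VMAT assumes a constant gantry speed of 6°/s — 1.5°
per frame at 4 Hz (240 sections per rotation), 0.75° at 8 Hz (480
sections) — locked 1:1 to the cine frames, starting at 0°. With the
same matched frames, IMRT and VMAT records at a shared angle agree
exactly, which the tests assert.

Ground truth for a prediction frame at time $t$ is the phantom state at
$t$: the SI position interpolates the per-frame true positions (the
actual mechanical trajectory, including its noise component) and the
hysteresis phase comes from the generating cycle table. In oracle mode —
true positions and library direction labels passed through at the
native 2-Hz rate — the matched entry *is* the generating frame, and the
pipeline must return ΔCOM = 0 and Dice = 1 identically; this end-to-end
identity is a required test, not an observation.

Group comparisons use the two-tailed Welch $t$ test at the 0.05 level,
with the degenerate zero-variance/equal-means case defined as $p = 1$.

One statistical caution is built into the tests: the injected
matching-error fractions (0 → 0.1 → 0.2) shift mean errors by only a
few hundredths of a millimeter, far below the between-frame standard
deviation of ΔCOM in a single realistic run. Monotonicity in the error
fraction is therefore asserted where the law of large numbers makes it
deterministic — at the matching level over hundreds of seeded draws, and
at the pipeline level against the exact zero baseline of oracle mode —
rather than as a flaky comparison between two noisy realistic runs.

## Problem sizes and runtime

The suite and the acceptance script run the full conditions: 8 phantoms
× 3 series × 80 volumes of 64³ voxels, AR forecasting at 4 Hz (936
first-step predictions), and BEV projection of matched and truth masks
over the 6-field IMRT schedule plus the 1.5° VMAT arc (≈ 6,500
frame–angle records). Unit tests use a geometrically similar 32³
phantom where volume content is incidental to the property under test.
The LSTM is exercised on short windows and reduced epochs in most
tests, with one full-size (120-point window, 150-epoch) sinusoid check;
a full LSTM cohort run is supported but takes roughly a second of
training per sliding window.

## What the phantom does and does not establish

The generator emulates: navigator-extractable contrast, sub-voxel edge
structure, realistic amplitudes and periods with cycle-to-cycle
irregularity, exhale dwell and inhale/exhale time asymmetry, a coupled
tumor with an elliptical hysteresis loop, and the exact frame counts and
rates of the acquisition protocol. It does not emulate: MR pulse-sequence
physics or structured artifacts, super-resolution reconstruction,
multi-organ anatomy, non-ellipsoidal or deforming tumor shapes beyond
isotropic modulation, drifting baselines, or irregularities such as
coughs. Passing tests therefore demonstrate the *pipeline's* correctness
and its error budget under controlled motion — not clinical segmentation
performance on low-contrast anatomy, and not robustness to breathing
patterns outside the jittered-kernel family.

Other known limitations: the in-plane slice has zero thickness; the
matching-error base is an interpretation (see above); timing/latency is
logged nowhere because it is hardware-bound and out of scope; and the
forecaster sees the extracted waveform, so systematic extraction bias is
invisible to it by construction (it cancels between library and
prediction) while random extraction noise is the dominant term in the
realistic first-step error.
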