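---
title: "Methods: water-reaching behavior and mesoscale imaging analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water-reaching behavior and mesoscale imaging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoreach)
```

# The task and its trial state machine

The pipeline analyzes a head-fixed water-reaching task in which rewarded and
non-rewarded trials strictly alternate, always starting with a rewarded
trial. Each trial is referenced to camera onset (t = 0): a visual cue at
2 s, an auditory tone at 6 s, and — on rewarded trials only — a ~20-µl water
drop delivered with the tone. If a spout touch is detected after reward
delivery, recording ceases 4 s after the touch; otherwise (and on all
non-rewarded trials) it ceases 10 s after the tone. Rewarded trials
therefore span 10–16 s and non-rewarded trials exactly 16 s, with a 4-s
inter-trial interval. `build_timeline()` encodes these rules; a reported
touch before reward delivery is rejected as a sensor artifact rather than
silently accepted, and a touch at or beyond the 16-s timeout is rejected
because recording has already ceased. All analyses run on the first 10 s of
every trial (`truncate_trial()`), which makes trial lengths commensurable
across categories.

Touch-sensor times are treated as *advisory*: they shorten recordings but
never drive behavioral scoring, because capacitive sensors of this kind
under-report paw contact. Scoring comes from pose.

# Behavioral categorization

The original scoring was manual and blind. The package operationalizes the
written category definitions as a deterministic rule cascade over
markerless-pose tracks (`classify_trial()`):

1. **Reach event** — the left paw rises more than `lift_threshold` above
   the platform height *and* is displaced from its pre-cue rest position
   toward the spout by at least `forward_threshold` (projection on the
   rest-to-spout direction).
2. **Spout contact** — the paw comes within `contact_radius` of the spout
   keypoint.
3. **Retrieval** — after first contact, the paw comes within
   `contact_radius` of the mouth keypoint inside `retrieval_window_s`.

Rewarded trials map to: no reach event → `no_reach`; reach + contact +
retrieval → `success`; reach + contact without retrieval → `partial_fail`
(the drop is dislodged but not drunk); reach without contact →
`complete_fail`; at least `groom_min_cycles` paw–mouth oscillation cycles
without spout contact → `groom`. Non-rewarded trials collapse any reach or
groom into `unrewarded_reach`, mirroring the original scheme's decision to
merge grooming and groom-to-reach behavior on those trials. An *early
reach* (`detect_early_reach()`) is a reach event onsetting strictly before
reward delivery in a trial whose final category is `success`; early and
unrewarded reaches together index impulsive, cue-uncoupled reaching.

Defaults (all configurable via `classifier_params()`): `lift_threshold`
10 % and `forward_threshold` 15 % of the spout distance, `contact_radius`
10 %, `retrieval_window_s` 2 s, three groom cycles. Expressing thresholds
in spout-distance fractions makes them camera-zoom invariant. These values
are this package's operationalization of a manual protocol — they are not
published constants — and the ground-truth recovery suite shows they
separate the simulated behaviors essentially perfectly.

Tracking confidence below 0.5 marks a frame unreliable; interior gaps of at
most 5 frames (~83 ms at 60 Hz) are linearly interpolated, longer gaps are
masked, and a trial more than half masked is `disregard`ed — the synthetic
analogue of the "too difficult to score" category. Ambiguity in whether
"no reach" requires both paws resting is resolved by testing the reaching
(left) paw only.

# Reach kinematics

The **spout distance** — the vertical platform-to-spout separation,
computed from landmark-height medians over confident frames — is the
natural length unit: 1.0 spout distances is the most efficient
platform-to-spout route. `path_length()` sums left-paw frame-to-frame
Euclidean displacements from water delivery to 1.1 s afterward (the time a
proficient mouse needs to complete a reach) and divides by the spout
distance. Only consecutive usable frames contribute; interpolated short
gaps count, while a masked gap inside the window flags the trial and
excludes it from distribution summaries.

Histogram bins follow the convention bin *k* = [*k*, *k*+1) spout
distances, so a trial measuring exactly 4.0 lands in bin 4; bin edges are
not otherwise specified in the source protocol and the half-open choice
makes assignment exhaustive and exclusive. Distance statistics are
hierarchical by construction: mean and *sample* SD (n−1) per mouse across
its successful trials, then genotype values as means of per-mouse values.
Pooling trials across mice is deliberately impossible through the public
API (`trajectory_stats()`, `genotype_compare()`), because unequal trial
counts would otherwise bias group contrasts.

# Widefield imaging model

Acquisition strobes two illumination channels at 120 Hz combined:
blue-excitation frames carry GCaMP fluorescence, green-illumination frames
carry reflectance (hemodynamics, no indicator emission), 12-bit, 68 µm/px
after 8×8 binning. `demultiplex()` splits the interleaved stack
(fluorescence-first per the sidecar's `channel_order`, which is
authoritative) into two 60-Hz movies, dropping a trailing unpaired frame
with a warning.

Percent ΔF/F is `(F − F0)/F0 × 100` per pixel, with F0 the mean from trial
start to reward delivery. Hemodynamic correction subtracts the reflectance
ΔF/F from the fluorescence ΔF/F frame-by-frame — subtraction of percent
traces is the single supported mode; a ratiometric variant is intentionally
not offered. Because both channels are normalized over the same baseline
window, a shared artifact entering both channels with equal gain cancels
exactly (verified to numerical precision in the tests).

ROI metrics follow the 5×5-pixel convention: the window is centered on the
ROI centroid (rounded to the nearest pixel, ties toward the smaller
index). **Peak amplitude** is measured from the 1–5 s baseline to the
trace maximum inside a category-specific search window — reward to +4 s
for success/partial-fail trials, whose reaches are cue-locked, and the full
10 s for unrewarded-reach trials, whose reaches can occur anywhere; ties
break to the earliest peak. **Activated area** counts pixels whose maximum
over the same search window exceeds 4× their own baseline SD, restricted
to the brain mask (union of atlas labels) with zero-variance pixels
excluded and reported. Whether the original analysis used per-pixel or a
global SD is not documented; per-pixel is the default and
`sd_mode = "global"` is exposed as a sensitivity switch without any claim
of fidelity. Area is likewise computed on corrected movies with the
any-frame-in-window rule; both choices are stated here because the source
protocol leaves them open.

All windows in the package are half-open `[t0, t1)` and frame-snapped by
floor/ceiling at the stream's rate (`frame_window()`), so windows tile
without overlap.

# Atlas and registration

The packaged reference atlas (`default_atlas()`) is a *synthetic*
rectangular layout — 12 named dorsal-cortex regions per hemisphere (M1, M2,
sspm, sspfl, ssphl, sspun, sspn, sspbfd, ssptr, visp, rspagl, rspd) in a
hemisphere-mirrored grid with bregma/lambda/midline landmarks — not an
anatomical tracing. It provides exactly what the ROI metrics need: named,
disjoint, interior regions and landmark geometry. Learned landmark
prediction is out of scope; `register_atlas()` takes user-supplied (or
simulated) landmark coordinates, fits the least-squares affine from
reference to image (at least three non-collinear points; exact for three),
warps labels by nearest-neighbor through the inverse transform, and
reports RMS landmark residual as the registration quality metric.

# The synthetic-session simulator

The simulator is the package's validation instrument: it generates the
three input streams (event log, pose CSVs, strobed TIFF-able movies) with
the statistical structure of a real session *and records every latent*, so
each downstream stage can be tested for recovery rather than plausibility.

Behavioral defaults emulate a proficient (day-8, wild-type-like) session:
~120 trials, success probability 0.89, unrewarded-reach probability 0.094,
early-reach probability 0.018, reach path-length targets from
Normal(2.1, 0.6) spout distances truncated to [1, 4.5] (a reach that
touches the spout cannot be shorter than the direct route; the truncation
shifts the realized mean to 2.146, which recovery tests use as the
target). Trajectories are keyframe scripts — rest, lift, spout approach,
grasp, mouth return for success, with the appropriate truncations for the
failure modes — rendered at 60 Hz. For spout-contact categories the
platform-to-spout segment is a straight base path plus rectified transverse
lobes whose amplitude is solved (by `uniroot` on the discrete polyline) so
the frame-to-frame path length over the reward→+1.1 s window equals the
target to well under the 2 % tolerance the tests assert; the lobes swing
away from the mouth so extra path length can never fake a grasp-to-drink
event. Tracking jitter defaults to 0.05 px (sub-pixel tracker noise) and
2 % of frames fall in low-confidence dropout bursts of 1–4 frames to
exercise the interpolation path; heavier corruption is available for
robustness experiments but is not the default study condition.

The imaging model adds, on a flat 12-bit baseline (2000/2500 counts for
fluorescence/reflectance, leaving headroom for transients), (i) ROI-uniform
calcium transients with a difference-of-exponentials kernel (rise 0.1 s,
decay 1.0 s, unit peak) approximating slow GCaMP6s kinetics — the source
protocol does not model indicator kinetics, so this is a modeling choice —
onset at the trial's reach onset; (ii) a shared hemodynamic waveform (a
0.8-amplitude ~0.1-Hz vasomotion sinusoid with per-trial phase jitter plus
a reach-locked dip) scaled into percent ΔF/F by per-channel gains (default
2 % in both, so correction removes it exactly up to noise); and (iii)
independent Gaussian shot noise (0.2 % of baseline). Published per-ROI
ΔF/F magnitudes are not reported numerically; the default amplitudes
(2–8 %, strongest in contralateral motor cortex) are plausible widefield
GCaMP6s values, not literature constants. Frames are interleaved
fluorescence-first and quantized (round half up) to [0, 4095]. The fused
assembly loop and the per-pixel ΔF/F kernel are compiled (Rcpp) because
they touch ~2×10⁷ values per trial; both use R's RNG, so sessions are
bit-reproducible under `set.seed()`.

All randomness flows from one session seed with per-trial substreams
derived deterministically from (seed, trial index), so any single trial
can be regenerated without replaying the session — this is what lets the
batch pipeline's imaging stage re-create movies on demand instead of
storing them.

What the simulator does **not** emulate: cortical texture and vasculature,
behavioral video, photon-statistics (noise is Gaussian, not Poisson),
pose-estimation failure modes beyond confidence dropout, and inter-mouse
kinematic idiosyncrasies. Passing recovery tests therefore demonstrates
correctness of the *analysis*, not robustness to every artifact of real
data.

# Batch pipeline and cohort design

`run_pipeline()` chains simulate → classify → kinematics → imaging →
report over a (genotype × mouse × day) cohort from a single YAML-able
config and one seed. Per-genotype success schedules let a cohort emulate
the headline phenotype (one group holding ~0.9 success, the other
declining toward 0.3); the residual probability is split among the other
categories in their default proportions. Each stage writes CSV tables; the
report stage emits one row per (genotype, day, mouse), genotype contrasts
as means of per-mouse values with SEM over mice, and a manifest (package
version, seed, config MD5) with no timestamps, so re-running a config
yields byte-identical tables. Inferential statistics (mixed-effects ANOVA
and multiple-comparison corrections in the original work) are deliberately
excluded: synthetic cohorts validate descriptive recovery, and the
per-mouse tables are ready for `stats::aov()` or `lme4` if a user wants
inference.

# Validation problem sizes and numerical choices

The shipped validation suite uses: 500-trial sessions for classifier
fidelity (noise-free and default-noise), 100 success trials at 128×128 for
hemodynamic-correction recovery of {2, 5, 8} % amplitudes under a 2 %
artifact and 0.2 % noise (median recovered within ±0.3 % absolute;
uncorrected bias ≥ 1.5 %), 64×64 × 600-frame movies for the activated-area
tail checks (the all-noise activation fraction is compared against the
chi-integrated Gaussian tail probability, with slack for the shared-F0
centering the analytic formula ignores), 100 random tracks for the
path-length oracle (agreement to 1e-9 relative), and 4–6 mice × 50–60
trials for hierarchical-aggregation recovery. These sizes give tight Monte
Carlo intervals while keeping the default test run fast.

Numerical conventions collected in one place: half-open frame-snapped
windows; round-half-up 12-bit quantization; centroid rounding ties toward
the smaller index; earliest-peak tie-breaks; sample SD throughout;
`eps = 1e-3` counts as the dark-pixel threshold for F0. Degenerate inputs
error loudly (zero spout distance, all-dark planes, collinear landmarks,
streams shorter than the analysis window) rather than returning silent
NAs.

# Known limitations

The classifier thresholds, while zoom-invariant, assume a roughly vertical
reach geometry (platform below spout); a strongly oblique camera would
need recalibrated forward/lift thresholds. The hemodynamic model is
single-compartment and channel-shared; real reflectance corrections are
wavelength-dependent and spatially heterogeneous, so the exact-cancellation
property is an idealization. The synthetic atlas supports ROI bookkeeping
and registration geometry but not anatomical conclusions. And the
simulator's trial categories are mutually exclusive by construction,
whereas real mice mix behaviors within a trial; agreement numbers on
synthetic sessions are therefore upper bounds on real-data performance.
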