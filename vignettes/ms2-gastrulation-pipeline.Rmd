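---
title: "Quantifying transcription through gastrulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription through gastrulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In the early *Drosophila* embryo, Notch signalling switches on transcription
in the mesectoderm (MSE) — two single-cell stripes flanking the mesoderm
(ME) — midway through nuclear cycle 14 (nc14). Live imaging with the MS2/MCP
reporter shows that mean transcription from Notch-responsive enhancers
roughly doubles around 50 minutes into nc14, coinciding with the onset of
mesoderm invagination. Asking whether that step is caused by gastrulation
requires measuring, in the same movie, (i) per-nucleus transcription over
time and (ii) the timing of the morphogenetic movements, and then relating
the two.

`ms2gastrula` implements that measurement chain end to end: 3D nucleus
segmentation and tracking on the histone channel, spot-proxy trace
extraction and normalization on the MCP channel, automatic detection of
gastrulation milestones from dorso-ventral (DV) nuclear movement, changepoint
detection of the transcription-level transition, and per-nucleus
classification of transcriptional increases. Because raw embryo movies are
tens of gigabytes, the package ships a synthetic embryo generator with full
per-nucleus ground truth; every stage is validated against it.

## Trace processing model

The raw per-nucleus signal is the maximum MCP-channel intensity over the
nucleus's voxels ("spot proxy"). Processing follows a fixed chain:

1. **Short-track filter.** Only nuclei tracked for *more than*
   `min_track_frames` (default 10) frames are kept.
2. **Two-pass activity calling.** A straight line is fitted to the mean of
   all nuclei over time (pass-1 baseline). Each trace is median-smoothed
   (width 3 frames); a frame is ON when the smoothed value is at least
   `on_ratio` (default 1.2, inclusive) times the baseline at that time; a
   nucleus is active when it accumulates at least `min_on_frames`
   (default 5) ON frames. The baseline is then refitted to the mean of the
   pass-1 *inactive* nuclei and the calls are repeated. The inclusive
   comparison and the cumulative (not necessarily consecutive) ON count are
   frozen conventions; the bundled probes use single contiguous pulses, for
   which the two readings coincide.
3. **Normalization.** For active nuclei,
   `normalized(t) = (raw(t) - baseline2(t)) / bleach(t)`, where `bleach(t)`
   is the median-smoothed (width 5) inactive-nuclei mean divided by its
   value at the window start. Dividing by the relative decline of an
   internal dark reference removes photobleaching without any external
   calibration. With the generator's linear bleaching and zero noise this
   normalization inverts the generative model exactly, which the tests
   assert at 1e-9.
4. **Early-activity exclusion.** Nuclei whose first ON frame precedes 15
   min into nc14 (30 min in `gal4` mode, where maternal Gal4 causes early
   stochastic firing) are discarded and the analysis is truncated to later
   times.
5. **Optional klar compensation.** Embryos depleted of Klarsicht are
   optically clearer and report 11% brighter MCP signal; when enabled,
   normalized values are scaled by 0.89.

A deliberate convention: the running median shrinks its window
symmetrically at series ends, so it is exact on linear series everywhere.
This keeps the bleach curve anchored at exactly 1 at the window start and
makes the zero-noise inversion property hold to float precision.

## Movement and milestones

The DV movement profile is the mean ventral-signed Y velocity of the
transcribing nuclei (µm/min, median-smoothed over 5 frames). "Ventral
positive" is movement toward the ventral midline; each track's sign comes
from its starting position relative to the cohort's mean initial Y. With
two MSE stripes flanking the midline a raw signed mean would cancel, so the
per-track signing is essential; a magnitude mode is available for
comparison with plots drawn that way.

Milestones are read off the profile automatically:

* one dominant ventral peak → mesoderm invagination; its onset is the
  threshold crossing at `peak_fraction` (default 0.2) of peak height,
  found by walking *backwards* from the peak (so noise crossings long
  before the peak are ignored) and interpolating linearly;
* an earlier opposite-signed peak (tilted mounting: the embryo rolls during
  apical constriction) → `t_constriction` is that peak's onset and
  invagination is placed at the movement minimum between the peaks;
* no peak above the noise floor (0.5 µm/min) → no milestones, as when
  invagination fails.

## Transition detection

The transition between two transcription levels is the best two-plateau
piecewise-constant fit of the cohort mean trace, by exhaustive search over
changepoints with at least `min_seg` (5) samples per side, minimizing the
residual sum of squares. A transition is only accepted when the one-plateau
SSE exceeds the two-plateau SSE by a variance ratio of at least 2; a flat
trace therefore reports "no transition", mirroring the requirement that a
clear change be observable before a transition time is used.

The pipeline wraps the raw search with three documented refinements, all
tuned on the generator: the search window starts only after cohort onset is
complete (median onset + 3·MAD + 2 min — a robust bound, since false-active
nuclei produce stray late onsets), the cohort mean is median-smoothed over
9 frames before the search, and the changepoint is re-estimated in a window
symmetric about the first estimate, because unequal plateau lengths bias
the changepoint of a jittered (ramp-like) step.

"Increasing" nuclei are those whose mean normalized signal in the 15 min
after invagination onset (a) exceeds the mean of all active nuclei over the
same window and (b) is at least 1.7× their own mean over the 15 min before
onset (inclusive). The grammatically ambiguous "from 15 min of the start"
is read as the 15-minute window *after* the start. Cohort-level agreement
between transcription and morphogenesis is summarized as the squared
Pearson correlation of per-embryo (invagination onset, transition time)
pairs pooled across conditions, excluding embryos without an accepted
transition.

## The synthetic embryo generator

The generator emulates the ventral field of view of an nc14 embryo at the
acquisition geometry of the study: 0.36 µm/px in XY, 1 µm z-steps, 15 s
frames. Its defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_mse`, `n_me`, `n_ne` | 48 each | nuclei per region; a 144 µm field at 6 µm pitch holds ~24 per stripe row |
| `t_onset` | 25 min | earliest MSE transcription onset (+ per-nucleus \|N(0, 4)\| jitter) |
| `t_constriction`, `t_invagination`, `t_end` | 42, 50, 62 min | control milestones; the fog-like preset shifts invagination to 60 min and stretches the phase |
| `p_on`, `p_off` | 0.4, 0.2 | per-frame telegraph switching: ON bursts of ~1.2 min at duty 2/3 |
| `amp_pre`, `step_factor`, `p_step` | 400 AU, 2.0, 0.4 | ON spot amplitude; 40% of MSE nuclei double at invagination (± 2 min per-nucleus jitter) |
| `b0`, `bleach_rate` | 200 AU, 0.003/min | shared background and linear photobleaching (~19% over nc14) |
| `noise_sd` | 20 AU | additive Gaussian measurement noise |

The fluorescence model is `v(t) = (b0 + S(t)·A(t)) · max(0, 1 − r·t) + ε`:
background and signal bleach together, as fluorophore loss affects both.
Movement uses half-cosine ramps (zero velocity at phase boundaries): an
optional dorsal "rolling" drift during apical constriction, a ventral
convergence of MSE/NE toward the midline during invagination (capped so
stripes keep their order and stop short of the midline), and a z-descent of
ME nuclei as the mesoderm internalizes. Rendering places anisotropic 3D
Gaussian blobs (half-maximum at the 3 µm nucleus radius) in the histone
channel and, per transcribing nucleus, one bright punctum at a fixed
random intra-nuclear offset in the MCP channel, quantized to 16 bits.

Choices worth flagging. The telegraph switching rates are not constrained
by the source data; they were fixed once so that a 48-nucleus cohort mean
resolves the twofold step on the few-minute timescale at which the study
reports it — with much slower switching, burst autocorrelation masquerades
as level changes. The step is instantaneous per nucleus; only its time is
jittered. Positional jitter is off by default (trajectories are
deterministic given the config) and enabled explicitly in recovery tests.

What the generator does **not** emulate: optics (no PSF, no Poisson shot
noise by default), mitosis and nc13 history, membrane geometry, nuclear
packing at realistic density, and the crowding collapse late in
gastrulation — rendered nuclei are Gaussian blobs whose tails merge when
stripes converge, so segmentation recall is validated on windows before
peak crowding. Passing tests therefore demonstrate the correctness of the
implemented rules and their recovery behavior under this statistical model,
not segmentation performance on real embryo movies.

## Segmentation and tracking internals

Per frame: 3×3×3 median filter (replicate borders); percentile rescale
(1st/99.8th percentiles to [0, 1]) so a fixed threshold survives bleaching;
a log-Gaussian radial band-pass in the Fourier domain centred at
1/(2·3 µm) with one-octave bandwidth (frequencies computed in physical
units, which handles the 0.36 vs 1 µm anisotropy exactly); Otsu threshold
taken once from the first frame and held fixed; per-plane and 3D hole
filling; removal of sub-minimum debris (0.25× the expected nucleus volume);
watershed on the anisotropic Euclidean distance transform, seeded at
distance maxima separated by at least the nucleus radius; the full size
filter (0.25×–4×); and a one-voxel non-overlapping thickening in which
contested voxels join the physically nearer object. Clusters larger than a
single nucleus are deliberately *not* removed before the watershed — they
are exactly the merged objects the watershed must split.

Tracking links each detection to the nearest track ending in the previous
frame within a strict 6 µm cap, falling back to tracks ending two frames
back (bridging one-frame gaps). Claims are resolved per frame: if two
detections claim the same track, both start new tracks. Ties at exactly
equal distance go to the track holding the lower detection index;
evaluation order is lowest-index-first. These conventions are frozen and
probed by the test suite's brute-force oracle.

## Problem sizes and numerical conventions

The bundled validation uses trace-level cohorts of 144 nuclei × 280 frames
(seconds per embryo), rendered stacks of roughly 130×90×12 voxels × 10–40
frames for imaging-path tests, 20-embryo cohorts for milestone and
transition recovery, and 10+10 control/fog cohorts for the timing
comparisons. Voxel indices are 0-based in physical conversions: the centre
of voxel *i* is at (*i* + 0.5)·voxel size; all distances are µm and all
times are minutes into nc14 (frame 1 = 0). Changepoint ties resolve to the
earliest candidate; nearest-object ties in thickening resolve to the lower
label.

## Known limitations

* Milestone onsets inherit a small positive lag (~0.8 min) because a
  threshold crossing on a smooth ramp necessarily trails the true phase
  start; this is well inside the ±2 min recovery target.
* The transition time of a per-nucleus-jittered step is intrinsically
  ambiguous at the ±1–2 min level (the cohort mean is a ramp, not a step);
  medians over 10-embryo cohorts inherit roughly ±1 min of spread.
* The klar compensation direction (multiply by 1 − 0.11) encodes the
  reading that cleared embryos over-report brightness by 11%.
* `detect_spot_dog` assumes one spot per nucleus (the reporter is a single
  locus); sister-chromatid doublets are not modelled.
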