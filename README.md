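# ms2gastrula

Quantification of live MS2/MCP transcription dynamics through gastrulation
in the early *Drosophila* embryo.

## What it does and for whom

During nuclear cycle 14 (nc14), Notch-responsive enhancers switch on
transcription in the mesectoderm (MSE) — the stripes of cells flanking the
mesoderm — and their mean output roughly doubles around 50 minutes into
nc14, as the mesoderm invaginates. Relating that transcriptional step to
the morphogenetic events requires a quantitative pipeline from raw
two-channel 4D movies (a histone marker for nuclei, MCP-GFP for nascent
MS2 spots) to per-nucleus transcription traces and per-embryo event times.

`ms2gastrula` is that pipeline, for researchers analysing MS2-type live
imaging of early embryos:

* **Segmentation** of nuclei per 3D frame: median filtering, Fourier-domain
  blob enhancement, fixed thresholding, anisotropic distance-transform
  watershed, size filtering and one-voxel thickening.
* **Tracking** by nearest-centroid linking with a strict 6 µm cap and a
  two-frame lookback; conflicting claims spawn new tracks.
* **Trace processing**: per-nucleus spot-proxy extraction (maximum MCP
  intensity over the nucleus), short-track filtering (> 10 frames),
  two-pass baseline fitting and ON/OFF activity calling (ON at ≥ 1.2×
  baseline; active at ≥ 5 ON frames), photobleaching normalization against
  the inactive-nuclei mean, early-activity exclusion (15 min; 30 min with
  maternal Gal4), total output, and optional 11% *klar* clearing
  compensation.
* **Gastrulation analysis**: dorso-ventral movement profiles of
  transcribing nuclei, automatic milestone detection (apical constriction,
  invagination onset, end of gastrulation), exhaustive two-plateau
  changepoint detection of the transcription transition, classification of
  "increasing" nuclei (post/pre window means, ≥ 1.7× own level and above
  the cohort mean), and pooled R² between event and transition times.
* **Spot-level proxies**: difference-of-Gaussians spot localization,
  mean histone intensity in a 5×5 window around the spot (chromatin
  compaction proxy), spot mobility relative to the nucleus centroid
  (median-filtered over 8 frames), nuclear factor levels, nuclear axis
  lengths, and cell-shape/ME-contact metrics on provided label images.
* **A synthetic embryo generator** (telegraph bursting, amplitude step at
  invagination, shared photobleaching, staged DV movement, 16-bit
  two-channel rendering) with per-nucleus ground truth, so the whole chain
  is testable without any raw data.

In the core trace model, a nucleus's fluorescence is
`v(t) = (B0 + S(t)·A(t))·b(t) + ε` with telegraph state `S`, spot amplitude
`A` (stepping ×2 at invagination in a fraction of MSE nuclei), and shared
linear bleaching `b(t)`; normalization recovers `S(t)·A(t)` as
`(v − baseline)/bleach curve`.

## Worked example

Simulate one control embryo and run the full trace-level analysis:

```r
library(ms2gastrula)
rep <- run_pipeline(run_config("control", seed = 7))
print(rep)
```

```
<run_report> preset control, seed 7: 43 active nuclei
<gastrulation_events> constriction -, invagination 50.89, end 61.36 min (1 peak)
<transition_result> 50.25 min: 258.4 -> 351.7 AU (fold 1.36)
  cohort fold change at invagination: 1.35
  fraction of active nuclei increasing: 0.26
```

Reading the output: 43 of the 48 simulated MSE nuclei were called
transcriptionally active. The ventral movement profile shows a single peak
(ventrally mounted embryo, hence no constriction time), with invagination
onset detected at 50.9 min into nc14 — the generator's true onset is
50 min. The cohort mean transcription shows a clear level transition at
50.3 min, rising from 258 to 352 AU (fold 1.36: with 40% of nuclei
doubling, the cohort mean rises ×1.4), and 26% of active nuclei
individually pass the "increasing" criteria. A `fog_like` preset delays
invagination and the detected transition by ~10 min; an `acat_like` preset
(no invagination) yields no milestones and no transition.

The rendered route (`run_config(..., render = TRUE)`) additionally writes
and re-analyses a two-channel 16-bit TIFF stack through segmentation,
tracking and trace extraction. A thin command-line wrapper lives at
`inst/cli/ms2gastrula.R`.

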