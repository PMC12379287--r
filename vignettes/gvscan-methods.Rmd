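---
title: "Methods: collapse-based ultrasound quantification of gas-vesicle biosensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collapse-based ultrasound quantification of gas-vesicle biosensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvscan)
```

## The measurement problem

Gas vesicles (GVs) are air-filled protein nanostructures that scatter
ultrasound and collapse irreversibly above a pressure threshold. Bacteria
engineered to express GVs from acoustic reporter genes become ultrasound
visible, and a collapse-based pulse sequence can separate their signal from
tissue: frames acquired at a high ("collapsing") voltage destroy the GVs over
a few frames, so contrast that changes across collapsing frames is
GV-specific while static speckle is not. `gvscan` implements the complete
computational path around this idea — simulation of acquisitions with the
statistical structure the analysis assumes, frame-difference reconstruction,
whole-abdomen scan assembly, quantification, dose-response fitting for the
biosensor circuits, and the supporting screening and assay statistics — so
that every stage is testable without any instrument data.

## Signal model of the simulator

One acquisition is a stack of beamformed envelope frames. Frame $f$ at pixel
$p$ is modeled as

$$ I_f(p) \;=\; b(p)\,S(p) \;+\; g(p)\,c_f \;+\; \varepsilon_f(p), $$

with $b$ the tissue echogenicity map, $S$ a multiplicative, unit-mean,
right-skewed speckle field (the squared magnitude of a smoothed complex
Gaussian field — fully developed speckle is exponential; the smoothing
length, 2 px, sets the speckle grain), $g$ the GV contrast amplitude, $c_f$
the per-frame GV visibility, and $\varepsilon$ independent zero-mean
Gaussian noise. Three modeling choices matter:

* **Speckle is shared across frames of a static scene.** Collapse
  differencing only works because tissue speckle is correlated frame to
  frame; simulating a fresh field per frame would destroy the very property
  the reconstruction exploits.
* **The collapse profile encodes the two conventions.** For the in vivo
  variant the GV-specific signal *rises* from the first to the second
  collapsing frame before decaying; the 7-frame default profile is
  $c = (0.6, 1, 0.5, 0.25, 0.1, 0.05, 0)$. Its magnitudes are free model
  parameters — only the rise-then-decay shape is constrained. In vitro,
  the first collapsing frame is brightest and the signal decays
  exponentially to near zero by the last frame. Low-voltage frames carry a
  small pre-collapse visibility, default $0.1\,c_1$, since intact GVs
  scatter linearly even below the collapse threshold.
* **Frame averaging is modeled as reduced noise.** The 50-accumulation in
  vitro schedules are simulated with noise sd
  $\sigma/\sqrt{\text{accumulations}}$ rather than 50 explicit sub-frames —
  identical in expectation and far cheaper.

Breathing motion is simulated as a rigid translation (rounded to whole
pixels) plus partial replacement of the speckle field by a fresh
realization, with the affected frames flagged in ground truth. The flags
are for testing motion detectors; reconstruction never reads them. No
deformable motion, attenuation, or RF-domain physics is modeled: the
simulator operates on envelope images, matching the data the analysis
actually consumes.

Every simulator output is a pure function of its parameters and an integer
seed, and restores the caller's RNG state.

## Acquisition schedules and scan geometry

`build_schedule()` encodes the five named configurations: the L22-14v
in vitro schedule (10 frames at 1.6 V, then 46 collapsing frames at 25 V),
the L22-14vX in vitro schedule (1 + 7 frames, collapse at 20 V, three
focused beams per transmit for a threefold frame-rate gain), the two in
vivo schedules (1 + 7 frames at 25 V / 20 V), and the ex vivo gut schedule
(in vivo schedule at 8 mm focus). `plan_in_vivo_scan()` enumerates the
stage grid — three 9.6-mm lateral steps by eighty 0.5-mm longitudinal steps
for the whole abdomen, i.e. 240 acquisitions — in row-major acquisition
order starting at the rib cage. All world coordinates are in millimeters,
the axial axis points away from the transducer face, pixel (0,0) is
shallow-left, and pixel intervals are half-open.

## Reconstruction

With collapsing frames indexed $1..K$:

* **BURST** (in vitro): first collapsing frame minus last, isolating
  everything destroyed by collapse.
* **BURST\*** (in vivo/ex vivo): *second minus first* collapsing frame.
  The GV signal rises between those frames while tissue does not, and
  using only two adjacent frames keeps the image robust to slow motion.
  Note the opposite frame order to BURST.
* **B-mode**: the first collapsing frame, unmodified.

Difference images are signed and never clipped before quantification; the
display stage alone handles negative values. Motion screening is an
automated surrogate for the manual breathing exclusions of the original
protocol: the score is one minus the Pearson correlation between the two
frames the active reconstruction differences, optionally restricted to a
background band, with exclusion above a threshold (default 0.5 — a design
choice, no published value exists). A manual exclusion list remains the
authoritative override. On the simulator's labelled ensembles the detector
reaches full recall with no false positives at that default (asserted in
the tests).

## Assembly

Per-station acquisitions are concatenated laterally at the stage spacing.
When the image width differs from the 9.6-mm step, the default policy crops
each block to the step width centered on the beam axis; an
overlap-averaging policy is available behind a flag (the original protocol
does not state which it used, so both are exposed, and the crop default
keeps the signal-conservation invariant exact). Excluded acquisitions are
zeroed only in the BURST\* channel — B-mode keeps the anatomy, mirroring a
display of B-mode everywhere with holes in the overlay.

Volumes are `[longitudinal, axial, lateral]` arrays with deliberately
anisotropic voxel spacing (0.5 mm between planes versus the pixel pitch in
plane), carried in metadata and never resampled away. GI-tract ROI masks
are supplied per plane (drawn by hand in practice; generated from simulator
truth in tests); BURST\* voxels outside the mask or in excluded
acquisitions are set to zero, and the exclusion map records the latter. A
station with no mask is treated as all-background with a warning, or
rejected in strict mode.

The ex vivo series keeps each 1-mm station's images with a signed length
coordinate relative to the cecum landmark, positive toward the rectum.

## Quantification conventions

* SBR is the mean sample-ROI intensity over the mean background-ROI
  intensity; decibels are $20\log_{10}$.
* Display normalization divides every image in a compared set by the
  *pooled* average background and fixes shared colormap limits
  $(A,\; B\cdot\max/\overline{bg})$, then converts to dB with
  subthreshold values floored to the lower limit. The constants are fixed
  per mode and transducer: BURST L22-14v $(A{=}3, B{=}1)$, BURST L22-14vX
  $(A{=}2, B{=}0.5)$, xAM L22-14v $(A{=}2, B{=}0.5)$, xAM L22-14vX
  $(A{=}2, B{=}0.4)$. Limits are computed once per compared set, making
  the output invariant to a common gain.
* Depth windows are half-open $[lo, hi)$ in mm, converted to pixel rows by
  rounding boundaries down. The 2-D B-mode map sums depth 4–8 mm; the 2-D
  BURST\* map sums the full ROI depth; the ex vivo profile sums 4–12 mm
  over the full 9.6-mm transducer width.
* Total BURST\* signal is the *signed* sum of all in-mask, non-excluded
  voxels. Negative difference values are included by default — the summing
  rule says "all pixel intensities" — with a clip-at-zero variant behind a
  flag for sensitivity analysis. By construction the 2-D map sums exactly
  to the 3-D total (a Fubini identity asserted in the tests).
* The overlay threshold is never published; the default policy takes a
  percentile (97.5%) of the BURST\* pixel distribution, so on
  signal-free noise at most 2.5% of pixels display; a fixed threshold may
  be given instead.

## Dose-response fitting

`fit_hill()` fits $y(c) = y_0 + (y_{max}-y_0)\,c^n/(K^n+c^n)$ — the
4-parameter Hill model with baseline, chosen because biosensor titrations
have a nonzero uninduced response. The fit is deterministic: a fixed
multi-start grid (K over quantiles of the positive concentrations crossed
with $n \in \{0.5, 1, 1.5, 2, 3, 4\}$), each start solved for
$(y_0, y_{max})$ by linear least squares since the model is linear in them
given $(K, n)$; the best start seeds a Levenberg–Marquardt polish of all
four parameters, and ties break toward the smallest $K$. Flat data are
flagged unidentifiable with $K$ undetermined and fold change 1. On
noiseless synthetic curves parameters recover to $10^{-6}$ relative error;
at 10% CV with 4 replicates the median relative error of $K$ over 200
seeded simulations is below 15% (both asserted in tests).

Maximal fold change is defined on condition means — the peak mean response
over the zero-dose mean — matching how fold-change arrows span the 0-dose
and peak-dose points of a titration figure; the fitted variant
$y_{max}/y_0$ is reported alongside. The cell-density detection limit uses
the blank mean plus three blank standard deviations as its default
criterion (the criterion is a package choice, recorded in the output, since
only detection outcomes are ever published).

## Screening statistic

Patch opacity is the mean patch-ROI intensity minus the mean of the
adjacent background ROI (an annulus around the patch), which cancels the
spatial nonuniformity of white-trans plate images. Relative patch opacity
anchors these corrected values so the parent strain at 0 mM inducer and
30 °C maps to 0 and at 1 mM maps to 1; the statistic is invariant to affine
intensity transforms applied to image and anchors together. Anchors are
computed per experiment batch by default (per plate available). The
original pick rule was visual; the quantitative surrogate used here calls a
candidate a hit when its 1 mM corrected opacity exceeds its 0 mM value by
0.25 of the anchor span, ranked by 1 mM relative opacity with ties broken
toward the lower 0 mM value. GFP-mode patches run through the identical
arithmetic on fluorescence images.

## Assay calculations

CFU/g is `colonies / (plated volume × overall dilution × homogenate
density)`, with a one-colony limit of detection reported for zero counts.
Flow events are gated on rectangular forward/side-scatter ranges and an
mCherry (Y2) threshold — the gate geometry is configuration, since no
numeric gate values are published; GFP summary statistics are the geometric
mean of B1 (nonpositive values floored to 1 channel unit before the log)
and the GFP-positive fraction, events strictly above 1000 in B1 over all
gated events. Histogram binning follows the Freedman–Diaconis rule
$h = 2\,\mathrm{IQR}\,n^{-1/3}$ with a floor of 100 bins (constant data
fall back to exactly 100). Thiosulfate quantification normalizes each
injection's thiosulfate peak area by its phosphate peak area (internal
standard: all samples share the same PBS background), fits a straight line
through the external standards without forcing the origin, inverse-predicts,
multiplies by the dilution factor, and averages technical replicates;
samples outside the standard range are flagged as extrapolated.

## Pipeline orchestration and reproducibility

`run_pipeline()` executes a configured run (two demo configurations ship:
a phantom titration and a reduced in vivo scan), writes TIFF + JSON and CSV
outputs, and emits a manifest hashing every file. One master seed fans out
to per-stage child seeds as $(s + 10007k) \bmod (2^{31}-1)$; re-running a
config with the same seed reproduces byte-identical outputs.

## What the simulator does and does not establish

The generator reproduces the statistical structure the analysis relies on:
frame-correlated speckle, the rise-then-decay collapse signature, additive
noise, rigid breathing displacements, stage-scan geometry, sigmoidal
titrations with CV-scaled replicate noise, bimodal GFP mixtures, and
patch plates with background gradients. It does not model attenuation,
time-gain compensation, nonlinear propagation, transducer impulse
responses, deformable tissue motion, or concentration-dependent collapse
pressure spectra. Passing tests therefore demonstrate the correctness and
calibration of the *computations* under the stated model — not that the
model captures every property of animal data. Headline in-study numbers
(fold changes of specific engineered circuits, in vivo group differences)
depend on wet-lab measurements and are out of reach of any simulation;
the package instead verifies the machinery that produced them:
acquisition-geometry counts, reconstruction identities, Monte-Carlo nulls,
round-trip parameter recovery, and anchored-statistic exactness.

## Problem sizes and numerical choices

Tests and the acceptance script run at reduced sizes chosen to keep the
statistical assertions meaningful: 24×24 to 50×144 px images, scan grids
from 1×2 up to the full 3×80 (simulated once at small frame size), 200-seed
ensembles for the Monte-Carlo null and the Hill recovery bound, and
20 000-event flow samples. Degenerate inputs are handled explicitly:
constant frames score 0 in motion screening with a warning; nonpositive
ratios return `NA` from `to_db()` rather than `-Inf`; flat titrations are
flagged rather than fitted; zero-IQR samples take the 100-bin fallback.
Half-open pixel/depth intervals and floor-rounding of window boundaries
make every integration window unambiguous.
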