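# gvscan

Collapse-based ultrasound imaging and quantification of gas-vesicle
bacterial biosensors, as a tested, reusable R pipeline.

## The problem

Gas vesicles (GVs) are air-filled protein nanostructures that scatter
ultrasound and collapse irreversibly above a pressure threshold. Bacteria
carrying acoustic reporter genes express GVs and become visible to
ultrasound deep in tissue — for example, engineered probiotic biosensors
that report gut inflammation markers such as thiosulfate. Imaging them
relies on *collapse differencing*: across a series of frames acquired at a
collapsing voltage, GV-specific signal changes while tissue speckle does
not. With collapsing frames indexed 1..K:

* **BURST** (in vitro): frame 1 − frame K — everything destroyed by
  collapse.
* **BURST\*** (in vivo / ex vivo): frame 2 − frame 1 — the GV signal
  *rises* between the first two collapsing frames, and a two-adjacent-frame
  difference stays robust to tissue motion.
* **SBR** = mean(sample ROI) / mean(background ROI), reported in dB as
  20·log₁₀(SBR).
* Dose responses follow the Hill model
  y(c) = y₀ + (y_max − y₀)·cⁿ/(Kⁿ + cⁿ).

`gvscan` is for researchers analyzing (or prototyping analyses of)
collapse-based acquisitions and the surrounding biosensor characterization:
it simulates every input the pipeline consumes — multi-frame stacks with
frame-correlated speckle and breathing motion, stage-scan grids,
titrations, patch plates, flow-cytometry mixtures — reconstructs,
assembles masked 3-D volumes, quantifies, and fits, with every stage under
test against closed-form and Monte-Carlo oracles.

## What's inside

| Stage | Functions |
|---|---|
| Schedules & scan plans | `build_schedule()`, `plan_in_vivo_scan()`, `transmit_event_count()` |
| Synthetic scenes | `scene_truth()`, `simulate_acquisition()`, `simulate_scan()`, `place_inclusion()`, `simulate_dose_response()`, `simulate_patch_plate()`, `simulate_flow_sample()` |
| Reconstruction | `burst_invitro()`, `burst_star()`, `bmode()`, `screen_motion()`, `reconstruct_scan()` |
| Assembly | `stitch_transverse()`, `build_volume()`, `assemble_ex_vivo()`, `roi_set()` |
| Quantification | `sbr()`, `to_db()`, `normalize_display()`, `integrate_2d()`, `overlay()`, `total_signal()`, `ex_vivo_profile()` |
| Dose response | `fit_hill()` (with `tidy()`/`glance()`/`autoplot()`), `max_fold_change()`, `detection_limit()` |
| Screening | `measure_patch()`, `relative_opacity()`, `select_hits()` |
| Assays | `cfu_per_gram()`, `mutant_fraction()`, `gate_and_summarize()`, `fd_bins()`, `thiosulfate_conc()` |
| Orchestration & I/O | `run_pipeline()`, `demo_config()`, TIFF + JSON read/write |

## Worked example

Fit a simulated biosensor titration and report its maximal fold change:

```r
library(gvscan)

tab <- simulate_dose_response(y0 = 1, ymax = 50, half_max_conc = 75,
                              hill_n = 1.5, n_reps = 4, noise_cv = 0.1,
                              seed = 7)
fit <- fit_hill(tab)
fit
#> <hill_fit> y0 = 1.389, ymax = 49.12, K = 68.97 uM, n = 1.74
#>   fitted fold change ymax/y0 = 35.36; residual sd 2.15 on 32 obs

max_fold_change(tab, fit)
#> # A tibble: 1 × 3
#>   fold_change at_concentration fitted_fold_change
#>         <dbl>            <dbl>              <dbl>
#> 1        47.7              300               35.4
```

The fitted half-max constant K lands within 8% of the generating 75 µM at
this noise level; the empirical fold change (peak condition mean over the
0-dose mean, here 47.7× at 300 µM) sits above the fitted-curve ymax/y₀
because replicate noise inflates the peak mean — both variants are
reported so the difference is visible. `autoplot(fit)` draws the points
and curve.

An end-to-end in vivo scan — simulate a 3 × 10-position stage scan over a
scene with two GV inclusions, reconstruct BURST\* with motion screening,
assemble the ROI-masked volume, and quantify:

```r
man <- run_pipeline(demo_config("invivo-scan"), "demo_run")
man$results$total_signal
#> [1] 471.9248
```

`demo_run/` then holds the volume as multi-page TIFF + JSON sidecars, the
motion-screening table, a quantification JSON (total BURST\* signal,
overlay threshold, excluded-acquisition count), and a manifest with an MD5
hash of every output; re-running with the same seed reproduces the hashes
byte for byte.

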