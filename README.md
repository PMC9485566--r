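# cinscope

Population-imaging and intrinsic-property analysis for striatal
cholinergic interneurons (CINs), the tonically active neurons whose
hyperactivity is a hallmark of the dopamine-depleted (parkinsonian)
striatum. The package is for experimenters who record dozens of
identified CINs at once with a calcium indicator at slow scan rates
(6–10 frames/s), and/or characterise single CINs in whole-cell current
clamp, and want the full analysis chain — from fluorescence to
population statistics, and from sweeps to an intrinsic-property table —
as tested, seedable R functions.

## What it computes

**Spike inference.** Per ROI, ΔF/F₀ = (F − F₀)/F₀ and its time
derivative d(ΔF/F₀)/dt; a frame is active when the positive derivative
exceeds *k*·SD of the cell's baseline (default *k* = 2.5, robust
quiet-frame SD). Rows stack into a binary R × C event raster.

**Ensemble statistics.** Frame-wise coactivity c(t) = Σᵢ A[i,t]; a
Monte-Carlo significance threshold from per-cell circular-shift
surrogates (the "dashed line": the smallest count with surrogate tail
probability < α); the rate of activity accumulation (OLS slope of the
cumulative coactivity vs frame); per-neuron % active frames compared
across conditions as CDFs with Kolmogorov–Smirnov tests and Bonferroni
family correction; inter-event-interval (IISI) distributions at three
scales; rank tests (Wilcoxon, Mann–Whitney U, Kruskal–Wallis / Friedman
with Dunn's post hoc) and the df = 1 χ² for proportions.

**Ephys battery.** Input resistance R_N = dV/dI of a cubic I–V fit at
−60 mV; rheobase (minimum 1-s step current evoking one AP); sag ratio
(peak/steady deflection of a −100 pA step); phase-plot (dV/dt vs V) AP
features — threshold, amplitude, half-width, max depolarization /
repolarization rates, mAHP amplitude and half-width, rising-limb
indentation; spontaneous rate and ISI CV; I–F curves.

**Synthetic ground truth.** A seeded forward model generates gamma-renewal
and burst/pause spike trains, GCaMP6f-like traces and TIFF movies with
embedded coactive ensembles, and membrane responses with sag and
stereotyped APs — so every stage above is validated by round trip.

## Worked example

A small end-to-end synthetic study (12 cells, 2 min per condition;
the packaged defaults use 20 cells × 10 min):

```r
library(cinscope)

cfg <- demo_study_config(n_cells = 12, duration = 120, n_surrogates = 200)
rep <- run_study(cfg, seed = 7)
rep$summary
#>    condition slope_events_per_s n_sig_frames n_sig_peaks n_excess_frames
#> 1    control           23.93090           23          23           0.205
#> 2   depleted           28.92157           60          60           6.215
#> 3 antagonist           22.10374           13          13          -2.390
#>   mc_threshold mean_percent_active frac_intervals_gt_2s
#> 1            6            19.91667          0.000000000
#> 2            6            24.18056          0.023342939
#> 3            6            18.31944          0.002665651
```

Reading the table: the dopamine-depleted regime accumulates activity
faster (28.9 vs 23.9 events/s), carries more above-chance coactivity
frames (`n_excess_frames` 6.2 vs 0.2 — flagged frames beyond what the
raster's own surrogate null expects), is more active per cell (24.2 % vs
19.9 % of frames), and has heavier long-interval mass (2.3 % of IISIs
beyond 2 s: pauses between spike trains). The antagonist segment —
the same cells with drive reduced — falls back to control levels.

```r
rep$cdf_comparisons
#> <cdf_comparison_set> 3 comparison(s), Bonferroni alpha = 0.01667
#>   control vs depleted        D = 0.833, p = 0.00013  (n = 12, 12) *
#>   control vs antagonist      D = 1.000, p = 7.4e-07  (n = 12, 12) *
#>   depleted vs antagonist     D = 0.833, p = 0.000156 (n = 12, 12) *
rep$paired_test
#> <test_report> Wilcoxon signed rank: statistic = 69, p = 0.02061 (n = 12, 12)
```

Single-cell ephys, from the same session:

```r
base <- membrane_scenario(R_m = 300, tau_m = 25, E_L = -60, V_th = 0)
s <- sag_fraction_for_ratio(1.053, base)   # -> 0.1321
ms <- membrane_scenario(R_m = 300, tau_m = 25, E_L = -60, V_th = 0,
                        sag_fraction = s)
sag_ratio(simulate_current_step(ms, -100, fs = 10000))
#> [1] 1.053

ap_features(make_ap_waveform(ap_shape_params()))
#> <ap_feature_set> threshold -41.0 mV, amplitude 56.0 mV, half-width 4.97 ms,
#>   dV/dt max 40.0 / -12.0 mV/ms, mAHP 8.0 mV / 131 ms, indented = FALSE
```

Real data enter through `fluor_traces()` / `read_traces()` (cells ×
frames CSV), `extract_roi_traces()` (multi-page TIFF + ROI table), and
`sweep_recording()` / `read_sweep()` (time/voltage/current CSV).

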