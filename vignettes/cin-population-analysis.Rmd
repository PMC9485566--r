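---
title: "Methods: population calcium-imaging and intrinsic-property analysis of striatal cholinergic interneurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population calcium-imaging and intrinsic-property analysis of striatal cholinergic interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinscope)
```

## Scope and model

`cinscope` analyses two kinds of recordings from striatal cholinergic
interneurons (CINs) and their neighbours:

* **population calcium imaging** at slow scan rates (6–10 frames/s) with a
  fast genetically encoded indicator (GCaMP6f-like kinetics), from which
  electrical activity is *inferred* per cell and per frame; and
* **whole-cell current clamp**, from which the intrinsic-property battery
  (input resistance, rheobase, sag, action-potential shape, AHP, firing
  statistics) is extracted.

Because CIN population recordings of this kind are not publicly deposited,
the package ships a seeded forward model (`make_spike_train()`,
`imaging_scenario()`, `render_fluorescence()`, `render_movie()`,
`membrane_scenario()`, `simulate_current_step()`, `make_ap_waveform()`)
that generates data with known ground truth under labelled condition
regimes — a "control" regime (tonic, largely independent cells) and a
"dopamine-depleted" regime (faster burst/pause firing with embedded
coactive ensembles). Every analysis stage is validated by round trip
against that ground truth.

## Spike inference from fluorescence

For each ROI, the calcium transient is `dFF = (F - F0)/F0` and the
activity indicator is the positive part of its time derivative,
`d(dFF)/dt`, computed as a first-order forward difference times the frame
rate. A frame is called active when the derivative exceeds
`k_sd` (default 2.5) baseline standard deviations for that cell, and runs
of consecutive suprathreshold frames are collapsed to their first frame so
that one calcium transient contributes one event (`collapse = FALSE`
reproduces per-frame rasters). Stacking the binary rows gives the R × C
event raster (`event_raster`).

**Two F0 conventions** are exposed because "background" fluorescence can
mean either the annulus around the ROI or the quiescent level of the ROI
itself: `f0_mode = "background"` uses the per-cell background recorded
with the traces (the annulus mean that `extract_roi_traces()` computes),
and `f0_mode = "rolling"` uses a running 20th percentile of the trace over
30 s. Maximum-normalisation of transient amplitudes is available as a
flag; it does not affect event inference, which is scale-free in the SD
units of each cell.

**Baseline SD estimator.** The threshold refers to the *baseline* signal,
i.e. the derivative's behaviour when the cell is quiet. A robust SD taken
over the full derivative trace (1.4826·MAD) is adequate for sparse
recordings, but it fails exactly where the dopamine-depleted regime lives:
at 4 Hz mean firing and 10 frames/s, roughly 40 % of derivative samples
carry transient signal, the full-trace MAD rises to the signal scale, and
the 2.5-SD threshold climbs above every true rise. The default estimator
(`baseline_estimator = "quiet_mad"`) therefore restricts the MAD to quiet
frames: frames whose *previous* dFF sample lies below the cell's 25th
percentile. Dense firing keeps dFF elevated, so the low-dFF stretches are
the inter-event baseline; conditioning on the previous frame (rather than
the frame itself) keeps the selection independent of the derivative sample
when the trace is pure i.i.d. noise, so the estimator remains unbiased in
the no-signal limit — the false-event rate at `k_sd = 2.5` on pure
Gaussian derivatives stays at the normal tail mass (≈ 0.62 % of frames),
which the test suite checks to within three binomial standard errors.
`"mad"` (full trace) and `"sd"` are retained as options.

**Forward-model alignment.** Each spike adds a peak-normalised
difference-of-exponentials transient (defaults: rise 0.05 s, decay 0.5 s,
amplitude 0.2 dFF — representative fast-indicator values, configurable).
Transient onsets are aligned to the start of the spike's frame. With
continuous onsets, the kernel rise is split between two frame samples in a
phase-dependent way and the frame receiving the detectable derivative jump
becomes ambiguous; alignment resolves the ambiguity within the one-frame
temporal precision that 6–10 fps imaging has anyway, and makes the
forward → inverse round trip exact: on noiseless traces whose inter-spike
intervals span at least two frames, `infer_events()` reproduces the
ground-truth raster with Jaccard index 1.

**Resolvability.** Two frames is also the practical ISI floor: firing
faster than fps/2 fuses transients, and the fused event is counted once.
This is a property of the instrument model, not of the detector, and it is
why the packaged depleted regime keeps its within-burst rate at 5 Hz at
10 fps (see below).

## Ensemble statistics and the Monte-Carlo null

`coactivity()` sums the raster column-wise: cells coactive per frame.
Significance of coactivity peaks is assessed against surrogate rasters in
which each cell's row is independently circularly shifted by a uniform
random offset (`mc_threshold()`, default 1000 surrogates). Circular
shifting preserves each cell's event count and its within-cell interval
structure, destroying only cross-cell alignment, which is the quantity
under test; a per-cell permutation shuffle is available as an alternative
null that additionally destroys interval structure. The pooled surrogate
frame-coactivity distribution yields the dashed-line threshold: the
smallest count whose surrogate tail probability is below `alpha`
(default 0.05). On a 2-cell × 4-frame raster with one event per cell the
surrogate distribution matches exhaustive enumeration of all 16 shift
pairs (coincidence probability 1/4), which the tests verify.

Because coactivity counts are discrete, the realised tail probability at
the threshold can land anywhere below `alpha`, so the raw number of
flagged frames mixes chance level with genuine ensemble load. The profile
therefore also reports `expected_chance_frames` (flagged frames expected
under the raster's own null) and `n_excess_frames` (observed − chance),
and the study signature uses the excess. Adjacent significant frames are
additionally deduplicated into `n_sig_peaks`, since whether a "peak" is a
frame or a run of frames is a reporting convention; both counts are kept.

The **rate of activity accumulation** is the slope of an ordinary
least-squares line fitted to the running sum of coactivity against the
frame index (reported per frame and per second). For a raster with
constant per-frame counts the cumulative curve is exactly linear and the
slope equals the per-frame count exactly; for stationary rasters the OLS
slope coincides with the chord `(cum[C] − cum[1])/(C − 1)` of the
cumulative curve. An optional window restricts the fit to a condition
segment (drug wash-in designs).

Per-neuron activity is `percent_active()` (active frames / total × 100);
conditions are compared by pooling all neurons per condition and running
two-sample Kolmogorov–Smirnov tests per planned comparison with a
Bonferroni-adjusted family alpha (`activity_cdf()`). Inter-event
intervals (`iisi_extract()`) are binned at three scales (< 1 s, 1–60 s,
60–120 s) because the distribution is heavily skewed; the pooled empirical
CDF covers all intervals. Group comparisons dispatch the
distribution-free test matching the design (`group_compare()`): Wilcoxon
signed rank for paired, Mann–Whitney U for unpaired, Kruskal–Wallis or
Friedman for several samples with Dunn's Bonferroni-adjusted post hoc;
proportions use the df = 1 chi-square (`proportion_compare()`). Identical
paired samples (all differences zero) are reported with p = 1 rather than
as an error.

## Membrane model and waveform synthesis

The membrane simulator is a leaky integrator (R_m, tau_m, E_L) with exact
per-sample exponential updates. An HCN-like sag is modelled as a gate `z`
that relaxes with `sag_tau` while a hyperpolarizing step is on and scales
the drive by `1 − sag_fraction·z`; the closed-form response of this linear
system is exposed as `step_response()` and the integrator matches it to
better than 0.1 mV at 10 kHz. `sag_fraction_for_ratio()` inverts the
closed form to find the sag fraction producing a target peak/steady ratio.

Action potentials are *spliced*, not conductance-modelled: the analyses
need waveform shape, and a constructive synthesis makes every shape
parameter recoverable by design. The rising limb follows a shaped
velocity profile whose maximum equals `max_depol_rate`; an indented limb
passes a pre-peak local maximum and a local minimum whose drop equals
`notch_depth × max_depol_rate` exactly (half-cosine segments, so the
profile is C¹). Repolarization is a raised-cosine descent to the mAHP
trough with peak rate `max_repol_rate`; the requested half-width above the
floor implied by the two rates is realised as dwell time at the peak
(`min_half_width()` reports the floor and infeasible requests are
errors); the mAHP recovers exponentially with the time constant tuned so
the half-amplitude crossings span `mahp_half_width`. A 50-draw random
round trip (`sample_ap_shapes()` → `make_ap_waveform()` →
`ap_features()`) recovers every feature within 5 % and the indentation
flag exactly; in practice the errors are below 2 %.

Feature conventions, where the underlying definitions are loose:

* **AP threshold** — the rising-limb voltage where dV/dt first reaches 4 %
  of that spike's maximal dV/dt (standard phase-plot convention); a fixed
  10 mV/ms crossing is the spike-*detection* criterion (`detect_spikes()`).
* **dV/dt** — centred differences on the raw trace, reported in mV/ms.
* **I–V steady state** — mean over the last 100 ms of the 1-s step; the
  sag "beginning" window is the first 200 ms of the step, which contains
  the deflection peak for membrane time constants up to ~35 ms.
* **R_N** — derivative of the fitted cubic V(I) at the potential of
  evaluation (default −60 mV), in MΩ, not a two-point chord.
* **mAHP search window** — 500 ms after the peak or until the trace ends.
* **Rheobase** — smallest amplitude on the tested grid (default 5 pA
  steps) evoking ≥ 1 spike in 1 s. Note that at the analytic
  leaky-integrator minimum the threshold is approached only
  asymptotically, so the grid search reports the next step above it;
  agreement with the analytic value is therefore "within one grid step".

## The packaged study and what it does (not) show

`demo_study_config()` fixes the synthetic study conditions:

* **control** — 20 cells, tonic 2 Hz (ISI CV 0.2), no ensembles;
* **depleted** — burst/pause firing at 4 Hz mean with embedded 10-cell
  ensemble events every 5 s. The within-burst rate is 5 Hz — the 2-frame
  ISI resolvability limit at 10 fps — with mean burst 4 s and pause 1 s to
  preserve the 4 Hz mean: faster within-burst firing fuses into single
  transients at these scan rates and the raster, correctly, stops
  reflecting it;
* **antagonist** — the same cells after glutamatergic-blockade-style
  reduction of drive: irregular ~2.2 Hz, no ensembles;

with 10 min per segment, 10 fps, dFF noise SD 0.01, `k_sd` 2.5, 1000
surrogates at alpha 0.05. `run_study()` derives every random draw from one
master seed and is bit-reproducible. Across seeds the depleted segment
shows a higher accumulation slope, a right-shifted activity CDF
(KS p < 0.01), more above-chance coactivity frames, and heavier
long-interval mass (pauses), and the antagonist segment restores the slope
toward control — the test suite requires this signature in at least 9 of
10 seeds.

The generator emulates: renewal and two-state burst/pause spiking,
double-exponential indicator kernels with additive Gaussian noise and
optional slow drift, forced coactive events, disk-soma movies, and
first-order membranes with sag and stereotyped spikes. It does **not**
emulate indicator saturation or bleaching, motion artifacts, neuropil
contamination, conductance-based burst generation, or spike-height
adaptation — so green tests certify the *analysis machinery* under the
stated forward model, not performance on arbitrary real recordings.
Parameters a user should expect to revisit on real data: the kernel time
constants (indicator- and temperature-dependent), `quiet_quantile` (should
exceed the fraction of time the densest cell spends firing), `k_sd`, and
the viability segment.

## Numerical and degenerate-input conventions

Frames are 1-based internally and exported tables carry explicit
frame-time columns. The derivative's final frame is set to zero (no
forward difference exists). Zero-variance cells are marked inactive with a
warning rather than an error; rasters with no events yield an empty
coactivity profile with an undefined threshold. Cells with fewer than two
events contribute no intervals. Half-width and crossing times are linearly
interpolated between samples. All randomness flows through per-scenario
seeds; sub-seeds are derived arithmetically and stay below 2^31.
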