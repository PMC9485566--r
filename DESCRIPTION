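Package: cinscope
Title: Population Calcium-Imaging and Intrinsic-Property Analysis for
    Striatal Cholinergic Interneurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse population activity of striatal cholinergic
    interneurons (CINs) recorded with calcium imaging, and their intrinsic
    electrophysiological properties recorded in current clamp.  Spike
    occurrence is inferred from the positive time derivative of dF/F0
    thresholded at a multiple of the baseline standard deviation; binary
    rasters are summarised by frame-wise coactivity with a Monte-Carlo
    surrogate significance threshold, the rate of activity accumulation,
    and cumulative distributions of per-cell activity and inter-event
    intervals.  A current-clamp feature battery extracts input resistance
    from cubic I-V fits, rheobase, sag ratio, phase-plot action-potential
    features (including rising-limb indentation), afterhyperpolarization
    metrics, and firing statistics.  A seeded forward model generates
    ground-truth spike trains, GCaMP6f-like fluorescence traces and movies,
    and membrane responses to current steps, emulating control and
    dopamine-depleted firing regimes so that every analysis stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
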