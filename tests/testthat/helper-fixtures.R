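# Shared fixtures, built in code.

# Population scenario whose trains respect the 2-frame ISI floor at
# 10 fps (tonic, cv = 0), with a margin before the recording end so no
# transient is clipped.
clean_scenario <- function(n_cells = 10, rate = 2.5, duration = 100,
                           fps = 10, noise_sd = 0, seed = 1) {
  trains <- lapply(seq_len(n_cells), function(i)
    make_spike_train("tonic", rate = rate, cv = 0, duration = duration - 2,
                     seed = seed * 100 + i))
  imaging_scenario(n_cells, duration = duration, fps = fps, trains = trains,
                   noise_sd = noise_sd, seed = seed)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Analytic LIF rheobase (pA) for a 1-s step: the asymptotic minimum
# current; a finite-time grid search returns the next step above.
lif_rheobase <- function(R_m, tau_m, dV, T = 1) {
  dV * 1000 / (R_m * (1 - exp(-T * 1000 / tau_m)))
}
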