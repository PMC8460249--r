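# Shared fixture builders; everything is generated in code.

quiet_acq <- function(...) acquisition_params(noise_sigma = 0, ...)

# A small noise-free spiking neuron: every stage downstream is exact.
noisefree_type1 <- function(seed = 1L, n_gl = 9L) {
  generate_recording(neuron_spec("TYPE_I", n_gl, seed = seed,
                                 noise_sigma = 0))
}

# Grand mean of per-neuron mean Spearman r over a simulated roster.
roster_grand_mean <- function(cell_type, n, seed_start = 1L, ...) {
  recs <- simulate_roster(cell_type, n, seed_start = seed_start, ...)
  vapply(recs, function(r) analyze_neuron(r)$summary$mean_r, 0)
}

# Linear weights of response_auc on a given time grid: applying the
# operation to unit impulses exposes the quadrature weights, so noise can
# be propagated through the AUC analytically in tests.
auc_weights <- function(tx, onset, window = 3) {
  vapply(seq_along(tx), function(i) {
    e <- numeric(length(tx)); e[i] <- 1
    response_auc(e, tx, onset, window)
  }, 0)
}
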