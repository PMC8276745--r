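# shared fixture builders; everything is generated in code at test time

tiny_ts <- function(n = 64, r = 3, tr = 2, runs = 0L, seed = 1) {
  with_seed(seed, roi_ts(matrix(rnorm(n * r), n, r), tr_s = tr,
                         run_starts = runs,
                         roi_labels = paste0("roi", seq_len(r))))
}

# phase matrix built directly (bypasses filtering) so window-level
# synchrony identities can be tested against closed forms
phase_matrix_from <- function(phases, tr = 2, run_starts = 0L,
                              labels = paste0("roi", seq_len(ncol(phases)))) {
  structure(list(phases = phases, tr_s = tr, run_starts = run_starts,
                 band = c(0.01, 0.5), roi_labels = labels),
            class = "phase_matrix")
}

# one-clique spec with a sustained global coupling level (for monotonicity
# and extremes)
const_coupling <- function(kappa, noise = 0, ...) {
  coupling_spec(baseline_coupling = kappa, noise_sd = noise, ...)
}

small_confounds <- function(events, cfg, seed = 1, ...) {
  generate_confounds(events, cfg, seed, ...)
}

with_seed <- socialsync:::with_seed
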