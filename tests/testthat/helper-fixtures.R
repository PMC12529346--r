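# Small in-code fixtures shared across test files.

# compact parcel table: 70 cortical parcels over 7 networks + 10 subcortical
tiny_parcel_table <- function() build_parcel_table(70, 10)

tiny_patterns <- function(seed = 3) make_state_patterns(6, tiny_parcel_table(), seed = seed)

# a z-scored multi-run session simulated from the HC chain
tiny_session <- function(seed = 5, frames = 60, noise = 1, n_runs = 2) {
  sim <- simulate_session(tiny_patterns(), default_group_markov()$HC,
                          frames_per_run = frames, n_runs = n_runs,
                          noise_sigma = noise, seed = seed)
  sim$ts_z <- zscore_session(sim$ts)
  sim
}

# deterministic state_seq builder
sseq <- function(labels, boundaries = 1L, K = max(labels)) {
  state_seq(labels, run_boundaries = boundaries, K = K)
}

# split a state_seq's labels into per-run chunks (independent re-derivation)
run_index_list2 <- function(s) {
  starts <- s$run_boundaries
  ends <- c(starts[-1] - 1L, length(s$labels))
  Map(function(a, b) s$labels[a:b], starts, ends)
}

# brute-force correlation-distance k-means objective of a labelling:
# sum over frames of 1 - cor(frame, mean of its cluster's frames)
partition_objective <- function(X, labels) {
  sum(vapply(seq_len(nrow(X)), function(i) {
    cen <- colMeans(X[labels == labels[i], , drop = FALSE])
    1 - stats::cor(X[i, ], cen)
  }, 0))
}
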