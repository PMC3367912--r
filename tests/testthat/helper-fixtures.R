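# Shared fixtures, built once per test run.

fixture_env <- new.env()

fixture_mesh <- function(n = 64, seed = 1) {
  key <- sprintf("mesh_%d_%d", n, seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- build_toy_cortex(n, seed = seed)
  fixture_env[[key]]
}

fixture_gain <- function(n = 64, seed = 1, n_sensors = 24) {
  key <- sprintf("gain_%d_%d_%d", n, seed, n_sensors)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- compute_gain(fixture_mesh(n, seed), n_sensors, seed = seed + 1)
  fixture_env[[key]]
}

# A short session for generator-level checks: one block cycle (180 s),
# 32-vertex hemispheres, 16 sensors.
fixture_session <- function(seed = 3, truth = default_truth(), n_cycles = 1) {
  key <- sprintf("session_%d_%s_%d", seed, digest_truth(truth), n_cycles)
  if (is.null(fixture_env[[key]])) {
    mesh <- fixture_mesh(32, 1)
    gain <- compute_gain(mesh, 16, seed = 2)
    sched <- make_event_schedule(default_paradigm(n_cycles))
    fixture_env[[key]] <- generate_session(mesh, gain, sched, truth,
                                           seed = seed, return_sources = TRUE)
  }
  fixture_env[[key]]
}

digest_truth <- function(truth) {
  paste0(truth$power_ratio, "_", truth$alpha_snr, "_",
         length(truth$artifact_epochs %||% integer(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Epochs built directly from an array (bypassing a full session) for
# spectral unit tests.
epochs_from_array <- function(dat, window, fs, condition = NULL) {
  structure(list(data = dat, window = window, condition = condition,
                 onsets = numeric(dim(dat)[1]),
                 event_index = seq_len(dim(dat)[1]), fs = fs,
                 kept = seq_len(dim(dat)[1]), rejected = integer(0)),
            class = "epoch_set")
}
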