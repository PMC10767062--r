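# Small decoding sets shared across tests: n epochs of `dur` seconds at 64 Hz,
# `n_ch` channels driven by one fixed kernel bank, each epoch its own envelope.
tiny_epochs <- function(n, snr, seed, n_ch = 4, dur = 6, fs = 64) {
  kernels <- simulate_kernels(n_ch, fs, seed = seed + 500L)
  tibble::tibble(
    epoch = seq_len(n),
    envelope = lapply(seq_len(n), function(i) {
      simulate_envelope(dur, fs, seed = seed + i)
    })
  ) |>
    dplyr::mutate(eeg = lapply(seq_len(n), function(i) {
      simulate_eeg(envelope[[i]], kernels, snr, fs, seed = seed + 1000L + i)
    }))
}

# Balanced two-level toy records (2 subjects x 2 stimuli x 2 presentations).
toy_records <- function(fam_answers, mw_bins) {
  grid <- tidyr::expand_grid(subject_id = 1:2, stimulus_id = 1:2,
                             presentation = 1:2)
  grid$familiarity_answer <- fam_answers
  grid$mw_answer_bin <- mw_bins
  grid$accuracy <- 0
  grid
}
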