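# Small builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except what the tests themselves write.

# a reduced-scale simulation spec: 16 channels (the 12 posterior ones plus
# 4 fillers), no roster exclusions, no artifacts unless asked for
small_spec <- function(n_mainstream = 5, n_populist = 5, seed = 1L, ...) {
  simulation_spec(n_mainstream = n_mainstream, n_populist = n_populist,
                  n_other_party = 0, n_nonvoter = 0, n_blank = 0,
                  n_low_trials = 0, n_behavior_missing = 0,
                  n_channels = 16, artifact_rate = 0, seed = seed, ...)
}

# a null spec: every injected effect and group difference switched off
null_spec <- function(n_mainstream = 5, n_populist = 5, seed = 1L, ...) {
  small_spec(n_mainstream = n_mainstream, n_populist = n_populist,
             seed = seed,
             effect_amplitude_n400 = 0, effect_amplitude_late = 0,
             subject_sd = 0, attitude_sep = 0, ...)
}

# deterministic toy epoch array from a data vector or function
toy_epochs <- function(n_channels = 2, n_times = 64, n_trials = 3,
                       sfreq = 256, fill = stats::rnorm,
                       participant_id = "p1") {
  dat <- array(fill(n_channels * n_times * n_trials),
               c(n_channels, n_times, n_trials))
  times <- -100 + (seq_len(n_times) - 1L) * 1000 / sfreq
  channels <- if (n_channels <= 12) posterior_channels()[seq_len(n_channels)]
  else default_montage(n_channels)$channel
  epoch_array(dat, times, channels, sfreq, participant_id)
}

toy_trials <- function(n, participant_id = "p1",
                       dimension = "economy",
                       item_type = rep(item_types(), length.out = n)) {
  data.frame(participant_id = rep(participant_id, length.out = n),
             trial_index = seq_len(n),
             dimension = rep(dimension, length.out = n),
             item_type = item_type,
             agreement = rep("agree", n), rt = rep(800, n),
             artifact = rep(FALSE, n), stringsAsFactors = FALSE)
}

# decoding timecourses drawn directly from a null accuracy model: real and
# chance are exchangeable draws around 0.5 (used to exercise the cluster
# statistics without running classifiers)
null_timecourses <- function(n_subj, n_windows, acc_sd = 0.05,
                             dimension = "economy") {
  do.call(rbind, lapply(seq_len(n_subj), function(i) {
    data.frame(participant_id = sprintf("s%02d", i), dimension = dimension,
               window_start = (seq_len(n_windows) - 1L) * 10,
               window_stop = seq_len(n_windows) * 10,
               real_accuracy = stats::rnorm(n_windows, 0.5, acc_sd),
               chance_accuracy = stats::rnorm(n_windows, 0.5, acc_sd),
               stringsAsFactors = FALSE)
  }))
}
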