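#' Simulation specification
#'
#' Parameters of the synthetic-data generator. The generator emulates the
#' structure the analysis chain assumes: 61-channel epochs from -100 to
#' 1200 ms around a critical word; 126 survey items (3 issue dimensions x
#' 2 item types x 21 items); a group-dependent congruency effect in the
#' N400 window for economy items and a late effect for culture items;
#' polarized agreement for economy/culture but not anti-establishment; and
#' IAT latencies whose compatibility shift is independent of voting group.
#'
#' @param n_mainstream,n_populist Final-sample voter counts per group.
#' @param n_other_party,n_nonvoter,n_blank Roster members later excluded by
#'   the vote filter.
#' @param n_channels Number of EEG channels (>= 13; the first 12 are the
#'   posterior analysis set).
#' @param sfreq Sampling rate in Hz.
#' @param trials_per_cell Survey items per dimension x item-type cell.
#' @param effect_amplitude_n400 Congruency effect injected for economy items
#'   on incongruent trials, expressed as the window-mean amplitude at POz
#'   over `effect_window_n400` (microvolts; negative = N400-like).
#' @param effect_window_n400 Window (ms) of the economy effect; a Gaussian
#'   temporal kernel is centered on its midpoint with SD a quarter of the
#'   window width and normalized to unit window mean.
#' @param effect_amplitude_late Late effect for culture items on
#'   incongruent trials (window-mean microvolts at POz over
#'   `effect_window_late`).
#' @param effect_window_late Window (ms) of the late culture effect.
#' @param noise_sd Total single-trial background SD per sample (microvolts);
#'   split evenly in variance between 1/f-shaped and white components.
#' @param subject_sd SD (microvolts) of the per-participant random effect on
#'   both effect amplitudes.
#' @param attitude_sep Separation of the latent populism score between voter
#'   groups for economy and culture items (logit units; the groups sit at
#'   +/- `attitude_sep / 2`). Anti-establishment uses a common shift.
#' @param attitude_sd SD of the per-participant latent populism score.
#' @param anti_shift Common latent shift for anti-establishment items.
#' @param artifact_rate Probability that a trial carries an injected
#'   high-amplitude artifact.
#' @param n_low_trials Participants (alternating groups) given only
#'   `low_trial_count` artifact-free epochs in one economy cell, so they
#'   fail both the ERP and the decoding trial-count rules.
#' @param low_trial_count Artifact-free epochs left in the degraded cell.
#' @param n_behavior_missing Participants whose agreement responses are all
#'   recorded as missing.
#' @param rt_meanlog,rt_sdlog Log-normal response-time parameters (ms),
#'   identical across groups.
#' @param iat_block_trials Trials per IAT block 1-7.
#' @param iat_floor_ms Construction floor of IAT latencies (ms).
#' @param iat_meanlog,iat_sdlog Log-normal parameters of the latency above
#'   the floor.
#' @param iat_shift_meanlog,iat_shift_sdlog Per-participant compatibility
#'   shift applied on the log-latency scale to blocks 6 and 7; drawn
#'   independently of voting group.
#' @param seed Integer seed for the generator.
#'
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_mainstream = 40,
                            n_populist = 29,
                            n_other_party = 9,
                            n_nonvoter = 3,
                            n_blank = 1,
                            n_channels = 61,
                            sfreq = 256,
                            trials_per_cell = 21,
                            effect_amplitude_n400 = -2.0,
                            effect_window_n400 = c(300, 600),
                            effect_amplitude_late = -2.0,
                            effect_window_late = c(1080, 1200),
                            noise_sd = 4,
                            subject_sd = 3,
                            attitude_sep = 1.0,
                            attitude_sd = 0.55,
                            anti_shift = 0.5,
                            artifact_rate = 0.04,
                            n_low_trials = 2,
                            low_trial_count = 13,
                            n_behavior_missing = 2,
                            rt_meanlog = log(1150),
                            rt_sdlog = 0.45,
                            iat_block_trials = c(20, 20, 20, 40, 40, 20, 40),
                            iat_floor_ms = 300,
                            iat_meanlog = log(350),
                            iat_sdlog = 0.4,
                            iat_shift_meanlog = 0.12,
                            iat_shift_sdlog = 0.22,
                            seed = 1L) {
  spec <- as.list(environment())
  if (spec$sfreq <= 0) stop("parameter error: sfreq must be positive")
  if (spec$noise_sd < 0 || spec$subject_sd < 0)
    stop("parameter error: noise SDs must be non-negative")
  if (spec$n_mainstream < 1 || spec$n_populist < 1)
    stop("parameter error: group counts must be >= 1")
  if (spec$n_channels < 13)
    stop("parameter error: n_channels must be >= 13 (12 posterior + rest)")
  if (length(spec$iat_block_trials) != 7L)
    stop("parameter error: iat_block_trials must have 7 entries")
  class(spec) <- "simulation_spec"
  spec
}

#' Synthetic montage
#'
#' Channel labels and flat 2-d scalp coordinates. The first 12 channels are
#' the posterior analysis set (resolvable by their 10-10-like names); the
#' remaining channels get systematic labels (`E13`, `E14`, ...) spread over
#' the rest of the scalp.
#'
#' @param n_channels Total number of channels (>= 13).
#' @return A data.frame with columns `channel`, `x`, `y`.
#' @export
default_montage <- function(n_channels) {
  post <- data.frame(
    channel = posterior_channels(),
    x = c(-0.15, 0.15, -0.35, 0.35, -0.15, 0.15, -0.35, 0.35,
          0, -0.25, 0.25, 0),
    y = c(-0.35, -0.35, -0.35, -0.35, -0.55, -0.55, -0.55, -0.55,
          -0.55, -0.75, -0.75, -0.75))
  n_extra <- n_channels - nrow(post)
  if (n_extra < 1) stop("n_channels must exceed the 12 posterior channels")
  # lay the remaining channels on a regular grid over the central/anterior
  # scalp (y in [-0.15, 0.85])
  ncol_grid <- ceiling(sqrt(n_extra))
  nrow_grid <- ceiling(n_extra / ncol_grid)
  gx <- seq(-0.6, 0.6, length.out = ncol_grid)
  gy <- seq(-0.15, 0.85, length.out = nrow_grid)
  grid <- expand.grid(x = gx, y = gy)[seq_len(n_extra), ]
  extra <- data.frame(
    channel = sprintf("E%02d", 12L + seq_len(n_extra)),
    x = grid$x, y = grid$y)
  rbind(post, extra)
}

# Gaussian spatial profile peaking at POz; the default SD (0.5 in montage
# units) gives the broad posterior topography typical of N400 effects
spatial_profile <- function(montage, sd = 0.5) {
  poz <- montage[montage$channel == "POz", ]
  exp(-((montage$x - poz$x)^2 + (montage$y - poz$y)^2) / (2 * sd^2))
}

#' Simulate the participant roster
#'
#' Voter groups, demographics and latent attitude scores. Demographics
#' follow the study population: mainstream voters skew younger and more
#' often female; left-right self-placement is higher for populist voters.
#'
#' @param spec A [simulation_spec()].
#' @return A participant table with extra latent columns
#'   `latent_attitude` (per-participant populism score) and
#'   `leaning` (+1 populist-leaning, -1 mainstream-leaning; drives EEG
#'   congruency for participants excluded by the vote filter).
#' @export
simulate_participants <- function(spec) {
  votes <- c(rep("mainstream", spec$n_mainstream),
             rep("populist", spec$n_populist),
             rep("other_party", spec$n_other_party),
             rep("nonvoter", spec$n_nonvoter),
             rep("blank", spec$n_blank))
  n <- length(votes)
  ids <- sprintf("P%03d", seq_len(n))
  leaning <- ifelse(votes == "populist", 1L, -1L)
  undecided <- votes %in% c("other_party", "nonvoter", "blank")
  leaning[undecided] <- sample(c(-1L, 1L), sum(undecided), replace = TRUE)
  age_mean <- ifelse(votes == "populist", 25, 23)
  age_sd <- ifelse(votes == "populist", 6, 4)
  age <- pmin(pmax(round(stats::rnorm(n, age_mean, age_sd)), 18), 55)
  p_female <- ifelse(votes == "populist", 11 / 28, 26 / 41)
  gender <- ifelse(stats::runif(n) < p_female, "female", "male")
  lr_mean <- ifelse(leaning > 0, 6.2, 4.3)
  left_right <- pmin(pmax(round(stats::rnorm(n, lr_mean, 1.8)), 1), 10)
  interest <- sample(1:5, n, replace = TRUE, prob = c(1, 2, 3, 3, 2))
  latent <- stats::rnorm(n, 0, spec$attitude_sd)
  validate_participants(data.frame(
    participant_id = ids, vote = votes, age = age, gender = gender,
    left_right = left_right, interest_politics = interest,
    latent_attitude = latent, leaning = leaning,
    stringsAsFactors = FALSE))
}

# Design + behavioral trial table for one participant. Artifact flags are
# ground truth here; simulate_eeg() injects matching voltage artifacts so
# reject_artifacts() re-derives them from the data.
simulate_participant_trials <- function(spec, participant, behavior_missing = FALSE,
                                        low_trial_cell = NULL) {
  design <- expand.grid(item = seq_len(spec$trials_per_cell),
                        item_type = item_types(),
                        dimension = issue_dimensions(),
                        stringsAsFactors = FALSE)
  n <- nrow(design)
  design <- design[sample.int(n), c("dimension", "item_type")]
  shift <- ifelse(design$dimension == "anti_establishment", spec$anti_shift,
                  participant$leaning * spec$attitude_sep / 2)
  z <- participant$latent_attitude + shift
  p_agree <- stats::plogis(ifelse(design$item_type == "populist", z, -z))
  agreement <- ifelse(stats::runif(n) < p_agree, "agree", "disagree")
  if (behavior_missing) agreement <- rep("missing", n)
  rt <- stats::rlnorm(n, spec$rt_meanlog, spec$rt_sdlog)
  # background artifacts are scattered at most one per condition cell
  # (emulating the rare, isolated epochs that survive ICA-style cleaning),
  # so trial-count rules bite only for deliberately degraded participants;
  # the expected artifact count per cell is trials_per_cell * artifact_rate
  artifact <- rep(FALSE, n)
  p_cell <- min(1, spec$trials_per_cell * spec$artifact_rate)
  for (dm in issue_dimensions()) {
    for (it in item_types()) {
      if (stats::runif(1) < p_cell) {
        cell <- which(design$dimension == dm & design$item_type == it)
        artifact[sample(cell, 1L)] <- TRUE
      }
    }
  }
  if (!is.null(low_trial_cell)) {
    in_cell <- design$dimension == low_trial_cell[1L] &
      design$item_type == low_trial_cell[2L]
    clean <- which(in_cell & !artifact)
    excess <- length(clean) - spec$low_trial_count
    if (excess > 0)
      artifact[sample(clean, excess)] <- TRUE
  }
  validate_trials(data.frame(
    participant_id = participant$participant_id,
    trial_index = seq_len(n),
    dimension = design$dimension, item_type = design$item_type,
    agreement = agreement, rt = round(rt), artifact = artifact,
    stringsAsFactors = FALSE))
}

# Background noise: equal-variance mix of 1/f-shaped and white components,
# generated as one spectrally shaped Gaussian field (columns independent).
# The filter gain is normalized analytically so each sample has unit SD in
# expectation.
background_noise <- function(n, m) {
  w <- matrix(stats::rnorm(n * m), n, m)
  k <- seq_len(n) - 1L
  p2 <- c(0, 1 / pmin(k[-1L], n - k[-1L]))      # 1/f power shape
  p2 <- p2 / mean(p2)
  gain <- sqrt(0.5 * p2 + 0.5)
  x <- Re(stats::mvfft(stats::mvfft(w) * gain, inverse = TRUE)) / n
  x
}

#' Simulate one participant's epoched EEG
#'
#' Per trial, voltage = 1/f background + white sensor noise + (a
#' posteriorly weighted congruency effect if the trial's item type
#' contradicts the participant's leaning and its dimension carries an
#' effect). Congruent means populist items for populist-leaning and
#' non-populist items for mainstream-leaning participants. Trials flagged
#' as artifacts in the trial table additionally receive a high-amplitude
#' in-band voltage transient.
#'
#' @param spec A [simulation_spec()].
#' @param participant One row of [simulate_participants()].
#' @param trials Trial table from the behavioral generator (ground-truth
#'   artifact flags included).
#' @return An [epoch_array()].
#' @export
simulate_eeg <- function(spec, participant, trials) {
  dt <- 1000 / spec$sfreq
  n_times <- floor(1300 * spec$sfreq / 1000) + 1L
  times <- -100 + dt * (seq_len(n_times) - 1L)
  montage <- default_montage(spec$n_channels)
  nch <- nrow(montage)
  ntr <- nrow(trials)
  x <- background_noise(n_times, nch * ntr) * spec$noise_sd
  # layout: times x (channels x trials) -> channels x times x trials
  dat <- aperm(array(x, c(n_times, nch, ntr)), c(2L, 1L, 3L))

  w <- spatial_profile(montage)
  amp_n400 <- spec$effect_amplitude_n400 +
    stats::rnorm(1L, 0, spec$subject_sd)
  amp_late <- spec$effect_amplitude_late +
    stats::rnorm(1L, 0, spec$subject_sd)
  # Gaussian kernels centered on their effect window, SD a quarter of the
  # window width, normalized so the kernel's mean over the window is 1:
  # the amplitude parameter therefore equals the injected window-mean
  # effect at POz, the quantity the ERP analysis extracts
  window_kernel <- function(window) {
    center <- mean(window)
    sdt <- diff(range(window)) / 4
    k <- exp(-(times - center)^2 / (2 * sdt^2))
    inside <- times >= window[1L] & times < window[2L]
    k / mean(k[inside])
  }
  kern_n400 <- window_kernel(spec$effect_window_n400)
  kern_late <- window_kernel(spec$effect_window_late)
  incongruent <- (participant$leaning < 0 & trials$item_type == "populist") |
    (participant$leaning > 0 & trials$item_type == "non_populist")
  for (tr in which(incongruent)) {
    kern <- switch(trials$dimension[tr],
                   economy = amp_n400 * kern_n400,
                   culture = amp_late * kern_late,
                   NULL)
    if (!is.null(kern))
      dat[, , tr] <- dat[, , tr] + outer(w, kern)
  }
  # in-band 500 uV transients on artifact trials
  half_sine <- 500 * sin(pi * seq(0, 1, length.out = max(3L, round(
    0.1 * spec$sfreq))))
  for (tr in which(trials$artifact)) {
    ch <- sample.int(nch, 1L)
    start <- sample.int(n_times - length(half_sine), 1L)
    idx <- start + seq_along(half_sine) - 1L
    dat[ch, idx, tr] <- dat[ch, idx, tr] + half_sine
  }
  epoch_array(dat, times, montage$channel, spec$sfreq,
              participant$participant_id)
}

#' Simulate behavioral trial tables for a roster
#'
#' @param spec A [simulation_spec()].
#' @param participants Roster from [simulate_participants()]; simulated
#'   afresh when omitted.
#' @return A list with `participants` and `trials` (all participants
#'   stacked; agreement, RT and ground-truth artifact flags filled in).
#'   Attributes `behavior_missing` and `low_trial` name the degraded
#'   participants.
#' @export
simulate_behavior <- function(spec, participants = NULL) {
  if (is.null(participants)) participants <- simulate_participants(spec)
  final <- participants$participant_id[
    participants$vote %in% c("mainstream", "populist")]
  miss_ids <- head(final, spec$n_behavior_missing)
  # alternate groups for the low-trial participants, mirroring "one populist
  # voter and one mainstream voter"
  main_ids <- participants$participant_id[participants$vote == "mainstream"]
  pop_ids <- participants$participant_id[participants$vote == "populist"]
  low_ids <- character(0)
  if (spec$n_low_trials > 0) {
    take_m <- ceiling(spec$n_low_trials / 2)
    take_p <- spec$n_low_trials - take_m
    low_ids <- c(utils::tail(main_ids, take_m), utils::tail(pop_ids, take_p))
  }
  rows <- lapply(seq_len(nrow(participants)), function(i) {
    p <- participants[i, ]
    simulate_participant_trials(
      spec, p,
      behavior_missing = p$participant_id %in% miss_ids,
      low_trial_cell = if (p$participant_id %in% low_ids)
        c("economy", "populist") else NULL)
  })
  trials <- do.call(rbind, rows)
  attr(trials, "behavior_missing") <- miss_ids
  attr(trials, "low_trial") <- low_ids
  list(participants = participants, trials = trials)
}

#' Simulate an IAT trial table
#'
#' Seven-block layout. Latencies are `floor + lognormal`; blocks 6 and 7
#' receive a per-participant compatibility shift on the log scale, drawn
#' independently of voting group (positive shift = slower reversed blocks =
#' positive D, i.e. implicit preference for the pairing of blocks 3/4).
#'
#' @param spec A [simulation_spec()].
#' @param participants Roster; simulated afresh when omitted.
#' @param shift_meanlog,shift_sdlog Override the spec's compatibility-shift
#'   distribution (used for null configurations).
#' @return An IAT table: `participant_id`, `block`, `trial_index`,
#'   `latency`.
#' @export
simulate_iat <- function(spec, participants = NULL,
                         shift_meanlog = spec$iat_shift_meanlog,
                         shift_sdlog = spec$iat_shift_sdlog) {
  if (is.null(participants)) participants <- simulate_participants(spec)
  nb <- spec$iat_block_trials
  out <- lapply(participants$participant_id, function(pid) {
    delta <- stats::rnorm(1L, shift_meanlog, shift_sdlog)
    blocks <- rep(seq_len(7L), nb)
    meanlog <- spec$iat_meanlog + ifelse(blocks %in% c(6L, 7L), delta, 0)
    lat <- spec$iat_floor_ms +
      stats::rlnorm(length(blocks), meanlog, spec$iat_sdlog)
    data.frame(participant_id = pid, block = blocks,
               trial_index = sequence(nb), latency = round(lat),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a complete study dataset
#'
#' Roster, behavioral trial tables, IAT and (optionally) per-participant
#' epoched EEG with injected effects and artifacts. All randomness derives
#' from `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @param dir Optional directory: when given, EEG containers are streamed
#'   to disk participant by participant (see [write_dataset()]) and the
#'   returned `eeg` element holds participant ids only.
#' @param eeg Simulate EEG at all? `FALSE` gives a behavior-only dataset.
#' @return A list with `participants`, `trials`, `iat` and `eeg`.
#' @export
simulate_dataset <- function(spec, dir = NULL, eeg = TRUE) {
  with_seed(derive_seed(spec$seed, "roster"), {
    beh <- simulate_behavior(spec)
  })
  iat <- with_seed(derive_seed(spec$seed, "iat"),
                   simulate_iat(spec, beh$participants))
  participants <- beh$participants
  eeg_out <- NULL
  if (eeg) {
    if (!is.null(dir)) {
      dir.create(file.path(dir, "epochs"), recursive = TRUE,
                 showWarnings = FALSE)
      utils::write.table(participants, file.path(dir, "participants.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(iat, file.path(dir, "iat.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    eeg_out <- list()
    for (i in seq_len(nrow(participants))) {
      p <- participants[i, ]
      tr <- beh$trials[beh$trials$participant_id == p$participant_id, ]
      e <- with_seed(derive_seed(spec$seed, "eeg", p$participant_id),
                     simulate_eeg(spec, p, tr))
      if (is.null(dir)) {
        eeg_out[[p$participant_id]] <- list(epochs = e, trials = tr)
      } else {
        write_epochs(e, tr, file.path(dir, "epochs", p$participant_id))
        eeg_out[[p$participant_id]] <- p$participant_id
      }
    }
  }
  list(participants = participants, trials = beh$trials, iat = iat,
       eeg = eeg_out)
}
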