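#' Issue dimensions of the survey design
#'
#' The three political issue dimensions of the survey task, in canonical
#' order.
#'
#' @return Character vector of length 3.
#' @export
issue_dimensions <- function() c("anti_establishment", "economy", "culture")

#' Item types of the survey design
#'
#' @return Character vector: `"populist"`, `"non_populist"`.
#' @export
item_types <- function() c("populist", "non_populist")

#' Posterior electrode set used for N400 amplitude extraction
#'
#' The 12 centro-parietal / parieto-occipital channels over which mean N400
#' amplitudes are extracted.
#'
#' @return Character vector of 12 channel labels.
#' @export
posterior_channels <- function() {
  c("CP1", "CP2", "CP3", "CP4", "P1", "P2", "P3", "P4",
    "Pz", "PO3", "PO4", "POz")
}

#' Construct an epoch array
#'
#' The container consumed by every EEG stage: a `channels x times x trials`
#' voltage array (microvolts) with an explicit, uniformly spaced time axis in
#' milliseconds relative to critical-word onset.
#'
#' @param data Numeric array, `n_channels x n_times x n_trials` (microvolts).
#' @param times Numeric vector of sample times in ms; strictly increasing and
#'   uniformly spaced at `1000 / sfreq`.
#' @param channels Character vector of channel labels, one per row of `data`.
#' @param sfreq Sampling rate in Hz.
#' @param participant_id Participant identifier (scalar character).
#'
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, times, channels, sfreq, participant_id) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (channels x times x trials)")
  d <- dim(data)
  if (length(channels) != d[1L])
    stop("length(channels) must equal dim(data)[1]")
  if (length(times) != d[2L])
    stop("length(times) must equal dim(data)[2]")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0)
    stop("`sfreq` must be a positive scalar")
  dt <- 1000 / sfreq
  if (length(times) > 1L) {
    steps <- diff(times)
    if (any(steps <= 0))
      stop("`times` must be strictly increasing")
    if (max(abs(steps - dt)) > 1e-6 * dt)
      stop("`times` must be uniformly spaced at 1000/sfreq ms")
  }
  structure(
    list(data = data, times = as.numeric(times),
         channels = as.character(channels), sfreq = sfreq,
         participant_id = as.character(participant_id)),
    class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_array> participant %s: %d channels x %d samples x %d trials\n",
    x$participant_id, d[1L], d[2L], d[3L]))
  cat(sprintf("  time %.1f .. %.1f ms @ %g Hz\n",
              x$times[1L], x$times[length(x$times)], x$sfreq))
  invisible(x)
}

#' @export
dim.epoch_array <- function(x) dim(x$data)

n_trials <- function(e) dim(e$data)[3L]

#' Validate a trial table
#'
#' One row per trial, aligned 1:1 with the trial axis of the matching epoch
#' array. Required columns: `participant_id`, `trial_index`, `dimension`,
#' `item_type`, `agreement`, `rt`, `artifact`.
#'
#' @param trials A data.frame of trial metadata.
#' @return The validated data.frame (with `artifact` defaulted to `FALSE`
#'   when absent).
#' @export
validate_trials <- function(trials) {
  need <- c("participant_id", "trial_index", "dimension", "item_type",
            "agreement", "rt")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(trials$dimension %in% issue_dimensions()))
    stop("unknown issue dimension in trial table")
  if (!all(trials$item_type %in% item_types()))
    stop("unknown item type in trial table")
  if (!all(trials$agreement %in% c("agree", "disagree", "missing")))
    stop("agreement must be 'agree', 'disagree' or 'missing'")
  bad_rt <- !is.na(trials$rt) & trials$rt <= 0
  if (any(bad_rt)) stop("rt must be positive or NA")
  if (is.null(trials$artifact)) trials$artifact <- FALSE
  trials$artifact <- as.logical(trials$artifact)
  trials
}

#' Validate a participant table
#'
#' @param participants A data.frame with columns `participant_id`, `vote`,
#'   `age`, `gender`, `left_right`, `interest_politics`.
#' @return The validated data.frame.
#' @export
validate_participants <- function(participants) {
  need <- c("participant_id", "vote")
  miss <- setdiff(need, names(participants))
  if (length(miss))
    stop("participant table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(participants$participant_id))
    stop("participant_id must be unique")
  ok <- c("mainstream", "populist", "other_party", "nonvoter", "blank")
  if (!all(participants$vote %in% ok))
    stop("unknown vote code: ",
         paste(unique(setdiff(participants$vote, ok)), collapse = ", "))
  participants
}
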