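#' Write an epoch array and its trial table to disk
#'
#' The on-disk container is language-neutral: a raw little-endian float64
#' array file (`<stem>.dat`, channel-fastest order, i.e. the R array written
#' in its natural column-major layout), a JSON sidecar (`<stem>.json`) with
#' shape, time axis, channel labels, sampling rate and participant id, and a
#' TSV trial table (`<stem>.trials.tsv`).
#'
#' @param e An [epoch_array()].
#' @param trials Trial table aligned with the trial axis of `e`.
#' @param stem File path stem (no extension); directories are created.
#' @return `stem`, invisibly.
#' @export
write_epochs <- function(e, trials, stem) {
  stopifnot(inherits(e, "epoch_array"))
  trials <- validate_trials(trials)
  if (nrow(trials) != n_trials(e))
    stop("alignment error: ", n_trials(e), " trials in epoch array but ",
         nrow(trials), " trial metadata rows")
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(e$data), con, size = 8, endian = "little")
  sidecar <- list(
    format = "erpvote-epochs-v1",
    shape = dim(e$data),
    times_ms = e$times,
    channels = e$channels,
    sfreq = e$sfreq,
    participant_id = e$participant_id)
  jsonlite::write_json(sidecar, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(trials, paste0(stem, ".trials.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' Read an epoch array container written by [write_epochs()]
#'
#' @param stem File path stem (no extension).
#' @return A list with elements `epochs` ([epoch_array()]) and `trials`
#'   (data.frame).
#' @export
read_epochs <- function(stem) {
  json_path <- paste0(stem, ".json")
  if (!file.exists(json_path))
    stop("format error: missing sidecar ", json_path)
  sidecar <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  need <- c("shape", "times_ms", "channels", "sfreq", "participant_id")
  miss <- setdiff(need, names(sidecar))
  if (length(miss))
    stop("format error: sidecar missing field(s): ",
         paste(miss, collapse = ", "))
  shape <- as.integer(sidecar$shape)
  if (length(shape) != 3L)
    stop("format error: shape must have 3 entries")
  dat_path <- paste0(stem, ".dat")
  if (!file.exists(dat_path))
    stop("format error: missing array file ", dat_path)
  n <- prod(shape)
  con <- file(dat_path, "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, "numeric", n = n + 1L, size = 8, endian = "little")
  if (length(raw) != n)
    stop("format error: array file has ", length(raw),
         " values, expected ", n)
  e <- epoch_array(array(raw, shape), sidecar$times_ms, sidecar$channels,
                   sidecar$sfreq, sidecar$participant_id)
  trials <- utils::read.delim(paste0(stem, ".trials.tsv"),
                              stringsAsFactors = FALSE)
  trials <- validate_trials(trials)
  if (nrow(trials) != shape[3L])
    stop("alignment error: ", shape[3L], " trials in epoch array but ",
         nrow(trials), " trial metadata rows")
  list(epochs = e, trials = trials)
}

#' Write a full simulated dataset to a directory
#'
#' Layout: `participants.tsv`, optional `iat.tsv`, and one epoch container
#' per participant under `epochs/`.
#'
#' @param dataset A list as returned by [simulate_dataset()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "epochs"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.table(dataset$participants, file.path(dir, "participants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$iat))
    utils::write.table(dataset$iat, file.path(dir, "iat.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  for (pid in names(dataset$eeg)) {
    rec <- dataset$eeg[[pid]]
    write_epochs(rec$epochs, rec$trials, file.path(dir, "epochs", pid))
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @param load_eeg Read the epoch containers? With `FALSE` only the tables
#'   are loaded.
#' @return A list with `participants`, `iat` (or `NULL`) and `eeg` (named
#'   list of `list(epochs, trials)` per participant, or participant ids if
#'   `load_eeg = FALSE`).
#' @export
read_dataset <- function(dir, load_eeg = TRUE) {
  participants <- validate_participants(
    utils::read.delim(file.path(dir, "participants.tsv"),
                      stringsAsFactors = FALSE))
  iat_path <- file.path(dir, "iat.tsv")
  iat <- if (file.exists(iat_path))
    utils::read.delim(iat_path, stringsAsFactors = FALSE) else NULL
  stems <- sub("\\.json$", "",
               list.files(file.path(dir, "epochs"), pattern = "\\.json$",
                          full.names = TRUE))
  eeg <- if (load_eeg) {
    out <- lapply(stems, read_epochs)
    names(out) <- vapply(out, function(x) x$epochs$participant_id, "")
    out
  } else basename(stems)
  list(participants = participants, iat = iat, eeg = eeg)
}
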