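#' Spatio-temporal feature matrix for one analysis window
#'
#' Features are the concatenation, channel block by channel block, of the
#' voltage samples whose times fall in the half-open window. Feature count
#' is `floor(window_ms * sfreq / 1000) * n_channels` on a grid aligned with
#' the window.
#'
#' @param e An [epoch_array()].
#' @param window Half-open `[start, stop)` window in ms.
#' @return A trials x features numeric matrix.
#' @export
window_features <- function(e, window) {
  stopifnot(inherits(e, "epoch_array"))
  n_samp <- floor((window[2L] - window[1L]) * e$sfreq / 1000)
  if (n_samp < 1L)
    stop("empty analysis window [", window[1L], ", ", window[2L],
         ") at sfreq ", e$sfreq)
  first <- match(TRUE, e$times >= window[1L])
  if (is.na(first) || first + n_samp - 1L > length(e$times))
    stop("analysis window [", window[1L], ", ", window[2L],
         ") outside the epoch")
  sel <- first:(first + n_samp - 1L)
  d <- dim(e$data)
  # channels x times x trials -> trials x (channel-major features)
  block <- e$data[, sel, , drop = FALSE]
  m <- matrix(aperm(block, c(3L, 2L, 1L)), d[3L],
              length(sel) * d[1L])
  m
}

# stratified fold assignment; remainder trials distributed round-robin
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(sample.int(k), length(idx))
  }
  folds
}

#' Class-balanced repeated cross-validated linear SVM accuracy
#'
#' Per repeat: the majority class is randomly undersampled to parity, the
#' balanced trials are partitioned into stratified folds, and a linear
#' maximum-margin classifier (fixed regularization constant C) is trained
#' on all but the held-out fold. Accuracy is the mean over all folds and
#' repeats.
#'
#' @param features Trials x features matrix.
#' @param labels Two-level factor or character vector, one per trial.
#' @param config An [analysis_config()].
#' @return Mean classification accuracy (proportion).
#' @export
balanced_cv_decode <- function(features, labels, config = analysis_config()) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes")
  counts <- table(labels)
  if (min(counts) < config$cv_folds)
    stop("class with fewer trials (", min(counts),
         ") than folds (", config$cv_folds, ")")
  n_min <- min(counts)
  accs <- numeric(0)
  for (rep_i in seq_len(config$cv_repeats)) {
    keep <- unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > n_min) sample(idx, n_min) else idx
    }), use.names = FALSE)
    x <- features[keep, , drop = FALSE]
    y <- droplevels(labels[keep])
    if (config$scale_features) {
      x <- scale(x)
      x[is.nan(x)] <- 0
    }
    folds <- stratified_folds(y, config$cv_folds)
    for (f in seq_len(config$cv_folds)) {
      test <- folds == f
      fit <- e1071::svm(x[!test, , drop = FALSE], y[!test],
                        kernel = "linear", cost = config$svm_c,
                        scale = FALSE, fitted = FALSE)
      pred <- stats::predict(fit, x[test, , drop = FALSE])
      accs <- c(accs, mean(pred == y[test]))
    }
  }
  mean(accs)
}

# window grid tiling [from, to) in steps of width ms
window_grid <- function(from, to, width) {
  starts <- seq(from, to - width, by = width)
  cbind(start = starts, stop = starts + width)
}

#' Sliding-window decoding time course for one participant and dimension
#'
#' Real accuracy per window via [balanced_cv_decode()] on populist vs
#' non-populist item labels; empirical chance accuracy by re-running the
#' identical procedure with randomly shuffled labels
#' (`config$n_chance_shuffles` reruns, mean taken).
#'
#' @param e An [epoch_array()] (preprocessed).
#' @param trials Matching trial table; artifact trials are dropped.
#' @param dimension Issue dimension to decode.
#' @param config An [analysis_config()]; `decode_time_range` restricts the
#'   analyzed windows, otherwise the full epoch is tiled.
#' @return A data.frame: participant_id, dimension, window_start,
#'   window_stop, real_accuracy, chance_accuracy.
#' @export
decode_timecourse <- function(e, trials, dimension,
                              config = analysis_config()) {
  trials <- validate_trials(trials)
  keep <- trials$dimension == dimension & !trials$artifact
  labels <- factor(trials$item_type[keep], levels = item_types())
  if (min(table(labels)) < config$min_trials_mvpa)
    stop("participant ", e$participant_id, " has < ",
         config$min_trials_mvpa, " trials for ", dimension)
  sub <- e
  sub$data <- e$data[, , keep, drop = FALSE]
  rng <- config$decode_time_range
  if (is.null(rng)) rng <- c(e$times[1L],
                             e$times[length(e$times)] + 1000 / e$sfreq)
  grid <- window_grid(rng[1L], rng[2L], config$mvpa_window_ms)
  res <- apply(grid, 1L, function(wnd) {
    x <- window_features(sub, wnd)
    real <- balanced_cv_decode(x, labels, config)
    chance <- mean(vapply(seq_len(config$n_chance_shuffles), function(s) {
      balanced_cv_decode(x, sample(labels), config)
    }, 0))
    c(real, chance)
  })
  data.frame(participant_id = e$participant_id, dimension = dimension,
             window_start = grid[, "start"], window_stop = grid[, "stop"],
             real_accuracy = res[1L, ], chance_accuracy = res[2L, ],
             stringsAsFactors = FALSE)
}

# sign-flip permutation t statistics: S (perms x n of +/-1), D (n x w)
flip_t <- function(S, D) {
  n <- nrow(D)
  M <- (S %*% D) / n
  ssq <- matrix(colSums(D^2), nrow(S), ncol(D), byrow = TRUE)
  V <- pmax(ssq - n * M^2, 0) / (n - 1)
  T <- M / sqrt(V / n)
  T[is.nan(T)] <- 0     # 0/0: no variance and no effect
  T
}

# max cluster mass in a vector of t values given threshold + min run length
max_cluster_mass <- function(tv, tcrit, min_run) {
  sig <- tv > tcrit
  if (!any(sig)) return(0)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= min_run
  if (!any(ok)) return(0)
  max(vapply(which(ok), function(i) sum(tv[starts[i]:ends[i]]), 0))
}

#' Cluster-mass permutation test of decoding above empirical chance
#'
#' Per window, a paired one-tailed t-test of real vs chance accuracy
#' across participants. Candidate clusters are runs of at least
#' `min_cluster_windows` consecutive windows with p below `cluster_alpha`;
#' the cluster mass is the summed t. The null distribution is the maximum
#' cluster mass over permutations in which each participant's (real,
#' chance) pair is independently swapped; the corrected p is the
#' proportion of null masses at least as large (with the add-one
#' convention). A family-level Bonferroni across issue dimensions
#' multiplies p by the number of dimensions when
#' `config$bonferroni_dimensions` is set.
#'
#' @param timecourses data.frame stacking [decode_timecourse()] rows for
#'   one dimension across participants (>= 2), on a common window grid.
#' @param config An [analysis_config()].
#' @param n_dimensions Bonferroni family size.
#' @return A list of class `cluster_result`: `dimension`, `windows`
#'   (per-window start, t, p), `clusters` (start_ms, stop_ms, n_windows,
#'   mass, p, p_corrected), `null_max_mass`.
#' @export
cluster_permutation_test <- function(timecourses,
                                     config = analysis_config(),
                                     n_dimensions = 3L) {
  tc <- timecourses
  stopifnot(length(unique(tc$dimension)) == 1L)
  wide_real <- stats::xtabs(real_accuracy ~ participant_id + window_start,
                            tc)
  wide_chance <- stats::xtabs(chance_accuracy ~ participant_id +
                                window_start, tc)
  counts <- stats::xtabs(~ participant_id + window_start, tc)
  if (any(counts != 1L))
    stop("window grids differ across participants")
  n <- nrow(wide_real)
  if (n < 2L) stop("need >= 2 participants")
  starts <- as.numeric(colnames(wide_real))
  D <- unclass(wide_real - wide_chance)
  tcrit <- stats::qt(1 - config$cluster_alpha, n - 1)
  tv <- as.vector(flip_t(matrix(1, 1L, n), D))
  pv <- stats::pt(tv, n - 1, lower.tail = FALSE)

  obs <- cluster_spans(tv, tcrit, config$min_cluster_windows)
  S <- matrix(sample(c(-1, 1), config$n_permutations * n, replace = TRUE),
              config$n_permutations, n)
  Tperm <- flip_t(S, D)
  null_max <- apply(Tperm, 1L, max_cluster_mass, tcrit = tcrit,
                    min_run = config$min_cluster_windows)
  width <- config$mvpa_window_ms
  clusters <- if (nrow(obs)) {
    p_raw <- vapply(obs$mass, function(m)
      (1 + sum(null_max >= m)) / (1 + length(null_max)), 0)
    data.frame(start_ms = starts[obs$start], stop_ms = starts[obs$end] + width,
               n_windows = obs$end - obs$start + 1L, mass = obs$mass,
               p = p_raw,
               p_corrected = pmin(1, p_raw * if (config$bonferroni_dimensions)
                 n_dimensions else 1),
               stringsAsFactors = FALSE)
  } else {
    data.frame(start_ms = numeric(0), stop_ms = numeric(0),
               n_windows = integer(0), mass = numeric(0), p = numeric(0),
               p_corrected = numeric(0))
  }
  structure(list(dimension = tc$dimension[1L],
                 windows = data.frame(window_start = starts, t = tv, p = pv),
                 clusters = clusters, null_max_mass = null_max),
            class = "cluster_result")
}

# candidate clusters (start/end window indices and mass) in observed t
cluster_spans <- function(tv, tcrit, min_run) {
  sig <- tv > tcrit
  out <- data.frame(start = integer(0), end = integer(0), mass = numeric(0))
  if (!any(sig)) return(out)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= min_run
  for (i in which(ok))
    out <- rbind(out, data.frame(start = starts[i], end = ends[i],
                                 mass = sum(tv[starts[i]:ends[i]])))
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> dimension %s: %d windows, %d cluster(s)\n",
              x$dimension, nrow(x$windows), nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Robustness rerun at a doubled analysis window
#'
#' Repeats decoding and cluster statistics with windows of twice the
#' configured width and reports, per pair of corrected-significant
#' clusters, the time overlap between the two window sizes.
#'
#' @param eeg Named list of `list(epochs, trials)` per participant.
#' @param dimension Issue dimension.
#' @param config An [analysis_config()].
#' @param alpha Corrected significance level for the overlap report.
#' @return A list: `base`, `doubled` (both `cluster_result`) and
#'   `overlap_fraction` (share of base significant-cluster time covered by
#'   doubled significant clusters; `NA` when neither run has significant
#'   clusters).
#' @export
sanity_rerun <- function(eeg, dimension, config = analysis_config(),
                         alpha = 0.05) {
  run <- function(cfg) {
    tcs <- lapply(eeg, function(rec)
      decode_timecourse(rec$epochs, rec$trials, dimension, cfg))
    cluster_permutation_test(do.call(rbind, tcs), cfg)
  }
  base <- run(config)
  cfg2 <- config
  cfg2$mvpa_window_ms <- 2 * config$mvpa_window_ms
  doubled <- run(cfg2)
  sig_spans <- function(cr) {
    cl <- cr$clusters[cr$clusters$p_corrected < alpha, , drop = FALSE]
    cl[c("start_ms", "stop_ms")]
  }
  a <- sig_spans(base); b <- sig_spans(doubled)
  overlap <- NA_real_
  if (nrow(a)) {
    covered <- 0
    total <- sum(a$stop_ms - a$start_ms)
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
      covered <- covered + max(0, min(a$stop_ms[i], b$stop_ms[j]) -
                                 max(a$start_ms[i], b$start_ms[j]))
    overlap <- covered / total
  } else if (nrow(b) == 0L) {
    overlap <- NA_real_
  } else overlap <- 0
  list(base = base, doubled = doubled, overlap_fraction = overlap)
}
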