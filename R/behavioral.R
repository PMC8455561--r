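#' Self-report index (SRI)
#'
#' Kelley-style index per participant and issue dimension:
#' `SRI = (% populist items agreed + % non-populist items disagreed) -
#' (% populist items disagreed + % non-populist items agreed)`.
#' Percentages are taken over the answered (non-missing) items of each item
#' type, so the index ranges over \[-200, 200\]. Participants with no
#' answered items of a type get a flagged-missing record.
#'
#' @param trials Trial table (all participants stacked).
#' @return data.frame: participant_id, dimension, pop_agree, pop_disagree,
#'   main_agree, main_disagree (percentages), sri, missing (logical).
#' @export
compute_sri <- function(trials) {
  trials <- validate_trials(trials)
  ids <- unique(trials$participant_id)
  rows <- list()
  for (pid in ids) {
    for (dm in issue_dimensions()) {
      d <- trials[trials$participant_id == pid & trials$dimension == dm &
                    trials$agreement != "missing", ]
      pop <- d[d$item_type == "populist", "agreement"]
      non <- d[d$item_type == "non_populist", "agreement"]
      if (!length(pop) || !length(non)) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, dimension = dm, pop_agree = NA_real_,
          pop_disagree = NA_real_, main_agree = NA_real_,
          main_disagree = NA_real_, sri = NA_real_, missing = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      pa <- 100 * mean(pop == "agree")
      ma <- 100 * mean(non == "agree")
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, dimension = dm, pop_agree = pa,
        pop_disagree = 100 - pa, main_agree = ma, main_disagree = 100 - ma,
        sri = (pa + (100 - ma)) - ((100 - pa) + ma), missing = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Trim slow response times and summarize condition means
#'
#' Trials slower than the cutoff are excluded from the RT means; the
#' data-derived cutoff `mean + 2 SD` of the untrimmed RTs is reported
#' alongside. Condition means collapse across agreement and disagreement,
#' i.e. one mean per participant x dimension x item type.
#'
#' @param trials Trial table.
#' @param cutoff_ms Fixed trimming cutoff (ms).
#' @return A list: `trials` (with logical `rt_trimmed` column),
#'   `condition_means` (participant_id, dimension, item_type, mean_rt, n)
#'   and `derived_cutoff_ms`.
#' @export
trim_rts <- function(trials, cutoff_ms = 2700) {
  stopifnot(cutoff_ms > 0)
  trials <- validate_trials(trials)
  rt <- trials$rt
  derived <- mean(rt, na.rm = TRUE) + 2 * stats::sd(rt, na.rm = TRUE)
  trials$rt_trimmed <- !is.na(rt) & rt > cutoff_ms
  keep <- trials[!trials$rt_trimmed & !is.na(trials$rt), ]
  cm <- stats::aggregate(rt ~ participant_id + dimension + item_type,
                         keep, function(x) c(mean(x), length(x)))
  condition_means <- data.frame(
    cm[c("participant_id", "dimension", "item_type")],
    mean_rt = cm$rt[, 1L], n = cm$rt[, 2L], stringsAsFactors = FALSE)
  list(trials = trials, condition_means = condition_means,
       derived_cutoff_ms = derived)
}

#' IAT D scores
#'
#' Improved-algorithm D per participant: delete latencies above
#' `delete_ms`; compute, for the combined block pairs (3, 6) and (4, 7),
#' the pooled ("inclusive") sample SD and the block-mean differences
#' `mean(block 6) - mean(block 3)` and `mean(block 7) - mean(block 4)`;
#' each difference is divided by its pair's inclusive SD and D is the
#' equal-weight mean of the two ratios. Positive D = slower reversed
#' blocks. A warning is issued if any retained latency falls below
#' `min_ms`.
#'
#' @param iat IAT table: participant_id, block (1-7), trial_index,
#'   latency (ms).
#' @param delete_ms Deletion threshold for slow trials.
#' @param min_ms Fast-latency warning threshold.
#' @return data.frame: participant_id, d, d_first_pair, d_second_pair,
#'   sd_36, sd_47, m3, m4, m6, m7.
#' @export
compute_d <- function(iat, delete_ms = 10000, min_ms = 300) {
  stopifnot(all(iat$latency > 0))
  iat <- iat[iat$latency <= delete_ms, ]
  if (any(iat$latency < min_ms))
    warning("latencies below ", min_ms, " ms present")
  rows <- lapply(unique(iat$participant_id), function(pid) {
    d <- iat[iat$participant_id == pid, ]
    lat <- function(b) d$latency[d$block == b]
    for (b in c(3, 4, 6, 7))
      if (!length(lat(b)))
        stop("scoring error: participant ", pid, " has empty block ", b)
    sd36 <- stats::sd(c(lat(3), lat(6)))
    sd47 <- stats::sd(c(lat(4), lat(7)))
    d1 <- (mean(lat(6)) - mean(lat(3))) / sd36
    d2 <- (mean(lat(7)) - mean(lat(4))) / sd47
    data.frame(participant_id = pid, d = (d1 + d2) / 2,
               d_first_pair = d1, d_second_pair = d2,
               sd_36 = sd36, sd_47 = sd47,
               m3 = mean(lat(3)), m4 = mean(lat(4)),
               m6 = mean(lat(6)), m7 = mean(lat(7)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman-Brown adjusted split-half reliability of D
#'
#' Pearson correlation between the two combined-pair D scores, adjusted to
#' full test length: `r_sb = 2 r / (1 + r)`.
#'
#' @param dscores Table from [compute_d()].
#' @return A list: `r`, `r_sb`, `n`.
#' @export
split_half_reliability <- function(dscores) {
  ok <- stats::complete.cases(dscores[c("d_first_pair", "d_second_pair")])
  if (sum(ok) < 3L) stop("need both half-scores for >= 3 participants")
  r <- stats::cor(dscores$d_first_pair[ok], dscores$d_second_pair[ok])
  list(r = r, r_sb = 2 * r / (1 + r), n = sum(ok))
}
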