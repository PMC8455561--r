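#' Run the full analysis chain on a dataset
#'
#' Executes preprocess, ERP, decoding, behavioral and voting-model stages
#' on a dataset directory (see [write_dataset()]) or an in-memory dataset
#' from [simulate_dataset()], writing TSV tables, an exclusion log and a
#' machine-readable `results.json` to `outdir`. Stage failures abort with
#' the stage name and the offending participant. Two runs with equal
#' config and seed produce identical outputs.
#'
#' @param dataset Dataset directory path or list from [simulate_dataset()].
#' @param outdir Output directory (created).
#' @param config An [analysis_config()]. For desk-scale runs reduce
#'   `cv_repeats`, `n_chance_shuffles` and `n_permutations` and restrict
#'   `decode_time_range`.
#' @param decode Run the sliding-window decoding stage? It dominates the
#'   run time.
#' @return A list with all stage results (invisibly also written to
#'   `outdir`).
#' @export
run_pipeline <- function(dataset, outdir, config = analysis_config(),
                         decode = TRUE) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, pid, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "'",
           if (!is.null(pid)) paste0(" (participant ", pid, ")"), ": ",
           conditionMessage(e), call. = FALSE))
  }
  participants <- validate_participants(dataset$participants)

  # --- preprocess ---------------------------------------------------------
  eeg <- list()
  all_trials <- list()
  for (pid in names(dataset$eeg)) {
    rec <- dataset$eeg[[pid]]
    stage("preprocess", pid, {
      e <- bandpass_filter(rec$epochs, config$filter_band[1L],
                           config$filter_band[2L])
      e <- rereference_average(e)
      e <- baseline_correct(e)
      tr <- reject_artifacts(e, rec$trials, config$artifact_threshold_uv)
      eeg[[pid]] <- list(epochs = e, trials = tr)
      all_trials[[pid]] <- tr
    })
  }
  trials <- if (length(all_trials)) do.call(rbind, all_trials) else
    validate_trials(dataset$trials)
  excl <- stage("exclusions", NULL,
                apply_exclusions(participants, trials, config))
  write_exclusion_log(excl$log, file.path(outdir, "exclusions.tsv"))

  results <- list(exclusions = excl)

  # --- erp ----------------------------------------------------------------
  if (length(eeg)) {
    stage("erp", NULL, {
      keep <- intersect(names(eeg), excl$erp_retained)
      avgs <- lapply(keep, function(pid)
        average_conditions(eeg[[pid]]$epochs, eeg[[pid]]$trials))
      n400 <- extract_n400(avgs, config)
      utils::write.table(n400, file.path(outdir, "n400_amplitudes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      results$n400 <- n400
      results$n400_suite <- n400_hypothesis_suite(n400, participants)
      results$n400_diff <- n400_differential(n400)
    })
  }

  # --- decode -------------------------------------------------------------
  if (decode && length(eeg)) {
    stage("decode", NULL, {
      keep <- intersect(names(eeg), excl$mvpa_retained)
      cluster_results <- list()
      tcs_all <- list()
      for (dm in issue_dimensions()) {
        tcs <- lapply(keep, function(pid)
          with_seed(derive_seed(config$seed, "decode", pid, dm),
                    decode_timecourse(eeg[[pid]]$epochs, eeg[[pid]]$trials,
                                      dm, config)))
        tc <- do.call(rbind, tcs)
        tcs_all[[dm]] <- tc
        cluster_results[[dm]] <- with_seed(
          derive_seed(config$seed, "cluster", dm),
          cluster_permutation_test(tc, config))
      }
      tc_all <- do.call(rbind, tcs_all)
      utils::write.table(tc_all, file.path(outdir, "decoding_timecourses.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      results$decoding <- tcs_all
      results$clusters <- cluster_results
    })
  }

  # --- behavioral ---------------------------------------------------------
  stage("behav", NULL, {
    bt <- trials[trials$participant_id %in% excl$behav_retained, ]
    sri <- compute_sri(bt)
    utils::write.table(sri, file.path(outdir, "sri.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    results$sri <- sri
    sri_eco <- merge(sri[!sri$missing, ],
                     participants[c("participant_id", "vote")])
    results$sri_tests <- group_ttests(sri_eco, dv = "sri", group = "vote",
                                       by = "dimension")
    results$sri_anova <- mixed_anova(
      sri_eco, dv = "sri", between = "vote", within = "dimension")
    results$rt <- trim_rts(bt, config$rt_cutoff_ms)
  })
  if (!is.null(dataset$iat)) {
    stage("iat", NULL, {
      dsc <- compute_d(dataset$iat, config$iat_delete_ms, config$iat_min_ms)
      utils::write.table(dsc, file.path(outdir, "iat_d.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      results$dscores <- dsc
      results$iat_reliability <- split_half_reliability(dsc)
    })
  } else results$dscores <- NULL

  # --- predict ------------------------------------------------------------
  if (!is.null(results$n400_diff)) {
    stage("predict", NULL, {
      frame <- build_predictors(results$n400_diff, results$dscores,
                                results$sri, participants)
      results$predictors <- frame
      results$models <- run_model_suite(
        frame, include_iat = !is.null(results$dscores))
      utils::write.table(results$models$metrics,
                         file.path(outdir, "model_comparison.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    })
  }

  # --- report -------------------------------------------------------------
  report <- list(
    n_roster = nrow(participants),
    n_vote_retained = length(excl$vote_retained),
    n_erp_retained = length(excl$erp_retained),
    n_mvpa_retained = length(excl$mvpa_retained),
    n_behav_retained = length(excl$behav_retained),
    iat_present = !is.null(dataset$iat),
    n_model_obs = if (!is.null(results$models))
      results$models$metrics$n_obs[1L] else NULL,
    model_metrics = if (!is.null(results$models))
      results$models$metrics else NULL,
    clusters = if (!is.null(results$clusters))
      lapply(results$clusters, function(cr) cr$clusters) else NULL,
    iat_reliability = if (!is.null(results$iat_reliability))
      results$iat_reliability[c("r", "r_sb")] else NULL)
  report <- report[!vapply(report, is.null, TRUE)]
  jsonlite::write_json(report, file.path(outdir, "results.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(results)
}
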