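#' Analysis configuration
#'
#' Collects every tunable parameter of the analysis chain. Defaults are the
#' study's published analysis settings; the problem-size knobs
#' (`cv_repeats`, `n_chance_shuffles`, `decode_time_range`) may be reduced
#' for desk-scale runs without changing the semantics of any stage.
#'
#' @param n400_window Half-open `[start, stop)` window in ms for N400 mean
#'   amplitude extraction. Default `c(300, 600)`.
#' @param n400_channels Electrode labels entering the N400 analysis.
#' @param mvpa_window_ms Width of the non-overlapping decoding windows (ms).
#' @param cv_folds Number of cross-validation folds.
#' @param cv_repeats Repetitions of the full cross-validation with fresh
#'   fold allocations.
#' @param svm_c Fixed regularization constant of the linear SVM.
#' @param n_chance_shuffles Shuffled-label reruns per participant and window
#'   whose mean forms the empirical chance accuracy.
#' @param n_permutations Permutation samples for the cluster-mass null.
#' @param cluster_alpha Per-window inclusion alpha for cluster forming.
#' @param min_cluster_windows Minimum consecutive windows per cluster.
#' @param min_trials_erp Minimum artifact-free epochs per condition cell for
#'   the ERP stage.
#' @param min_trials_mvpa Minimum trials per dimension x item-type cell for
#'   the decoding stage.
#' @param rt_cutoff_ms Response-time trimming cutoff (ms).
#' @param iat_delete_ms Latencies above this are deleted before D-scoring.
#' @param iat_min_ms Latencies below this trigger a warning in D-scoring.
#' @param artifact_threshold_uv Absolute amplitude threshold (microvolts)
#'   for epoch rejection.
#' @param filter_band Zero-phase band-pass edges in Hz.
#' @param scale_features Z-score features before classification? All
#'   features share units (microvolts), so the default is `FALSE`.
#' @param decode_time_range Optional `c(start, stop)` ms restricting which
#'   decoding windows are analyzed; `NULL` tiles the full epoch.
#' @param bonferroni_dimensions Multiply cluster p-values by the number of
#'   issue dimensions tested? Default `TRUE`.
#' @param seed Integer seed from which every stochastic stage derives its
#'   generator.
#'
#' @return A list of class `erpvote_config`.
#' @export
analysis_config <- function(n400_window = c(300, 600),
                            n400_channels = posterior_channels(),
                            mvpa_window_ms = 10,
                            cv_folds = 10,
                            cv_repeats = 10,
                            svm_c = 1.0,
                            n_chance_shuffles = 10,
                            n_permutations = 5000,
                            cluster_alpha = 0.05,
                            min_cluster_windows = 2,
                            min_trials_erp = 14,
                            min_trials_mvpa = 20,
                            rt_cutoff_ms = 2700,
                            iat_delete_ms = 10000,
                            iat_min_ms = 300,
                            artifact_threshold_uv = 100,
                            filter_band = c(0.1, 30),
                            scale_features = FALSE,
                            decode_time_range = NULL,
                            bonferroni_dimensions = TRUE,
                            seed = 1L) {
  cfg <- list(
    n400_window = n400_window, n400_channels = n400_channels,
    mvpa_window_ms = mvpa_window_ms, cv_folds = cv_folds,
    cv_repeats = cv_repeats, svm_c = svm_c,
    n_chance_shuffles = n_chance_shuffles,
    n_permutations = n_permutations, cluster_alpha = cluster_alpha,
    min_cluster_windows = min_cluster_windows,
    min_trials_erp = min_trials_erp, min_trials_mvpa = min_trials_mvpa,
    rt_cutoff_ms = rt_cutoff_ms, iat_delete_ms = iat_delete_ms,
    iat_min_ms = iat_min_ms,
    artifact_threshold_uv = artifact_threshold_uv,
    filter_band = filter_band, scale_features = scale_features,
    decode_time_range = decode_time_range,
    bonferroni_dimensions = bonferroni_dimensions,
    seed = as.integer(seed))
  stopifnot(cfg$mvpa_window_ms > 0, cfg$cv_folds >= 2, cfg$cv_repeats >= 1,
            cfg$svm_c > 0, cfg$n_chance_shuffles >= 1,
            cfg$n_permutations >= 1,
            cfg$cluster_alpha > 0, cfg$cluster_alpha < 1,
            cfg$min_cluster_windows >= 1)
  class(cfg) <- "erpvote_config"
  cfg
}

# Derive a reproducible child seed from a base seed and a stage/participant
# tag; keeps every stream below 2^31.
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  # FNV-1a style 31-bit hash of the tag string
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(tag)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
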