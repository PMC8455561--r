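test_that("feature counts follow the window/sampling-rate arithmetic", {
  # 2048 Hz, 61 channels, 10 ms window: 20 time points x 61 = 1220
  e <- toy_epochs(n_channels = 61, n_times = 2663, n_trials = 2,
                  sfreq = 2048)
  expect_equal(ncol(window_features(e, c(300, 310))), 1220)
  # 256 Hz: 2 x 61 = 122
  e2 <- toy_epochs(n_channels = 61, n_times = 333, n_trials = 2,
                   sfreq = 256)
  expect_equal(ncol(window_features(e2, c(300, 310))), 122)
  # 100 Hz: floor gives one sample per channel
  e3 <- toy_epochs(n_channels = 5, n_times = 130, n_trials = 2, sfreq = 100)
  expect_equal(ncol(window_features(e3, c(300, 310))), 5)
  expect_error(window_features(e3, c(300.5, 305)), "empty")
  # feature values are the raw voltages, channel block by channel block
  f <- window_features(e2, c(0, 10))
  first <- match(TRUE, e2$times >= 0)
  expect_equal(f[1, 1:2], e2$data[1, first:(first + 1), 1])
})

test_that("balanced CV decoding behaves at chance and at separation", {
  set.seed(42)
  cfg <- analysis_config(cv_folds = 10, cv_repeats = 2, seed = 1)
  n <- 60
  x <- matrix(rnorm(n * 20), n, 20)
  y <- rep(item_types(), each = n / 2)
  # shuffled labels: chance
  acc0 <- mean(replicate(5, balanced_cv_decode(x, sample(y), cfg)))
  expect_lt(abs(acc0 - 0.5), 0.1)
  # classes offset by 10 noise SDs: near-perfect
  x2 <- x + outer(as.integer(y == "populist"), rep(10, 20))
  expect_gt(balanced_cv_decode(x2, y, cfg), 0.95)
  # class imbalance is undersampled to parity
  y3 <- rep(item_types(), c(30, 20))
  expect_error(balanced_cv_decode(x[1:35, ], rep(item_types(), c(30, 5)),
                                  cfg), "fewer trials")
  acc3 <- balanced_cv_decode(x2[1:50, ], y3, cfg)
  expect_gt(acc3, 0.9)
})

test_that("accuracy is insensitive to duplicated majority-class trials", {
  set.seed(31)
  n <- 48
  x <- matrix(rnorm(n * 10), n, 10)
  y <- rep(item_types(), each = n / 2)
  x <- x + outer(as.integer(y == "populist"), rep(1.5, 10))
  cfg <- analysis_config(cv_repeats = 4, seed = 2)
  a1 <- balanced_cv_decode(x, y, cfg)
  # duplicate majority-class trials: balancing undersamples them again
  xd <- rbind(x, x[y == "populist", ][1:10, ])
  yd <- c(y, rep("populist", 10))
  a2 <- balanced_cv_decode(xd, yd, cfg)
  expect_lt(abs(a1 - a2), 0.12)
})

test_that("the decoding timecourse tiles the epoch and respects filters", {
  spec <- small_spec(n_mainstream = 1, n_populist = 1, seed = 71)
  ds <- simulate_dataset(spec)
  rec <- ds$eeg[[1]]
  cfg <- analysis_config(cv_repeats = 1, n_chance_shuffles = 1, seed = 3)
  # full tiling: floor(epoch_length / window)
  n_expected <- floor((max(rec$epochs$times) + 1000 / spec$sfreq -
                         min(rec$epochs$times)) / cfg$mvpa_window_ms)
  set.seed(3)
  tc <- decode_timecourse(rec$epochs, rec$trials, "economy",
                          analysis_config(cv_repeats = 1,
                                          n_chance_shuffles = 1,
                                          decode_time_range = c(-100, 0)))
  expect_equal(nrow(tc), 10)
  expect_true(all(tc$real_accuracy >= 0 & tc$real_accuracy <= 1))
  # too few trials: refused
  few <- rec$trials
  few$artifact[few$dimension == "economy"][1:10] <- TRUE
  expect_error(decode_timecourse(rec$epochs, few, "economy", cfg),
               "< 20 trials")
  expect_equal(n_expected, 130)
})

test_that("cluster statistics: no clusters when real equals chance", {
  tc <- null_timecourses(8, 20)
  tc$chance_accuracy <- tc$real_accuracy
  cr <- cluster_permutation_test(tc, analysis_config(n_permutations = 200))
  expect_equal(nrow(cr$clusters), 0)
  expect_true(all(cr$windows$t == 0))
})

test_that("cluster-forming respects the minimum run length", {
  set.seed(88)
  tc <- null_timecourses(10, 15, acc_sd = 0.02)
  # inject a strong single-window effect plus a two-window effect
  tc$real_accuracy[tc$window_start == 40] <-
    tc$real_accuracy[tc$window_start == 40] + 0.2
  tc$real_accuracy[tc$window_start %in% c(100, 110)] <-
    tc$real_accuracy[tc$window_start %in% c(100, 110)] + 0.2
  cr <- cluster_permutation_test(tc, analysis_config(n_permutations = 500,
                                                     seed = 4))
  expect_true(all(cr$clusters$n_windows >= 2))
  expect_true(any(cr$clusters$start_ms == 100 & cr$clusters$stop_ms == 120))
  expect_false(any(cr$clusters$start_ms == 40))
  # mass equals the summed t inside the cluster
  i <- which(cr$clusters$start_ms == 100)
  tw <- cr$windows
  expect_equal(cr$clusters$mass[i],
               sum(tw$t[tw$window_start %in% c(100, 110)]),
               tolerance = 1e-10)
})

test_that("mismatched window grids across participants are refused", {
  tc <- null_timecourses(4, 10)
  tc <- tc[!(tc$participant_id == "s01" & tc$window_start == 50), ]
  expect_error(cluster_permutation_test(tc, analysis_config()), "grids")
})

test_that("permutation p-values are calibrated and uniform under the null", {
  set.seed(3001)
  cfg <- analysis_config(n_permutations = 500, bonferroni_dimensions = FALSE)
  n_rep <- 200
  res <- replicate(n_rep, {
    tc <- null_timecourses(12, 30)
    cr <- cluster_permutation_test(tc, cfg)
    if (nrow(cr$clusters)) min(cr$clusters$p) else 1
  })
  rate <- mean(res < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
  # within clusters that formed, raw permutation p is roughly uniform:
  # check via the family-wise rate at a second threshold
  expect_lt(mean(res < 0.01), 0.04)
})

test_that("decoding recovers the injected economy effect where injected", {
  spec <- small_spec(n_mainstream = 4, n_populist = 4, seed = 303)
  ds <- simulate_dataset(spec)
  cfg <- analysis_config(cv_repeats = 1, n_chance_shuffles = 1,
                         decode_time_range = c(400, 500),
                         n_permutations = 500, seed = 5)
  cfg_null <- cfg
  tcs <- lapply(ds$eeg, function(r) {
    e <- baseline_correct(r$epochs)
    rbind(decode_timecourse(e, r$trials, "economy", cfg),
          decode_timecourse(e, r$trials, "anti_establishment", cfg))
  })
  tc <- do.call(rbind, tcs)
  eco <- tc[tc$dimension == "economy", ]
  anti <- tc[tc$dimension == "anti_establishment", ]
  # economy decodes above its chance runs; anti-establishment does not
  expect_gt(mean(eco$real_accuracy - eco$chance_accuracy), 0.05)
  expect_lt(mean(anti$real_accuracy - anti$chance_accuracy), 0.05)
})

test_that("doubling the window halves the grid and keeps conclusions", {
  spec <- small_spec(n_mainstream = 3, n_populist = 3, seed = 404)
  ds <- simulate_dataset(spec)
  eeg <- lapply(ds$eeg, function(r)
    list(epochs = baseline_correct(r$epochs), trials = r$trials))
  cfg <- analysis_config(cv_repeats = 1, n_chance_shuffles = 1,
                         decode_time_range = c(400, 500),
                         n_permutations = 300, seed = 6)
  set.seed(6)
  out <- sanity_rerun(eeg, "economy", cfg)
  expect_equal(nrow(out$base$windows), 10)
  expect_equal(nrow(out$doubled$windows), 5)
  if (!is.na(out$overlap_fraction)) {
    expect_gte(out$overlap_fraction, 0)
    expect_lte(out$overlap_fraction, 1)
  }
})
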