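test_that("condition averaging is the arithmetic mean over clean trials", {
  set.seed(10)
  e <- toy_epochs(n_channels = 2, n_times = 32, n_trials = 4)
  tr <- toy_trials(4, dimension = "economy",
                   item_type = c("populist", "populist", "non_populist",
                                 "non_populist"))
  # identical epochs average to themselves
  e2 <- e
  for (k in 1:4) e2$data[, , k] <- e$data[, , 1]
  a <- average_conditions(e2, tr)
  expect_equal(a$cells[["economy|populist"]]$waveform, e$data[, , 1])
  # two trials: elementwise mean
  a2 <- average_conditions(e, tr)
  expect_equal(a2$cells[["economy|non_populist"]]$waveform,
               (e$data[, , 3] + e$data[, , 4]) / 2)
  # artifact trials never enter; empty cells are absent
  tr$artifact[3:4] <- TRUE
  a3 <- average_conditions(e, tr)
  expect_null(a3$cells[["economy|non_populist"]])
  expect_equal(a3$cells[["economy|populist"]]$n, 2)
})

test_that("N400 extraction is the time-mean over the half-open window", {
  sf <- 1000
  n <- 1300
  times <- -100 + (0:(n - 1))
  chans <- posterior_channels()
  dat <- array(0, c(12, n, 1))
  # constant c over the window at POz
  dat[12, , 1] <- 7.5
  e <- epoch_array(dat, times, chans, sf, "p1")
  tr <- toy_trials(1, item_type = "populist")
  a <- average_conditions(e, tr)
  n4 <- extract_n400(a)
  expect_equal(n4$amplitude[n4$electrode == "POz"], 7.5)
  # hand-built 3-sample window: mean of 1, 2, 3 is 2
  e3 <- epoch_array(array(rep(c(1, 2, 3), each = 1), c(1, 3, 1)),
                    times = c(300, 400, 500), channels = "POz",
                    sfreq = 10, participant_id = "p1")
  a3 <- average_conditions(e3, tr)
  cfg <- analysis_config(n400_channels = "POz")
  expect_equal(extract_n400(a3, cfg)$amplitude[1], 2.0)
})

test_that("split-plot ANOVA matches a hand-computed cell-means oracle", {
  # balanced 2-group x 3-condition design, brute-force SS decomposition
  set.seed(21)
  a <- 2; n <- 4; k <- 3
  subj <- sprintf("s%d", 1:(a * n))
  grp <- rep(c("g1", "g2"), each = n)
  d <- expand.grid(participant_id = subj, w = paste0("c", 1:k),
                   stringsAsFactors = FALSE)
  d$vote <- grp[match(d$participant_id, subj)]
  d$value <- rnorm(nrow(d)) + as.numeric(factor(d$w)) * 0.3 +
    ifelse(d$vote == "g1", 0.2, 0) * as.numeric(factor(d$w))
  out <- mixed_anova(d, dv = "value", between = "vote", within = "w")

  Y <- xtabs(value ~ participant_id + w, d)[subj, ]
  m <- mean(Y); mg <- tapply(rowMeans(Y), grp, mean)
  mc <- colMeans(Y); ms <- rowMeans(Y)
  mgc <- rbind(colMeans(Y[grp == "g1", ]), colMeans(Y[grp == "g2", ]))
  ss_group <- k * n * sum((mg - m)^2)
  ss_subj <- k * sum((ms - mg[grp])^2)
  ss_cond <- a * n * sum((mc - m)^2)
  gi <- as.integer(factor(grp))
  ss_int <- n * sum((mgc - outer(mg, rep(1, k)) -
                       outer(rep(1, a), mc) + m)^2)
  ss_res <- sum((Y - mgc[gi, ] - ms + as.vector(mg[grp]))^2)
  get <- function(eff, col) out[[col]][out$effect == eff]
  expect_equal(get("vote", "ss"), ss_group, tolerance = 1e-10)
  expect_equal(get("vote", "ss_error"), ss_subj, tolerance = 1e-10)
  expect_equal(get("w", "ss"), ss_cond, tolerance = 1e-10)
  expect_equal(get("vote:w", "ss"), ss_int, tolerance = 1e-10)
  expect_equal(get("w", "ss_error"), ss_res, tolerance = 1e-10)
  F_int <- (ss_int / ((a - 1) * (k - 1))) /
    (ss_res / ((a * n - a) * (k - 1)))
  expect_equal(get("vote:w", "F"), F_int, tolerance = 1e-10)
  # SS decomposition reconciles with the total
  strata_err <- unique(out[c("stratum", "ss_error")])$ss_error
  expect_equal(sum(out$ss) + sum(strata_err), attr(out, "ss_total"),
               tolerance = 1e-8)
  # partial eta squared in [0, 1] by construction
  expect_true(all(out$peta2 >= 0 & out$peta2 <= 1))
})

test_that("two-level within factors force epsilon = 1", {
  set.seed(5)
  d <- expand.grid(participant_id = sprintf("s%d", 1:6),
                   w = c("a", "b"), stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d))
  out <- mixed_anova(d, dv = "value", within = "w")
  expect_equal(out$epsilon[out$effect == "w"], 1)
})

test_that("epsilon is exactly 1 under a spherical contrast covariance", {
  # subjects built so the sample covariance of the orthonormal contrasts
  # is proportional to the identity
  Z <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)) * 2
  C <- erpvote:::orthonormal_contrasts(3)
  Y <- Z %*% t(C) + matrix(rnorm(4), 4, 1)[, rep(1, 3)]
  d <- data.frame(participant_id = rep(sprintf("s%d", 1:4), 3),
                  w = rep(c("l1", "l2", "l3"), each = 4),
                  value = as.vector(Y))
  out <- mixed_anova(d, dv = "value", within = "w")
  expect_equal(out$epsilon[out$effect == "w"], 1, tolerance = 1e-10)
  # and epsilon stays within its theoretical bounds on noisy data
  set.seed(9)
  d$value <- rnorm(nrow(d))
  out2 <- mixed_anova(d, dv = "value", within = "w")
  eps <- out2$epsilon[out2$effect == "w"]
  expect_gte(eps, 1 / 2)
  expect_lte(eps, 1)
})

test_that("ANOVA type-I error is calibrated under the null", {
  set.seed(77)
  n_rep <- 200
  p_int <- replicate(n_rep, {
    d <- expand.grid(participant_id = sprintf("s%d", 1:10),
                     item_type = item_types(), stringsAsFactors = FALSE)
    d$vote <- rep(c("m", "p"), each = 5)[
      as.integer(factor(d$participant_id))]
    d$value <- rnorm(nrow(d))
    out <- mixed_anova(d, dv = "value", between = "vote",
                       within = "item_type")
    out$p[out$effect == "vote:item_type"]
  })
  rate <- mean(p_int < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.10)
  # p-values approximately uniform
  expect_gt(suppressWarnings(ks.test(p_int, "punif"))$p.value, 0.01)
})

test_that("group label swaps leave the interaction F unchanged", {
  set.seed(31)
  spec <- small_spec(n_mainstream = 4, n_populist = 4, seed = 13)
  ds <- simulate_dataset(spec)
  avgs <- lapply(ds$eeg, function(r)
    average_conditions(baseline_correct(r$epochs), r$trials))
  n4 <- extract_n400(avgs)
  p <- ds$participants
  suite1 <- n400_hypothesis_suite(n4, p)
  p2 <- p
  p2$vote <- ifelse(p$vote == "mainstream", "populist", "mainstream")
  suite2 <- n400_hypothesis_suite(n4, p2)
  f1 <- suite1$by_dimension$economy
  f2 <- suite2$by_dimension$economy
  expect_equal(f1$F[f1$effect == "vote:item_type"],
               f2$F[f2$effect == "vote:item_type"], tolerance = 1e-10)
})

test_that("missing design cells are reported by name", {
  d <- expand.grid(participant_id = sprintf("s%d", 1:4),
                   w = c("a", "b"), stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d))
  d <- d[-1, ]
  expect_error(mixed_anova(d, dv = "value", within = "w"), "missing cell")
})

test_that("independent-samples t-tests report pooled-SD effect sizes", {
  set.seed(12)
  d <- data.frame(value = c(rnorm(20, 1), rnorm(25, 0)),
                  vote = rep(c("m", "p"), c(20, 25)),
                  dimension = "economy")
  tt <- group_ttests(d)
  ref <- t.test(value ~ vote, d, var.equal = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-12)
  sp <- sqrt((19 * var(d$value[d$vote == "m"]) +
                24 * var(d$value[d$vote == "p"])) / 43)
  expect_equal(tt$cohens_d,
               (mean(d$value[d$vote == "m"]) -
                  mean(d$value[d$vote == "p"])) / sp, tolerance = 1e-12)
  expect_equal(tt$p_bonferroni, pmin(1, tt$p * 1))
})
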