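# brute-force logistic log-likelihood for the metric oracles
loglik_logistic <- function(y, p) sum(y * log(p) + (1 - y) * log(1 - p))

toy_frame <- function(n = 30, beta = c(0, 1.2), seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  p <- plogis(beta[1] + beta[2] * x)
  data.frame(participant_id = sprintf("s%02d", 1:n),
             outcome = rbinom(n, 1, p),
             n400_economy = x, iat_d = rnorm(n), sri_economy = rnorm(n),
             age = round(age <- runif(n, 18, 55)), age2 = (age - mean(age))^2,
             gender = factor(sample(c("female", "male"), n, TRUE),
                             levels = c("female", "male")),
             interest_politics = sample(1:5, n, TRUE),
             left_right = sample(1:10, n, TRUE))
}

test_that("intercept-only fit equals the closed-form log-odds", {
  f <- data.frame(outcome = rep(c(0, 1), c(40, 29)))
  fit <- fit_logistic(f, character(0))
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(29 / 40),
               tolerance = 1e-8)
  expect_equal(fit$loglik_model, fit$loglik_null, tolerance = 1e-10)
})

test_that("logistic recovery: known generating model, n = 500", {
  set.seed(55)
  n <- 500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 0.9 * x))
  f <- data.frame(outcome = y, n400_economy = x)
  fit <- fit_logistic(f, "n400_economy", standardize = FALSE)
  b <- fit$coefficients["n400_economy"]
  se <- fit$se["n400_economy"]
  expect_lt(abs(b - 0.9), 2 * se)
})

test_that("model metrics match explicit likelihood and count arithmetic", {
  f <- toy_frame(20, seed = 7)
  fit <- fit_logistic(f, c("n400_economy", "sri_economy"),
                      standardize = FALSE)
  m <- model_metrics(fit)
  # independent metric computation from raw probabilities
  p_model <- fit$fitted
  p_null <- rep(mean(f$outcome), 20)
  ll1 <- loglik_logistic(f$outcome, p_model)
  ll0 <- loglik_logistic(f$outcome, p_null)
  expect_equal(fit$loglik_model, ll1, tolerance = 1e-8)
  expect_equal(fit$loglik_null, ll0, tolerance = 1e-8)
  expect_equal(m$mcfadden, 1 - ll1 / ll0, tolerance = 1e-8)
  expect_equal(m$nagelkerke,
               (1 - exp(2 * (ll0 - ll1) / 20)) / (1 - exp(2 * ll0 / 20)),
               tolerance = 1e-8)
  C <- sum((p_model > 0.5) == (f$outcome == 1))
  M <- max(table(f$outcome))
  expect_equal(m$lambda_adj, (C - M) / (20 - M), tolerance = 1e-12)
})

test_that("lambda is zero for modal-class prediction and one when perfect", {
  f <- data.frame(outcome = rep(c(0, 1), c(12, 8)), x = rnorm(20) * 1e-8)
  names(f)[2] <- "n400_economy"
  fit0 <- fit_logistic(f, character(0))
  expect_equal(model_metrics(fit0)$lambda_adj, 0)
  # a perfectly separable predictor is refused, not silently shrunk
  f2 <- data.frame(outcome = rep(c(0, 1), each = 10),
                   n400_economy = rep(c(-2, 2), each = 10))
  expect_error(fit_logistic(f2, "n400_economy"), "separation")
})

test_that("pseudo-R2s are invariant to affine predictor rescaling", {
  f <- toy_frame(40, seed = 9)
  fit_a <- fit_logistic(f, "n400_economy", standardize = FALSE)
  f2 <- transform(f, n400_economy = 3 * n400_economy - 5)
  fit_b <- fit_logistic(f2, "n400_economy", standardize = FALSE)
  expect_equal(model_metrics(fit_a)$mcfadden,
               model_metrics(fit_b)$mcfadden, tolerance = 1e-8)
  expect_equal(model_metrics(fit_a)$nagelkerke,
               model_metrics(fit_b)$nagelkerke, tolerance = 1e-8)
  expect_equal(model_metrics(fit_a)$lambda_adj,
               model_metrics(fit_b)$lambda_adj)
})

test_that("Wald equality test matches hand-specified covariance arithmetic", {
  f <- toy_frame(60, seed = 11)
  fit <- fit_logistic(f, c("n400_economy", "sri_economy"))
  w <- wald_equality(fit, "n400_economy", "sri_economy")
  V <- fit$vcov
  manual <- (fit$coefficients["n400_economy"] -
               fit$coefficients["sri_economy"])^2 /
    (V["n400_economy", "n400_economy"] + V["sri_economy", "sri_economy"] -
       2 * V["n400_economy", "sri_economy"])
  expect_equal(w$statistic, unname(manual), tolerance = 1e-10)
  expect_equal(w$p, pchisq(unname(manual), 1, lower.tail = FALSE))
  # identical coefficients give W = 0, p = 1
  mf <- structure(list(coefficients = c(a = 1.5, b = 1.5),
                       vcov = matrix(c(0.2, 0.05, 0.05, 0.3), 2, 2,
                                     dimnames = list(c("a", "b"),
                                                     c("a", "b")))),
                  class = "model_fit")
  w2 <- wald_equality(mf, "a", "b")
  expect_equal(w2$statistic, 0)
  expect_equal(w2$p, 1)
  # and a hand-specified covariance reproduces manual arithmetic
  mf$coefficients <- c(a = 2, b = 1)
  w3 <- wald_equality(mf, "a", "b")
  expect_equal(w3$statistic, 1 / (0.2 + 0.3 - 0.1), tolerance = 1e-12)
})

test_that("Wald equality rejects at the nominal rate under equal truth", {
  set.seed(71)
  rej <- replicate(200, {
    n <- 80
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.5 * x1 + 0.5 * x2))
    f <- data.frame(outcome = y, n400_economy = x1, sri_economy = x2)
    fit <- fit_logistic(f, c("n400_economy", "sri_economy"),
                        standardize = FALSE)
    wald_equality(fit, "n400_economy", "sri_economy")$p < 0.05
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})

test_that("noise predictors have calibrated coefficient coverage", {
  set.seed(13)
  cover <- replicate(200, {
    f <- data.frame(outcome = rbinom(40, 1, 0.5), n400_economy = rnorm(40))
    fit <- fit_logistic(f, "n400_economy", standardize = FALSE)
    abs(fit$coefficients["n400_economy"]) < 2 * fit$se["n400_economy"]
  })
  expect_gt(mean(cover), 0.88)
})

test_that("the predictor frame joins, drops, and logs correctly", {
  spec <- small_spec(n_mainstream = 4, n_populist = 4, seed = 17)
  set.seed(17)
  parts <- simulate_participants(spec)
  ids <- parts$participant_id
  nd <- data.frame(participant_id = ids, n400_diff = rnorm(8))
  dsc <- data.frame(participant_id = ids, d = rnorm(8))
  sri <- data.frame(participant_id = rep(ids, each = 3),
                    dimension = issue_dimensions(),
                    sri = rnorm(24), missing = FALSE)
  sri$missing[sri$participant_id == ids[2] &
                sri$dimension == "economy"] <- TRUE
  frame <- build_predictors(nd, dsc, sri, parts)
  expect_equal(nrow(frame), 7)
  expect_true(ids[2] %in% attr(frame, "dropped")$participant_id)
  expect_true(grepl("sri", attr(frame, "dropped")$missing[1]))
  # join order-independence
  frame2 <- build_predictors(nd[sample(8), ], dsc[sample(8), ],
                             sri[sample(24), ], parts[sample(8), ])
  expect_equal(frame, frame2, ignore_attr = TRUE)
  # age squared computed from centered age
  expect_equal(frame$age2, (frame$age - mean(frame$age))^2)
})

test_that("the six-model suite keeps rows fixed and nests likelihoods", {
  f <- toy_frame(50, seed = 23)
  f$sri_economy <- f$sri_economy + f$outcome       # informative
  suite <- run_model_suite(f)
  expect_equal(unique(suite$metrics$n_obs), 50)
  expect_equal(suite$metrics$model, paste0("m", 1:6))
  ll <- suite$metrics$loglik
  mcf <- suite$metrics$mcfadden
  # nesting: m4 contains m1 and m3; m6 contains m4
  expect_gte(ll[4] + 1e-10, ll[1]); expect_gte(ll[4] + 1e-10, ll[3])
  expect_gte(ll[6] + 1e-10, ll[4])
  expect_gte(mcf[4] + 1e-10, max(mcf[1], mcf[3]))
  expect_error(run_model_suite(f[setdiff(names(f), "iat_d")]),
               "iat_d")
})
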