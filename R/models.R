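#' Assemble the predictor frame for the voting models
#'
#' Joins the EEG differential, the IAT D score, the economy SRI and the
#' demographic covariates on participant, restricted to the final voter
#' sample, and drops incomplete cases with a logged reason. Age squared is
#' computed from centered age.
#'
#' @param n400_diff Table from [n400_differential()].
#' @param dscores Table from [compute_d()] (or `NULL` if no IAT was run).
#' @param sri Table from [compute_sri()].
#' @param participants Participant table.
#' @return A data.frame of complete cases with columns `participant_id`,
#'   `outcome` (0 mainstream, 1 populist), `n400_economy`, `iat_d`,
#'   `sri_economy`, `age`, `age2`, `gender`, `interest_politics`,
#'   `left_right`; attribute `dropped` logs removed participants.
#' @export
build_predictors <- function(n400_diff, dscores, sri, participants) {
  p <- participants[participants$vote %in% c("mainstream", "populist"),
                    c("participant_id", "vote", "age", "gender",
                      "left_right", "interest_politics")]
  p$outcome <- as.integer(p$vote == "populist")
  sri_eco <- sri[sri$dimension == "economy" & !sri$missing,
                 c("participant_id", "sri")]
  names(sri_eco)[2L] <- "sri_economy"
  nd <- n400_diff
  names(nd)[names(nd) == "n400_diff"] <- "n400_economy"
  frame <- merge(p, nd, by = "participant_id", all.x = TRUE)
  frame <- merge(frame, sri_eco, by = "participant_id", all.x = TRUE)
  if (!is.null(dscores)) {
    dd <- dscores[c("participant_id", "d")]
    names(dd)[2L] <- "iat_d"
    frame <- merge(frame, dd, by = "participant_id", all.x = TRUE)
  } else frame$iat_d <- NA_real_
  frame$gender <- factor(frame$gender, levels = c("female", "male"))
  vars <- c("n400_economy", "sri_economy", "age",
            "gender", "interest_politics", "left_right")
  if (!is.null(dscores)) vars <- append(vars, "iat_d", after = 1L)
  complete <- stats::complete.cases(frame[vars])
  dropped <- frame$participant_id[!complete]
  reasons <- vapply(which(!complete), function(i) {
    paste(vars[is.na(frame[i, vars])], collapse = ","); }, "")
  out <- frame[complete, c("participant_id", "outcome", "n400_economy",
                           "iat_d", "sri_economy", "age", "gender",
                           "interest_politics", "left_right")]
  out <- out[order(out$participant_id), ]
  # age squared from age centered on the analyzed sample
  out$age2 <- (out$age - mean(out$age))^2
  out <- out[c("participant_id", "outcome", "n400_economy", "iat_d",
               "sri_economy", "age", "age2", "gender",
               "interest_politics", "left_right")]
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(participant_id = dropped,
                                     missing = reasons,
                                     stringsAsFactors = FALSE)
  out
}

#' Fit one logistic voting model
#'
#' Maximum-likelihood logistic regression of voting choice (populist = 1)
#' on the named predictors, with the intercept-only null model fitted on
#' the same rows. Numeric predictors are z-scored by default so that
#' coefficients of different-unit predictors are comparable in Wald tests.
#' Perfect separation is detected and raised as an error rather than
#' silently penalized.
#'
#' @param frame Predictor frame from [build_predictors()].
#' @param predictors Character vector of predictor column names; empty for
#'   the intercept-only model.
#' @param standardize Z-score numeric predictors before fitting?
#' @return A list of class `model_fit`: `coefficients`, `se`, `vcov`,
#'   `loglik_model`, `loglik_null`, `n_obs`, `predictors`, `standardized`,
#'   `fitted`, `glm`.
#' @export
fit_logistic <- function(frame, predictors, standardize = TRUE) {
  miss <- setdiff(predictors, names(frame))
  if (length(miss))
    stop("missing predictor column(s): ", paste(miss, collapse = ", "))
  if (length(unique(frame$outcome)) != 2L)
    stop("outcome must contain both classes")
  d <- frame
  if (standardize) {
    for (v in predictors)
      if (is.numeric(d[[v]])) {
        s <- stats::sd(d[[v]])
        d[[v]] <- if (is.finite(s) && s > 0)
          (d[[v]] - mean(d[[v]])) / s else d[[v]] - mean(d[[v]])
      }
  }
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fit <- stats::glm(stats::as.formula(paste("outcome ~", rhs)),
                    family = stats::binomial(), data = d)
  if (!fit$converged) stop("logistic fit did not converge")
  mu <- stats::fitted(fit)
  if (length(predictors) && (any(mu > 1 - 1e-8) || any(mu < 1e-8)))
    stop("perfect separation detected; consider penalized estimation")
  null <- stats::glm(outcome ~ 1, family = stats::binomial(), data = d)
  structure(list(
    coefficients = stats::coef(fit),
    se = sqrt(diag(stats::vcov(fit))),
    vcov = stats::vcov(fit),
    loglik_model = as.numeric(stats::logLik(fit)),
    loglik_null = as.numeric(stats::logLik(null)),
    n_obs = nrow(d), predictors = predictors,
    standardized = standardize, fitted = mu, outcome = d$outcome,
    glm = fit), class = "model_fit")
}

#' Goodness-of-fit and classification metrics for a voting model
#'
#' McFadden pseudo-R2 `1 - l_model / l_null`; Nagelkerke pseudo-R2
#' `(1 - exp(2 (l_null - l_model) / n)) / (1 - exp(2 l_null / n))`; and
#' lambda, the adjusted correctly-predicted count
#' `(C - M) / (n - M)` where C is the count classified correctly at
#' probability threshold 0.5 and M the modal-class count: the proportional
#' reduction in classification error relative to always predicting the
#' modal class.
#'
#' @param fit A `model_fit` from [fit_logistic()].
#' @return A list: `mcfadden`, `nagelkerke`, `lambda_adj`, `n_correct`,
#'   `n_modal`, `n_obs`.
#' @export
model_metrics <- function(fit) {
  n <- fit$n_obs
  ll1 <- fit$loglik_model; ll0 <- fit$loglik_null
  mcfadden <- 1 - ll1 / ll0
  nagelkerke <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  pred <- as.integer(fit$fitted > 0.5)
  C <- sum(pred == fit$outcome)
  M <- max(table(fit$outcome))
  list(mcfadden = mcfadden, nagelkerke = nagelkerke,
       lambda_adj = (C - M) / (n - M), n_correct = C, n_modal = M,
       n_obs = n)
}

#' Wald test of the equality of two coefficients
#'
#' `W = (b_a - b_b)^2 / (var_a + var_b - 2 cov_ab)`, compared to
#' chi-squared with one df.
#'
#' @param fit A `model_fit`.
#' @param coef_a,coef_b Names of the two coefficients.
#' @return A list: `statistic`, `p`, `difference`.
#' @export
wald_equality <- function(fit, coef_a, coef_b) {
  b <- fit$coefficients
  if (!all(c(coef_a, coef_b) %in% names(b)))
    stop("both coefficients must be in the fitted model")
  V <- fit$vcov
  dvar <- V[coef_a, coef_a] + V[coef_b, coef_b] - 2 * V[coef_a, coef_b]
  W <- (b[coef_a] - b[coef_b])^2 / dvar
  list(statistic = unname(W),
       p = stats::pchisq(unname(W), 1, lower.tail = FALSE),
       difference = unname(b[coef_a] - b[coef_b]))
}

#' The six-model comparison of voting predictors
#'
#' Model 1: EEG differential only; 2: IAT D only; 3: economy SRI only;
#' 4: EEG + SRI; 5: demographics (age, age squared, gender, interest in
#' politics, left-right self-placement); 6: all predictors. All models are
#' fitted on the identical complete-case rows.
#'
#' @param frame Predictor frame from [build_predictors()].
#' @param standardize Z-score numeric predictors?
#' @param include_iat Fit the IAT-dependent models (2 and 6)? Set `FALSE`
#'   for datasets without an IAT table.
#' @return A list of class `model_suite`: `fits` (list of `model_fit`),
#'   `metrics` (data.frame, one row per model), `wald_n400_sri` (equality
#'   test of the two predictors in Model 4).
#' @export
run_model_suite <- function(frame, standardize = TRUE,
                            include_iat = TRUE) {
  specs <- list(
    m1 = "n400_economy",
    m2 = "iat_d",
    m3 = "sri_economy",
    m4 = c("n400_economy", "sri_economy"),
    m5 = c("age", "age2", "gender", "interest_politics", "left_right"),
    m6 = c("n400_economy", "iat_d", "sri_economy", "age", "age2",
           "gender", "interest_politics", "left_right"))
  if (!include_iat) specs <- specs[c("m1", "m3", "m4", "m5")]
  needed <- unique(unlist(specs))
  miss <- setdiff(needed, names(frame))
  if (length(miss))
    stop("missing predictor column(s): ", paste(miss, collapse = ", "))
  # a model that separates perfectly is recorded as failed (with the
  # reason) rather than silently penalized or aborting its siblings
  fits <- lapply(specs, function(pred)
    tryCatch(fit_logistic(frame, pred, standardize = standardize),
             error = function(e)
               structure(list(error = conditionMessage(e)),
                         class = "model_fit_failure")))
  metrics <- do.call(rbind, lapply(seq_along(fits), function(i) {
    if (inherits(fits[[i]], "model_fit_failure"))
      return(data.frame(model = names(specs)[i],
                        predictors = paste(specs[[i]], collapse = "+"),
                        loglik = NA_real_, mcfadden = NA_real_,
                        nagelkerke = NA_real_, lambda_adj = NA_real_,
                        n_obs = NA_integer_, note = fits[[i]]$error,
                        stringsAsFactors = FALSE))
    m <- model_metrics(fits[[i]])
    data.frame(model = names(specs)[i],
               predictors = paste(specs[[i]], collapse = "+"),
               loglik = fits[[i]]$loglik_model,
               mcfadden = m$mcfadden, nagelkerke = m$nagelkerke,
               lambda_adj = m$lambda_adj, n_obs = m$n_obs, note = "",
               stringsAsFactors = FALSE)
  }))
  wald <- if (inherits(fits$m4, "model_fit_failure")) {
    warning("model 4 failed (", fits$m4$error,
            "); coefficient-equality test unavailable")
    NULL
  } else wald_equality(fits$m4, "n400_economy", "sri_economy")
  structure(list(fits = fits, metrics = metrics, wald_n400_sri = wald),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("<model_suite> six logistic voting models\n")
  print(x$metrics, row.names = FALSE)
  if (!is.null(x$wald_n400_sri))
    cat(sprintf("Wald equality (EEG vs SRI in m4): W = %.3f, p = %.3f\n",
                x$wald_n400_sri$statistic, x$wald_n400_sri$p))
  invisible(x)
}
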