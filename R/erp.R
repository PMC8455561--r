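#' Average epochs into condition ERPs
#'
#' Arithmetic mean over artifact-free trials per dimension x item-type
#' cell. Cells with zero usable trials are absent from the result, never
#' zero-filled.
#'
#' @param e An [epoch_array()] (preprocessed).
#' @param trials Matching trial table with artifact flags.
#' @return A list of class `erp_averages`: `participant_id`, `channels`,
#'   `times`, and `cells`, a named list (`"<dimension>|<item_type>"`) of
#'   `list(waveform = channels x times matrix, n = trials averaged)`.
#' @export
average_conditions <- function(e, trials) {
  stopifnot(inherits(e, "epoch_array"))
  trials <- validate_trials(trials)
  if (nrow(trials) != n_trials(e))
    stop("alignment error: trial table does not match epochs")
  cells <- list()
  for (dm in issue_dimensions()) {
    for (it in item_types()) {
      idx <- which(trials$dimension == dm & trials$item_type == it &
                     !trials$artifact)
      if (!length(idx)) next
      wf <- rowMeans(e$data[, , idx, drop = FALSE], dims = 2L)
      cells[[paste(dm, it, sep = "|")]] <- list(waveform = wf,
                                                n = length(idx))
    }
  }
  structure(list(participant_id = e$participant_id, channels = e$channels,
                 times = e$times, cells = cells),
            class = "erp_averages")
}

#' Extract N400 window amplitudes
#'
#' Time-mean amplitude over the half-open N400 window for each condition
#' cell and each posterior electrode.
#'
#' @param avgs One `erp_averages` object or a list of them (cohort).
#' @param config An [analysis_config()].
#' @return A data.frame: participant_id, dimension, item_type, electrode,
#'   amplitude (microvolts).
#' @export
extract_n400 <- function(avgs, config = analysis_config()) {
  if (inherits(avgs, "erp_averages")) avgs <- list(avgs)
  out <- lapply(avgs, function(a) {
    sel_t <- a$times >= config$n400_window[1L] &
      a$times < config$n400_window[2L]
    if (!any(sel_t)) stop("N400 window outside epoch span")
    miss <- setdiff(config$n400_channels, a$channels)
    if (length(miss))
      stop("channels absent from data: ", paste(miss, collapse = ", "))
    sel_c <- match(config$n400_channels, a$channels)
    rows <- lapply(names(a$cells), function(key) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
      amp <- rowMeans(a$cells[[key]]$waveform[sel_c, sel_t, drop = FALSE])
      data.frame(participant_id = a$participant_id, dimension = parts[1L],
                 item_type = parts[2L], electrode = config$n400_channels,
                 amplitude = amp, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-participant N400 differential score at POz
#'
#' The averaged differential amplitude between populist and non-populist
#' items for the economy dimension at POz (populist minus non-populist);
#' the EEG predictor entering the voting models.
#'
#' @param n400 Table from [extract_n400()].
#' @param dimension Issue dimension of the differential.
#' @param electrode Electrode of the differential.
#' @return data.frame: participant_id, n400_diff.
#' @export
n400_differential <- function(n400, dimension = "economy",
                              electrode = "POz") {
  sub <- n400[n400$dimension == dimension & n400$electrode == electrode, ]
  pop <- sub[sub$item_type == "populist", c("participant_id", "amplitude")]
  non <- sub[sub$item_type == "non_populist", c("participant_id", "amplitude")]
  m <- merge(pop, non, by = "participant_id", suffixes = c("_pop", "_non"))
  data.frame(participant_id = m$participant_id,
             n400_diff = m$amplitude_pop - m$amplitude_non,
             stringsAsFactors = FALSE)
}

# orthonormal contrasts spanning the complement of the unit vector
orthonormal_contrasts <- function(k) {
  m <- stats::contr.helmert(k)
  m / rep(sqrt(colSums(m^2)), each = k)
}

#' Mixed-design ANOVA with Greenhouse-Geisser correction
#'
#' Classical sums-of-squares decomposition for a fully balanced
#' split-plot design: one optional between-subjects factor and any number
#' of crossed within-subjects factors. For every effect involving a
#' within-subjects part with two or more numerator df, the
#' Greenhouse-Geisser epsilon is computed from the pooled covariance of the
#' orthonormalized within-subject contrasts,
#' `epsilon = tr(S)^2 / (m * tr(S %*% S))`, and Mauchly's test decides
#' whether the corrected p-value is the one to report.
#'
#' @param data Long-format data.frame, one row per subject x within-cell.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject-identifier column.
#' @param between Optional name of the between-subjects factor column.
#' @param within Character vector of within-subjects factor columns.
#' @return A data.frame of class `anova_table`, one row per effect:
#'   `effect`, `df1`, `df2`, `ss`, `ss_error`, `F`, `p_uncorrected`,
#'   `epsilon`, `mauchly_p`, `sphericity_violated`, `p` (GG-corrected when
#'   sphericity is violated), `peta2`.
#' @export
mixed_anova <- function(data, dv = "value", subject = "participant_id",
                        between = NULL, within = character(0)) {
  stopifnot(length(within) >= 1L)
  data <- as.data.frame(data)
  for (f in c(subject, between, within)) data[[f]] <- factor(data[[f]])
  data$.dv <- data[[dv]]

  # balance checks: every subject must have exactly one row per within cell
  tab <- table(data[c(subject, within)])
  if (any(tab == 0L)) {
    idx <- which(tab == 0L, arr.ind = TRUE)[1L, , drop = TRUE]
    nm <- mapply(function(d, i) dimnames(tab)[[d]][i],
                 seq_along(idx), idx)
    stop("missing cell: ", paste(names(dimnames(tab)), nm, sep = "=",
                                 collapse = ", "))
  }
  if (any(tab > 1L))
    stop("design not balanced: multiple observations per subject x cell; ",
         "aggregate first")
  if (!is.null(between)) {
    g <- unique(data[c(subject, between)])
    if (anyDuplicated(g[[subject]]))
      stop("subjects must belong to exactly one between-group")
    n_groups <- nlevels(g[[between]])
    if (min(table(g[[between]])) < 2L)
      stop("need >= 2 subjects per group")
  } else {
    n_groups <- 1L
  }

  within_rhs <- paste(within, collapse = "*")
  fixed <- if (is.null(between)) within_rhs else
    paste(between, within_rhs, sep = "*")
  form <- stats::as.formula(sprintf(".dv ~ %s + Error(%s/(%s))",
                                    fixed, subject, within_rhs))
  fit <- stats::aov(form, data = data)
  sm <- summary(fit)

  rows <- list()
  for (stratum in names(sm)) {
    st <- sm[[stratum]][[1L]]
    terms <- trimws(rownames(st))
    resid_i <- which(terms == "Residuals")
    if (!length(resid_i)) next
    ss_err <- st[resid_i, "Sum Sq"]
    df_err <- st[resid_i, "Df"]
    for (i in setdiff(seq_len(nrow(st)), resid_i)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = terms[i], stratum = stratum, df1 = st[i, "Df"],
        df2 = df_err, ss = st[i, "Sum Sq"], ss_error = ss_err,
        F = st[i, "F value"], p_uncorrected = st[i, "Pr(>F)"],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)

  # Greenhouse-Geisser epsilon + Mauchly per within-part
  Yinfo <- subject_cell_matrix(data, dv = ".dv", subject = subject,
                               between = between, within = within)
  eps <- rep(NA_real_, nrow(out))
  mau <- rep(NA_real_, nrow(out))
  for (i in seq_len(nrow(out))) {
    fac <- strsplit(out$effect[i], ":", fixed = TRUE)[[1L]]
    wpart <- intersect(within, fac)
    if (!length(wpart)) next
    sph <- sphericity_stats(Yinfo, wpart)
    eps[i] <- sph$epsilon
    mau[i] <- sph$mauchly_p
  }
  out$epsilon <- eps
  out$mauchly_p <- mau
  out$sphericity_violated <- !is.na(mau) & mau < 0.05
  out$p <- ifelse(out$sphericity_violated,
                  stats::pf(out$F, out$epsilon * out$df1,
                            out$epsilon * out$df2, lower.tail = FALSE),
                  out$p_uncorrected)
  out$peta2 <- out$ss / (out$ss + out$ss_error)
  attr(out, "ss_total") <- sum((data$.dv - mean(data$.dv))^2)
  class(out) <- c("anova_table", "data.frame")
  out
}

# subjects x within-cells matrix (cells in expand.grid order over `within`,
# first factor fastest) plus the group assignment
subject_cell_matrix <- function(data, dv, subject, between, within) {
  cells <- do.call(expand.grid, c(lapply(data[within], levels),
                                  stringsAsFactors = FALSE))
  key <- interaction(data[within], drop = FALSE, lex.order = FALSE)
  cell_key <- interaction(cells, drop = FALSE, lex.order = FALSE)
  subj <- levels(data[[subject]])
  Y <- matrix(NA_real_, length(subj), nrow(cells),
              dimnames = list(subj, as.character(cell_key)))
  Y[cbind(as.integer(data[[subject]]),
          match(as.character(key), as.character(cell_key)))] <- data[[dv]]
  grp <- if (is.null(between)) factor(rep("all", length(subj))) else {
    g <- unique(data[c(subject, between)])
    factor(g[[between]][match(subj, as.character(g[[subject]]))])
  }
  k <- vapply(data[within], nlevels, 1L)
  list(Y = Y, group = grp, k = k, within = within)
}

# epsilon and Mauchly p for the effect spanned by `wpart`
sphericity_stats <- function(Yinfo, wpart) {
  mats <- lapply(Yinfo$within, function(f) {
    k <- Yinfo$k[[f]]
    if (f %in% wpart) orthonormal_contrasts(k)
    else matrix(1 / sqrt(k), k, 1L)
  })
  # cells are ordered first-factor-fastest; kronecker makes the *last*
  # operand's index fastest, so reverse
  C <- Reduce(kronecker, rev(mats))
  m <- ncol(C)
  if (m == 1L) return(list(epsilon = 1, mauchly_p = NA_real_))
  U <- Yinfo$Y %*% C
  gchr <- as.character(Yinfo$group)
  gmeans <- rowsum(U, gchr) / as.vector(table(gchr))
  centered <- U - gmeans[gchr, , drop = FALSE]
  n_resid <- nrow(U) - nlevels(Yinfo$group)
  S <- crossprod(centered) / n_resid
  tr <- sum(diag(S))
  eps <- tr^2 / (m * sum(S * S))
  # Mauchly's W with Box's chi-square approximation
  detS <- det(S)
  mau_p <- NA_real_
  if (detS > 0 && n_resid > m) {
    W <- detS / (tr / m)^m
    f <- n_resid - (2 * m^2 + m + 2) / (6 * m)
    x2 <- -f * log(W)
    mau_p <- stats::pchisq(x2, m * (m + 1) / 2 - 1, lower.tail = FALSE)
  }
  list(epsilon = eps, mauchly_p = mau_p)
}

#' Independent-samples t-tests with Bonferroni correction and Cohen's d
#'
#' One two-sample t-test (pooled variance) per stratum of `by`, Bonferroni
#' correction across strata, and Cohen's d from the pooled SD.
#'
#' @param data data.frame with the score, group and stratum columns.
#' @param dv,group,by Column names.
#' @return data.frame: stratum, n1, n2, t, df, p, p_bonferroni, cohens_d.
#' @export
group_ttests <- function(data, dv = "value", group = "vote", by = "dimension") {
  strata <- unique(data[[by]])
  rows <- lapply(strata, function(s) {
    d <- data[data[[by]] == s & !is.na(data[[dv]]), ]
    gs <- sort(unique(as.character(d[[group]])))
    stopifnot(length(gs) == 2L)
    x <- d[[dv]][d[[group]] == gs[1L]]
    y <- d[[dv]][d[[group]] == gs[2L]]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    data.frame(stratum = s, n1 = length(x), n2 = length(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               cohens_d = (mean(x) - mean(y)) / sp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' The N400 congruency hypothesis suite
#'
#' Omnibus mixed ANOVA (Voting Behavior x Item Type x Issue Dimension x
#' Electrode), per-dimension follow-up ANOVAs (Voting Behavior x Item Type
#' on electrode-averaged amplitudes), and per-group follow-ups (Item Type
#' main effect) for the dimension showing the interaction.
#'
#' @param n400 Table from [extract_n400()], restricted to retained
#'   participants.
#' @param participants Participant table supplying the vote group.
#' @param followup_dimension Dimension for the per-group follow-ups.
#' @return A list: `omnibus`, `by_dimension` (named list of anova tables),
#'   `by_group` (named list, Item Type main effect per voter group).
#' @export
n400_hypothesis_suite <- function(n400, participants,
                                  followup_dimension = "economy") {
  d <- merge(n400, participants[c("participant_id", "vote")],
             by = "participant_id")
  omnibus <- mixed_anova(d, dv = "amplitude", between = "vote",
                         within = c("item_type", "dimension", "electrode"))
  elec_avg <- stats::aggregate(amplitude ~ participant_id + vote +
                                 dimension + item_type, d, mean)
  by_dimension <- lapply(issue_dimensions(), function(dm) {
    mixed_anova(elec_avg[elec_avg$dimension == dm, ], dv = "amplitude",
                between = "vote", within = "item_type")
  })
  names(by_dimension) <- issue_dimensions()
  groups <- sort(unique(elec_avg$vote))
  by_group <- lapply(groups, function(g) {
    mixed_anova(elec_avg[elec_avg$dimension == followup_dimension &
                           elec_avg$vote == g, ],
                dv = "amplitude", within = "item_type")
  })
  names(by_group) <- groups
  list(omnibus = omnibus, by_dimension = by_dimension, by_group = by_group)
}
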