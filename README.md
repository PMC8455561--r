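# erpvote

EEG decoding and behavioral statistics for pre-electoral attitude
studies.

## What this package is for

Pre-electoral EEG studies present survey items expressing populist or
non-populist views while recording event-related potentials (ERPs)
time-locked to the item's final, politically decisive word, and later ask
participants how they actually voted. `erpvote` implements the complete
analysis chain such a study needs, as tested, reusable R functions:

- **Self-report index (SRI).** A Kelley-style agreement index per issue
  dimension:
  `SRI = (% populist items agreed + % non-populist items disagreed) −
  (% populist items disagreed + % non-populist items agreed)`,
  with percentages over answered items of each type (range −200 to 200),
  plus response-time trimming and the mixed ANOVA / t-test family around
  it.
- **N400 congruency analysis.** Condition averaging, mean amplitudes in
  the 300–600 ms window over 12 posterior electrodes (CP1–4, P1–4, Pz,
  PO3/4, POz), and mixed-design ANOVAs (between: voting group; within:
  item type × issue dimension × electrode) with Greenhouse–Geisser
  correction (ε from orthonormalized contrast covariances, Mauchly-gated)
  and partial η².
- **Sliding-window multivariate decoding.** Linear SVM (C = 1) on
  spatio-temporal voltage patterns in non-overlapping 10 ms windows
  (e.g. 20 time points × 61 channels = 1220 features at 2048 Hz), with
  class balancing by undersampling, 10×10-fold cross-validation, an
  empirical shuffled-label chance distribution, per-window paired t-tests
  against chance, and cluster-mass permutation correction (clusters of
  ≥ 2 consecutive windows, sign-flip null, Bonferroni across the three
  issue dimensions).
- **IAT D score.** Improved-algorithm scoring of a 7-block Implicit
  Association Test: deletion of latencies > 10,000 ms, pooled
  ("inclusive") SDs for combined blocks 3∪6 and 4∪7,
  `D = ((M6−M3)/SD36 + (M7−M4)/SD47) / 2`, and Spearman–Brown adjusted
  split-half reliability.
- **Voting-choice model comparison.** Six logistic models (EEG
  differential, IAT, SRI, EEG+SRI, demographics, pooled) on identical
  complete-case rows, with McFadden and Nagelkerke pseudo-R², λ (the
  proportional reduction in classification error over always predicting
  the modal class), and a Wald test of coefficient equality.
- **Synthetic-data generator.** Every stage is testable without any
  recording: the generator emulates 61-channel epochs (−100…1200 ms
  around the critical word), 126 survey items (3 dimensions × 2 item
  types × 21), a group-dependent N400-window congruency effect for
  economy items, a late effect for culture items, polarized agreement for
  economy/culture but not anti-establishment, and IAT latencies whose
  compatibility shift is independent of voting group.

## Worked example

```r
library(erpvote)

spec <- simulation_spec(n_channels = 16, sfreq = 128, seed = 42)
ds   <- simulate_dataset(spec)                # 82-participant roster
excl <- apply_exclusions(ds$participants, ds$trials)
length(excl$vote_retained)                    # 69
length(excl$mvpa_retained)                    # 67

avgs <- lapply(ds$eeg[excl$erp_retained], function(r)
  average_conditions(baseline_correct(r$epochs), r$trials))
n4    <- extract_n400(avgs)
suite <- n400_hypothesis_suite(n4, ds$participants)
subset(suite$by_dimension$economy, effect == "vote:item_type",
       c(effect, F, p, peta2))
#>           effect        F            p    peta2
#> 3 vote:item_type 74.05409 2.462195e-12 0.532556

frame <- build_predictors(n400_differential(n4), compute_d(ds$iat),
                          compute_sri(ds$trials), ds$participants)
run_model_suite(frame)$metrics[, c("model", "mcfadden", "lambda_adj")]
#>   model   mcfadden lambda_adj
#> 1    m1 0.46346255  0.6428571
#> 2    m2 0.00074972  0.0000000
#> 3    m3 0.29759127  0.4285714
#> 4    m4 0.76075896  0.8214286
#> 5    m5 0.25442111  0.4642857
#> 6    m6 0.84207273  0.8928571
```

The economy-dimension Voting Behavior × Item Type interaction is the
N400 congruency signature: survey items that contradict a participant's
future vote elicit a more negative posterior potential. In the model
table, λ of the combined EEG + self-report model (m4) exceeds either
predictor alone, while the IAT-only model (m2) adds essentially nothing
— the qualitative pattern the chain is designed to measure.

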