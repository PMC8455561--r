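---
title: "Models, parameters and design choices in erpvote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in erpvote}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`erpvote` implements the analysis chain of a pre-electoral EEG study in
which participants judge survey items expressing populist or
non-populist views while their EEG is recorded, and are later asked how
they voted. This vignette explains the statistical machinery, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the places where the design was genuinely open and a
choice had to be made.

## The data model

Epoched EEG is held as a `channels × times × trials` array of microvolt
values with an explicit time axis in milliseconds, zero at the onset of
the item's final ("critical") word; the default epoch spans −100 to
1200 ms. Windows throughout the package are half-open `[start, stop)`
intervals in ms, which makes the 10 ms non-overlapping tiling of the
decoding stage unambiguous. Trial metadata (issue dimension ∈
{anti-establishment, economy, culture}, item type ∈ {populist,
non-populist}, agreement, response time, artifact flag) aligns 1:1 with
the trial axis. The on-disk container is a raw little-endian float64
array plus a JSON sidecar and a TSV trial table — deliberately
language-neutral and diffable.

## Preprocessing

The zero-phase band-pass (default 0.1–30 Hz) is realized by applying the
two-pass (squared) Butterworth magnitude response in the frequency
domain to demeaned, reflection-padded traces. This has the same transfer
magnitude as forward–backward IIR filtering, removes DC exactly, avoids
edge transients on epochs that are short relative to the 0.1 Hz time
constant, and vectorizes over all channels and trials at once. The
attenuation contract — at least 20 dB one octave beyond each edge — is
what the tests pin down; the realization is an implementation detail.

Average-reference re-referencing and baseline correction (mean over
[−100, 0) ms per channel and trial) are exact linear operations.
Artifact rejection flags a trial when any sample on any channel exceeds
±100 µV. Ocular-artifact correction by ICA is out of scope: the
synthetic data contain no ocular components, and no numeric criterion
for the post-ICA epoch scrutiny exists to reimplement; the amplitude
threshold stands in for it as a documented, configurable rule.

Exclusion bookkeeping happens in four logged stages: vote filter
(participants who voted for unclassifiable parties, did not vote, or
returned a blank ballot are removed), a ≥ 14 artifact-free-epochs rule
per condition cell for the ERP analyses, a ≥ 20-trials rule per
dimension × item-type cell for the decoding analyses, and a
responses-present rule for the behavioral analyses. "Relevant
conditions" for the 14-epoch rule is interpreted as each dimension ×
item-type cell, matching the cells the ERP analysis averages. One
source-data inconsistency is worth recording: the study's collected
counts (41 mainstream + 28 populist) and final counts (40 + 29) cannot
both be right; the generator trusts the final counts, which every
downstream number depends on.

## N400 analysis and the mixed ANOVA

Mean amplitudes are extracted over [300, 600) ms at 12 posterior
electrodes and analyzed with a split-plot ANOVA: voting group between
subjects; item type (2) × issue dimension (3) × electrode (12) within.
The implementation takes sums of squares from the classical `aov` error
strata. For every effect with a within-subjects part of two or more
numerator df, the Greenhouse–Geisser ε is computed from the pooled
covariance `S` of the orthonormalized within-subject contrasts,
`ε = tr(S)² / (m · tr(S²))`, and Mauchly's test (Box's χ² approximation)
at α = 0.05 decides whether the GG-corrected p is the one reported —
matching the convention of applying the correction only when sphericity
is violated, while always reporting ε. Partial η² is
`SS_effect / (SS_effect + SS_error)` from the effect's own stratum; with
one between factor and balanced within cells the sum-of-squares types
coincide. Follow-ups per dimension use electrode-averaged amplitudes
(the interaction df are identical either way); follow-ups per voter
group test the item-type main effect. Cohen's d for two-sample t-tests
uses the pooled SD.

## Sliding-window decoding

For each participant and dimension, every 10 ms window contributes a
trials × features matrix (channel-blocked concatenation of the
`floor(width · sfreq / 1000)` samples aligned to the window start — the
floor rule, not the raw half-open sample count, so that 2048 Hz × 61
channels gives exactly 1220 features regardless of grid phase). A
linear SVM with fixed C = 1 (LIBSVM via `e1071`, no feature scaling —
all features share µV units) is trained in a stratified k-fold
cross-validation, repeated with fresh random fold allocations; the
majority class is undersampled to parity before every repeat. Empirical
chance is the same procedure run with shuffled labels; the number of
shuffled reruns per window is a configurable parameter (default 10)
because the source procedure does not state it — the mean over reruns is
used.

Group statistics: per window, a paired one-tailed t-test of real versus
chance accuracy across participants (one-tailed because only
above-chance decoding is meaningful; the paired-with-sign-flip
construction is the standard one consistent with testing against an
empirical chance distribution). Candidate clusters are runs of at least
two consecutive windows with p < 0.05; the cluster mass is the summed t;
the null distribution is the maximum cluster mass over permutations in
which each participant's (real, chance) pair is independently swapped
(vectorized sign-flip algebra — the per-window sum of squares is
flip-invariant, so all permutation t values come from one matrix
product). The corrected p uses the add-one convention
`(1 + #{null ≥ observed}) / (1 + n_perm)`, and a family-level Bonferroni
across the three dimensions is applied by default. A sanity rerun at
20 ms windows reports cluster overlap between window sizes.

## Behavioral indices

The SRI percentages use the answered items of each item type as
denominator, giving the [−200, 200] range of the Kelley-index tradition;
the published formula is ambiguous on this point and the per-type
reading is the one under which "agree with everything" scores exactly 0.
RT condition means are computed after removing trials slower than
2700 ms; the data-derived `mean + 2 SD` cutoff is reported alongside the
fixed default. IAT D-scoring deletes latencies above 10,000 ms, computes
the *inclusive* SD as the sample SD of the pooled pair latencies
(blocks 3∪6 and 4∪7 — the improved-algorithm reading of "inclusive"),
divides each combined-block mean difference by its pair SD and averages
the two ratios. No error-latency penalties are applied because the
source procedure describes none. Split-half reliability correlates the
two pair scores and applies Spearman–Brown, `r_sb = 2r / (1 + r)`.

## Voting models

Six logistic regressions on identical complete-case rows: EEG
differential (economy, POz) only; IAT D only; economy SRI only;
EEG + SRI; demographics (age, age², gender, interest in politics,
left–right self-placement); and all predictors. Numeric predictors are
z-scored by default — the source table is silent on scaling, and
standardization is what makes a Wald equality test of a µV-scaled and an
index-scaled coefficient meaningful; raw-scale fitting is available by
flag. Age² is computed from age centered on the analyzed sample
(collinearity hygiene, documented since the source is silent). λ uses
classification threshold 0.5 — the only convention under which a
no-information model scores exactly 0. Perfect separation is detected
and reported as a failed model (never silently penalized); the remaining
models still run, which matters because a pooled 8-predictor model on
~65 observations with strong predictors genuinely separates in a
non-negligible fraction of synthetic cohorts.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
study conditions: an 82-participant roster (40 mainstream + 29 populist
final, 9 other-party, 3 non-voters, 1 blank ballot), 61 channels,
126 items in 6 cells of 21, epochs −100…1200 ms. Background noise is an
equal-variance mix of 1/f-shaped and white Gaussian noise at
`noise_sd = 4` µV per sample — a clean-recording regime, deliberately
free of rhythmic (alpha) background and ocular components, so that
desk-scale cohorts recover the injected effects reliably; real
recordings are noisier and effect recovery there requires the full
study sample.

Injected effects are defined on the scale the analysis measures: the
economy congruency effect is a Gaussian temporal kernel (SD a quarter of
the 300–600 ms window) normalized so that its *window mean* at POz
equals `effect_amplitude_n400` (−2 µV), weighted across the scalp by a
broad posterior Gaussian peaking at POz; the culture effect is the same
construction over 1080–1200 ms; anti-establishment items carry no
effect by construction. Incongruent means populist items for
mainstream-leaning and non-populist items for populist-leaning
participants. The per-participant random effect on amplitudes
(`subject_sd = 3` µV) is deliberately large: it reproduces the realistic
situation in which the group-level ERP effect is strong while the
participant-level differential is only a moderate voting predictor, and
it decouples the signed N400 predictor (which drives the logistic
models) from unsigned decodability (which drives the MVPA stage).

Agreement is generated from a logistic link on a per-participant latent
populism score, shifted by ±`attitude_sep/2` between groups for economy
and culture and by a common `anti_shift` for anti-establishment — so
economy/culture SRIs are polarized (d ≈ 1.5 at the study scale) and the
anti-establishment SRI is not. RTs are log-normal and group-independent.
IAT latencies are floor-plus-lognormal (floor 300 ms, so the fast-latency
check passes by construction); the compatibility shift for reversed
blocks is applied on the log-latency scale (keeps the floor intact under
negative draws) and is drawn independently of voting group, giving a
positive population D (≈ 0.2), no group difference, and split-half
reliability near 0.8. Background artifacts are scattered at most one per
condition cell (expected count `trials_per_cell × artifact_rate` per
cell, ~0.8 by default, matching a mean of ~20.2 clean trials of 21), so
the trial-count rules remove exactly the two deliberately degraded
participants (13 clean epochs in one economy cell — failing both the
≥ 14 and the ≥ 20 rule); two further participants have all agreement
responses recorded as missing. This reproduces the bookkeeping chain
82 → 69 → 67 → 65 deterministically.

What the generator does *not* emulate: rhythmic background activity,
ocular/muscular artifacts and their correction, channel-level noise
correlations, stimulus-level item variability (items are abstract
labels), undecided-at-test-time status, and any real-data effect sizes.
Passing tests therefore demonstrate that the chain's statistics are
correct and calibrated — not that real recordings would yield the
published numbers.

## Numerical choices and degenerate inputs

Permutation p-values use the add-one convention. t statistics with zero
numerator and zero variance are defined as 0 (so "real equals chance
everywhere" yields no clusters rather than NaN). Stratified folds
distribute remainder trials round-robin under the stage's seeded
generator. Every stochastic stage draws from a generator derived from
the configured seed via a 31-bit string hash (stage and participant
tags), so full runs are reproducible bit-for-bit and per-participant
results do not depend on cohort order. Mixed-ANOVA inputs must be
complete and balanced; missing cells are reported by name rather than
imputed. Epoch containers refuse shape/metadata mismatches with explicit
alignment or format errors.

## Problem sizes used by the test suite

The package's own checks run at reduced, documented scales chosen for a
single CPU: a 16-channel montage (the 12 posterior electrodes plus 4
fillers), 128 Hz sampling for ERP/model Monte Carlos and 256 Hz where
10 ms windows need two samples, 10–24 participants for calibration runs,
500-sample permutation nulls, and single-repeat cross-validation for
replicate-level power checks (the full 10×10 scheme remains the
default). Null-calibration replicates for the cluster test draw
binomial-granularity accuracies (42 test trials) directly from the
exchangeable null rather than re-running the classifier 200 × 20 × 130
times; the classifier's own null behavior (chance centering) is verified
separately on a simulated null cohort. The study-scale acceptance script
runs the full 61-channel chain once with decoding restricted to the two
effect regions.

## Known limitations

The EEGLAB-style reader mentioned as an optional import is not provided;
the package's own container is the supported format. The mixed ANOVA
requires balance (the designs here are balanced by construction).
Cluster inference is one-tailed (above-chance); below-chance structure
is not searched for. The IAT model omits error-trial penalties. Power
statements in the tests are properties of the generator's default
regime, not of any real dataset.
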