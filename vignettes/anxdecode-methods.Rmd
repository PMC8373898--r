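---
title: "Methods: region super learning, shared-response alignment, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region super learning, shared-response alignment, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `anxdecode`, the assumptions they
make, the parameters that matter, and the design decisions taken where the
analysis admitted more than one reasonable reading. Everything quantitative
stated here is computed by the package's test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## The data model

The common currency of every estimator is the `timepoint_dataset`: one
T × V matrix per subject (T task time points × V atlas voxels), a stimulus
label per time point shared by all subjects, and a group label per subject.
Three assumptions are load-bearing:

1. **Temporal alignment.** All subjects saw the same block sequence, so the
   m-th time point carries the same condition for everyone. The synthetic
   generator enforces this by sharing one randomized block order per cohort;
   `assemble_dataset()` verifies it and refuses inconsistent label
   sequences.
2. **Voxel correspondence within a region is not assumed** — that is exactly
   what the shared response model repairs. Only the region membership of
   voxels (the atlas) is shared.
3. **Subjects are exchangeable units.** All cross-validation splits
   subjects, never time points: time points within a subject are strongly
   dependent, and splitting them would leak subject identity into training.

### Time-point extraction

Task volumes are selected by block membership: volume `i` (0-based) is kept
when its full acquisition interval `[i·TR, (i+1)·TR)` lies inside a task
block shifted by a hemodynamic lag (default 4 s — the initial rise of the
evoked response is discarded). At TR 2 s every 15-s block then contributes
exactly 7 volumes regardless of onset phase. Real studies typically
subsample further from a design matrix; the package emulates this with
`volumes_per_block` (default 3 for synthetic cohorts: the plateau volumes
starting at the lag) and truncation to a target T. The default design —
two runs of six 15-s blocks — yields 36 plateau volumes, and the final one
is dropped to reach T = 35. The odd T is deliberate: a subject's
majority vote over 35 binary predictions cannot tie. Condition labels end
up 18/17, balanced to within one block. With other TRs or block layouts T
will differ; every estimator takes T from the data.

### Standardization

Voxels are z-scored per subject against the **whole run** (task and
fixation volumes), then the task rows are selected. This mirrors how
block-design activation is interpreted: a response is a deviation from the
run baseline. Z-scoring over the task rows alone (available as
`standardize = "task"`) would remove any condition-independent activation
shift — precisely the group signal the primary analysis hunts — so it is not
the default. Zero-variance voxels standardize to zeros rather than NaN, so
masks containing dead voxels survive.

## The region super learner

The classifier is adaptive boosting over a regularized logistic weak
learner: each round fits the weak learner to the current sample weights,
up-weights misclassified time points by `exp(alpha)` with
`alpha = learning_rate · log((1−err)/err)`, and stops at `n_estimators`
rounds, a perfect weak learner, or a weak learner no better than chance.
The weak learner's own controls are the grid's `penalty` (L1, L2, none),
`C` (inverse regularization strength) and `max_iterations` (optimizer
cap) — so `max_iterations` belongs to the logistic fit and `n_estimators`
to the boosting loop, the only reading under which both are meaningful.
L2 and unpenalized fits solve the weighted Newton equations directly
(deterministic, exact); L1 goes through coordinate descent (glmnet), with
the iteration cap rescaled ×100 because a coordinate-descent pass is far
cheaper than a Newton step.

The full grid is `n_estimators ∈ {10, 50, 100, 150}`,
`learning_rate ∈ {0.05, 1, 2}`, `max_iterations ∈ {100, 500, 1000}`,
`penalty ∈ {L1, L2, none}`, `C ∈ {0.5, 1, 2}` — 324 configurations per
region. Region and classifier grid are tuned **jointly** in the inner CV
(the region is just another hyperparameter); a `search = "staged"` mode
first ranks regions at the grid's first configuration and then tunes the
classifier on the winner, for a large speedup at some risk of missing
region × configuration interactions.

Decisions taken where the design was open:

- **Inner score**: majority-voted subject accuracy (the headline metric),
  with a `inner_metric = "timepoint"` switch.
- **Tie-breaking** among equal-scoring configurations: lowest region id,
  then smallest `n_estimators`, then grid order — determinism over
  library-order accidents.
- **Stratification** uses the group label only; age, site and subtype are
  reporting covariates (`accuracy_by_covariate()`, percentile bootstrap
  with 2000 resamples), not fold constraints.
- **Precision averaging** is macro (unweighted), with per-class values
  always reported alongside.
- A **whole-brain pseudo-region** (id 0, the union of all labeled voxels)
  can be added to the candidate list; on planted-single-region cohorts it
  ranks below the planted region because the signal is diluted over many
  uninformative voxels.

## The shared response model

Model: `X_i = W_i S + E_i` per subject, `W_i` V × k with orthonormal
columns, `S` k × T shared. The deterministic engine minimizes
`Σ_i ‖X_i − W_i S‖²_F` by alternating the closed-form `S` update (mean of
`W_i' X_i`) with the orthogonal Procrustes `W` update; the recorded
objective is non-increasing by construction, and the test suite asserts
this on every fit. The probabilistic engine places `s_t ~ N(0, Σ_s)` and
`E_i ~ N(0, σ²_i I)` and runs EM; because EM guarantees monotone
*likelihood*, its `objective_trace` records the negative log-likelihood
(computed exactly via the matrix determinant lemma), and `noise_vars`
reports the σ²_i. Both engines share the `SharedSpace` contract:
orthonormal maps (tested to 1e-6), non-increasing trace, `k` below the
smallest voxel count.

Numerical choices: per-voxel centering over training time points, stored
and reapplied at transform; seeded random orthonormal initialization (QR of
a Gaussian matrix with sign-fixed R); `tol = 1e-6` on the relative
objective change; `max_iter = 200`. The shared space is identifiable only
up to a k × k rotation, so all recovery tests align by Procrustes before
comparing, and a held-out subject's map is the Procrustes solution against
the learned `S` (`srm_new_subject()`) — the shared response is never refit
on test subjects. Note the irreducible noise floor: voxel noise of SD σ
passes through the orthonormal projection unchanged, so even a perfect map
cannot push the correlation with the true shared response above
`1/sqrt(1+σ²)`.

`k` defaults to 10 for real data of realistic region size but should not
exceed the stimulus structure one hopes to find; the synthetic cohorts use
`k_shared = 3` and the pipeline decodes at `k = 3` accordingly.

## Stimulus decoding and the four-class ensemble

The stimulus decoder is deliberately minimal: a linear SVM at fixed
`cost = 1`, five subject folds, no inner CV, no majority vote — per-time-point
predictions are the object of interest. Folds split subjects even here
(stricter than strictly necessary for a within-subject label, but it keeps
the "no subject straddles a boundary" invariant global). The four-class
model does no new learning: it crosses each subject's predicted group with
each time point's predicted condition, scores balanced accuracy (mean
per-class recall), and runs a one-way fixed-effects ANOVA across the four
classes' per-fold precisions. When every class mean is identical the
between-class sum of squares is zero and F is reported as 0 (p = 1) rather
than the 0/0 a naive computation produces.

## Group RSA and the Mann–Whitney comparison

Per-condition betas are ordinary least squares of each voxel's time course
on fear/anger indicators (an optional ridge term stabilizes near-degenerate
designs; with the default orthogonal indicator design the betas are exactly
the per-condition voxel means). The group comparison pools each group's
per-voxel mean betas — averaged over the group's subjects and over
conditions, giving one value per voxel per group — and applies a two-tailed
Mann–Whitney U test with `U = #{(a,b): a > b} + ties/2` reported for the
anxious group. The full Bayesian representational-similarity machinery
with cross-subject covariance learning is intentionally out of scope; the
downstream group test is unchanged by that simplification.

p-values: exact (null U distribution) when the pooled sample is tie-free
and `n1·n2 ≤ 10 000`; full enumeration of group assignments for small tied
samples; otherwise a normal approximation with tie correction, continuity
correction and an Edgeworth kurtosis term using the exact excess kurtosis
of U, `γ₂ = −(6/5)(n1²+n2²+n1n2+n1+n2)/(n1n2(N+1))`. The Edgeworth term
keeps the approximation within 0.0025 of the exact p for sample sizes of 5
and up (verified exhaustively over all U values); below that the exact
path always applies anyway. Degenerate all-tied input warns and returns
p = 1. The RSM is `1 − r` between group-averaged condition patterns, zero
diagonal, NA (with a warning) for zero-variance patterns.

## Connectome

Region-mean series are voxel means per subject averaged within group over
all 35 task time points regardless of condition; the network is the
absolute Pearson correlation matrix. Both thresholding conventions are
provided because both are in circulation: an absolute cut (default 0.6,
which defines the reported edge tables) and a top-percentile cut (default
top 30%); they coincide when the percentile quantile equals the absolute
cut, which the tests exercise. Zero-variance series drop their edges with
a warning rather than erroring, since a dead region should not kill the
whole network stage.

## What the synthetic generator does and does not emulate

`generate_cohort()` plants exactly the structure the estimators assume:

- a **group term** — mean shift of `group_effect` (default 2) noise SDs on
  all voxels of the signal region during task volumes, anxious subjects
  only;
- a **stimulus term** — `stim_effect · W_i s_c` inside the signal region,
  with `s_fear, s_anger` drawn once per cohort and `W_i` orthonormal per
  subject: responses shared across subjects only up to the subject map,
  which is what makes unaligned cross-subject decoding chance-level and
  aligned decoding near-ceiling;
- optional **coupling** — a task-locked fluctuation shared by the signal
  region and any `shared_signal_regions`, sized (default amplitude 1
  against group-averaged noise of SD ≈ 0.03) to plant unambiguous
  suprathreshold edges;
- i.i.d. Gaussian voxel noise, `noise_sd = 1`.

Defaults are the study conditions: 22 anxious + 23 non-anxious subjects,
20 regions × 40 voxels in a 12³ grid, T = 35, seed-derived sub-draws (a
documented stream scheme keyed on the root seed, so any component can be
regenerated independently). The signal region defaults to 12 — an interior
id, so the lowest-region-id tie-break cannot hand the search the right
answer for free.

Deliberately **not** emulated: hemodynamic convolution (responses are
boxcar-shaped at the plateau volumes), physiological noise, motion, scanner
drift, spatial autocorrelation, and site effects. Passing tests on these
cohorts therefore show that the estimators recover the structure they
assume, at the planted effect sizes — not that real preprocessed fMRI
satisfies those assumptions, and not that real-data accuracies will match
the synthetic ones.

## Problem sizes and validation design

The test suite validates at two scales. Unit tests use 8-subject,
4-region cohorts. The end-to-end checks run at the study conditions:
planted-region recovery over 5 cohorts, null calibration
(`group_effect = 0`) over 20 cohorts against the 95% binomial band around
the 51.1% majority baseline, the alignment contrast over 5 cohorts (the
chance band for unaligned decoding uses the 45 subjects per cohort as the
effective sample, because time points within a subject share that
subject's map), and connectome false-edge rates over 10 noise cohorts
against the null |r| distribution at T = 35. These runs use a single
boosted-logistic configuration (n_estimators 10, learning rate 1, L2,
C = 1, 100 iterations) with the region as the searched hyperparameter —
the full 324-point grid multiplies cost by two orders of magnitude without
changing what the checks validate. Statistical oracles are brute force:
pair counting for U, explicit sum-of-squares decomposition for F,
enumeration for exact p-values.

## Known limitations

- The weak learner's L1 path depends on coordinate-descent convergence;
  extremely small `max_iterations` with separable data can underfit (the
  ×100 rescaling makes the printed grid values safe).
- The probabilistic SRM reports the posterior mean of `S`; its Frobenius
  reconstruction error is not guaranteed monotone (the likelihood is).
- Balanced accuracy of the four-class model inherits any bias of its two
  source models; it is a composition, not a jointly trained classifier.
- `percentile` connectome mode ties are kept (≥ the quantile), so the
  retained fraction can slightly exceed the nominal one on tied data.
- Exact Mann–Whitney enumeration with ties is capped at 2×10⁵ assignments;
  beyond that the corrected normal approximation is used.
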