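---
title: "Evaluating synthetic tabular health data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating synthetic tabular health data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sdeval)
```

`sdeval` scores a synthetic tabular dataset against the real mixed-type table
it imitates along four axes — fidelity, utility, privacy, and a
fidelity–utility tradeoff. This vignette explains the procedure, the
assumptions behind each metric, every tunable that matters, and the places
where the design was genuinely open and a choice had to be made.

## The evaluation procedure

The real dataset is split **once** into 80% training and 20% test rows under
a fixed seed (`split_train_test()`, train size `floor(0.8 n)`). The training
part is what a generator is fitted on and what fidelity and privacy compare
against; the test part serves two roles: the common test set of both utility
scenarios, and the *control* sample of every privacy attack. Evaluation is
then repeated over `n_folds` (default 10) independent generation+evaluation
passes on that one fixed split — the fold seed is `base_seed + fold_index`,
and a fresh synthetic dataset of the training size is drawn per fold — and
fold values are aggregated into best/worst/mean, where "best" is the value
nearest each metric's ideal (0 for distances, differences, risks and G; 1
for the DD-plot R²; 0.5 for the distinguishability AUC). An alternative
reading of "folds" would re-evaluate one fixed synthetic dataset repeatedly;
we regenerate per fold because a generator's sampling noise is part of what
the aggregate should reflect, and `run_folds()` also accepts a list of
pre-generated external datasets (one per fold) for generators trained
elsewhere.

Preprocessing is deliberately minimal: rows containing any missing cell are
deleted at load time (`load_table()` reports the count) and no imputation is
offered. Column typing comes from a JSON schema descriptor, or from
inference: a column is categorical if any value is non-numeric *or* it has
at most 20 distinct values — small integer codes (disease stages, risk
factors) behave as categories in health tables, which is why the threshold
defaults that high.

## Fidelity

**Hellinger distance.** Each attribute's real and synthetic marginals are
placed on one support — categoricals by the union of category lists (a
category seen only on one side gets probability 0 on the other), numerics by
20 equal-width bins spanning the *combined* range — and
`H = sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))` is averaged over attributes,
unweighted. The bin count and the combined-range policy are this package's
choices: equal-width binning over the union range is symmetric in the two
datasets, deterministic, and penalizes out-of-range synthetic values
naturally. More bins sharpen sensitivity but inflate the distance between
two finite samples of the same distribution; 20 keeps that sampling floor
below ~0.1 at a few thousand rows.

**Pairwise correlation difference.** Associations are measured with a
ϕk-style coefficient so numerical and categorical attributes share one
scale: both columns are binned (categoricals by category, numericals into 10
quantile bins), the Pearson χ² of the contingency table is computed, the
expected chance contribution under independence — the table's degrees of
freedom, the statistic's "pedestal" — is subtracted with a floor at 0, and
the remainder is mapped to ρ ∈ [0, 1] by inverting the χ²(ρ) curve of a
bivariate normal discretized with the *observed* marginal bin probabilities
at the observed sample size (bivariate rectangle probabilities via
`mvtnorm`, root-finding by `uniroot` to 1e-4; values beyond the curve's
ceiling at ρ = 0.999 cap at 1). Quantile bins keep sparse cells rare; the
pedestal subtraction removes the positive bias a raw χ² inversion would
give independent columns. On bivariate-normal input the construction
recovers |ρ| within ±0.05 at n = 10,000 (a property the test suite checks at
ρ ∈ {0, 0.3, 0.6, 0.9}). PCD is the mean absolute difference of the two
upper-triangular association vectors, with a paired two-sided t-test;
degenerate cases are pinned down explicitly (all differences zero → p := 1;
constant nonzero differences, where the t statistic is undefined → p := 0,
since a systematic shift should read as significant). A constant column has
no association signal and is defined to associate 0 with everything, with a
warning.

**DD-plot R².** Depth is Mahalanobis, `D(x) = 1/(1 + d²(x))`, computed on
the shared numeric embedding (one-hot categoricals, numerics standardized
with the *real training* statistics so both datasets live in one space). The
covariance is ridge-regularized with `1e-6 · trace(S)/d` on the diagonal
because one-hot blocks are exactly collinear. Halfspace or simplicial depth
would be more robust to non-ellipticity but cost combinatorially more;
Mahalanobis depth is closed-form and adequate for the moderate dimensions of
typical clinical tables. R² is measured about the identity line `y = x` —
not an OLS fit, because agreement (not linearity) is the claim — and clamped
into [0, 1]; an exact copy gives exactly 1, gross multivariate mismatch hits
the 0 clamp.

**Distinguishability.** A random forest (1,000 trees, depth 3 via
`maxnodes = 8`) separates pooled real (label 0) and synthetic (label 1)
rows; each row's synthetic-class probability is averaged over the trees
where the row was out-of-bag, and one AUC-ROC is computed from these OOB
probabilities. "Averaging OOB scores across trees" admits several readings;
per-row OOB vote averaging followed by a single AUC is the standard OOB
construction and is what `randomForest`'s vote matrix provides. At 1,000
trees the chance a row is never out-of-bag is negligible (< 1e-434); if it
occurred the row would be excluded. Shallow trees keep the classifier
honest: it can exploit real structural differences but cannot memorize
individual rows.

## Utility

One prediction task per attribute (all remaining columns as features, no
feature selection), five families with **fixed** default hyperparameters:
random forest (100 trees), k-NN (k = 5), decision tree (`rpart` defaults),
RBF-kernel SVM, and an MLP with one hidden layer of 100 units and at most
500 iterations. k-NN is implemented internally (Euclidean distance on the
encoded features) with deterministic tie-breaks — neighbour ties by row
order, vote ties by training level order — because bit-reproducibility under
a seed is a contract of the whole framework and randomized tie-breaking
would violate it.

Classification metrics (ACC, PREC, REC, F1) use support-weighted multiclass
averaging; under it weighted recall equals accuracy algebraically, so the
ACC and REC difference columns always coincide (to roundoff) — a useful
internal consistency check. Regression targets are min-max normalized with
the real-training min/max (test values and predictions clipped to [0, 1]),
which puts MAE/MSE/RMSE on the same [0, 1] scale as the classification
metrics; R² on the test set is clamped below at 0, and defined 0 outright
for a constant training target. The summary is, per metric, the mean
absolute TSTR−TRTR difference over all (task, family) pairs plus a paired
two-sided t-test. TSTR with a synthetic dataset equal to the real training
set is an exact fixed point (all differences 0) because each (task, family)
fit reseeds deterministically.

## The G tradeoff

`G = ½·PCD + ½·mean(the eight per-metric utility differences)`. The AUC and
DD-plot terms stay out of G deliberately — G weights one association-level
fidelity number against one downstream-utility number, and its ideal is 0.
Applied to the output of a differentially private generator at budget ε the
same quantity reads as G_ε. The privacy budget is accepted and recorded by
the baseline generators for interface parity, but they implement no DP
mechanism — DP belongs to the generators under evaluation, not to the
evaluator.

## Privacy attacks

All five attacks share three conventions. First, a *control* run: the same
attack executed against the held-out test rows measures what an adversary
gets from population structure alone, and the headline number is the excess
over that baseline normalized by the attainable headroom,
`max(0, (attack − control)/(1 − control))` (0 when the control saturates).
Second, record distance is Gower's — the mean of range-normalized numeric
gaps and categorical mismatch indicators — with numeric ranges taken from
the real training data so distances are comparable across datasets. Third,
every attack caps its attempts at `n_attacks` (default 500, binomial error
≈ ±0.02) and is deterministic under the config seed.

*Univariate singling out* derives single-attribute predicates from the
synthetic data (at-or-beyond the synthetic min/max and 1%/99% quantiles;
the rarest synthetic categories) and succeeds when a predicate matches
exactly one record. *Multivariate singling out* turns sampled synthetic
records into all-attribute conjunctions, numeric attributes as ±5%-of-range
intervals. *Linkability* splits the columns into two auxiliary sets (default
alternating halves), finds each target's k = 1 nearest synthetic records per
half, and succeeds when the neighbour sets intersect. *Membership inference*
thresholds the nearest-synthetic distance at the 5% quantile of the
control's distances — the threshold is the attack's one free parameter, and
deriving it from the control distribution fixes the false-positive rate by
construction rather than by guesswork. *Attribute inference* hides one
column, finds the nearest synthetic record on the rest, and guesses its
value (categorical: exact match; numeric: within 5% of range); the
dataset-level summary averages adjusted risk over every column as the
secret. The control baseline matters most here: a secret that is a
deterministic function of known columns is guessed perfectly in both runs
and correctly scores an adjusted risk of 0.

## The fixture generator and what passing tests mean

`fixture_spec()` defines the ground truth the test-suite evaluates against:
per-column marginals (normal, lognormal, uniform, categorical) joined by a
Gaussian copula with a known latent correlation matrix, categoricals
realized by thresholding their latent coordinate at probability-matched
cutpoints. The default 8-column spec (five bounded numerics, three
multi-level categoricals, moderate latent correlations of 0.3–0.6) emulates
the shape of a small clinical table. It does *not* emulate heavy tails
beyond lognormal, missingness mechanisms, rare categories below a few
percent, hierarchical or temporal structure, or deterministic clinical
constraints (e.g. pregnancies in males). Passing the parameter-recovery
tests therefore shows the metrics are calibrated on elliptical-copula data
of moderate dimension — not that they are robust to everything real health
data does.

The two baseline generators close the loop. The Gaussian copula fit
transforms columns to normal scores (categoricals by uniformly jittered
ranks inside their category block, which is why the fit takes a seed) and
estimates the latent correlation from them, projecting to the nearest PSD
matrix when the jitter pushes it slightly off; sampling inverts empirical
quantile tables. The NPC baseline resamples whole pseudo-observation rows
(`rank/(n+1)`) with ±1/(2n) jitter — enough to break bit-identity with
training rows on numeric columns while preserving cross-column ranks.

## Numerical choices and degenerate inputs, collected

- Train size `floor(train_frac · n)`; split by one seeded permutation.
- Constant numeric columns: encode to all zeros; contribute 0 to Gower;
  associate 0 (warning); zero latent correlation in the copula fit.
- Hellinger: 20 equal-width bins, combined range; identical single-valued
  columns fall in one bin and give 0.
- Association inversion: `uniroot` tolerance 1e-4; χ² pedestal = degrees of
  freedom; cap at 1 beyond the ρ = 0.999 ceiling.
- Depth ridge `1e-6 · trace/d`; DD-plot R² clamped to [0, 1]; identical
  datasets give exactly 1.
- Regression R² clamped to [0, 1]; 0 for constant training targets;
  predictions clipped to [0, 1] so MAE/MSE/RMSE stay bounded.
- Paired t-tests: p := 1 when all paired differences are 0; p := 0 for
  constant nonzero differences.
- All k-nearest computations break ties by index order; every stochastic
  step runs under `local_seed_eval`, which restores the caller's RNG state.

## Problem sizes in the test suite

The suite exercises split arithmetic up to n = 70,000 but runs the heavy
metrics at sizes chosen to balance statistical resolution against runtime:
fixed points on 1,000-row fixtures; the distinguishability null on a
2,000-row sample over 10 seeds; association recovery at n = 10,000;
privacy extremes at n = 2,000 over 10 seeds; copula parameter recovery at
n = 5,000 over 3 seeds. These are the sizes at which the stochastic
tolerances (±0.05 on associations and the AUC null, < 0.05 on independent
attack risks) have comfortable margins.

## Known limitations

- The association coefficient inherits ϕk's blind spots: it reports the
  *strength* of dependence, never its sign or shape, and quantile binning
  can dilute dependence concentrated in narrow ranges.
- Mahalanobis depth assumes elliptical contours; strongly multimodal data
  can agree in depth while differing in shape.
- The utility protocol fixes hyperparameters; a generator could look worse
  merely because a family's defaults suit the real data's scale better.
- Privacy attacks are black-box and record-level; white-box or shadow-model
  attacks against a specific generator can be stronger.
- Singling-out predicates are heuristic (extremes and rare categories);
  the reported rate is a lower bound on what an exhaustive predicate search
  could find.
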