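---
title: "Methods: abstention, setting noise, and module combination in modscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: abstention, setting noise, and module combination in modscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, their assumptions, the tunable parameters and their
defaults, what the synthetic generator does and does not emulate, and the
design decisions taken where the methodology left genuine freedom. It
states no empirical result that the test suite or the acceptance script do
not themselves compute.

## 1. Data model

The universal record is the *score sheet*: one child, an integer age in
months, a binary diagnostic label (case / non-case, possibly unknown), a
cohort tag (`training` = clinic-style collection, `deployment` =
home/analyst-style collection), and one ordinal answer code per question,
typically on 0–3. A skipped question is a first-class `SKIP` marker,
stored as `NA` and never conflated with severity 0: the distinction
matters both to the noise model (skipping is an *outcome*) and to the
learner (missing values follow a learned branch direction). Legacy
"not applicable" instrument codes (7/8/9 above a question's severity
range) are normalised to `SKIP` at read time with a reported count; the
original recoding used for such codes in historical instruments is not
documented anywhere we could follow, so normalisation-to-skip is this
package's choice.

When two respondents answer overlapping questions for the same child
(parent and clinician), `merge_answers()` builds the joint sheet with the
clinician's answer overriding the parent's wherever the clinician
actually answered; a clinician skip keeps the parent's answer. The exact
joint feature construction is not standardised anywhere we could follow;
override-on-answer is this package's interpretation.

All modelling is siloed by age at 48 months (48 itself goes to the older
silo): symptom expression and instrument design differ enough between
toddlers and older children that the methodology trains fully separate
models per silo.

## 2. The abstention cascade

`train_cascade()` performs three training runs:

1. A helper gradient-boosted classifier produces *out-of-fold* scores via
   label-stratified cross-validation (`cv_folds`, default 5). Each child
   is labelled `incorrect` if the helper's hard prediction — cut at the
   threshold attaining the target sensitivity (default 0.9) on the
   out-of-fold scores — disagrees with the true label. The helper is then
   discarded; it never runs at prediction time.
2. The *indeterminate filter* is trained on those correct/incorrect labels
   and estimates `P(misclassified)`.
3. The final binary classifier is trained only on children the filter
   deems likely-correct.

Two decisions here deserve comment. First, the correct/incorrect labels
come from **out-of-fold** predictions: in-sample predictions of a boosted
ensemble are nearly perfect, would label almost nothing `incorrect`, and
would starve the filter — out-of-fold is the only workable reading.
Second, the *default* filter threshold after training is
`max(0.5, q)` where `q` is the smallest threshold keeping the training
abstention fraction within the allowance: a child is abstained on by
default only if it is *more likely incorrect than correct* and within the
coverage budget. Using the allowance quantile alone would force ~30%
abstention even on cleanly separable data, which contradicts the intent of
the design (abstention should be spent only where it buys accuracy).

`tune_thresholds()` re-tunes both thresholds on a labelled dataset,
sequentially: the filter threshold is chosen among the observed filter
scores to maximise conclusive-subset AUC subject to the abstention
allowance (ties towards larger thresholds, i.e. fewer abstentions), then
the decision threshold is the largest value whose conclusive-subset
sensitivity reaches the target. Sequential rather than joint tuning is an
interpretation; the joint grid is small enough that a joint variant would
be easy, but sequential matches the "filter first, then operating point"
structure of the method and is what the exhaustive-sweep acceptance check
verifies.

A note on feasibility: a sensitivity target alone is *always* attainable
(a threshold below the minimum score predicts everyone positive), so the
"target unattainable" error paths in both tuners are defensive only. On
anti-informative scores the tuners legitimately return the degenerate
all-positive operating point with specificity 0 — the tests assert exactly
this.

## 3. The learner

All module classifiers are gradient-boosted decision trees. No
GBDT implementation is available in the package's dependency footprint,
so `gbt_fit()` implements a compact Newton-boosting kernel in C++:
logistic loss, second-order leaf values `-G/(H + λ)`, L2 penalty
`lambda` (default 1), shrinkage `learning_rate` (default 0.1), depth
limit (default 3), and `min_child_weight` (default 1) on hessian mass.
Missing values are handled the standard sparsity-aware way: each split
evaluates routing the missing bucket left or right and keeps the better
direction, so skips carry information at both training and prediction
time. The booster is fully deterministic — all resampling (folds,
bootstraps) happens in R under seeds derived from one master seed per
named stage, so every stage can be re-run independently and reruns are
bit-identical.

Hyper-parameters can be tuned by a bootstrapped grid search
(`gbt_grid_search()`): per grid point, `n_boot` bootstrap resamples, fit
on the in-bag children, scored by out-of-bag AUC, selection by mean. The
default `train_config()` grid has a single point (100 trees, depth 3,
shrinkage 0.1) because the acceptance-scale simulations do not need the
search; passing a longer grid enables it. When `weight_balance` is on,
samples are weighted so every (age-in-years × label) cell carries equal
total weight, preventing age-prevalence confounding within a silo.

## 4. Setting noise: estimation and injection

`estimate_noise_map()` tabulates, per question, the conditional
distribution of the deployment answer (including `SKIP`) given the source
answer, over children observed under both settings. Cells receive Laplace
smoothing `smoothing_alpha` (default 0.5) because sparse
(question, source-code) combinations are common at realistic pair counts.
A source code never observed in the pairs falls back to the *identity*
row rather than a uniform row: pass-through is conservative and preserves
information, whereas uniform would actively randomise unseen codes.
Source-side skips carry no information about the conditional table and
pass through unchanged at injection time.

`inject_noise()` resamples every answer independently from its question's
conditional row. Independence across questions mirrors the per-question
structure of the probability map; no cross-question analyst behaviour is
modelled. An optional `replicates` parameter emits several noisy copies
per child (default 1 — whether the original methodology augmented
multiplicatively is unstated).

The estimate→inject→estimate loop is a fixed point up to multinomial
sampling error; the acceptance suite verifies recovery within ±0.05
elementwise at 2000 observations per source code.

## 5. Distribution-shift feature rejection

For question *q* and class *c* ∈ {case, control},
d·c = |mean deployment severity − mean training severity| (skips
excluded) and se·c = √(se²train + se²deploy). The combined statistic is
the ratio of the class-averaged difference to the class-averaged standard
error, and the question is rejected when it exceeds `k_se` (default 3).
The exact cross-class combination is ambiguous in the source methodology
("averaged over the two samples"); averaging numerator and denominator
separately before taking the ratio is this package's reading, the
threshold is a parameter so alternatives can be tested, and the statistic
is by construction sign-symmetric and scale-invariant (doubling all
severities doubles d and se together). Under the null the statistic is
roughly a half-normal ratio, so the 3-SE rule rejects well under 5% of
stable questions; a +1-severity shift at 300 children per class is
rejected essentially always — both operating characteristics are measured
in the acceptance suite.

## 6. Perturbation ranking and the clinician shortlist

`perturb_rank()` simulates answer-severity misestimation near the
decision boundary: children with model response in
`(threshold, threshold + 0.1]` have each question dropped one severity
(floored at 0), one question at a time; children in
`[threshold − 0.1, threshold)` have it raised (capped at the question
maximum); skips are untouched; the ranking is by mean absolute response
shift. The band is a parameter; the conventional secondary band is
`(0.1, 0.3]`. Clamping at the severity bounds is our choice for boundary
answers. The dataset is copied, never modified.

`shortlist_clinician()` merges the importance-ranked list and the two
band rankings: top `top_k` (default 7) of each, union, ordered by best
rank across lists with ties broken by question id. How the original lists
were "prioritized" beyond intersection is unstated; min-rank is this
package's rule. The expert-consultation third list is a caller-supplied
allow-list hook, since it is a human step.

`backward_eliminate()` is explicitly a *reconstruction* of a
bootstrap-driven backward-subtraction initial selector whose original
details live outside this package's sources: at each step it removes the
question whose removal least degrades mean bootstrapped out-of-bag AUC.
It is plumbing, kept apart from the faithful stages.

## 7. Inverse-covariance combination

Module responses are pooled as
r_comb = (Iᵀ Σ⁻¹ R) / (Iᵀ Σ⁻¹ I), with Σ the covariance of response
residuals. The residual is `score − label` with label ∈ {0, 1} — the
natural reading of "residuals compared to the true diagnosis". The
weights sum to one by construction; with diagonal Σ they are classical
inverse-variance weights (the acceptance suite checks agreement with the
closed form to 1e-10). Numerical choices:

- a ridge (default 1e-6) is added to Σ's diagonal; duplicated or
  near-collinear modules otherwise make Σ singular, and the error message
  tells the user to raise the ridge;
- Σ is estimated leave-one-out for reporting: child *i*'s combined
  response uses Σ estimated from all other children (computed exactly via
  rank-one downdates of the sufficient statistics, not by refitting);
- children missing a module are combined over the submatrix of available
  modules, mirroring per-pair sample restriction in screener comparisons;
- the combined response is not clipped to [0, 1]; the band operates on the
  raw value.

The dual-threshold band (below lower = negative, inside closed band =
inconclusive, above upper = positive) is tuned by `tune_band()` over all
candidate pairs of midpoints between adjacent observed responses (plus
open ends): among pairs meeting the coverage allowance and the sensitivity
target it maximises conclusive specificity, ties to the narrower band,
then to the lower band position. Midpoint candidates make the grid
exhaustive over achievable three-way partitions while avoiding
boundary-equality ambiguity.

## 8. Evaluation machinery

AUC uses the rank (Mann–Whitney) statistic with rank-average tie
handling, identical to trapezoidal integration of the empirical ROC.
Operating points use strict `score > threshold` positivity; the threshold
for a sensitivity target is the largest one attaining it. The bootstrap
screener comparison draws `n_boot` (default 10 000) resamples of the
common children, computes the AUC difference and the difference in
specificity at *per-resample* thresholds achieving 90% sensitivity
(re-deriving the threshold inside each resample matches the quoted
procedure, and matters: a fixed threshold would understate the
variability), and reports means with empirical 5th/95th percentiles —
read as a percentile CI; bias-corrected variants are out of scope.
Single-class resamples are redrawn, not skipped, keeping the effective
draw count; redraws are counted and reported.

## 9. The synthetic world

The generator is a stated world, not a dial. One latent trait per child,
t ~ N(μ_class, 1), with μ_case − μ_control = `class_separation`
(default 1.5). Question *q* maps `t · discrimination_q + ε`, ε ~ N(0,1),
through three strictly increasing cutpoints to codes 0–3 — a
graded-response model, the minimal structure that yields ordinal
severities correlated with diagnosis, per-question drift, and skips.
Defaults: 2:1 case:control imbalance (echoing at-risk referral cohorts
where most non-cases carry an alternate delay — which is also why the
control class sits at a smaller latent gap rather than being
neurotypical); ages uniform over 18–72 months; discriminations spread
over 0.6–1.4; cutpoint offsets spread over ±0.6; deployment drift
`shift_bias` with half the questions stable, a quarter drifting up
(+0.7 latent units) and a quarter down (−0.35); per-question skip rates
5–25% averaging 15%. Paired records share the latent trait *and* the
per-question noise draw between settings, so with zero shift and zero
skips the two sheets are identical — the identity useful for testing and
the reason the estimated noise map is non-degenerate otherwise.

The baseline comparator sums non-skip codes and adds N(0, sd) noise
(default sd 5 on the ~0–60 sum scale). The noise is there because in this
single-factor world a noise-free sum is nearly the Bayes-optimal
statistic, which would misrepresent conventional screeners — distinct
instruments with imperfect validity. No acceptance criterion depends on
this default.

For the abstention-benefit acceptance check the spec of that check calls
for a world tuned to full-sample AUC ≈ 0.8; `class_separation = 1.45`
(shift and skips off) was calibrated once against the default learner and
frozen.

What the generator does **not** emulate: multi-factor item dependence
(one latent factor only), analyst identity and inter-rater structure
(one analyst-equivalent channel), item wording effects, age-dependent
item functioning, or the psychometrics of any real instrument. A green
test therefore establishes that the *machinery* behaves as specified on
data with the right coarse structure — not that any clinical accuracy
figure would be reproduced.

## 10. Determinism and budgets

Every random stage derives an independent stream from one master seed via
a stage-name hash (streams are 32-bit safe). Reruns of any stage, the
pipeline, or the acceptance script with the same seed are bit-identical,
and the pipeline manifest records MD5 hashes to make this checkable.
Unit tests run at deliberately small sizes (seconds); the acceptance
suite runs at the sizes its criteria state (minutes). The demonstration
pipeline at default sizes completes in well under a minute on one CPU.

## 11. Known limitations

- The cascade's filter quality degrades gracefully but silently when the
  correct/incorrect labels are nearly one-sided (easy regimes): the
  filter then defaults to a constant score and abstention turns off.
- `backward_eliminate()` is O(questions² × bootstraps) model fits; it is
  meant for shortlisting on modest instruments, not genome-scale feature
  screens.
- The combination stage assumes module responses are probabilities on a
  common scale; uncalibrated scores should be calibrated upstream.
- Coverage tuned on clinic-style data is not guaranteed on shifted
  deployment data (the filter flags more children under shift); when a
  hard coverage guarantee is needed, tune thresholds on deployment-style
  (noise-injected) data instead.
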