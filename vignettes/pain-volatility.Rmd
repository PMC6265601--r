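---
title: "Measuring and predicting pain volatility: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and predicting pain volatility: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painvol)
```

# The problem

People living with chronic pain rarely show meaningful change in *mean* pain
severity over months, even under intensive treatment. What varies — and what
correlates with distress, unpredictability and downstream risks such as
opioid misuse — is the *fluctuation* of pain over time. Self-tracking apps
produce exactly the kind of dense, irregular, self-initiated record streams
on which fluctuation can be measured, but they also come with heavy
missingness, free-text fields, and severe class imbalance once users are
labelled. This package implements a complete, testable pipeline for that
setting.

# The volatility statistic

For a series of severity ratings $R = \langle R_1, \dots, R_n \rangle$ on
the 0–10 scale, taken in record order, pain volatility is the mean absolute
successive difference

$$ V(R) = \frac{1}{n-1} \sum_{i=2}^{n} |R_i - R_{i-1}|. $$

Two modelling commitments are baked into `compute_volatility()`:

* **Record order, not clock time.** Consecutive means consecutive in the
  ordered record stream, regardless of the elapsed time between ratings.
  Users report at irregular, self-chosen times; time-weighting would
  conflate engagement frequency with pain dynamics.
* **Divisor $n-1$.** A series of $n$ ratings has $n-1$ successive changes,
  and $V$ is their mean. This makes $V$ of a perfect 0/10 alternation equal
  to exactly 10, the maximum attainable on the scale.

$V$ is translation-invariant and scales linearly with the rating unit, like
the standard deviation. It differs from the SD in how it ranks patterns: a
steady upward drift (1,3,5,7,9) has a large SD (3.16) but a small $V$ (2),
while a tight saw-tooth (3,7,3,7,3,7) has a smaller SD (2.19) but a larger
$V$ (4). The saw-tooth is what volatility is meant to capture; the SD
misorders the two. `compute_sd()` is kept as the comparison statistic and
both are computed per window by `window_volatility()`.

$V$ needs $n \ge 2$; both statistics error on shorter series rather than
returning a placeholder.

# Windows and eligibility

A *month* is a 30-day block anchored at the user's first record (calendar
months would give users windows of different lengths and make $V$
incomparable across users). The predictor window is $[t_0, t_0+30\text{d})$
and the outcome window $[t_0+150\text{d}, t_0+180\text{d})$, both half-open
so no record can be counted twice; a record at exactly day 30 belongs to
neither window. Eligibility requires at least five records in *both*
windows — two is the mathematical minimum for $V$, five is a reliability
cut — and the count is of records, not distinct days. Users reporting
gender `other` are representable throughout but excluded from the modelling
cohort (the population they form is too small to learn from); the exclusion
happens in `filter_eligible()`, not in the readers.

Ties in record ordering: when two records share a timestamp the reader
preserves file order. The export format carries no finer ordering
information, so any tie-break would be arbitrary; preserving input order at
least makes the pipeline deterministic for a given file.

# Threshold derivation

The low/high volatility classes are not defined by a fixed cutoff but by
clustering the data at hand: the predictor- and outcome-window $V$ scores of
all eligible users are pooled (two values per user, so both periods shape
the threshold) and split into two clusters by one-dimensional $k$-means with
$k = 2$.

`kmeans_1d()` runs Lloyd's algorithm initialized from $k$ random distinct
data values, with 25 restarts keeping the lowest within-cluster sum of
squares. For $k=2$ in one dimension the global optimum is a single split of
the sorted values, which an $O(n)$ prefix-sum scan can find exactly; the
implementation verifies the restart winner against that scan and, if every
random restart stalled in a local optimum (which happens on tie-heavy score
distributions), re-seeds Lloyd at the optimal split's cluster means — a
fixed point of the iteration — so the returned solution always attains the
global optimum. The test suite additionally checks this equality against an
independent exhaustive split search on random instances.

The threshold is placed at the midpoint of the gap between the largest
low-cluster value and the smallest high-cluster value. Any point in the gap
is consistent with the clustering; the midpoint is the symmetric choice. A
score strictly greater than the threshold is `high`; a score exactly at the
threshold is `low`. Degenerate inputs (all scores identical) raise an error
rather than fabricating a threshold.

`subsample_stability()` guards against the threshold being an artifact of
particular users: it re-derives the threshold on four random half-samples of
the pooled scores and reports the spread. On cohorts with separated regimes
the half-sample thresholds agree with the full-data threshold to well within
±0.2.

# The 130 features

`extract_features()` is a pure function of (profile, predictor window,
threshold) producing the canonical schema of `feature_schema()`:

| block | features | notes |
|---|---|---|
| gender | 1 categorical | male/female/other/unknown |
| age | 1 categorical, 8 bins | unknown, (0,20], …, (60,70], >70; lower-exclusive, upper-inclusive |
| number of conditions | 1 categorical, 5 bins | unknown, 1, 2, 3, >3 |
| condition categories | 5 binary | fibromyalgia, headaches, back pain, arthritis, depression-anxiety |
| record counts | 2 integer | records; distinct days with a record |
| severity | 3 | mean, SD (divisor $n-1$, matching `compute_sd`), mild/moderate/severe group |
| trend | 1 numeric | OLS fitted-line change over the window |
| volatility | 2 | predictor-window $V$; low/high flag against the global threshold |
| descriptors | 64 binary | 24 locations + 20 symptoms + 13 characteristics + 7 environments |
| factors | 43 binary | 15 aggravating + 14 alleviating + 14 ineffective |
| medications | 5 binary | opioids, tricyclics, anticonvulsants, cannabinoids, SNRIs |
| neuropathic pain | 1 binary | see below |
| mental health | 1 binary | see below |

Decisions worth spelling out:

* **Categoricals count as one feature.** The canonical schema keeps single
  factor columns; one-hot expansion (`encode_features()`) happens at model
  fit time against fixed schema levels, so the encoding never depends on
  which rows are present.
* **Unknowns are categories, not errors.** Users who report nothing get
  `unknown` gender/age/condition-count and all-zero flags; a user listing
  zero conditions is indistinguishable from one who declined to fill the
  field, so both map to `unknown`.
* **Severity grouping boundaries** are mild < 4 ≤ moderate ≤ 7 < severe,
  applied to the window mean.
* **Trend change** regresses severity on elapsed days (not record index —
  index-based slopes depend on sampling density) and reports fitted end
  minus fitted start, i.e. slope × elapsed span; 0 when all records share a
  timestamp.
* **Volatility level** uses the *global* clustering threshold, not a
  window-local re-clustering, so the flag means the same thing for every
  user.
* **Medication flags are record-attached**: a category fires only when a
  medication of that category appears on a record in the window, not merely
  in the profile. The profile supplies the medication-to-category mapping.
* **Neuropathic pain** fires when a *single* record carries at least two of:
  characteristics "pins and needles or tingling", "burning", "numbness",
  "electric shocks", or the aggravating factor "light touch or clothing".
  Pooling across records would conflate co-occurrence with accumulation.
* **Mental health** fires on any record with symptom "anxiety" or
  "depression", or aggravating factor "negative mood" or "stress".

Token vocabularies are configuration, not code: the package ships a fixture
CSV with the canonical cardinalities (24/20/13/7 descriptors, 15/14/14
factors) whose member order fixes the feature-column order. Deployments
against a real export replace the fixture with the app's own token lists;
`load_vocabularies()` enforces the cardinalities and the presence of the
tokens the two composite flags refer to.

# Prediction protocol

Four classifiers are exposed through one surface (`fit_predict()`): logistic
regression with ridge and with LASSO penalties (via glmnet, penalty strength
chosen by internal cross-validation on the training fold with the
one-standard-error rule), a random forest (100 trees; `mtry` =
round(2·√130) = 23 candidate features per split, the two-times-root-n rule
applied to the canonical feature count), and an SVM with Gaussian RBF kernel
(library-default cost and width, exposed as configuration — the defaults are
deliberate, since no principled tuning is specified for this protocol).

Evaluation is stratified $k$-fold cross-validation (default $k=5$): each
class is shuffled and dealt into folds so per-fold class counts differ by at
most one from exact proportionality, and every user is tested exactly once.
Performance is reported as three measures with high volatility as the
positive class: accuracy on the low class, accuracy on the high class, and
overall accuracy (algebraically the label-frequency-weighted mean of the
other two).

Class imbalance — roughly 3.5 low-volatility users per high-volatility
user — makes unbalanced training collapse onto the majority class: overall
accuracy looks respectable while high-class accuracy approaches zero. The
cure is random subsampling of the majority class down to the minority size,
applied *within each training fold only* (the test fold always keeps the
natural mix; balancing it would change the estimand), repeated three times
with fresh subsamples to show stability. Folds are held fixed across the
three subsamples so subsample-to-subsample variation is isolated from fold
variation. Standardization of continuous features and penalty selection
likewise see training-fold rows only.

# The synthetic cohort generator

No public dataset of this shape exists, so `generate_cohort()` creates one
with a *known* latent structure; it is first-class, tested code, not a test
fixture.

* **Regimes.** Each user has a latent volatility regime (low/high) in each
  month. The month-6 regime is Bernoulli with P(high) = 171/782 ≈ 0.219,
  the prevalence in the population the generator emulates; the month-1
  regime equals the month-6 regime with probability `regime_persistence`
  (default 0.75). When the regimes differ the switch month is uniform.
* **Severity paths** are discretized mean-reverting AR(1) walks: a latent
  path around a per-user mean (uniform on 3–7, matching stable
  moderate-severe chronic pain) with innovation scale calibrated per regime,
  rounded and clipped to 0–10. `calibrate_step_scale()` inverts the
  scale-to-realized-$V$ map by root finding on a fixed 100 000-step
  simulated path (common random numbers make the map deterministic and
  monotone); the realized mean absolute step lands within 5% of target.
  Targets: 0.8 (low) and 3.0 (high), giving regimes whose month-level $V$
  distributions separate cleanly around the 1.5–2 region — with the default
  record density over 95% of low-regime months fall below 1.6 and over 95%
  of high-regime months above it. The AR coefficient defaults to 0.3;
  stronger persistence would lower the attainable ceiling of the mean
  absolute step (heavily autocorrelated paths cannot alternate fast).
  Target 0 returns a constant path and target 10 the only pattern that
  attains it, 0/10 alternation; targets above 10 are impossible on the
  scale and error.
* **Record counts** per user-month are Poisson with mean 12 (about three
  reports a week, realistic for an engaged app user) floored at 5 so the
  default cohort is fully eligible; the floor is configuration
  (`records_per_month`) because no empirical count distribution is
  available to copy. The first record is placed at the exact window origin
  so generated months align with analysis windows.
* **Planted signal.** Five designated descriptor tokens (the first token of
  five vocabularies) have month-1 window-level presence probability
  0.5 ± `signal_strength`/2 depending on the month-6 regime (default
  0.25). This gives downstream models a signal beyond volatility
  persistence and gives tests a dial that can be set to exactly zero.
* **Missingness** defaults: 25% gender unknown, 31% age unknown, 2% of
  users report no descriptors at all, 8% no factors — the rates of the app
  population being emulated.

With these defaults, month-1 information predicts the month-6 class at
roughly the 70–75% level for both classes after balancing — deliberately in
the range reported for real pain-app cohorts — while unbalanced training
reproduces the imbalance pathology.

**What the generator does not emulate:** engagement decay and dropout
(every user reports in all six months), within-day reporting rhythms,
correlated descriptor co-occurrence structure, free-text idiosyncrasy, and
any relationship between demographics and volatility. Passing tests
therefore show that the pipeline recovers structure *of the kind planted*,
under honest missingness and imbalance; they do not certify accuracy levels
on real data.

**On the null configuration:** `signal_strength = 0` removes the planted
descriptor signal but month-6 volatility remains predictable through regime
persistence, because month-1 volatility is itself a feature. A true null —
used by the at-chance sanity check — therefore sets `signal_strength = 0`
*and* `regime_persistence = 0.5`, making month 6 independent of everything
observable in month 1.

# Numerical and degenerate-input choices

* Volatility and SD error below two ratings; clustering errors when all
  values coincide (no threshold is defensible) and when fewer than $k$
  distinct values exist.
* Threshold ties go to `low` (strict `>` for `high`).
* Lloyd's iteration caps at 200 sweeps (never reached in practice);
  restarts that lose a cluster are abandoned.
* glmnet's internal CV uses up to 10 folds, reduced on small training sets
  so folds keep at least 3 observations.
* Standardization uses training-fold mean/SD; zero-variance columns pass
  through unscaled.
* All randomness flows through explicit seeds (`withr::with_seed`), so every
  pipeline stage is reproducible and the generator is byte-identical across
  runs for a fixed (config, seed).

# Problem sizes in the shipped checks

The test suite exercises the pipeline on synthetic cohorts of 200–2000
users (the larger sizes where a distributional property needs tight
sampling error), and the end-to-end prediction checks use cohorts of 782
and 800 users — the former matching the scale of the modelling cohort the
pipeline is designed around. `scripts/acceptance.R` runs the full pipeline
at that 782-user scale and writes every quantity it computes to JSON.

# Known limitations

* The exported file dialect is bespoke (pipe/semicolon delimited); it is a
  stand-in for whatever export a real deployment provides, and the readers
  are strict by design (errors name the offending line and token).
* The condition-to-category and medication-to-category mappings shipped
  under `inst/extdata` are small synthetic stand-ins, labelled as such;
  real deployments supply their own curated tables.
* The SVM is run at library defaults; its weaker balanced performance is
  expected and documented rather than tuned away.
* $V(R)$ ignores elapsed time between ratings by definition; users who
  report in bursts may have volatility dominated by within-burst dynamics.
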