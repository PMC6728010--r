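---
title: "Guarding, pain and emotion: methods behind guardnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guarding, pain and emotion: methods behind guardnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guardnet)
```

`guardnet` analyses how observer-rated guarding behaviour relates to pain,
movement-specific anxiety, general emotional distress, and observer-rated
movement self-efficacy in people with chronic low-back pain performing
everyday exercises. This vignette explains the statistical machinery, the
synthetic cohort that stands in for the access-controlled recordings, and
the design decisions taken where the methodology was genuinely open.

## The analysis pipeline

Each *exercise instance* (one patient, one exercise, one challenge level)
carries self-reports of pain (0–10) and anxiety (0–10); distress is a
13-item HADS total (0–39) collected once per patient and replicated across
their instances. Four physiotherapist raters view the clip and mark
guarding present/absent and self-efficacy low/medium/high.

Aggregation follows the published coding rules: the **guarding score** is
the count of raters marking guarding present (0–4) and **self-efficacy**
is the median of the ordinal codes (low = 1, medium = 2, high = 3).
Half-integer medians from even panels are retained rather than rounded —
nothing in the coding scheme mandates rounding, and retaining them
preserves information for the rank-based correlations; `rounding =
"floor"/"ceiling"` in `self_efficacy_median()` supports sensitivity
analysis. An instance enters the analysis only if at least one of pain,
anxiety or distress is present along with at least one rater label. Panels
smaller than four raters are aggregated as the raw sum by default; an
opt-in flag rescales to the nominal panel, covering data sets with
incomplete panels.

**Interrater agreement** is the one-way random, absolute-agreement,
average-measures intraclass correlation, ICC(1,k) = (MSB − MSW)/MSB,
applied directly to the binary guarding codes and the ordinal
self-efficacy codes, overall and within exercise type. The one-way model
is the right choice because rater panels are assembled per video set:
rater identity is not a crossed factor. A degenerate "no between-subject
variance" status (not NaN) is returned when MSB = 0, and negative ICCs are
reported with a warning rather than truncated. An F-based confidence
interval is available but optional.

**Associations** use Spearman rank correlation with average ranks for
ties and a two-sided p-value from the t approximation on n − 2 degrees of
freedom; with the effect sizes involved here, the difference from an exact
permutation p is immaterial. The correlation matrix uses pairwise-complete
observations with per-pair n, matching how such tables report
per-correlation sample sizes. The lower/higher dichotomizations are:
pain and anxiety higher at ≥ 5/10 (one stated rule covers both), distress
higher at > 19/39, self-efficacy higher when better than medium
(> 2) — the last is the natural reading of "better than medium" and is
configurable in `dichotomy_config()`.

## The linear-Gaussian network

All five analysis variables are treated as continuous in a linear-Gaussian
Bayesian network. This is the only treatment consistent with evaluating
the model by a real-valued mean squared error on the 0–4 guarding score,
and it keeps the score decomposable. Discrete/multinomial networks are out
of scope. Each node is an OLS regression on its parents with residual
variance RSS/n (the MLE divisor), so the network score is an exact
penalized log-likelihood:

$$\mathrm{BIC}(G) = \sum_j \left[\log L_j - \tfrac{|pa(j)|+2}{2}\log n\right]$$

in the higher-is-better convention with natural logarithms. The "+2"
counts intercept and variance. Scores are computed from the moment matrix
$X^\top X$ of the data, so one family evaluation is a small `solve()`
independent of n; families are memoized by (child, parent-set), which is
what makes exhaustive enumeration and repeated restarts cheap.

**Hill climbing** starts from the empty graph and greedily applies the
best strictly improving single-edge addition, deletion or reversal,
rejecting cycle-creating moves. Ties (score-equivalent moves arise
systematically, e.g. the two orientations of the first edge) are broken
lexicographically by (operation, tail, head), so a run is fully
deterministic. Restarts draw random start DAGs from seeded random
topological orders; the edge density of each start is itself drawn
uniformly from [0.15, 0.75] so that successive searches enter different
basins of attraction — with a fixed density the restarts tend to rediscover
the same local optima. **Exhaustive search** enumerates all DAGs on up to
five nodes (1, 3, 25, 543, 29281 graphs) and is the oracle the climber is
tested against.

Arc strength is the BIC decrease if that single edge were deleted; by
decomposability only the head's family score changes, which the tests
verify numerically. Strengths above 10 are flagged "highly meaningful",
the conventional reading of large score differences on this scale; the
flag is reported, never enforced.

The **constraint-based comparators** learn each node's Markov blanket —
Grow-Shrink by scan-order inclusion then backward removal, IAMB by
repeatedly admitting the candidate with maximal |partial correlation|
given the current blanket interleaved with backward removal — using the
Fisher-z test: $z = \sqrt{n - |Z| - 3}\,\mathrm{atanh}(r)$ on the partial
correlation computed from the inverse covariance of the involved block.
Blankets are symmetrized by intersection, neighbours resolved by subset
search within the smaller blanket, v-structures oriented from recorded
separating sets, orientations propagated by Meek rules R1–R3 (R4 only
arises under background knowledge, which is never supplied), and any
remaining undirected edges oriented by the same lexicographic rule as the
climber, skipping orientations that would close a cycle. The returned
object is always a DAG. α defaults to 0.05, the conventional level; note
that α controls error per test, so on pure noise the probability of a
perfectly empty graph is roughly $(1-\alpha)^{\binom{k}{2}}$, not
$1-\alpha$.

**Prediction** of guarding has two modes. `"full"` (the default) assembles
the joint normal implied by the fitted network — $\mu = (I-B^\top)^{-1}a$,
$\Sigma = (I-B^\top)^{-1} D (I-B^\top)^{-\top}$ — and returns the exact
conditional mean given all other variables; `"parents"` returns the child
regression only. Both are exposed because either could underlie a reported
cross-validated error; the CV report names the mode used. Singular
conditioning blocks (e.g. near-noiseless nodes) fall back to the
Moore-Penrose pseudo-inverse, which yields the correct conditional mean on
the support of the distribution. **Cross-validation** is 5-fold on a
seeded random partition at the instance level, matching the apparent
original procedure; `group_by` supports patient-level folds, motivated by
the non-independence of instances within patient, and the two give
noticeably different errors on cohorts with strong patient effects.
Variables enter the score unstandardized; BIC and the learned structure
are invariant to per-variable affine rescaling of the data only up to
likelihood constants, but the cross-validated MSE is in squared guarding
units either way.

## The synthetic cohort

The generator is a linear-Gaussian structural equation model over
{pain, anxiety, distress, guarding_latent, selfeff_latent} with the
default graph

pain → anxiety ← distress, anxiety → guarding_latent,
anxiety → selfeff_latent, guarding_latent → selfeff_latent,

i.e. the pain–guarding and distress–guarding relationships exist but are
mediated entirely by anxiety. The attachment of distress (distress →
anxiety) is a modelling choice: the analysis narrative specifies only that
distress relates to guarding indirectly, and routing it through anxiety is
the most parsimonious graph consistent with that; it is replaceable via
`ground_truth()`. Defaults were set once to reproduce the published
descriptive profile of the patient cohort — pain mean ≈ 5 (SD ≈ 3) on
0–10, anxiety mean ≈ 1 with a long upper tail, HADS distress mean ≈ 18
(SD ≈ 7), guarding score mean ≈ 3 (SD ≈ 1.4), self-efficacy median ≈ 2 —
with guarding↔self-efficacy the strongest observed pairwise association
and pain↔anxiety the second. Pain carries a patient-level random intercept
(SD 2.2) plus instance noise (SD 2.0); distress is drawn once per patient
(SD 7) and replicated, which the generator expresses by flagging distress
as a patient-level node (its "residual" is the patient draw), satisfying
both the positive-residual invariant and within-patient constancy.

The observation layer maps pain/anxiety to rounded integers clipped to
[0,10] and distress to [0,39]. Each of the four raters marks guarding
present with probability `plogis(1.5 + 1.8·(guarding_latent + u) + bias_r)`
and codes self-efficacy by cutting `selfeff_latent + bias_r − u + noise`
at (−0.85, 0.85), where `u ~ N(0, 0.5)` is the rater's per-clip
*impression*, shared between the two judgements. The impression term
models the correlated-observer effect — the same person rates both
constructs, which inflates their observed association — and the rater
noise (SD 0.9) plus small biases (±0.2) put guarding ICC(1,4) in the
"good" 0.6–0.85 band and self-efficacy agreement slightly above it, as in
the published reliabilities. Instance counts per patient are
`1 + Binomial(8, 5/8)`, a discrete distribution on [1,9] with mean 6; the
family is a configuration choice since only the mean and range are
documented.

What the generator does *not* emulate: non-Gaussian self-report
distributions beyond what clipping induces (real anxiety ratings are
zero-inflated beyond a censored normal), learning or fatigue effects
across a session, exercise-specific difficulty shifts, rater drift, and
any biomechanical signal. Passing recovery tests on this cohort therefore
shows that the estimators work under the model's assumptions at the
study's scale — not that the assumptions hold for real movement data.

## Numerical choices and test scales

Score comparisons use an absolute tolerance of 1e-12 when accepting a
hill-climb move (so float noise cannot masquerade as improvement) and
1e-8 when asserting score equivalence across Markov-equivalent DAGs.
Collinear parent sets score −Inf and are flagged rather than erroring the
whole search. Partial correlations are clamped to [−1, 1] and |r| = 1 is
reported as a degenerate test with p = 0. RSS values are floored at zero
before forming variances; exact-zero variances are floored at the smallest
positive double only to keep log-likelihoods finite on degenerate inputs.

The test suite fixes its simulation sizes as follows: oracle-equivalence
checks run on 1,000 random matrices/vectors; score equivalence on all 25
three-node DAGs over 50 datasets of n = 120; hill-climb vs exhaustive on
100 random 3–4-node datasets at n = 500 with 5 restarts; structure
recovery on 50 SEM draws of n = 5,000 with 50 restarts (the restart count
is deliberately generous: at this n the global BIC optimum is the truth's
equivalence class in most but not all draws, and the climber should be
limited by the data, not the search); CI-test calibration on 10,000
replicates of n = 200; cohort-scale checks on the default 17-patient
generator. These sizes make the full suite run in a few minutes on one
CPU while leaving each stochastic assertion a comfortable margin.

## Limitations

The package learns associations, not causes: the network encodes
conditional independencies, and edge directions within an equivalence
class are fixed by deterministic tie-breaks, not by evidence. Instances
within a patient are dependent; instance-level cross-validation therefore
leaks patient information between folds (the patient-level mode exists
precisely to quantify that). ICC confidence intervals use the standard
one-way F approximation, which is anti-conservative for binary ratings
with extreme prevalence. The generator's effect sizes are one defensible
calibration, not an estimate from data; conclusions about real cohorts
require the real recordings.
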