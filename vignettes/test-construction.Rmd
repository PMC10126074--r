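---
title: "Constructing and calibrating a voice learning and memory test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and calibrating a voice learning and memory test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

voxmem implements the construction, calibration, and scoring machinery of a
standardized three-alternative forced-choice (3AFC) voice learning and
memory test. One target voice must be recognized among two unfamiliar foil
voices, with difficulty manipulated through the acoustic similarity of the
three voices and the presentation duration of the utterances. This vignette
explains the models and procedures, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generators do
and do not emulate.

## The acoustic voice space

Each speaker is summarized by three acoustic quantities: mean fundamental
frequency (f0, Hz), formant dispersion (FD, Hz — the mean frequency
difference of successive formants F1 through F4, which telescopes to
(F4−F1)/3), and harmonics-to-noise ratio (HNR, dB). Voice distinctiveness
and discriminability track positions in this space, which is why distances
in it are used as a proxy for perceptual confusability.

`buildVoiceSpace()` z-standardizes the three dimensions within a gender
stratum (triplets are always gender-matched, so between-gender variation
must not leak into the metric). Standardization parameters are stored in
the returned object, making every coordinate auditable back to raw Hz/dB.
Choices made here, where the design was genuinely open:

* f0 is standardized on the raw Hz scale by default. A log-Hz switch
  (`logF0 = TRUE`) exists because pitch perception is closer to
  logarithmic; the transform used is recorded in the object. Nothing
  downstream depends on which is chosen, only the resulting metric.
* Sample SDs use the n−1 denominator, fixed.
* A pooled (both-gender) space is available via `stratum = "pooled"` but is
  not the default, because foils must share the target's gender.

`rmsNormalize()` scales waveforms to a common RMS level (default 60 dB re
2e-5, the convention under which 60 dB is a comfortable playback level for
unscaled digital audio). `aggregateFeatures()` defines only an aggregation
contract over a pluggable framewise analyzer — the package deliberately
contains no pitch-tracking, formant-tracking, or HNR DSP of its own; the
feature-table input path is fully functional without any audio backend.

## Equilateral triplets and similarity levels

A 3AFC trial should not contain a voice that perceptually "sticks out", so
candidate triplets are (near-)equilateral triangles in the standardized
space: `findEquilateralTriplets()` keeps triples whose equilaterality
defect `(max side − min side) / mean side` is at most a tolerance (default
0.10, configurable — published criteria for "equal distances" are not
printed in main texts, so the default is a documented stand-in chosen to
yield non-empty similarity strata on realistic simulated spaces). Collinear
triples have defect ≥ 0.75 and can never qualify at sane tolerances.
Triangle size maps inversely to difficulty: small triangles mean
acoustically similar, confusable, hard trials. `stratifyTriplets()` labels
triplets high/medium/low similarity at two size cut-points (default:
empirical tertiles of qualifying sizes; absolute cut-points can be given).

Learning targets are the voices that are members of the most triplets
(`selectTargets()`), which maximizes the foil combinations available; ties
break lexicographically by speaker id so the whole design pipeline is
deterministic without a seed. `assignTriplets()` then runs a backtracking
constraint search giving every target one test triplet per similarity level
plus one additional medium triplet for the immediate recognition trials,
under global foil-disjointness (every foil identity appears in exactly one
assigned triplet, and never with a second target). Among feasible choices
the search prefers triplets with the smallest equilaterality defect — a
package heuristic, since the original procedure does not state how it chose
among qualifying triplets. The search uses scarcest-slot-first ordering and
forward checking, and carries a node budget (default 20,000 expansions)
after which an instance is reported infeasible-within-budget: proving
infeasibility exactly is exponential, and on simulated spaces a budgeted
verdict plus a tolerance escalation (see the fixtures section) is both fast
and deterministic. Small instances are always searched completely, and an
independent validator re-checks every returned assignment.

## The three-phase blueprint

`assembleBlueprint()` produces the full trial-level plan:

* **Learning phase** — two cycles of alternating familiarization and
  immediate recognition trials. On a familiarization trial the target
  utters three sentences; the same three sentences are used for every
  target, in both cycles. Each immediate recognition trial presents a
  previously unheard sentence spoken by the target and its two learning
  foils; cycle 2 uses new sentences again. Each target therefore accrues
  exactly five distinct sentences (3 familiarization + 2 immediate).
* **Repetition phase** — a passive playlist: per target one
  familiarization sentence and one immediate-trial sentence.
* **Testing phase** — per target the full 3 × 3 factorial of acoustic
  similarity (its three assigned test triplets) and duration (250 ms,
  750 ms, full length), one never-heard sentence per (target, similarity)
  triplet, randomized once into a fixed order.

Constraints enforced and independently re-checked by
`validateBlueprint()`: no sentence appears in both learning and testing
phases; no test-phase foil ever occurred during learning (test foils are
genuinely unfamiliar); target positions are balanced to within ±1 of
uniform per phase. Sentence-to-trial allocation is uniform random without
replacement under the constraints, seeded; position balancing is a
constrained shuffle. Position balance and factorial completeness are
asserted for assembled full designs only — an item subset
(`subsetBlueprint()`, used for the reduced 26- and 22-item versions)
inherits its trials unchanged, so those two properties are design-level,
not subset-level, invariants. Practice/dummy trials (12 before learning, 6
before testing) and break scheduling are carried as metadata only and
never analyzed.

`countStimuli()` counts every distinct (speaker, sentence, duration)
presentation. For the full design with 8 targets this gives 72 learning
stimuli (8 targets × 5 sentences + 16 learning foils × 2 sentences) and
216 testing stimuli (8 × 3 × 3 target presentations plus 48 test foils ×
3 durations), 288 in total; sub-counts are reported so either reading of
a phase total can be audited. The 26-item subset yields 78 testing
stimuli and 150 in total.

`truncateStimulus()` cuts 250/750 ms segments from voice onset with a
10 ms raised-cosine offset ramp (configurable to a hard cut) — plumbing to
avoid clicks, not a claim about the original stimulus processing.

## The IRT engine

Respondent correctness is modelled with unidimensional logistic item
response models. The Rasch model sets
P(correct) = logistic(θ − b); the 2PL frees a per-item discrimination,
P = logistic(a(θ − b)). A person whose ability equals the item difficulty
solves it with probability one half; the 3AFC chance level of 1/3 is a
property of the trial format, not of these models (a guessing floor exists
only in the simulators, as a misspecification scenario).

**Identification.** `fitRasch()` fixes the common discrimination at 1 and
estimates the latent prior SD; `fit2PL()` fixes the latent prior to
standard normal and frees per-item slopes. Free-parameter counts are thus
J + 1 and 2J, the models are nested, and the likelihood-ratio test of 2PL
against Rasch has J − 1 degrees of freedom — the convention behind the
analysis stack this engine mirrors, stated in each `IRTFit` so comparisons
are like-for-like. The Rasch-equivalent common slope on the 2PL scale is
the Rasch-estimated latent SD; the selection workflow uses exactly this
correspondence.

**Estimation.** Marginal maximum likelihood by EM. The latent ability is
integrated over 61 equally spaced quadrature nodes spanning ±6 prior SDs
(the grid lives in prior-SD units, θ = μ + σz with z on [−6, 6]; with an
estimated latent SD above 1, a grid fixed in θ units would truncate
posterior tails noticeably — scaling the grid keeps EAP integrals accurate
to ~1e−9 against dense-grid oracles). Midpoint weights h·φ(z) are used;
for these Gaussian-decaying integrands the equally spaced rule is
accurate far beyond the EM tolerance. E-steps compute person-node
posteriors; M-steps are damped Newton solves per item (2PL in
slope-intercept space, slopes clipped to a configurable interval, default
[0.05, 5], to prevent divergence) and closed-form latent-moment updates.
The EM is deterministic (difficulties initialized from logit response
rates, no random starts), tolerance 1e−5 on the maximum absolute parameter
change, at most 500 iterations; non-convergence is recorded, not raised,
and the stored log-likelihood trace is checked for monotonicity. Items
answered all-correct or all-incorrect by scored respondents are flagged
inestimable and excluded with a warning. Missing responses (omissions) are
excluded from the likelihood cell-wise — never imputed, never scored
incorrect.

**Standard errors** come from the observed information of the marginal
likelihood: the analytic score (Fisher's identity: posterior-expected
complete-data score) differentiated numerically by central differences.

**Abilities and reliability.** `eapAbilities()` returns posterior means
and SDs per person; persons without scored responses get the prior mean
and SD. Under Rasch the sum score is sufficient, so equal sum scores give
equal EAPs. `empiricalReliability()` is the empirical marginal
reliability var(θ̂) / (var(θ̂) + mean(SE²)). `testInformation()` gives
I(θ) = Σ a²P(1−P) and SE(θ) = I(θ)^−1/2.

**Item fit.** `itemFit()` reports infit and outfit mean squares computed
from standardized residuals against the EAP abilities, flagged outside
[0.7, 1.3] by default (the published procedure names only
"likelihood-based fit measures", so the statistic and bounds are package
choices, configurable). A binned observed-vs-expected chi-square is
reported alongside; for it, both the binning ability and the expected
probability of item j condition on the responses to the *other* items
(leave-one-out posterior). This matters: binning on the full EAP selects
persons into bins partly by their response to the very item under test and
inflates the statistic badly even when the model is true, whereas the
leave-one-out version is approximately calibrated and has high power
against a 1/3 guessing floor. `empiricalICC()` provides the binned
observed proportions (with counts conserved under bin merging) for
graphical inspection; note its bins do use the full EAP, so with few items
the observed curve is visibly steeper than the model curve — a known
property of this graphic, not misfit by itself.

**DIF.** `difTest()` compares, for two groups, a null model with shared
difficulties but group-specific latent means and SDs (the first group's
mean anchors the scale; J + 3 parameters) against two fully group-specific
Rasch fits (2J + 2 parameters), so the omnibus LR test has J − 1 degrees
of freedom. Per-item Wald tests of difficulty differences use
all-other-items-as-anchor alignment: item j's shift is measured relative
to the mean shift of the remaining items, with the anchor uncertainty
propagated into the SE. Items inestimable in either group are excluded
with a warning. Type-I behavior was verified by simulation (~5% at
α = 0.05 over replicated null fits), and a +1 logit shift at 250 persons
per group is flagged essentially always.

## Stepwise item selection

`stepwiseSelect()` reproduces the elimination workflow as an auditable
algorithm:

1. Remove every item with observed mean accuracy below 1/3, computed over
   scored (non-omitted) trials only.
2. While the 2PL fits significantly better than the Rasch model
   (LR test, α = 0.05), drop the currently worst item under the 2PL and
   refit. "Worst" is lexicographic: largest |a_j − σ̂_Rasch| (deviation
   from the Rasch-equivalent common slope), ties broken by the larger
   infit/outfit deviation. The elimination order is a package choice —
   the original "stepwise manner" is not specified — and the trace makes
   it auditable rather than claiming replication of a particular
   published path.
3. Once the LR test is non-significant (the recorded model switch),
   continue under Rasch: while any item violates the fit bounds, drop the
   worst violator and refit.

A guardrail aborts (with a partial trace) rather than eliminate below 10
retained items. Every elimination carries exactly one reason
(`below_chance`, `ill_fitting`, `dif`) and the triggering statistic; the
whole procedure is deterministic. `difScreen()` then runs the DIF test per
grouping variable and excludes items whose per-item Wald p-values survive
Benjamini–Hochberg adjustment across items at 0.05 (the published report
names an omnibus test and two excluded items, but no correction; BH at
0.05 is the package default, configurable). `finalizeSelection()` refits
Rasch on the final set and reports difficulties, EAP abilities, empirical
reliability, the information curve, item fit, and the Rasch-vs-2PL BIC
comparison used as the final parsimony adjudication.

## Scoring and norms

`scoreResponses()` removes omission trials — response time at or above
4000 ms, boundary inclusive — before computing sum scores and proportions
correct; omission accounting conserves trials per person, and persons with
zero scored trials are reported as missing with a warning. `tVsChance()`
is the one-sample t test against 1/3 (one-sided "greater" by default). The
packaged `defaultNorms()` table carries the descriptive norms of the
published validation cohort of the instrument this toolkit models (N =
454; overall 0.51 ± 0.18, by gender and by three age bands). The age bands
are printed with a shared 31-year boundary; `normLookup()` assigns age 31
to the younger band, warns above the normed range, and refuses ages below
18. `flagExtremes()` labels scores at least 2 SDs below/above a norm mean
as potential phonagnosia / potential super-recognition, boundaries
inclusive; both overall and group-specific norms can be used, since it is
not stated which the original screening applied. The flags are screening
signals: any clinical conclusion requires comprehensive follow-up testing.
`digitSpanScore()` scores the auditory digit-span companion task: largest
sequence length with at least five of six correct, lengths starting at 4,
honoring the abort rule; failing at length 4 returns the below-floor
sentinel 3.

## Synthetic data: what it emulates, what it does not

`simulateVoiceFeatures()` draws gender-clustered features (defaults: male
f0 ~ N(115, 15) Hz, female ~ N(210, 20) Hz, F1 ~ N(500, 60) Hz, FD ~
N(1000, 80) Hz, HNR ~ N(15, 3) dB) with formant gaps rescaled so FD equals
the mean successive difference exactly. These are realistic magnitudes for
adult speakers, documented as configurable stand-ins — not measurements of
any real speaker pool. `simulateResponses()` generates correctness from
P = c + (1−c)·logistic(a(θ − b)) with optional per-item guessing floors
(1/3 being the 3AFC misspecification scenario), group labels, per-item
group difficulty shifts (DIF), and omissions: omitted trials are missing
with RTs at or above 4000 ms, answered trials get log-normal RTs capped
below the cutoff (only the cutoff is specified by the scoring rules; the
RT shape is invented plumbing). `makeFixture()` chains everything into
bundles sized like the construction stages: 72 items × 232 respondents
(item selection), 26 × 454 (validation), 22 × 454 (final), with omission
rates 1.2% / 1.7% matching the reported stage-wise rates. Because
membership-ranked targets in a random Gaussian cloud can be mutually too
close to be assignable, the fixture path filters target candidates for
per-level triplet availability, tries ranked target combinations in
deterministic order, and escalates the equilaterality tolerance through a
fixed ladder (0.10–0.30) until the assignment is feasible.

What passing tests on these fixtures shows: the geometry, assembly,
estimation, selection, and scoring machinery is internally correct and
calibrated under its own generating assumptions. What it does not show:
that real voice recordings yield these feature distributions, that real
respondents behave like the logistic models, or that the published
participant-level results (reliabilities, validation correlations, group
means) are reproduced — those depend on undeposited response data and are
out of reach by design.

## Numerical choices and problem sizes

Quadrature 61 nodes over ±6 prior SDs; EM tolerance 1e−5, max 500
iterations; discrimination bounds [0.05, 5]; degenerate inputs (all-zero
waveforms, zero-variance dimensions, single-item 2PL, zero-variance
scores) raise typed errors rather than returning garbage. Ties break
lexicographically everywhere. The test suite runs its simulations at
deliberately modest sizes — 400–1000 simulated respondents, 12–24 items,
25–100 replicates per calibration check — chosen so the full suite
finishes in a few minutes while keeping Monte-Carlo error small relative
to the asserted bands; the acceptance checks state their bands
accordingly (e.g., LR rejection rate ≤ 0.12 around a nominal 0.05 over 50
replicates).

## Known limitations

* No 3PL/4PL estimation and no multidimensional models; the engine covers
  exactly the Rasch/2PL comparison the construction procedure needs.
* Infit/outfit against EAP point estimates are mildly biased toward 1
  with short tests (the well-known double-use of the item in the ability
  estimate); the leave-one-out chi-square is the calibrated detector.
* The DIF per-item Wald SEs treat the two group fits as independent given
  the anchor alignment; a joint-information treatment would be slightly
  tighter.
* The assignment search proves infeasibility only within its node budget
  at tight tolerances.
* Audio handling is limited to RMS scaling and onset truncation; feature
  extraction is delegated to a user-supplied backend.
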