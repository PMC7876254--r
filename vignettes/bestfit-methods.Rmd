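---
title: "Methods: constructing and validating the gaze-based best-fit diagnostic algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing and validating the gaze-based best-fit diagnostic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gazedx` builds a screening classifier for autism spectrum disorder (ASD)
from area-of-interest (AOI) eye-tracking features collected over a short,
fixed stimulus sequence. This vignette is the package's own account of the
method: the model and its assumptions, the parameters that matter, the
numerical choices, what the synthetic-cohort generator does and does not
emulate, and the known limitations.

## The measurement model

Gaze is sampled at 50 Hz as monitor coordinates (pixels, origin top-left)
with a per-sample validity flag. The stimulus is a fixed sequence of 12
movie clips — three *social* clips (a still face, two children drawing, a
classroom scene) and nine *preferential* clips (geometric patterns, and
side-by-side human/geometric displays) — separated by 2.0 s attention
grabbers, about 95 s in total. One hundred AOIs (circles and rectangles,
possibly overlapping and nested) are defined across the clips on the
1280 × 1024 monitor.

The packaged stimulus file carries the published clip identities, order and
durations; AOI *geometry*, however, is not published, so the fixture uses
plausible stand-in shapes with the correct per-clip semantics (eye regions
inside face regions, half-screen human/geometric panels in the preferential
clips) and exactly 100 AOIs in total. The geometry is data, not code: a
custom YAML file with the real AOIs can be passed to `gf_stimulus()` and
everything downstream is unchanged.

Scores are computed on raw samples, with each valid sample contributing
exactly 20 ms of dwell:

* `aoi_rate_score()` — dwell inside the AOI divided by the analysis window,
  for three windows: the full clip, the first 1.0 s, the first 2.0 s. The
  early windows target the initial orienting period, where reduced attention
  to faces is most pronounced in young children with ASD. We divide by the
  *window* length (1.0 s or 2.0 s), not the clip length, so that all 300
  rate attributes live on the same [0, 1] scale; windows are half-open
  [0, w) in clip time.
* `aoi_count_score()` — a 0/1 indicator of a "fixed gaze" on the AOI at any
  point in the clip, designed to be robust to knowledge-driven distraction
  in older viewers who glance at a region once and move on.
* `overall_fixation_percentage()` — the share of the whole sequence with
  valid on-screen gaze; a data-quality metric, not a feature.

Two assumptions deserve emphasis. First, no velocity- or dispersion-based
fixation filter is applied: "fixation time" is read as raw sample dwell.
Second, the count score's notion of a fixed gaze is operationalised as a run
of at least `count_min_run` consecutive valid in-AOI samples. The function
default is 1 sample (any dwell at all); the attribute-matrix default is
**25 samples = 500 ms**. The longer default reflects what "presence of a
fixed gaze" should mean on frequently-viewed regions: with any-dwell
semantics, every salient AOI is crossed by essentially every participant and
the count family carries no information, whereas a sustained-fixation
reading leaves the binary attributes with usable between-participant
variance in both groups. 500 ms is deliberately above the conventional
100–250 ms minimum fixation duration because the score asks for a
*deliberate, held* gaze rather than a single fixation event.

## Candidate attribute extraction

Participants are split at **10.0 decimal years** (younger `< 10`, older
`>= 10`). Within each band and score family, an attribute becomes a
candidate when its ASD–TD contrast satisfies `p < 0.05` **or**
`|d| >= 0.5`, where `d` is Cohen's d with the pooled SD (ASD minus TD). The
OR rule is intentionally permissive — at this stage missing a potential
candidate is worse than admitting a weak one — and consequently no
multiple-testing correction is applied; the later stages (fixation floor,
per-AOI deduplication, cross-validation) are the guard against overfitting.

Three decisions here were genuinely open and are resolved as follows:

* **Test choice.** Rate attributes use Welch's *t*-test (a Mann–Whitney
  option is available via `test = "wilcox"`); binary count attributes use
  Fisher's exact test. Deterministic defaults were preferred over a
  distribution-dependent switch, which would make selection depend on a
  normality heuristic.
* **The 20% fixation floor.** Attributes on AOIs whose *gaze fixation
  percentage* is below 20% are dropped, to exclude chance findings on
  rarely-viewed regions. We compute this as the pooled ASD+TD mean of
  100 × the full-window rate score over the band's training rows. Pooling
  (rather than per-group means or per-individual minima) matches the rule's
  purpose: it measures how much evidence the cohort as a whole provides
  about that AOI.
* **Signed vs absolute d.** The 0.5 threshold is applied to |d|, with the
  direction captured separately as the candidate's orientation `sign(d)`;
  a diagnostic contrast in either direction is informative.

Within each AOI only the attribute with the largest |d| survives — this
also collapses the three rate windows sharing an AOI. Ties are broken
deterministically: `rate_full` > `rate_1s` > `rate_2s` > `count`, then
lexical attribute id. Degenerate contrasts (zero pooled SD with equal means)
cannot be oriented and are never selected.

Selection sees only the rows it is given. Second-control participants are
excluded from every training computation by construction
(they are an external validation sample), and the leave-one-out loop relies
on this row discipline for its honesty.

## The sigmoid ensemble

Each of the four (band × family) candidate sets is aggregated to one scalar
per participant: rate candidates are oriented and divided by their training
SD, count candidates are aligned to 0/1 (value if orientation +1, one minus
value otherwise), and the mean is taken over the candidate count. A rate
candidate whose training SD is zero contributes 0 and is flagged — it still
counts in the denominator, so a degenerate candidate dilutes rather than
distorts.

The aggregate is mapped to (0, 1) by a logistic sigmoid σ(a·x + b) fitted by
minimising mean binary cross-entropy with the slope constrained `a >= 0`
(the aggregate is ASD-oriented by construction; a negative slope would mean
the ensemble learned to invert its own orientation, which we forbid). The
sigmoid family, loss and optimiser are not dictated by the construction —
only "fit a sigmoid taking values in (0, 1)" is — so the package uses the
convex, reproducible choice: logistic/cross-entropy, optimised by L-BFGS-B
from a fixed, scale-aware grid of starting values (slopes {0, 0.5, 2, 8, 32}
divided by sd(x); intercepts {logit(prevalence), 0}). No randomness enters
any fit, which makes refits bit-reproducible. Bounds (a ≤ 500, |b| ≤ 50) cap
the parameters under perfect separation while leaving scores strictly inside
(0, 1); the iteration cap is 500 with a 10⁻⁸ projected-gradient tolerance.

**Age-band merging.** The younger and older sub-algorithms of each family
are merged into one age-continuous score

σ(A·[w(age)·s_young + (1 − w(age))·s_old] + B),  w(age) = 1 / (1 + e^{k(age − a₀)}),

with A ≥ 0, k ≥ 0, a₀ ∈ [5, 17] initialised at the 10-year boundary, fitted
by cross-entropy on all labelled training rows. The logistic age weight is
the simplest form that satisfies both requirements: the hard band split used
during selection (recovered as k → ∞) and a smooth continuum of scores along
age (any finite k). The same machinery produces the final blend of the two
chosen modality streams. The objective is cross-entropy rather than AUC:
"maximise predictability" admits either reading, and cross-entropy is smooth,
convex in the outer parameters, and yields calibrated-ish scores for the 0.5
decision rule; AUC differences between the two objectives were not the
design target.

**Modality selection.** Per band, the family with the higher within-band
training AUC is chosen; exact ties go to the rate family (the more granular,
dose–response modality). The fitted model records both merged algorithms, so
the choice is auditable after the fact.

Prediction applies the inclusive rule: score ≥ 0.5 calls ASD. Recordings
whose overall fixation percentage is below the configurable 70% floor are
still scored but flagged `low_fixation`; the flag marks the prediction as
unreliable rather than suppressing it, since a low percentage may itself be
diagnostic and the consumer should decide.

## Evaluation machinery

* `auc()` is the exact Mann–Whitney estimate via midranks (ties count ½),
  hence invariant under monotone transforms.
* `roc_curve()` enumerates every distinct score as a threshold (rule:
  `score >= t` is positive) — no binning, so small-sample ROC vertices are
  exact for the Youden scan.
* `youden_point()` maximises J = sensitivity + specificity − 1 over ROC
  vertices with a 10⁻¹² tolerance on J ties (vertices with mathematically
  equal J can differ in the last floating-point digit); remaining ties go to
  the higher sensitivity, then the higher threshold. Reported operating
  points are therefore always actual ROC vertices.
* `auc_ci()` is a stratified percentile bootstrap (cases and controls
  resampled separately, 2,000 replicates by default, seeded, caller's RNG
  state untouched). A purpose-built resampler replaces the proprietary
  ROC-analysis tooling sometimes used for such intervals.
* `loo_bestfit()` refits the *entire* construction — candidate selection,
  four sub-algorithms, merges, modality choice, final blend — once per held
  out participant and pools the out-of-sample scores into one ROC. Each
  fold's 0.5 call is also recorded as that participant's "vote", giving the
  majority-vote summary alongside the pooled-score AUC. The age-blend
  coefficients are re-estimated in every fold like everything else;
  freezing them would leak the held-out row's influence. A fold whose
  removal empties a class-band cell is skipped with a warning and excluded
  from the pooled report rather than silently imputed.

## The synthetic-cohort generator

Real cohorts of this kind are not publicly shareable, so the package
includes `simulate_cohort()`: within each clip, gaze is a first-order Markov
chain over the clip's AOI states plus *elsewhere on-screen* and
*off-screen*. A participant's stationary weights are drawn from a Dirichlet
around clip-level base weights (label-driven: eye regions 0.28, faces 0.12,
geometric figures 0.11, human figures 0.05, objects 0.03, other 0.02,
rescaled per clip to leave room for the elsewhere and off-screen states);
for ASD-like participants the weights of designated signal AOIs — and of any
AOI state geometrically nested inside them — are shifted on the log scale
and renormalised. Coordinates are emitted uniformly within the chosen
state's region (rejection sampling keeps *elsewhere* outside every AOI);
off-screen states emit invalid samples. The self-transition probability
ρ = 0.95 gives ~0.4 s mean fixations at 50 Hz, so sustained-fixation count
scores and rate scores decouple as they do in real gaze.

Defaults are the study conditions the package is designed around: 39 ASD
and 102 TD training participants plus 24 second-control participants (17 of
24 ASD-like, drawn with a smaller Dirichlet concentration — 12 vs 50 — to
mimic that group's clinical heterogeneity); ages uniform on [5, 17] so both
bands are populated; an off-screen base weight of 0.08, which puts cohort
mean fixation percentages near 90; and 2.5% of participants with degraded
tracking (off-screen weight 0.5, expected fixation ≈ 50%, far below the 70%
reliability floor — exercising the flag path). The default planted signal
is 8 AOIs spanning both directions (reduced dwell on eye/face regions,
increased dwell on geometric halves) at a dwell-logit shift of δ = 1.1.
There is no closed form from δ to the realised effect size, so δ was
calibrated once empirically via `realized_effects()` — the per-AOI Cohen's d
of full-window rate scores — to give a mean realised |d| ≈ 1.2 at 100
participants per group; recovery tests quote realised, not nominal, effects.

What the generator does *not* emulate: saccade kinematics and latencies,
pupil dynamics, temporal structure within a clip (the chain is stationary,
so the early-window attributes carry no extra signal beyond sampling noise),
ADHD-specific gaze signatures in the second-control group, and any
age-dependence of dwell preferences beyond what band-scoped signals inject.
Passing tests on these cohorts therefore demonstrate that the *pipeline*
recovers planted structure, stays calibrated under the null, and does not
leak across folds — they are not evidence about real-world diagnostic
accuracy, which only real recordings can provide.

## Problem sizes and numerical details in the test suite

The suite checks every score against naive per-sample loop oracles (1,000
randomised toy recordings), AUC against exhaustive pair counting and the
Youden point against brute-force threshold scans (500 random sets, n ≤ 30),
selection recovery on a 100-per-group cohort with the calibrated 8-AOI
signal (≥ 75% of planted AOIs recovered), null calibration over 10 seeded
zero-signal cohorts (a fitted model's held-out AUC must stay in [0.4, 0.6];
a null cohort in which the construction finds no candidates at all — which
the permissive OR rule makes possible — shows, a fortiori, no spurious
signal), the training-vs-LOO optimism gap on a 140-participant cohort, and
byte-level determinism of model and report files. Bootstrap coverage is
checked at a reduced size (40 replications of n = 60 per class) chosen to
keep the property informative at interactive runtimes; the type-I error of
the selection test is checked by 2,000-column Monte Carlo at n = 15 per
group. `scripts/acceptance.R` reruns the study-sized pipeline (141 training
participants, full LOO, 24-participant external validation) end to end from
a single seed.

## Limitations

The AOI geometry, the dwell-propensity weights and the δ calibration are
plausibility choices, not estimates from real data; absolute performance
numbers on simulated cohorts (training AUC, LOO AUC, external AUC) reflect
the planted signal strength and should be read only through their
qualitative ordering (training > LOO > chance). The classifier is
single-layered by design and produces a screening score, not a severity
measure. The 0.5 decision threshold, the 70% fixation floor and the 20%
fixation exclusion are protocol constants carried into the defaults;
`bestfit_config()` exposes them, but changing them changes the instrument.
Finally, the LOO implementation assumes the attribute matrix rows are
exchangeable units — family structure or site effects in a real multi-site
cohort would require grouped cross-validation instead.
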