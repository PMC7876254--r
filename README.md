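# gazedx

Constructing and validating a gaze-based diagnostic classifier for autism
spectrum disorder (ASD) in 5- to 17-year-olds.

Atypical gaze on social stimuli — reduced dwell on faces and eye regions,
relative preference for geometric over human figures — is one of the most
replicated behavioural markers of ASD. `gazedx` implements the full
construction of a *best-fit diagnostic algorithm* from area-of-interest (AOI)
eye-tracking features, for researchers who want to build, cross-validate and
externally validate such a classifier, or to study the statistical behaviour
of the construction itself on simulated cohorts.

## The method

A 12-clip stimulus sequence (3 *social* clips and 9 *preferential* clips,
about 95 s with inter-clip attention grabbers) carries 100 AOIs — circles and
rectangles over eyes, faces, human figures, geometric figures and objects on
a 1280 × 1024 monitor. Gaze is sampled at 50 Hz. Each AOI yields four
attributes per participant:

* **rate scores** — the fraction of an analysis window spent inside the AOI,
  over the full clip, the first 1.0 s, and the first 2.0 s (300 attributes);
* a **count score** — a 0/1 indicator of any sustained fixation on the AOI
  regardless of duration (100 attributes).

The classifier is built in five stages:

1. **Candidate extraction.** Within each age band (younger: < 10 years;
   older: ≥ 10 years) and score family, attributes whose ASD/TD contrast is
   significant (*p* < 0.05, Welch's *t* for rates, Fisher's exact for counts)
   *or* has |Cohen's *d*| ≥ 0.5 are retained; attributes on AOIs with a
   pooled gaze-fixation percentage below 20% are dropped; one attribute —
   the largest |*d*| — is kept per AOI.
2. **Four sub-algorithms** (band × family). Candidates are oriented so that
   larger is more ASD-like, standardised by their training SD (rates) or
   aligned as 0/1 (counts), averaged, and passed through a fitted sigmoid
   σ(a·x + b), a ≥ 0, minimising binary cross-entropy.
3. **Age-band merges.** The younger and older sub-algorithms of each family
   are blended age-continuously: σ(A·[w(age)·s_young + (1−w(age))·s_old] + B)
   with a logistic age weight w(age) = 1/(1 + e^{k(age−a₀)}), all
   coefficients fitted.
4. **Modality selection.** Per band, the family (rate vs count) with the
   higher within-band AUC is chosen; ties go to rate.
5. **Final blend.** The two chosen score streams are merged with the same
   age-blend machinery into one score in (0,1); a score ≥ 0.5 calls ASD.
   Recordings with an overall gaze-fixation percentage below 70% are flagged
   unreliable at prediction time.

Validation mirrors the construction: exact Mann–Whitney AUC with stratified
bootstrap confidence intervals, operating points at the maximised Youden
index (sensitivity + specificity − 1), leave-one-out cross-validation that
refits the *entire* construction — candidate selection included — for every
held-out participant, and no-refit evaluation on an external cohort.

Because raw clinical gaze datasets of this kind are not publicly shareable,
the package ships a seeded synthetic-cohort generator: gaze is a first-order
Markov chain over each clip's AOIs plus elsewhere/off-screen states, with
per-participant Dirichlet dwell propensities and configurable group
differences planted on designated AOIs (calibrated via realised Cohen's *d*).
Every pipeline stage is exercised end-to-end on these cohorts.

## Worked example

```r
library(gazedx)

stim <- gf_stimulus()                       # packaged 12-clip / 100-AOI schema
sim  <- simulate_cohort(stim, sim_config(n_asd = 20, n_td = 40,
                                         n_second_control = 12, seed = 7))
m    <- build_attribute_matrix(sim$gaze, stim)
m
#> Attribute matrix: 72 participants x 400 attributes ( 300 rate, 100 count )
#> Count score min run: 25 samples; mean fixation: 91.4 %

fit <- bestfit(m, sim$cohort)
fit
#> Best-fit gaze diagnostic algorithm
#>   candidates: rate 33 (younger) / 40 (older); count 13 / 23
#>   modality: younger = rate, older = rate
#>   training: n = 60 (20 ASD / 40 TD), AUC = 0.991
#>   decision threshold: score >= 0.5 -> ASD

ext <- sim$cohort[sim$cohort$group == "second_control", ]
evaluate_external(fit, m, ext, reps = 500, seed = 7)
#> Evaluation: 7 cases / 5 controls
#>   AUC = 0.857 (95% CI 0.600-1.000)
#>   Youden point: threshold 0.248, sensitivity 1.00, specificity 0.80, accuracy 0.92
```

Reading the output: the simulated training cohort separates almost perfectly
(training AUC 0.991 — optimistic, as training metrics are), while the
12-participant external cohort, scored without refitting, lands at AUC 0.857.
`loo_bestfit(m, sim$cohort)` quantifies the optimism honestly by refitting
everything per held-out participant. Real recordings and cohort tables enter
through `read_gaze_table()` / `read_cohort_table()` (documented CSV formats;
a toy fixture ships under `inst/extdata/`), and custom AOI geometry through
the YAML schema read by `gf_stimulus()`.

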