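---
title: "A four-item hydration self-assessment model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A four-item hydration self-assessment model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrassess)
```

## The problem

Hydration state over a full day is best summarised by the concentration of
a pooled 24-hour urine collection, conventionally expressed as urine
specific gravity (USG). Collecting and analysing 24-hour urine is
impractical outside a study setting, so active occupational populations
(wildland firefighters, construction, agriculture, athletes) need a
self-assessment instrument that classifies the 24-hour concentration from
things a person can observe themselves.

`hydrassess` implements such an instrument — a four-item binary score —
together with the entire chain needed to evaluate it: windowing of a
32-hour void stream into two overlapping 24-hour reference periods,
volume-weighted 24-hour USG, reference classification at two USG cut-offs,
diagnostic-accuracy statistics, stepwise variable selection, and a
synthetic-cohort generator so every stage can be tested end to end without
access to human data.

## The score

Each of four markers is scored 0 when it meets its "low concentration"
criterion, 1 otherwise (all thresholds inclusive on the low side):

| item      | marker                              | 0 when            |
|-----------|-------------------------------------|-------------------|
| intake    | self-reported 24-h fluid intake     | ≥ 2697 mL (F) / ≥ 3697 mL (M) |
| frequency | self-reported 24-h void count       | ≥ 7               |
| volume    | spot void volume before assessment  | ≥ 250 mL          |
| color     | urine color shade (7-level chart)   | ≤ 2               |

The total (0–4) predicts a **low** urine concentration for totals 0–1 and
a **high** concentration for totals 2–4. The reference is the
volume-weighted 24-h USG,

$$\mathrm{USG}_{24h} = \frac{\sum_i \mathrm{USG}_i \cdot V_i}{\sum_i V_i},$$

classified at either a low cut-off (low iff USG ≤ 1.012, "optimal fluid
intake") or a high cut-off (high iff USG ≥ 1.020, the conventional
underhydration threshold). USG is compared after rounding to three
decimals, the instrument's measurement resolution, so a value at the
boundary can never be misclassified by floating-point representation.

```{r score}
score_items(list(sex = "male", reported_intake_24h = 3000,
                 reported_void_count_24h = 8, spot_volume = 180,
                 color_score = 3))
```

## Windowing

A 32-hour collection assessed at 24 h and again at 32 h yields two
reference windows `(t − 24 h, t]`, sharing the middle 16 hours. Membership
is half-open: a void produced at the assessment moment belongs to the
period it concludes. This is a design choice — boundary handling has to be
fixed somewhere, and anchoring on the assessment time keeps the window a
true 24-hour biological reference. A window is flagged `partial` when the
stream cannot cover a full 24 h before its assessment.

## Diagnostic statistics

* **AUC** is computed by the mid-rank (Mann–Whitney) formulation. For a
  graded 5-level score ties are everywhere, and the mid-rank AUC is the
  unique tie-consistent empirical AUC: it equals both exhaustive
  concordant-pair counting (ties counted half) and trapezoidal integration
  of the empirical ROC, which the test suite verifies to 1e-12. Banding:
  excellent ≥ 0.90, good 0.80–0.89, fair 0.70–0.79.
* **Sensitivity / specificity / accuracy** are `tp/(tp+fn)`, `tn/(tn+fp)`,
  `(tp+tn)/n`, reported as percentages rounded half-up to one decimal; the
  raw fractions are retained. A zero denominator yields an explicit `NA`
  ("undefined") rather than an error so sparse per-item tables remain
  printable.
* **Rank-biserial correlation** `(W⁺ − W⁻)/(W⁺ + W⁻)` over the signed
  ranks of nonzero paired differences; **Cramér's V**
  `sqrt(χ²/[n(k−1)])` with the *uncorrected* Pearson χ² (the definition has
  no continuity term; the test wrappers offer correction as an option);
  **Spearman** is Pearson on mid-ranks.
* **Positive-class orientation** is explicit everywhere. For the low USG
  cut-off the positive class is `high_concentration` (suboptimal intake).
  For the high cut-off the published count layout places the
  low-concentration majority in the positive margin, even though the prose
  definition of sensitivity refers to detecting underhydration; both
  readings are defensible, so orientation is an argument
  (`evaluate_model(..., positive =)`) and the default for the high cut-off
  follows the published layout.

## Stepwise selection

The exploratory model-building procedure is forward selection on Wald
p-values (entry at p ≤ 0.10) with backward elimination (retention at
p < 0.05), adjustment covariates forced in during stepping and dropped
from the reported final model when not significant. Wald p-values match
the odds-ratio/CI language the procedure reports; under quasi-complete
separation the Wald statistic collapses (Hauck–Donner), so the
implementation falls back to the likelihood-ratio p-value there, which
keeps a perfectly predictive marker selectable. Ties are broken by
declared candidate order; visited-model bookkeeping guarantees
termination. The judgment-based step ("causal priority to practically
relevant markers") is not an algorithm; a manual `include =` list stands
in for it. Model fitting itself is standard IRLS via `stats::glm`
(tolerance 1e-8, 100 iterations) with explicit separation reporting.

## The synthetic cohort generator

No public dataset exists for this design, so the generator emulates one.
It is a statistical emulator, not renal physiology: no osmolar clearance
or ADH dynamics, only monotone couplings with interpretable parameters.

**Latent model.** Daily fluid intake is log-normal (male log-median
`log(4377)` mL, log-sd 0.48; female intake shifted by `log(2697/3697)` so
both sexes sit identically relative to their intake thresholds). The
systematic 24-hour concentration is

$$m = 1.012 + \beta \cdot \frac{I - T_{sex}}{T_{sex}}, \qquad \beta \le 0,$$

clamped to [1.000, 1.040] and quantized to 0.001 (measurement
resolution). Anchoring at the low reference cut-off makes the intake
marker cross its own threshold exactly where the reference classification
flips, so the instrument is coherent by construction. Per-window truth
adds Gaussian noise (sd `usg_noise_sd`, default 0.0025, shared + per-window
components so the two windows correlate strongly, as observed for
overlapping collections).

**Observables.** Every marker is a noisy monotone function of the
quantized systematic concentration: void count
`floor(rate + (1.012 − m)/0.0015)`; spot volume
`250·exp(−(m − 1.012)/s)` saturating at 900 mL (bladder capacity), with
`s` calibrated so the configured session mean is attained at the median
concentration; color via a fixed 7-level breakpoint table over
[1.000, 1.040] whose shades 1–2 cover USG ≤ 1.012 (levels at 1.006,
1.012, 1.017, 1.022, 1.027, 1.032). Reporting noise is per-marker: a
log-normal diary error (log-sd 0.35), a rounded-Gaussian tally miscount
(sd 1.8 voids — sized so reported and actual counts correlate ≈ 0.8, as
such tallies do in the field), log-normal spot-volume error (log-sd
0.35), and a one-level color misreading probability (0.35). These scales
are anchored to the descriptive behavior of the instruments (single-item
discrimination in the 0.55–0.75 AUC range), not to any test threshold.

**Morning/afternoon asymmetry.** The first-morning void carries overnight
accumulation: its volume gains a hydration-independent gamma component
(mean = configured morning minus afternoon spot means) and its
concentration a positive boost that varies between participants. Both are
scaled by the corresponding noise knobs, so they vanish in a zero-noise
configuration. This is what makes the morning spot markers weaker
discriminators and afternoon assessments slightly more accurate — the
qualitative ordering the evaluation chain should reproduce.

**The coupling dial.** `intake_usg_slope = 0` makes every observable
independent of the truth (model AUC at chance); zero noise
(`usg_noise_sd = 0`, `color_noise = 0`, `self_report_noise = 0`) makes
every marker an exact function of intake, the windows' weighted USG equal
to the latent truth, and the score a perfect classifier (AUC exactly 1).
Residual USG noise is deliberately unobservable to the respondent: it is
the part of concentration that intake does not explain, which no
self-assessment can see.

**Void placement** uses fixed segments of the 32-h stream (day-1 shift,
evening, forced first-morning void between waking and the morning
assessment, day-2 shift, forced last-afternoon void) with no voids during
the sleep block (default 23:00–06:00); roughly two-thirds of a window's
voids fall in the shared 16-h segment.

```{r cohort}
coh <- generate_cohort(generator_config(n_participants = 100, seed = 1))
coh
```

## What the synthetic tests do and do not show

Passing tests on synthetic cohorts demonstrate that the *chain* is
correct: the arithmetic of windowing, weighting, scoring and the
diagnostic statistics, the coupling logic, and the selection procedure.
They do not reproduce the human validation results — the published AUCs
(0.72/0.85/0.81/0.86), descriptive medians and spot-versus-24-h accuracy
percentages depend on the undeposited human dataset. The published
TP/TN/FP/FN counts are shipped as a fixture (`validation_counts()`), and
the printed sensitivity/specificity pairs are recomputed from them
exactly; everything else about the human cohort is covered only
qualitatively (for example, afternoon ≥ morning accuracy under the
generator's asymmetry). The generator also induces inter-marker
correlation only through the shared latent concentration; real markers
may share method variance (e.g. reporting styles) the emulator does not
model.

## Numerical and design choices

* All boundary comparisons are inclusive as the cut-off notation reads
  (≥ 2697/3697 mL, ≥ 250 mL, ≥ 7 voids, color ≤ 2, thirst ≤ 40%,
  duration ≥ 16 s, mass loss ≥ 1% with a 1e-9 relative tolerance for
  scale-precision arithmetic).
* Thirst percentage uses the full 175-mm VAS denominator literally; the
  125-mm "extremely" anchor is part of the instrument but not of the
  calculation.
* Urine mass is taken as volume (1 g ≡ 1 mL).
* Missing markers abort scoring rather than being imputed; the score is
  defined only on complete four-item records, and `classify_cohort()`
  reports incomplete records separately.
* Randomness: `generate_cohort()` seeds R's global RNG from
  `config$seed` — the conventional base-R simulation idiom — rather than
  threading a generator object; identical seed + configuration gives a
  byte-identical cohort, which the suite asserts on serialized output.
* Problem sizes: the test suite and the acceptance script use cohorts of
  400–1000 participants, 50 uncoupled replicates, 20 recovery replicates
  and 200 null-selection replicates; these sizes put Monte-Carlo error
  well inside the asserted bands while keeping a full run in the order of
  a minute.

## Known limitations

* The generator's couplings are monotone with two or three interpretable
  parameters each; it cannot represent non-monotone physiology (e.g.
  over-hydration with frequent small voids).
* Stepwise selection on correlated binary readouts of one latent variable
  is intrinsically unstable at small n; at the study's scale (n = 85) the
  procedure typically retains a subset of the four markers, which is why
  the recovery property is stated at n = 500.
* Covariates enter as main effects only; no interactions or splines.
* No confidence intervals for AUC and no calibration analysis — the
  evaluation layer mirrors the reporting layout it targets.
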