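---
title: "Methods: scoring, accuracy evaluation and synthetic cohorts for the ALTO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, accuracy evaluation and synthetic cohorts for the ALTO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altoscreen)
```

## The problem

Alopecia areata (AA) is an autoimmune, non-scarring hair loss with no
definitive biomarker; population studies therefore need a screening
instrument whose operating characteristics are known. The ALTO is an
eight-item self-administered questionnaire (Q1–Q5 with "yes / no / not
sure" responses, the conditional follow-ups Q3A and Q3B, and a
picture-selection item Q6 with photographs A–D and an explicit "no
representative photographs" choice E), evaluated in a pilot of 239
dermatology-clinic patients: 13 alopecia totalis/universalis, 46 patchy
alopecia (the two AA phenotypes, jointly the gold-positive class), and 180
with other hair loss. This package implements the questionnaire data
model, the nine boolean scoring algorithms, the diagnostic-accuracy
machinery, and — because the respondent-level data were never deposited —
both a synthetic-cohort generator and an inverse reconstruction of the
published summary table.

## Instrument model and skip logic

A validated respondent record stores each of Q1–Q5 as one of
`yes / no / not_sure / missing` and Q6 as a selection set. Three answered
states exist for Q6: one or more photographs; the explicit E choice; and
an answered-but-empty form. The last is not an aesthetic corner case: in
the published other-hair-loss column the photo selections (8+4+0+30) sum
to fewer than the 47 non-E answerers, so real respondents completed the
item without ticking anything. The cohort CSV dialect encodes these as a
semicolon-joined subset of `A;B;C;D`, the literal `E`, the literal
`none`, and an empty cell for a blank item.

Q3A/Q3B are administered only after an affirmative Q3. We also suppress
them when Q3 is "not sure" or missing: the form presents them as
follow-ups to a yes, and the published conditional-row denominators sit
far below the class sizes, consistent with that reading. Validation
enforces the invariant (follow-ups of a non-affirmative Q3 are coerced to
missing with a warning), so downstream code can rely on it.

"Not sure" is retained as its own token rather than collapsed to "no".
The option was added to the instrument to improve completion, not as a
synonym for a negative; keeping it distinct lets scoring policies be
compared. The default policy, `unsure_as_not_yes`, treats anything that
is not an affirmative yes as false — the algorithms are phrased as
"answered yes", so this is the faithful reading. The alternative
`unsure_as_missing` propagates unknowns through Kleene three-valued logic
and returns `indeterminate` when an unknown is decisive.

## Scoring rules and exclusion

Rules are monotone boolean expressions over atoms (`Q3`, `pic(C)`, ...)
with `&`, `|` and the n-ary `any(...)`, parsed from a small DSL and
serialised canonically. Only algorithms 1, 3 and 5 are described in the
running text of the pilot report:

| id | rule |
|----|------|
| 1 | `(Q1 \| Q2) & Q3 & any(Q3A, Q3B, Q4, Q5)` |
| 3 | `(Q1 \| Q2) & Q3 & Q3A & any(Q3B, Q4, Q5)` |
| 5 | `Q3 & any(Q3A, Q3B, Q4, Q5)` |

The remaining six were published only as a figure whose content is not
available to this implementation; they ship as placeholder definitions
that refuse to classify rather than silently guessing. The loader also
refuses definition files in which a text-verified rule has been edited.

The study excluded respondents "with missing data". We read this
per-algorithm: a respondent is excluded from an algorithm's denominator
iff some question that algorithm uses, among those applicable to the
respondent under skip logic, is unanswered ("not sure" counts as
answered). The published per-item missingness with per-row denominators
supports per-item bookkeeping rather than a single global drop. A
`global` exclusion mode (drop anyone missing any question used by any
defined algorithm, for every row) is exposed because the study's phrasing
is ambiguous between the two.

## Accuracy summaries

For a confusion matrix the package reports sensitivity TP/(TP+FN),
specificity TN/(TN+FP), PPV TP/(TP+FP) and NPV TN/(TN+FN), each with a
Clopper–Pearson interval in beta-quantile form (`qbeta(α/2, k, n−k+1)`,
`qbeta(1−α/2, k+1, n−k)`; 0 and 1 at the boundaries; default α = 0.05).
"Exact binomial" admits variants, but the beta-quantile form reproduces
every published CI bound (e.g. 53/59 → 79.2, 96.2 and 176/180 → 94.4,
99.4), which fixes the choice. PPV/NPV are computed from the observed or
reconstructed cells, never from prevalence formulas: the published values
are empirical cohort quantities.

When matching printed numbers, percents are rounded to one decimal with
ties half away from zero — the convention of the software family used for
the original analysis; it reproduces all nine published rows under
reconstruction, which a banker's-rounding convention does not guarantee.

## Reconstruction from printed summaries

`reconstruct_confusion(sens, spec, n_case, n_control)` enumerates
`tp ∈ 0..n_case`, `tn ∈ 0..n_control` and keeps every pair whose rounded
sensitivity/specificity equals the printed values. The preimage of
rounding need not be a single matrix, so all candidates are returned;
with 59 cases and 180 controls each of the nine published rows happens to
have a unique solution, and in each case the implied screen-positive
count, PPV and NPV equal the printed ones. The published NPV denominators
imply the per-algorithm evaluable sets may have differed slightly from
239; since the per-algorithm exclusion counts were not printed, the
reconstruction fixes 59/180 and would report residual inconsistency
rather than resolve it (none arises).

## Cohort comparison statistics

Age is compared across the three classes with classical one-way ANOVA
(respondents with unknown age dropped); pairwise contrasts use Welch two
sample t tests with Šidák adjustment `1−(1−p)^3` — the original report
names the correction but not the underlying pairwise test, and Welch is
the safer default given unequal class sizes and spreads (a pooled-variance
option is exposed). Sex and race composition use Fisher's exact test in
its Freeman–Halton r×c form with probability-ordering extremeness,
computed by the network algorithm in `stats::fisher.test` (an independent
full-enumeration oracle backs it in the test suite); column percents are
computed over known values only, mirroring the published footnotes on
unknown age, sex and race.

## The synthetic-cohort generator

The generator is the package's stand-in for the undeposited pilot data:
it draws seeded cohorts whose *marginal* structure matches the published
tables.

* **Class sizes** 13/46/180 exactly.
* **Item probabilities** are the printed fractions with the denominators
  the printed percentages imply — e.g. patchy Q3 42/46; Q2 uses the
  reduced denominators (5/12, 19/45, 7/175) implied by the printed
  percents; Q3A/Q3B rates are conditional on administration and
  answering (e.g. other-class Q3B 40/50 of 58 administered), with the
  unexplained shortfall mirrored as item-specific missingness rather
  than resolved.
* **Missingness** is missing-completely-at-random at per-item, per-class
  rates; no mechanism was described, so none is invented.
* **Skip logic** by construction: follow-ups are drawn only after an
  affirmative Q3, and a Q3 masked to missing takes its follow-ups with
  it.
* **Q5 ⇒ Q4** (complete scalp-and-body hair loss implies complete scalp
  loss): Q5 is drawn first and Q4 among Q5-negatives uses the residual
  probability `(p4−p5)/(1−p5)`, so the Q4 marginal is preserved exactly;
  specs violating `p4 ≥ p5` are rejected at construction.
* **Pictures**: an answered item is E with its printed probability,
  otherwise photographs are included independently at
  `p/(1−p_E)`, so the conditional-on-answered inclusion marginals equal
  the printed ones; an all-empty draw is the answered-but-empty state
  discussed above.
* **Demographics**: normal ages truncated at 18 (the study's eligibility
  floor; only means/SDs were printed), categorical sex/race at the
  printed per-class fractions, unknowns at the footnoted rates.
* **"Not sure" rates** default to zero: the published table reports only
  yes-counts, giving no basis for splitting the remainder, and the
  scoring default makes yes/non-yes the operative distinction.

Within a class, items are otherwise conditionally independent. That is a
deliberate, falsifiable default: the published marginals identify nothing
about the joint distribution. The single dependence knob the generator
exposes is a per-class copula weight coupling Q1/Q2 to Q3 (with
probability ρ the prior-diagnosis items reuse Q3's latent uniform),
which preserves all marginals; `calibrate_spec()` hill-climbs ρ toward
target operating points under common random numbers, accepting only
improvements, and claims no optimality.

### What passing tests do and do not show

Marginal-recovery tests (500 seeded cohorts, every published cell with a
denominator ≥ 10, three binomial SDs) show the generator reproduces the
published *marginals*. They cannot certify the *joint* behaviour: under
conditional independence algorithm 5's mean simulated sensitivity lands
within a point or two of the published 89.8% (it is nearly pinned by the
marginals), but its specificity settles near 75% against the published
82.8%. The implied false-positive rate among Q3-positive non-AA
respondents is lower in the real data than independence predicts —
evidence of negative within-class dependence between Q3 and the follow-up
block that the printed tables do not quantify. The package reports this
gap (the simulation check on specificity is logged, not asserted) instead
of retuning generator parameters to force agreement, which would amount
to inventing unpublished correlation structure. Synthetic cohorts are
therefore suitable for exercising the pipeline and for power-style
calculations anchored on marginals, not for re-estimating joint-dependent
operating points.

## Numerical and policy choices

* Tolerances: Clopper–Pearson is checked against a binomial
  tail-inversion bisection oracle to 1e-8; Fisher p-values against full
  enumeration to 1e-8; printed-table matching is exact at the printed
  precision after half-away-from-zero rounding.
* Fisher's exact test refuses exact computation above a grand total of
  500 and directs the caller to the Monte-Carlo option.
* Degenerate inputs: zero within-group variance makes ANOVA error with a
  clear message (the characteristics report flags it rather than
  failing); PPV/NPV with empty denominators are flagged undefined, not
  NaN; an empty reconstruction result signals inconsistent printed
  inputs, distinct from an error.
* Problem sizes: the acceptance checks use 200 simulated cohorts for
  operating points and 500 for marginal recovery — enough for the
  binomial SEs involved to be a few tenths of a percentage point.
* The aggregate "yes to at least one item" row is configurable (default:
  the five unconditional items Q1–Q5 over the full class denominator);
  the original table does not define which items its aggregate row
  spans.

## Known limitations

* Six of the nine algorithms are placeholders pending transcription of
  the published figure; all machinery accepts them the moment their DSL
  strings are supplied.
* The generator emulates the analysed cohort of 239; it does not model
  the 22 pre-excluded questionnaires, enrolment over time, free-text
  diagnoses beyond a label field, or any response-dependent missingness.
* Single-cohort accuracy estimates at n = 239 are noisy (binomial SE of
  a sensitivity near 90% with 59 cases is ≈ 4 points); comparisons
  should use the simulation-averaged operating points.
* The pilot was clinic-based; spectrum bias means these operating
  characteristics will not transfer unchanged to general-population
  screening. The package evaluates the instrument under the pilot's
  conditions only.
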