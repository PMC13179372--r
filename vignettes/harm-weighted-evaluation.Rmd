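---
title: "Harm-weighted evaluation of paired diagnostic raters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harm-weighted evaluation of paired diagnostic raters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmdx)
```

## The evaluation model

harmdx compares diagnostic raters against an adjudicated reference on a
six-category acid–base task: normal status, the four single (primary)
disorders (metabolic acidosis/alkalosis, respiratory acidosis/alkalosis),
and mixed disorder (simultaneous metabolic and respiratory disturbance).
The central premise is that categorical disagreement is not exchangeable:
calling a mixed disorder *normal* (false reassurance) can delay
escalation in a deteriorating patient, while swapping one single disorder
for a neighbour usually cannot. The package therefore layers four views
over the same paired cohort:

1. **Agreement** — accuracy with exact binomial intervals and unweighted
   Cohen's κ against the reference.
2. **Complexity stratification** — the mixed-reference stratum versus the
   rest, since performance on physiologically complex cases is the
   clinically informative margin.
3. **Multi-label decomposition** — the metabolic and respiratory
   components scored as two independent binary detections, decoupling
   "recognized the physiology" from "picked the right exclusive label".
4. **Harm weighting** — a per-case score from a three-tier severity
   hierarchy, compared between raters with paired non-parametric
   inference.

Assumptions worth making explicit: the reference standard is treated as
error-free ground truth; cases are independent (one observation per
patient); and raters emit hard labels, so no calibration or ROC analysis
applies.

## Error taxonomy and harm weights

`classify_error()` maps each ordered (reference, predicted) pair to one
of four tiers: `correct`, `false_reassurance` (mixed → normal),
`mixed_as_single` (mixed → any single disorder), and
`other_misclassification`. Over the 36 ordered pairs the tiers have
cardinalities 6/1/4/25, which the suite verifies by enumeration.

One placement was genuinely open: where *overclassification* (a single or
normal case predicted as mixed) sits. We assign it to the residual
lowest tier, reading the hierarchy as ordered by the danger of
*under-recognizing* complexity; overcalling complexity prompts further
work-up rather than false security. Users who weigh defensive
overclassification differently can supply their own weights — only the
strict hierarchy `w_fr > w_ms > w_other ≥ 0` is enforced.

The default weights are not arbitrary: with the top tier anchored at
1.0, reproducing the two published mean harm scores (0.064 and 0.184 over
50 cases) from the fixture's tier counts is a nonsingular 2×2 linear
system, solved by `calibrate_weights()`:
w = (1, 0.731428…, 0.308571…). The anchor is a free scale — mean harm is
linear in the weights (property-tested) — so only weight *ratios* are
substantive.

## The canonical fixture

No case-level data accompany the source study; all published quantities
are marginals (category distribution 24/8/6/5/4/3 over 50 cases, correct
counts 41/36, per-category detection fractions, two rounded κ values, an
exact McNemar p, harm means). `build_canonical_fixture()` embeds one
fixed 50-case assignment found by hand constraint satisfaction that
reproduces every such marginal simultaneously; `verify_constraints()`
recomputes each one and itemizes violations, and the suite asserts the
report is empty. Three derivations deserve note:

- **Paired discordance.** The exact McNemar p-value 0.267 with correct
  totals 41 vs 36 forces the discordant pair counts: b − c = 5 and
  2·P(X ≤ c | b + c, ½) = 0.267 has the unique solution (b, c) = (9, 4)
  (2 · 1093/8192 = 0.26685), giving the paired structure 32/9/4/5.
- **Component flags.** The published component false-negative counts (4
  metabolic, 4 respiratory for the AI, all four from its false-normal
  cases) are only attainable if some component flags differ from what the
  predicted category implies; seven AI assessments therefore carry
  independently coded flags, mirroring the study's independent
  multi-label coding channel.
- **Unpinned cells.** Off-diagonal placements not fixed by any printed
  count are set arbitrarily but frozen in source; the rounded-κ windows
  constrain but do not uniquely determine them. The fixture is
  observationally equivalent to the published statistics, not a recovery
  of the true records.

Because 37 of the 50 paired harm differences are zero under the default
weights, the signed-rank test runs on 13 nonzero differences; its p-value
(and the bootstrap interval endpoints) depend on exactly this pairing,
which the marginals do not pin down. The suite therefore asserts
significance bounds and bracketing for those quantities, not exact
published values.

## Statistical machinery and numerical choices

- **Clopper–Pearson intervals** use the closed beta-quantile form, with
  bounds clamped to 0/1 at k = 0 and k = n; tests compare them against a
  `uniroot` tail-inversion oracle for every (k, n) with n ≤ 30.
- **Cohen's κ** is computed case-wise; its CI uses the asymptotic
  Fleiss–Cohen–Everitt standard error with normal quantiles (the CI
  method was unstated in the source; this is the standard auditable
  choice). Degenerate marginals with p_e = 1 raise an explicit error. A
  matrix-route computation exists separately and the two paths are
  asserted equal.
- **Exact McNemar** doubles the smaller binomial tail and caps at 1;
  b + c = 0 returns 1. This is the only standard variant consistent with
  the published 0.267. Mid-p and continuity-corrected chi-square variants
  (the latter matching `stats::mcnemar.test`, including its correction
  cap at |b − c|) are available behind a flag.
- **Exact Wilcoxon signed-rank** uses zero-discarding by default (Pratt's
  zero-rank method behind a flag; the study's choice is unknowable from
  the published p alone). The exact null distribution is built by
  convolution over *doubled* average ranks — integers even under ties —
  for up to 25 nonzero differences; beyond that, the normal approximation
  with tie-corrected variance and continuity correction. The two-sided
  p-value is the point-symmetric tail mass P(|W − μ| ≥ |w − μ|), which
  the suite checks against full 2^m enumeration up to m = 12 and against
  `stats::wilcox.test` on tie-free data.
- **Bootstrap** resampling is paired at the case level — both raters'
  scores travel together, the only unit that respects the design — with
  percentile bounds, B = 5000 by default, fully seeded.
- **Power** uses the unpaired two-proportion arcsine approximation
  Φ(|h|√(n/2) − z₁₋α/₂), the standard form for post-hoc power at an
  observed Cohen's h; it is knowingly approximate for a paired design.
- **Rounding** for display is half-away-from-zero (proportions 2 dp,
  p-values 3 dp, harm means 3 dp); all returned objects keep full
  precision. Rounded-κ constraint checks use the same rule.
- **False-reassurance testing** takes an explicit null rate `p0` and
  performs the exact binomial test via `stats::binom.test`. No default
  null is supplied: the choice is substantive, and published evidence does
  not determine it (a zero null is degenerate — any positive count
  rejects it trivially).

## The synthetic generator

`generate_cohort()` samples reference categories i.i.d. from a
six-category distribution (default: the fixture's 24/8/6/5/4/3
proportions), then each rater's label from its reference-conditional
confusion row, and each component flag from detection/false-flag
probabilities conditioned on the *reference* components. Two deliberate
simplifications: raters are conditionally independent given the
reference (the marginals publish no inter-rater dependence model — the
fixture, which does encode the observed pairing, covers correlated
behaviour), and component flags are independent of the predicted label
given the reference, mirroring independent multi-label coding. The
generator emulates label-level behaviour only — no blood-gas values, no
case-mix drift, no within-rater learning — so passing recovery tests
shows the estimators are consistent for the generating profile, not that
real raters behave like the profile.

Parameter-recovery tests run at n = 50,000 cases, where the binomial
standard error on the mixed stratum (~24,000 cases) is ≈ 0.003 and a
±0.02 tolerance is a 6σ band; smaller property tests use hundreds to a
few thousand cases. All stochastic tests are pinned by fixed seeds.

## Limitations

The fixture is one member of the equivalence class of datasets matching
the published marginals; statistics that depend on the unpublished
case-level pairing (exact bootstrap endpoints, the exact signed-rank p)
are reproduced only up to the bounds stated above. Harm weights are a
modelling instrument, not measured clinical harm. The free-text
harmonizer is a deterministic keyword rule table — auditable and
editable, but no substitute for expert adjudication of genuinely
ambiguous narratives.
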