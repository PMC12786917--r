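---
title: "Methods: questionnaire-based prediction of endometriosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: questionnaire-based prediction of endometriosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoscreen)
```

## The problem

Endometriosis (EMS) is usually confirmed by laparoscopy and histology,
often years after symptom onset. A recurring observation in symptom
research is that no single pain parameter separates women with EMS from
women without it; what discriminates is the *pattern* — how many
group-discriminating symptoms a patient reports and how intense her pain
is overall. `endoscreen` implements a complete, reproducible version of
such an analysis for a case-control questionnaire design (reference
cohort: n = 119 histologically confirmed cases, n = 109 examination-
negative controls, all using hormonal contraception): record model,
composite scores, a hand-crafted decision tree, the diagnostic-accuracy
statistics used to evaluate it, and a synthetic cohort generator
calibrated to the published group marginals so that the entire pipeline
is testable without patient-level data (which was never published).

## Record model

A cohort is a data frame with one row per patient, with columns defined
by a codebook (`default_codebook()`): demographics, the "classical" EMS
symptoms with 0–10 numeric rating scales (NRS), eleven pain adjectives,
seven pain locations, the menstrual-timing question, the PainDETECT
items (seven 0–5 sensory items, a four-level pain-course pattern, a
radiating-pain flag, and three NRS intensity items), and an optional
disease label. Missing answers are represented explicitly (empty cells
in files, `NA` in memory) and are never imputed at this layer; the
scoring layer defines the missing-data rule instead, because the study
design tolerated missing answers ("a single missing answer is never
decisive" is a property of scores built from many items, not of the
storage model). Validation (`validate_cohort()`) is total — it reports
violations rather than failing — while file reading is strict and names
the row, column, and token of the first offence.

The menstrual-timing rows deserve a note: "pain before menses", "during",
"before/during", etc. are mutually exclusive categories of one question.
The package stores three booleans and reconstructs the categories from
them; the *before-and-during* category means before and during but not
after menses.

## Composite scores

**PainDETECT final score.** Sum of the seven sensory items (0–35), plus
a course-pattern adjustment (0 for persistent with slight fluctuations,
−1 for persistent with attacks, +1 for either attack pattern), plus 2
for radiating pain, clamped to 0–38 (the −1 adjustment could otherwise
produce −1). Missing components contribute 0, but a record with *no*
PainDETECT input at all is "not scorable" (`NA`), never a silent
negative. Bands partition the range: negative 0–12, unclear 13–18,
positive 19–38.

**Pain-intensity sum (`sum_vas`).** The default `"eight_item"` variant
sums the NRS for dysmenorrhea, dyspareunia, dysuria, dyschezia, chronic
pelvic pain, pain now, strongest pain in 4 weeks, and average pain;
missing items count 0. A `"five_item"` variant (the five classical
symptom scales only) is retained as an explicit flag because the
reference report is internally inconsistent here: its stated item list
implies group means of about 35 (cases) and 9.3 (controls) — the sums of
the printed per-item means — while its printed composite means (19.2 and
5.13) are much closer to the five-item sum (≈20 and ≈5.9). The package
asserts neither reading as the original computation; the eight-item
list follows the stated definition and is the default everywhere.

**Significant parameters (SP).** `default_sp_registry()` enumerates 34
binary rules — the items the reference analysis found group-
discriminating: 33 record-level rules (presence indicators, NRS
thresholds such as dysmenorrhea NRS > 3, the before-and-during timing
category, nine of the eleven adjectives, the three intensity scales
> 0, the seven locations, three of the four course patterns, and
PainDETECT final > 3) and one score-level rule, pain-intensity sum
> 8.5. The burning and diffuse adjectives and the persistent-with-
slight-fluctuations pattern are *not* SP rules. With this registry the
sum of per-rule prevalences reproduces both published mean SP counts
from the published per-item counts (18.80 vs 18.88 in cases, 5.95 vs
5.98 in controls) — the expectation identity used as a deterministic
acceptance check. A published cut-off of 8.5 is read as "strictly
greater than 8.5", i.e. at least 9 for integer scores, making the two
published statements of the root cut-off (8.5 and 9) the same rule.
Missing answers never trigger a rule, which gives the monotonicity
property tested in the suite: making any single answer more symptomatic
never lowers the SP count or the pain sum (the timing question, being a
single categorical answer, is exempt by construction).

## The decision tree

The engine (`classify()`, `evaluate_tree()`) evaluates arbitrary binary
trees whose predicates reference the SP count, the pain sum, or any
record item; topology is data (JSON documents), never code, and
predicates on missing answers evaluate to false.

The shipped default reconstructs the published hand-crafted rule from
its 11 named predicates. The published description gives the inventory
— SP count with cut-off 9 as root, pain sum with cut-off 12, dysuria,
dyspareunia, constipation, thighs/legs, vagina/mons pubis, cramping,
pulling, strongest pain in 4 weeks, flashing pain — but not the branch
arrangement. The arrangement is, however, strongly constrained by the
published confusion matrix (100, 9, 9, 110) together with the published
SP-cut-off table (76, 33, 4, 115): after the root, the remaining stages
must *demote* about three quarters of the high-SP controls (33 → 9
false positives) while keeping 96% of the high-SP cases (115 → 110 true
positives). No disjunction that rescues root-positive patients *to* the
positive class can do that — among high-SP patients of either group,
nearly everyone has at least one of these prevalent symptoms — so the
default topology is confirmation-shaped: a root-positive patient is
classified EMS only if (a) pain sum > 12 and strongest pain > 3 and at
least one of cramping / pulling / dyspareunia / constipation /
thighs-legs / vagina, or (b) pain sum > 12, strongest pain ≤ 3, and
flashing pain, or (c) pain sum ≤ 12 but dysuria (the single most
specific symptom, 35.3% vs 0.9%). The strongest-pain threshold (> 3) is
not printed anywhere and is configurable in the document. This
reconstruction is a package design choice, clearly labelled as such;
users can load any alternative topology from JSON.

## Diagnostic statistics

All group comparisons use the field's standard tests: Fisher's exact
test for 2×2 tables (two-sided p by the point-probability method — the
sum of probabilities of all tables no more probable than the observed
one; the test suite verifies this against full hypergeometric
enumeration) and the Mann–Whitney test for NRS comparisons (exact
enumeration when both groups have ≤ 8 untied observations, otherwise
the tie-corrected normal approximation). No multiple-testing adjustment
is applied, matching the reference analysis; `stats::p.adjust` composes
trivially with the returned p-values if wanted.

`diagnostic_summary()` computes the accuracy panel from a fixed table
orientation (rows = truth with controls first, columns = test result
with negatives first): sensitivity, specificity, PPV, NPV, accuracy,
LR+ = sens/(1−spec), LR− = (1−sens)/spec, DOR = LR+/LR− =
(tp·tn)/(fp·fn), and RR = PPV/(1−NPV). RR is deliberately defined as
the risk of disease given a positive versus a negative test — this is
the only definition that reproduces both published RR values (15.54 and
11.20) exactly from the published tables. Proportion intervals use the
Wilson score method (empirical coverage ≥ 93% at n = 100 is asserted in
simulation); ratio intervals use the log (Woolf-type) method. The
reference report does not state its CI method and some of its printed
intervals are not internally consistent, so confidence intervals are
never equality-tested against published values — only point estimates
are. When a cell is zero the Haldane–Anscombe +0.5 correction is
applied to the ratio estimates only and flagged in the output.

`roc_cutoff()` computes the AUC by the rank formula (equivalent to
concordant-pair counting, which the suite checks directly for n ≤ 50),
a Hanley–McNeil confidence interval, and the Youden-optimal cut-off
reported as the midpoint between adjacent distinct observed values,
resolving J-ties toward the higher specificity.

## The synthetic cohort generator

`generate_cohort()` draws labeled cohorts whose per-group *marginals*
match the reference tables; the joint structure is modelled, not known:

* **Binary items** (symptoms, adjectives, locations, demographics
  flags) come from a Gaussian copula with exchangeable latent
  correlation `copula_rho` (default 0.3) and the published Bernoulli
  marginals. Correlation leaves every marginal — and hence the expected
  SP count — untouched; it widens the SP-count distribution, which is
  what the tree's operating point is sensitive to. The default 0.3 is a
  field-typical choice for symptom inventories: strong enough to
  produce the heavy upper tail of multi-symptom controls visible in the
  published SP-cut-off specificity (0.697), weak enough that symptoms
  are not collinear.
* **NRS values** are zero-inflated: 0 whenever the symptom indicator is
  false, otherwise an integer from a rounded normal on 1–10 whose
  conditional moments are solved from the published *unconditional*
  mean/SD and the prevalence (conditional mean = mean/prevalence,
  clipped to [1, 10]; conditional variance floored at 0.25). This is
  the simplest model reproducing both the printed prevalence and the
  printed unconditional moments. The case-group dysmenorrhea mean is
  garbled in the reference table; the generator default (6.3) is
  derived from the published overall mean pain level (8 × 4.45 minus
  the seven legible means).
* **PainDETECT** is generated score-first: the final score is drawn
  from the published five-category distribution ({0}, 1–3, 4–12, 13–18,
  19–38), uniformly within the category, so the band prevalences and
  the >3 SP rule are calibrated exactly in expectation. The course
  pattern is then drawn conditionally on a non-zero score with
  probabilities scaled so the *unconditional* pattern marginals equal
  the published counts, and the seven sensory items are back-filled as
  a uniform random composition of the required sensory sum (drawing s
  of the 35 unit slots without replacement), so that re-scoring the
  record reproduces the drawn final score. Radiating pain has no
  published prevalence and is left missing. Uniform-within-band is a
  simplification: it reproduces the published band counts exactly but
  only approximates the published score means (≈10.4 vs 10 in cases,
  ≈2.6 vs 2.3 in controls).
* **Missingness** is applied last, independently per item, at the small
  published missing-data rates.

Two derived rules cannot be calibrated by marginals alone and are
documented as such: dysmenorrhea NRS > 3 (a consequence of the NRS
model; realised ≈ 0.75 vs published 0.74 in cases) and pain sum > 8.5
(a consequence of the eight NRS models jointly; realised well above the
published 0.86/0.21 because the published per-item means are
inconsistent with the published composite means, as discussed above).
The calibration audit `recover_marginals()` reports every item and
rule, with binomial standard errors, against its target.

**What passing tests do and do not show.** The generator reproduces
marginals, not the unknown true inter-item correlation, so synthetic
checks of the *tree* are band checks: across 50 cohorts at the study
size, mean sensitivity and specificity must fall in [0.85, 0.97],
bracketing the published 0.924/0.917. Observed values (≈0.93/0.87) sit
in that band; nothing stronger than that is claimed about real data.
Likewise the Youden-optimal SP cut-off on synthetic cohorts lands above
the published 8.5 (typically ≈12.5) because the exchangeable copula
produces a more symmetric control tail than the real cohort evidently
had; the cut-off itself is therefore treated as an input (registry
constant), not as a reproducible estimate.

## Numerical and design choices

* Scores are integers; all cut-offs are half-integers, so comparator
  choice at the boundary never arises in practice.
* Fisher's two-sided p uses a relative guard of 1e−7 when comparing
  point probabilities, matching standard practice.
* Problem sizes used by the test suite and the acceptance script were
  chosen to make Monte-Carlo error small relative to the asserted
  tolerances: 100× cohorts (n = 22,800) for 3-standard-error prevalence
  recovery, 15,000 per group for the correlation-invariance check
  (tolerance 0.15 ≈ 2.7 Monte-Carlo SDs), 2,000 replicates per
  proportion for Wilson coverage, and 50 cohorts at n = 228 for the
  tree's operating band.
* Determinism: a cohort spec carries its seed; equal specs produce
  byte-identical serialised cohorts.

## Limitations

* The tree topology is a constrained reconstruction, not the original.
* The generator's exchangeable correlation is a modelling convenience;
  real symptom clusters (e.g. bladder vs bowel) are not block-
  structured here, and tree results on synthetic data are accordingly
  band-level only.
* The pain-intensity composite inherits an inconsistency of its source
  and therefore ships in two variants.
* Confidence intervals are method-consistent within the package but
  intentionally never compared to published intervals.
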