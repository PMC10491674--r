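---
title: "Short-term versus long-term toxicity concordance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-term versus long-term toxicity concordance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxconcord)
```

## The question the package answers

Regulatory toxicology packages for a new molecular entity include repeat-dose
studies of increasing duration: short-term (at most 6 weeks), mid-term (more
than 6 and less than 20 weeks) and long-term chronic studies (26 weeks or
more). Long-term studies consume the most animals, so a recurring 3Rs
question is whether the findings of the short and mid-term studies already
predict what the chronic study will show. `toxconcord` treats the short/mid
observations as a *diagnostic test* for the long-term observations and
quantifies that predictivity per finding category with 2×2 contingency
tables, likelihood ratios, Fisher's exact test and false-positive /
false-negative frequencies.

## Data model

A dataset is two tab-delimited tables. A **study record** carries the
molecule, its modality (small chemical entity vs large molecule/biologic),
species, duration in weeks, administered dose levels with a dosing-interval
descriptor, and the study NOAEL (no observed adverse effect level — the
highest dose without adverse effects, or "not identified"). A **finding
record** carries one treatment-related observation: one of nine base
categories, a free-text term, the affected organ for post-mortem categories,
and — crucially — the study toxicologist's adverse / non-adverse call, which
is always an explicit input and never inferred.

Refinement derives everything else:

* **Species groups.** Rat and mouse form the rodent group; cynomolgus
  monkey, dog, minipig and marmoset the non-rodent group. Matching is
  case-insensitive over a configurable synonym table.
* **Duration classes.** `short` (≤ 6 w), `mid` (6–20 w), `long` (≥ 26 w).
  Durations in the 20–26 week gap satisfy none of the three definitions; we
  label them `unclassified` and exclude them from both analysis phases with
  a message, rather than silently absorbing them into a neighbouring class.
* **Per-day doses.** Dosing intervals differ between studies, so doses are
  compared per day: `dose × administrations_per_day` (0.5 for
  every-other-day dosing). Units are carried as opaque strings; the package
  refuses to compare across different units rather than guessing a
  conversion.
* **Controlled terminology and high-level labels.** Raw terms map to
  controlled terms per category (case-insensitive, whitespace-normalized).
  The nine base categories collapse to six high-level labels: the four
  clinical-sign categories stand for themselves; absolute body weight and
  body weight gain merge into *body weight changes*; and the three
  post-mortem categories (macroscopic, microscopic, organ weights) are
  replaced by the *target organ system* of the affected organ, looked up in
  the organ map — so a hepatocellular hypertrophy, an increased liver weight
  and a hepatic mass all contribute to the single label "liver". The
  organ-system vocabulary is data-driven (whatever the organ map file
  defines), not hard-coded.

## The concordance model

For each molecule, species group and high-level label, the **presence
matrix** records whether at least one matching finding occurred in at least
one study of the *test* phase (short and mid pooled; a configuration switch
allows short-only or mid-only pooling) and of the *long* phase. Presence is
an OR over studies; severity and reversibility are recorded but do not
affect presence. A *scope* restricts which findings count: `adverse`,
`non_adverse`, or `all`. A molecule enters a species group's universe only
if it has at least one study in *both* phases in that group, so every
contingency table over a group partitions the same fixed set of molecules.
Scope restriction is monotone by construction: presence under `adverse`
implies presence under `all`.

Counting molecules of the universe gives the 2×2 table — TP (finding in both
phases), FP (short/mid only), FN (long only), TN (neither) — and from it:

* sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)`;
* the positive likelihood ratio `+LR = sensitivity/(1−specificity)`: how
  much seeing the finding early raises the odds of seeing it in the chronic
  study;
* the inverse negative likelihood ratio `iLR− = specificity/(1−sensitivity)`:
  how much *not* seeing it early raises the odds of not seeing it late;
* `%FP = 100·FP/N` and `%FN = 100·FN/N` with `N = TP+FP+FN+TN`;
* a Fisher exact p-value, with rows below `alpha` flagged significant and
  only those reported in the published-table style output.

Likelihood ratios are read on the standard evidential scale: above 10 a
large and often conclusive shift in probability, 5–10 moderate, 2–5 small
but sometimes important, 1–2 rarely important; the `lr_cutoff` of 5 marks a
"high" ratio.

Two definitions of `iLR−` circulate: the ratio form above, and its exact
reciprocal written in count notation, `FN(FP+TN)/(TN(TP+FN))`. They cannot
both be the intended statistic. We implement `specificity/(1−sensitivity)`,
because reference values such as 1.67 for the table (2,0,3,37) and 6.82 for
(7,5,1,29) agree only with this form; a property test documents the exact
reciprocity between the two expressions.

### Undefined and infinite values

Zero cells are common at cohort sizes of 30–42 molecules. A zero FP cell
with non-zero sensitivity makes `+LR` infinite; we report `Inf` as a
first-class value (serialized literally in CSVs) instead of applying a
Haldane or other continuity correction, because the reference analyses
report infinities as such and a correction would silently change every
finite ratio too. An empty margin (no molecule with, or none without, the
finding in the long phase) leaves the ratio undefined (`NaN`); undefined is
a value, not an error.

### Sidedness of the Fisher test

The package's default is the one-sided test of *positive* association
(`alternative = "greater"`), with the conventional two-sided test available
as an option. The choice is empirical, the same way the `iLR−` ambiguity is
resolved: across all 27 reference rows shipped with the package, the
one-sided p reproduces every displayed p-value at two decimals, whereas the
two-sided p fails for exactly one row — the rodent non-adverse lymphoid
table (9,5,4,12), whose two-sided p is 0.063 (not significant) while its
one-sided p of 0.035 matches the displayed 0.04 and the row's inclusion
among significant findings. One-sidedness is also defensible on first
principles here: the scientific question is whether early and late findings
are *positively* concordant, never whether they are anticorrelated. The
acceptance tests assert both routes explicitly.

### Display conventions

Internal computation is always full precision; only serialization applies
display rules, chosen to match the conventions of the reference tables:
likelihood ratios round half away from zero at two decimals (3.647 → 3.65,
3.90625 → 3.91); the false positive/negative percentages truncate toward
zero at one decimal (2/30 → 6.6, not 6.7; 1/42 → 2.3); p-values below 0.005
display as "0". One reference value (2.875 printed as 2.87) was evidently
truncated rather than rounded at the source, so validation against printed
values uses half-a-printed-unit agreement (|difference| ≤ 0.005) rather than
string equality.

## Overall adversity and NOAEL progression

The per-molecule **overall adversity** flag is "yes" for a phase if any
finding of any study in that phase was called adverse, pooling species
groups — the flag describes the compound, not a species arm. Cross-tabulating
short/mid against long adversity gives the compound-level concordance
summary per modality.

For **NOAEL progression**, studies of one molecule, species group and phase
are pooled and the lowest identified per-day NOAEL taken; the long-phase
value is then classed as `same`, `increase` or `decrease` relative to the
short/mid value (`indeterminate` when either phase has no identified NOAEL).
The default tolerance is 0 — raw values are compared exactly — because NOAELs
sit on a discrete dose ladder; a relative tolerance is exposed for datasets
where dose ladders shift between phases. Whether a decrease reflects genuine
progression of toxicity or merely lower doses tested in the chronic study is
expert judgement read from study reports; the summary therefore *consumes* a
curated annotation table (`decrease_reason`) and never computes the
attribution. An optional `expert_change` annotation can override the
computed class; overrides are logged.

## The synthetic-cohort generator

Real study-level datasets of this kind are proprietary, so the package
ships a seeded generator that emulates the structure the analysis assumes
and makes every stage testable offline. Its defaults define the study
conditions used throughout the tests:

* 25 small + 18 large molecules; small molecules tested in rodents with
  probability 0.96 and non-rodents 0.90, large molecules 0.33 / 0.94
  (biologics are predominantly tested in cynomolgus monkey);
* per group: one short study (2 or 4 w), a mid study (13 w) with
  probability 0.5, one long study (26 or 39 w) — so every molecule
  satisfies the inclusion rule by construction;
* per high-level finding, a joint distribution `(p11, p10, p01, p00)` of
  presence in (short/mid, long), drawn independently per molecule × group;
  defaults give common, mostly concordant liver/lymphoid/body-weight
  findings and rare eye/nervous findings;
* findings materialize as records whose raw terms and organs are sampled
  from the shipped synthetic terminology fixtures (with occasional case
  perturbation), so the terminology path is exercised end-to-end;
* a NOAEL dose ladder (5/15/50/150 per day) with one-step decrease /
  same / increase probabilities 0.25/0.55/0.20 between phases and a 10%
  chance per phase that no NOAEL was established;
* about 30% of materialized findings are flagged adverse.

A single seed drives all sampling and is recorded in the returned ground
truth. The analytic likelihood ratios implied by a spec are available in
closed form (`expected_lr()`), so recovery of the generator's parameters by
the full pipeline is a testable property.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: adverse status is independent of dose, severity
and duration; presence draws are independent across findings, species
groups and molecules (no correlated multi-organ toxicity, no modality
effect on prevalence); terms are drawn uniformly within categories; and
decrease-reason annotations are not simulated. Conclusions about real
cohorts still require real data.

## Numerical and testing choices

* Fisher p-values are computed by `stats::fisher.test`; the test suite
  carries an independent hypergeometric-enumeration oracle and checks exact
  agreement on every 2×2 table with cells up to 6, under both sidedness
  conventions, plus symmetry and range properties.
* The contingency builder is checked against a brute-force
  molecule-by-molecule recount on 200 random presence fixtures, and the
  presence matrix against both the generator's sampled ground truth and an
  independent triple-loop recount of raw records.
* Parameter recovery: a cohort of 2000 molecules, tested in both species
  groups (4000 independent presence draws per finding), is pushed through
  terminology, aggregation and analysis, and empirical likelihood ratios
  are compared to the analytic values. A 10% relative-error bound is only a
  meaningful assertion where the estimator's own sampling noise allows it,
  so the per-label bound is asserted where the delta-method standard error
  of log LR at the expected cell counts is below 4% (a ≥ 2.5σ margin,
  decided from the spec probabilities, not from observed errors); across
  all finite labels the median relative error is additionally bounded by
  10%. Structural infinities (a zero off-diagonal probability) are
  recovered exactly.
* Null behaviour: with independent phase presence (`p11 = pS·pL`), 200
  replicate cohorts give one-sided Fisher p-values that are stochastically
  at least uniform (the test bounds the false-positive rate and mean), and
  the likelihood ratio pooled over replicates converges to 1.
* Problem sizes were chosen so the full suite exercises cohorts from 3 to
  2000 molecules and completes in well under a minute.

## Known limitations

* No multiple-testing correction is applied across finding categories; the
  per-row `alpha` filter follows the reference reporting convention.
* Dose units are never converted; mixed-unit datasets must be harmonized
  upstream.
* The inclusion rule (each molecule needs a short/mid and a long study) is
  warn-only by default so partial datasets load; strict mode is available.
* The 20–26 week duration gap is a genuine hole in the class definitions;
  such studies are excluded from both phases rather than imputed.
* Per-compound adversity pools species groups; a species-resolved adversity
  summary would need a different universe rule.
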