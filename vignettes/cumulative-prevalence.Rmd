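---
title: "Estimating the cumulative point prevalence of rare diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the cumulative point prevalence of rare diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`raremetrics` estimates the share of a population living with any rare
disease at a point in time, from a curated knowledge file that records, per
clinical entity, an epidemiological indicator and either a numeric point
prevalence, a predefined prevalence class, a count of reported cases or
families, or nothing usable. The estimate is a pair of bounds per 100,000
persons, built from three mutually exclusive evidence groups:

* **Numeric group** — disorders with numeric point-prevalence records. The
  arithmetic mean of the numeric values in the chosen geography tier is the
  disorder's contribution to *both* bounds.
* **Class-only group** — disorders with a prevalence class but no numeric
  value. Because the within-class distribution of true prevalences is
  unknown, no point value is imputed: the class minimum boundary feeds the
  minimum bound and the class maximum the maximum bound. The rarest class
  (<1/1,000,000) is degenerate by convention, contributing 0.1 per 100,000
  to both.
* **Indirect group** — disorders known only from case or family reports.
  Individually uninformative, they are pooled: the indirect point
  prevalence is the sum of all reported cases plus `cases_per_family`
  times the reported families, divided by the reference population. These
  disorders are *counted* in the rarest class but their *burden* enters the
  bounds only through this single pooled term, never per disease, so
  nothing is double-counted.

The cumulative bounds are the exact sums of the three groups. The model's
central assumptions are (a) that one point-prevalence figure can represent
a disease worldwide, (b) that the three evidence groups partition the
included diseases, and (c) that class boundaries bracket the truth for
class-only diseases. All three are simplifications; the result is best
read as a conservative, evidence-based bracket rather than a confidence
interval (no sampling uncertainty is propagated, deliberately — the
min/max construction *is* the uncertainty statement).

## The selection cascade

Selection reduces the raw file to at most one evidence item per disease,
with every input entity accounted for in exactly one disposition bucket:

1. **Entity level.** Only `disorder`-level entities are analysed; groups of
   disorders and disorder subtypes describe the same patients again and
   would inflate the sum.
2. **Medical domain.** Cancers, infectious diseases and poisonings are
   described by annual incidence, not point prevalence, and are excluded.
3. **Geographic preference.** Among point-prevalence records:
   worldwide, then Europe (EU member states plus Russia, Turkey, Iceland),
   then a USA figure *only if* it does not exceed the European rarity
   threshold of 5/10,000 (50 per 100,000). Records from other regions are
   never used. Disorders with no eligible record but with case/family
   counts are retained as count evidence; otherwise they are excluded with
   the most specific applicable reason.
4. **Rarity threshold.** Chosen evidence exceeding 50 per 100,000 (numeric
   mean > 50, or class 6–9/10,000 or >1/1,000) is excluded — such
   conditions are not rare under the European definition. The test is
   strict: a mean of exactly 50 stays in.

### Conventions the source rules leave open

These points are genuinely underdetermined by the published procedure; the
package fixes each once and states it here:

* **Within-tier conflicts.** If a tier holds several records, numeric
  records outrank class-only ones and the tier mean of the numerics is
  used ("mean prevalence values" read as the unweighted arithmetic mean).
  Among class-only records the most frequent class wins, ties going to the
  lower (rarer) class.
* **USA class-only records** are tested against the threshold by their
  class *minimum* boundary — a record is rejected only when its whole
  range exceeds the threshold, the conservative reading of "did not
  exceed".
* **Counts versus figures.** A disorder with both case/family counts and
  an eligible point-prevalence figure is treated by the figure; the
  evidence groups stay mutually exclusive.
* **Exclusion-reason priority.** A disorder excluded at the geography
  stage may carry several kinds of non-evidence. The ledger reports the
  most point-prevalence-specific reason: ineligible point-prevalence
  records → `excluded_no_eligible_geography`; otherwise any
  unknown/not-documented record → `excluded_unknown_or_undocumented`;
  otherwise `excluded_nonpoint_indicator`. Entities with no annotations at
  all are ledgered as unknown/undocumented.
* **Threshold after preference.** The rarity filter applies to the record
  chosen by geographic preference; a worldwide record above the threshold
  excludes the disorder even when a below-threshold European record
  exists. This mirrors the published cascade order.

## Class-interval convention

Numeric means are assigned classes on half-open intervals in per-100,000
units — [0, 0.1) → <1/1,000,000; [0.1, 1) → 1–9/1,000,000; [1, 10) →
1–9/100,000 — with the topmost includable class closed at the threshold,
[10, 50]. Every mean in [0, 50] maps to exactly one class and the class of
a boundary value agrees with the class that contains it from above, which
keeps class assignment consistent with the boundary values used in
aggregation.

## Numerical policy

Magnitudes are held as doubles in cases per 100,000. Every quantity the
pipeline sums is either a recorded decimal with at most one fractional
digit (class boundaries, reported components) or a ratio of integers
(means, the indirect term), so double arithmetic is exact to well below
the reporting precision; no rational type is needed. Rounding happens
once, at report time, and is *half-up* to one decimal
(`round_half_up()`) — base R's half-to-even would misreport figures such
as a 9.595% share. Percentages and person-millions follow the same rule.
Degenerate inputs are defined, not errored: empty datasets yield empty
ledgers, zero-row reports and zero bounds; a zero population or a
`cases_per_family` below one is refused.

## The synthetic generator

Real knowledge files are version-dependent downloads, so tests run against
a seeded generator whose default composition reproduces the published
file structure: 372 numeric-value disorders and 373 class-only disorders
(the source total of 745 is published; its numeric/class split is not, so
it is split near-evenly here), 2,496 case-report and 344 family-report
disorders, 868 incidence-domain disorders (684 cancers, 159 infectious,
25 poisonings), 1,719 disorders without usable point prevalence (split
600/560/559 across non-point indicators, unknown, and not-documented —
the split is not published and only the total matters downstream), and
200 groups plus 300 subtypes as level contaminants (counts likewise
unpublished; chosen once as plausible and held fixed). The published
arithmetic implies no above-threshold exclusions in that snapshot, so the
scaled configuration sets those to zero, while the generic default
configuration exercises both the above-threshold and the USA-only
above-threshold buckets. `published_scale_config(scale)` scales this
composition with largest-remainder rounding so integer counts preserve
the grand total.

Distributional choices, each fixed once:

* Per-disorder case counts are 1-shifted geometric with mean
  85,680 / 2,496 ≈ 34.3; family counts likewise with mean
  3,418 / 344 ≈ 9.9 — the published totals constrain only the means, and
  a geometric is the least-structured overdispersed count law with that
  support.
* Numeric values are drawn log-uniformly within their class interval,
  since the within-class distribution is explicitly unknown; log-uniform
  is scale-free across intervals spanning decades.
* Geographic patterns place exactly one record in the preferred tier plus
  decoy records in strictly lower-preference tiers (and occasional
  other-region decoys), so preference selection is exercised while the
  ground truth stays constructible.
* Onset is documented with probability 0.813 (then 69.9% exclusively
  pediatric, 18.2% mixed, 11.9% exclusively adult) and 71.9% of disorders
  are genetic, matching the published catalogue description.

The generator writes a **manifest** — dispositions, per-class counts,
case/family totals, and bounds — computed by direct construction while
generating, never by calling the pipeline. Parameter-recovery tests then
require the pipeline to reproduce the manifest exactly (dispositions,
counts) or to within 0.05 per 100,000 (bounds, a pure floating-point
allowance).

What the generator does *not* emulate: real disease names and codes,
correlations between prevalence class and onset/inheritance, geographic
heterogeneity of true prevalence, curation noise (conflicting duplicate
records within one tier are rare in the synthetic data), or annotation
validation status. Passing tests therefore demonstrate that the pipeline
implements the stated rules faithfully on files with this structure — not
that the rules themselves recover truth from a real, messier catalogue.

## Testing strategy and problem sizes

Three layers: unit tests of each rule at its boundary (e.g. a mean of
exactly 50, the 1.0 per 100,000 class edge); a literal brute-force
reference implementation (per-entity loops, its own class table) that must
agree with the vectorised pipeline on hand-built single-rule fixtures and
on 200 random datasets of up to 20 entities; and parameter recovery
against the generator manifest at a tenth of the published scale
(≈ 360 included disorders), with the full-scale composition (3,585
included) used where a property concerns composition shares, such as the
two most common classes carrying over 98% of the patient burden. These
sizes keep the full suite under a minute while leaving the estimates'
sampling noise far below the tested margins.

## National-definition coverage

`definition_coverage()` reports the share of diseases and of patient
burden inside a prevalence-threshold definition. A disease is covered only
if its *entire* plausible range lies at or below the threshold — numeric
diseases by their mean, class-only and case/family diseases by their class
maximum. This is conservative; with the published class structure a
threshold of 10 per 100,000 (the 1–9/100,000 class boundary) already
covers over 90% of diseases, while removing the 1–5/10,000 class removes
most of the patients. The published claim that the lowest national
definition encompasses at least 90.5% of diseases does not state whether
it was evaluated at 5 or at the adjacent class boundary of 10 per
100,000; the function takes the threshold as an explicit parameter and
the shipped checks use the class-boundary reading, under which class-only
evidence is decidable. Count-form definitions (a maximum number of
affected persons) are converted to per-100,000 thresholds with a
user-supplied reference population — e.g. 200,000 persons against the
1983 USA population gives 86 per 100,000, against the 2017 population
61.4 — which is why count-form definitions tighten as populations grow.

## Known limitations

* Only worldwide, European and USA evidence is used; diseases prevalent
  elsewhere but not in these regions are underrepresented, and the
  generalisation of European figures worldwide is untested.
* The indirect group's contribution is a lower bound: case reports
  undercount living patients.
* Incidence-described diseases (14% of the catalogue) are outside the
  estimate entirely.
* The bounds carry no sampling uncertainty; they bracket structural, not
  statistical, ignorance.
* The XML dialect is the package's own (schema in
  `inst/extdata/epidemiology.xsd`); real downloads must be mapped to it
  before analysis.
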