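---
title: "Assessing the informative value of risk-of-bias and reporting-quality scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the informative value of risk-of-bias and reporting-quality scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robdiv)
```

## The problem

Risk-of-bias (RoB) assessment is a mandatory, and famously time-consuming,
part of any systematic review: every included primary study is judged, item
by item, as low / unclear / high risk on design features such as
randomisation, blinding and outcome completeness, and reporting-quality (RQ)
checklists record whether each required experimental detail was reported at
all. In corpora where reporting is poor, most RoB judgements come out
"unclear" and most RQ items "not reported" — the assessments then consume
reviewer-months while contributing little beyond the repeated observation
that reporting needs to improve.

robdiv implements an analysis pipeline for asking, within one review's
corpus of assessments, *which elements carry distinctive information*, how
RoB/RQ differ between study types, and how much of the assessment burden a
partial (subsampled) assessment could save while still estimating the
corpus-level picture.

## The instrument

The bundled instrument merges the items of four tools — the ARRIVE and
CONSORT reporting checklists and SYRCLE's and Cochrane's RoB tools — into a
single ordered list of 48 items: 38 RQ items scored yes/no (Y/N) and 10 RoB
items, the SYRCLE set S1–S10, scored low/unclear/high (L/U/H). Item codes
keep the first letter of the source tool (A, C, S). Questions duplicated
across tools were merged; the absorbed codes are kept in each surviving
item's `merged_from` field so the bookkeeping is auditable. Where the source
material listed several merge targets for one absorbed code, we record the
code under the first-listed surviving item, so that every absorbed code has
exactly one home — a convention, not a claim about provenance. The Cochrane
RoB items, which have no published short codes of their own in this merged
list, carry synthetic codes CB1–CB5.

The bundled default is a reconstruction from the published operationalisation
table and should be treated as such; users with their own extraction list can
supply it as a CSV with the same columns (`load_instrument()`).

An `irrelevant` (I) response exists for items that cannot apply to a given
study. Two mechanisms produce it:

* **structural** irrelevance, a property of the (item, stratum) pair — e.g.
  animal-housing items are never scored for human studies, randomisation
  items never for studies without an intervention. This is encoded in the
  instrument's applicability map and applied automatically;
* **idiosyncratic** irrelevance, a property of the individual study (a study
  with a single prespecified analysis has no "additional analyses" to
  report). This can only be expressed by the extractor recording `I`, and is
  only legal for items whose response domain carries `I`.

A missing cell is a validation error, never silently `I`: absence of data
must not inflate the irrelevant bucket.

## Summaries and the DIV statistic

For each item, irrelevant scores are counted first and then removed from
every denominator. An RQ item's percentage reported is
$\%Y = 100\,Y/(Y+N)$; an RoB item reports the share of scored assessments at
each level. Items with zero scored assessments are reported as *not
computable* (`NA`), deliberately distinct from 0%.

The **distinctive informative value** of an RQ item is

$$\mathrm{DIV}(p) = 50 - \lvert p - 50\rvert, \qquad p = \%\ \text{reported},$$

a tent function peaking at 50% reported. The rationale: an element reported
by everyone (or no one) identifies no differences between the included
studies, whereas an element reported by about half of them is exactly where
subgroup analyses by reporting status are possible. DIV ranges from 0 to 50
and is used **only for ranking** — it is never summed into a composite
quality score, which the source tools explicitly discourage. DIV is computed
from the unrounded percentage; display values are rounded half-up to one
decimal only at the end, and the conventional reporting cut keeps items with
DIV ≥ 10 (`div_table()`).

No DIV analogue is computed for RoB items: with only ten items at three
levels, ranking by the level percentages themselves (`rank_items()` with
`pct_low` / `pct_unclear` / `pct_high`) is more interpretable.

## Stratified comparisons

The corpus is cross-classified by population (animal vs human) and design
(baseline disease-control comparison vs treatment study). `compare_all()`
runs one chi-square test per item across either stratum variable, on scored
counts only (2×2 tables for RQ, 2×3 for RoB), via `stats::chisq.test()`.
With the default `correction = "auto"` the Yates continuity correction is
applied exactly when the table is 2×2, replicating that function's default;
`"on"`/`"off"` force either behaviour, since published statistics do not
always say which was used. Items with an empty stratum level (e.g. an
animal-only item compared across populations) are skipped with a recorded
reason rather than silently dropped. The tests are explorative, so no
multiplicity adjustment is applied by default; Benjamini–Hochberg adjusted
p-values are available with `adjust = "BH"`.

## Figures

`heatmap_data()`/`plot_reporting_heatmap()` build the reporting heatmap: RQ
items × the four strata, cells shaded on a diverging scale so that fully
reported cells are green, fully unreported red, and the intermediate shades
mark exactly the high-DIV cells. `rob_plot_data()`/`plot_rob_summary()`
build the RoB traffic-light plot (green = low, yellow = unclear, red =
high). Not-computable cells are grey, never drawn as 0. Rows default to
instrument order (`sort_by = "div"` reorders); columns are labelled with
their stratum sizes. The data behind each figure is a plain tibble so every
figure is auditable.

## Partial-assessment strategies

`recommend_plan()` maps the reviewers' interest in study quality to a
procedure, following a five-row decision table: reviews that will inform
treatment guidelines or future experiments always get a full RoB analysis of
every study; reviews demonstrating reporting effects assess every study on
high-DIV elements only; the remaining interests assess a random subset of
studies (5–50%, or 25–50% when only specific aspects matter). Within a row's
admissible range the point fraction interpolates log-linearly between two
anchors — reviews of ≤ 50 papers sample 50% (with at least 25 studies
assessed), reviews of ≥ 1000 papers sample 5% — and is clamped into the
row's range. The range endpoints are returned alongside the point value,
since the choice within a range is ultimately the reviewer's.

`evaluate_plan()` quantifies what such a partial assessment costs in
accuracy: it repeatedly draws study subsets (stratified by
population × design with proportional largest-remainder allocation, so the
smallest stratum is never empty; simple random sampling available with
`stratified = FALSE`), recomputes all per-item summaries on each subset, and
reports per item and metric the bias, mean absolute error and empirical 95%
interval half-width against the full-corpus values. The subset size is
`min(N, max(min_studies, ceil(f·N)))`. Subsampling a finite population is
unbiased for a proportion, and the evaluator's output shows it; at fraction
1.0 every error is exactly zero. One seed drives a replicate-seed vector
drawn once up front, so results are reproducible bit-for-bit and independent
of replicate order.

## The synthetic corpus generator

Real assessment tables from a published review are rarely redistributable
piecemeal, so `generate_scores()` fabricates corpora with the statistical
structure the analysis assumes: four strata with default sizes 56
(animal-baseline), 74 (human-baseline), 22 (animal-treatment), 12
(human-treatment) — 164 studies, hence 48 × 164 = 7872 assessment cells —
and one independent categorical draw per (study, item) cell from per-item,
per-stratum response probabilities. Structurally inapplicable cells are
emitted as `I`; with the bundled applicability map and default sizes this
yields a fixed count of 882 irrelevant cells. Publication years are drawn
uniformly from 1981–2020 and are metadata only, and a handful of manuscripts
carry one study per review arm so that study ids outnumber manuscript ids.

`preset_calibrated()` calibrates the generator to the pooled percentages reported
for the motivating cystic-fibrosis/nasal-potential-difference corpus:
every published per-item percentage is used as that item's pooled
probability (e.g. ethical review reported 64.6%, selective outcome reporting
97.6% high RoB), identically in all four strata because only pooled
marginals were published. Items whose percentages were not published are
filled in once with values consistent with the published rankings: an
unpublished RQ item must sit below the DIV-10 reporting cut (so P(Y) ≤ 0.09
or ≥ 0.91), and an unpublished RoB simplex must not break into the published
top-3 lists for %low, %unclear or %high. `preset_null()` removes all
signal (for type-I-error calibration) and `preset_stratum_effects()` plants
treatment-stratum effects on adverse-event reporting, design reporting,
caregiver blinding and selective outcome reporting — mirroring the
direction of the published comparisons — for power testing.

`recover_params()` is the parameter-recovery harness: across generated corpora it
compares mean estimated percentages per item × stratum with the generating
probabilities and reports deviations and Wald-interval coverage.

What the generator deliberately does **not** model: between-item correlation
within a study (all published analyses are marginal per item, and a
correlation structure would add unverifiable assumptions), extractor
disagreement, time trends, and idiosyncratic irrelevance (available through
the `p_irr` column but 0 in all presets — which is why a generated corpus
shows ~11% irrelevant cells rather than the published 12.1%, the remainder
being study-specific judgements no stratum-level rule can reproduce).
Passing tests on synthetic corpora therefore demonstrate correctness of the
accounting, statistics and estimators under independence — not that real
assessment data behave this simply.

## Numerical conventions and problem sizes

* Display percentages are rounded half-up to one decimal (`round_half_up()`),
  matching the convention of the published tables; all statistics are
  computed from unrounded values.
* Ranking ties are broken by instrument order, making rankings stable and
  reproducible.
* The test suite exercises the stochastic components at sizes chosen to keep
  the full run around a minute while leaving the checks sharp: 1000 random
  tables against the brute-force chi-square oracle, 1000 null replicates for
  type-I calibration, 200 corpora for parameter recovery, and 200–500
  Monte-Carlo replicates for the subsampling evaluator. `scripts/acceptance.R`
  regenerates a full 164-study corpus and recomputes the headline quantities
  from scratch at those sizes.

## Limitations

The DIV statistic values *variation* in reporting, which is a
meta-researcher's criterion; for a clinician the universally-reported
element may still be the most important one. The bundled instrument is a
reconstruction (see above) and intentionally does not reproduce the verbatim
wording of the source tools. All comparisons are per-item chi-squares on
marginal counts: no modelling of item correlation, publication year, or
study-level covariates is attempted.
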