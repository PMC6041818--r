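---
title: "Measuring health inequality from disaggregated data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring health inequality from disaggregated data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthineq)
```

## The setting

Health-equity monitoring condenses *disaggregated data* — indicator
estimates per population subgroup within a setting — into summary
measures of inequality. The unit of computation is the **stratum**: all
subgroups for one setting × year × source × indicator × dimension. Three
dimension types behave differently:

* **binary** — exactly two subgroups (urban/rural, male/female);
* **ordered** — subgroups with an inherent ranking (wealth quintiles,
  education), which enables gradient measures;
* **non-ordered** — no natural ranking (districts, ethnic groups), which
  enables dispersion measures.

Two further flags change orientation and availability: whether the
indicator is **favourable** (to be maximised, e.g. coverage) or adverse
(to be minimised, e.g. mortality), and which recommended columns
(`se`, `population`, `setting_average`) were supplied. Subgroup
populations unlock the weighted measures; standard errors additionally
unlock SII/RII; without populations only the unweighted D and R remain.
This applicability matrix is implemented in `applicable_measures()` and is
deliberately exact: 15 measures overall, of which D and R are the only
population-free ones and SII/RII the only se-gated ones.

## The template contract

Input files carry 20 columns: 13 mandatory (identification plus the
control variables `favourable_indicator`, `indicator_scale`,
`ordered_dimension`, `subgroup_order`, `reference_subgroup`), 4
recommended (`se`, `population`, `setting_average`, `iso3`) and 3 optional
(CI bounds, flag). `validate_indicator_data()` enforces the contract:
missing mandatory cells, flag values outside {0, 1}, non-positive scales,
inconsistent per-stratum metadata, a reference subgroup inside an ordered
dimension, two subgroups flagged as ordered, duplicate subgroups, or a
`subgroup_order` that is not a set of distinct positive integers starting
at 1 are all **errors**; missing recommended values are **warnings** and
only degrade which measures can be computed. Reports are machine-readable
(JSON lines) and human-readable text; data problems never throw.

Two parsing decisions favour hand-edited spreadsheets: header matching is
case-insensitive and trimmed, with `95ci_lb`/`ci_lb` accepted as aliases
(leading digits are hostile to many tools); and only empty cells and the
literal `NA` count as missing — no other sentinel, so a stray `"-"` is
caught as an unparseable number rather than silently dropped. Gaps in
`subgroup_order` (1, 3, 5, …) are allowed with a warning: the phrase
"increasing sequence of integers starting at 1" does not literally forbid
them, and the ranks used downstream are the sort order, not the integer
values.

## The measures and their conventions

The formulas are the standard WHO-style definitions; each is pinned by a
hand-computed unit oracle so any deviation is visible and localised.
Conventions that were genuinely open, and the choices made:

* **Orientation of D and R.** Ordered strata compare advantaged vs
  disadvantaged for favourable indicators and the reverse for adverse
  ones, so a positive D always means the burden falls on the
  disadvantaged. Non-ordered strata without a reference compare max vs
  min. With a designated reference subgroup *r*, D and R compare *r* with
  the subgroup farthest from it (extreme-vs-reference); comparing *r*
  with every subgroup would yield a vector, not a summary, and the note
  on each result records which pair was used.
* **PAR truncation.** PAR is interpreted as attainable improvement, so a
  PAR whose sign is contrary to improvement (negative for favourable,
  positive for adverse indicators) is truncated to 0 and the note flags
  it. PAF inherits the truncated value.
* **Setting average precedence.** A reported `setting_average` is treated
  as the authoritative national figure and wins over the
  population-weighted mean of the subgroup estimates; weights still come
  from the populations.
* **SII/RII estimator.** Natural-scale weighted least squares of the
  subgroup estimates on their population rank midpoints, with
  population-share weights — fully determined by template-level
  information and with closed-form oracles (two points: the exact line;
  collinear points: the shared line). A bounded-link (logit-scale)
  variant would use `indicator_scale`; that scale is carried in the
  stratum but unused by the estimator, which is isolated in
  `compute_sii_rii()` for a future swap. The standard errors gate
  applicability only; they do not enter the point estimate.
* **Reporting scales.** MLD and TI ×1000; PAF, RCI, IDIS, IDISW ×100 of
  the underlying ratio. The factors are named constants, so the raw value
  is always `value / factor`.
* **Tie-breaks.** Best/max/min subgroups are chosen first by estimate,
  then alphabetically by subgroup name; bar-table sorting is stable with
  the same rule. This makes every output deterministic under row
  permutation, which the test suite asserts across shuffled datasets.
* **Binary strata** use the non-ordered formulas with J = 2; a
  two-subgroup dimension flagged as ordered is rejected upstream rather
  than silently coerced.

Degenerate inputs become skips with reasons, never errors: a zero
denominator skips R, a non-positive estimate skips MLD/TI, a non-positive
fitted value at rank 0 skips RII, a missing setting average skips the
measures that divide by it. `skipped_measures()` returns the companion
log, including measures that were simply not applicable.

## What the synthetic generator emulates

`generate_dataset()` emulates the two situations the template is designed
for: a multi-country series disaggregated by a binary dimension over
several years, and a subnational snapshot with ordered (wealth) and
non-ordered (district) dimensions. The structure is linear in subgroup
rank: the most disadvantaged subgroup sits at `base`, the most advantaged
at `base + gap`, every subgroup drifts by `trend` per year, and mean-zero
Gaussian noise of sd `noise_sd` is added and clipped to `[0, scale]`.

Defaults, chosen once as a realistic coverage scenario: 3 settings ×
3 survey years; one favourable indicator on a percentage scale
(`scale = 100`); `base = 50` and `gap = 30` (a large but commonly
observed rich–poor coverage gap); `trend = 0.5` points/year;
`noise_sd = 1` point; 10 000 people per stratum, split equally (or by a
Gamma-weighted random allocation). All settings share the same base level
so that the noise-free closed forms hold for every setting: D = `gap`
(invariant to the uniform drift), R = (`base` + `gap` + t)/(`base` + t) in
year offset t, binary BGV = (`gap`/2)² with equal populations. Emitted
standard errors follow the fixture convention
`se = noise_sd / sqrt(J p_j)`, consistent with estimate noise that scales
with subgroup sample size. An infeasible request (`base + gap` above the
scale) errors before generation.

What the generator does **not** emulate: survey design effects
(clustering, stratification), correlated noise between subgroups,
missing-at-random gaps in the middle of a series, non-linear gradients,
and estimates near the bounds where clipping makes noise asymmetric.
Passing tests on generated data therefore demonstrate correctness of the
computations and contracts, not robustness to every pathology of real
survey data.

## Numerical choices and problem sizes

All computations are closed-form or a two-parameter least-squares fit; no
iterative optimisation is involved, and the property tests assert
agreement to 1e-9 (1e-6 for the hand-derived oracles, whose expected
values are written as arithmetic expressions rather than rounded
decimals). The test suite exercises: ~120 randomized strata per algebraic
property (zero-inequality identities, scale equivariance, equal-population
reduction), 50 random ordered strata with populations up to 1000 for the
person-level concentration-index brute force, 200 generator seeds for the
noise-centred recovery check, and full pipeline runs on 3-setting
scenarios — sizes at which the whole suite runs in about a minute while
still covering every dimension type and gating combination.

## Limitations

* No standard errors or confidence intervals for the summary measures
  themselves; `se` is an applicability gate only.
* The SII/RII point estimate is the natural-scale WLS fit; bounded
  indicators very close to 0 or 100% may prefer a link-function variant.
* Benchmark metadata (region, income group) is not part of the template
  and must be supplied as a side table (`setting_info()` provides one for
  generated scenarios); when settings have different latest years the
  benchmark uses each setting's own latest year rather than forcing a
  common one.
* Graph rendering is out of scope: the bar/trend/compare tables are the
  graph-ready data, exportable as CSV/TSV.
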