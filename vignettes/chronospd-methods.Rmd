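---
title: "Methods: chronometric SPDs as population proxies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chronometric SPDs as population proxies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronospd)
```

## The problem

Archaeological radiocarbon dates are often the only continuous,
millennia-spanning proxy for relative population change: under the
"dates as data" premise, more people leave more datable material, so the
density of dated events through time tracks the relative direction of
demographic change. The premise is threatened by several biases, of
which *investigation bias* — researchers sampling some periods, regions,
or dating methods preferentially — is the hardest to assess from
radiocarbon data alone. Where an independent, higher-resolution
chronometric record exists (dendrochronological cutting dates in the
Upland US Southwest being the canonical case), the two records can be
arrayed as directly comparable time series, and both can be compared
against independent, period-resolved population reconstructions.

`chronospd` implements that comparison pipeline end to end: cleaning
both date tables with auditable rules, calibrating radiocarbon
determinations, collapsing same-site dates into occupation-phase bins,
summing bin-averaged densities into annual summed probability
distributions (SPDs), smoothing, area-equalized scaling against a
reference population series, and descriptive comparison. A synthetic
generator with a known demographic truth lets every stage — and the
headline property, recovery of a post-AD 1300 decline — be validated
without any external data.

## Calendar conventions

All internal grids are integer calendar years BP (before AD 1950),
`BP = 1950 - AD`, with astronomical year numbering (year 0 exists), so
AD 201 is 1749 BP and AD 1798 is 152 BP. Calibration curves are
canonicalized to strictly increasing cal BP on load and linearly
interpolated to an annual grid before use.

## Calibration

A radiocarbon determination $(x, \sigma)$ is mapped to a posterior mass
over calendar years $t$ by

$$ p(t) \;\propto\; \phi\!\left(\frac{x - \mu(t)}
  {\sqrt{\sigma^2 + \sigma_c(t)^2}}\right), $$

where $\mu(t)$ and $\sigma_c(t)$ are the calibration curve's mean and
error at $t$ and $\phi$ is the standard normal density — i.e. a flat
prior over calendar years. Numerical choices:

* Evaluation is restricted to the contiguous span of years within 10
  combined standard deviations of the measured age; a determination with
  no such years raises an out-of-curve error. The truncated mass is
  below $10^{-19}$ of the total, far under every tolerance used.
* The support is then trimmed so that at most $5 \times 10^{-7}$ of
  mass is dropped from each tail (retained mass $\ge 1 - 10^{-6}$);
  trim bounds and dropped mass are recorded in the density's metadata.
* Per-date normalization defaults on, so each calibrated density sums
  to 1 before binning; this is what makes bin averages weight dates
  equally. Unnormalized densities are supported via `normalize = FALSE`.

The 95% regions used for window filtering are *highest-density* regions,
not central intervals: years are admitted by descending mass until the
target level is reached, with ties broken toward older years for
reproducibility, and returned as maximal contiguous intervals.
Multimodal calibrated densities — routine on wiggly curves — make
central intervals misleading. Window intersection is closed-interval on
both sides, matching the inclusive phrasing of study windows such as
1750–150 BP.

## Cleaning rules

`filter_radiocarbon()` applies, in fixed order: (1) drop dates flagged
non-archaeological (the flag is an input column, not inferred); (2)
drop imprecise dates — 1σ error above 300 ¹⁴C years and/or above 25% of
the uncalibrated age. Whether these two thresholds were meant
conjunctively or disjunctively is genuinely ambiguous; the default
`error_rule = "either"` treats each as sufficient (standard
dates-as-data hygiene), and `"both"` is available. (3) Resolve
duplicate laboratory numbers: fully matching duplicates (age, error,
county) collapse to one record, counted as *deduplicated*; conflicting
duplicates are removed entirely, since there is no principled way to
pick the correct one. (4) Trim to study-area counties. (5) Keep dates
whose 95% highest-density region overlaps the study window.
`filter_treering()` keeps cutting ('B', 'G', 'L', 'c', 'r', with or
without a trailing '+') and near-cutting ('v', 'v+') symbols, in-area
counties, and years inside the window. Every rule reports its removal
count; `retained + removed + deduplicated = input` always holds, and
filtering is idempotent and order-insensitive.

County membership is configuration, not geometry: region rosters map
names such as `"Montezuma, CO"` (the Central Mesa Verde approximation)
and the five Northern Rio Grande counties to regions, with keys
case-folded and whitespace-collapsed for deterministic joins. GIS
centroid computation is out of scope.

## Binning and SPDs

Within a site, dates are clustered by single-linkage agglomeration cut
at height `h` (default 100 years) on the uncalibrated age (radiocarbon)
or calendar year (tree-ring): two dates share an occupation-phase bin
iff a chain of same-site dates connects them with consecutive gaps
$\le h$; a gap of exactly `h` merges, reading "within 100 years"
inclusively. This is computed exactly by splitting the sorted keys at
gaps $> h$, which coincides with transitive-closure connected
components in one dimension (the test suite checks this equivalence
against a brute-force oracle, including exact-gap boundary cases).

Each bin contributes the pointwise mean of its members' calibrated
densities, so a heavily dated phase counts once; the SPD is the
pointwise sum of bin averages on an annual grid, hence total mass
equals the number of bins (minus any mass clipped outside the grid,
which is tracked in metadata). Tree-ring dates enter the same machinery
as degenerate densities — all mass at the date's cal BP year — so both
proxies share binning and summation code paths exactly.

## Smoothing, scaling, comparison

Smoothing uses a centre-aligned Gaussian kernel, default 21-year window
with a 5-year standard deviation. At the ends of the series the kernel
is truncated to the available years and renormalized: this leaves
constant series fixed and avoids manufacturing artificial edge declines
(the very artefact edge effects are blamed for), at the cost that exact
mass conservation holds only when the series carries no mass within a
half-window of its edges — the pipeline's actual regime, since
densities are tail-trimmed well inside the study grid. By default only
the tree-ring SPD is smoothed: it is annually resolved and noisy at
year scale, while the radiocarbon SPD is already smeared across
sub-centennial scales by calibration. Both switches are configurable.

Reference population series are period-resolved tables
(`start_ad, end_ad, estimate`) treated as piecewise-constant over
`[start, end)`; integration is then a sum of annual person-years.
`scale_to_reference()` multiplies an SPD by
$\sum \text{person-years} / \sum \text{SPD}$ over the overlap window,
making the areas equal exactly (to $10^{-9}$), which puts a unitless
density and an absolute reconstruction on one axis.

`compare_series()` is purely descriptive — no significance machinery is
implied anywhere in the package. It reports per-century means, peak
years (ties toward older years), the first year of sustained post-peak
decline (default: a run of 20 consecutive negative first differences of
the smoothed series; shorter runs are routinely noise at annual
resolution), and the sign-agreement fraction of smoothed first
differences.

## The synthetic generator

The generator adopts deposition-proportional-to-population as its
simulation law. Its defaults are the package's frozen study conditions:

* **Truth**: boom–bust — exponential growth at 0.007/yr to a peak of
  20,000 persons at AD 1300 (roughly a quadrupling over the two
  pre-peak centuries, the order of magnitude of reconstructed late
  Pueblo-period regional growth), then exponential decline at 0.01/yr
  (~95% loss by AD 1600), above a floor of 500. A linear rise was
  rejected at design time: it leaves the event density nearly flat for
  a century left of the peak, making the peak year unidentifiable at
  realistic sample sizes regardless of method.
* **Events**: AD 600–1700, i.i.d. proportional to the annual level.
* **Radiocarbon measurement**: inverse calibration — ages drawn Normal
  about $\mu(t)$ with the combined error; reported errors uniform on
  20–80 ¹⁴C years (typical archaeological archive precision; not
  asserted as any deposit's empirical distribution).
* **Tree-ring records**: 2:1 cutting:near-cutting mix; near-cutting
  years offset 0–3 years before the true death year.
* **Contaminants**: known counts of non-archaeological flags, >300-yr
  errors, conflicting and exact lab-number duplicates, out-of-area
  counties, out-of-window ages, and non-cutting symbols are injected so
  that filter reports have *exact* expected values.

Clean records carry a pass-the-filters guarantee: measurements that
would trip the precision thresholds, or whose calibrated mode would
fall outside the study window, are redrawn for the same true event year
(a laboratory re-measurement, in effect). Without this, audit counts
would only hold in expectation. Synthetic curves are either the
identity curve ($\mu(t) = t$) or a sinusoidal "wiggly" curve
($\mu(t) = t + A\sin(2\pi t / P)$) mimicking plateaus and cliffs of
atmospheric curves.

What the generator does *not* emulate: taphonomic loss and per-county
investigation bias are available only as caller-side thinning, real
calibration-curve structure (the AD 1100–1400 plateau/cliff sequence)
is only caricatured by the sinusoid, site-size distributions are
uniform, and counties are sampled uniformly from the roster rather than
with the strong spatial unevenness of real archives. Passing tests
therefore demonstrate correctness of the machinery and recoverability
of a strong demographic signal under clean conditions — not robustness
to every bias afflicting real deposits.

## Validation sizes and determinism

The shipped tests use: 10,000 simulated determinations for 95%
highest-density-region coverage (observed ≈ 95.0%); 1,000 random small
sites for binning-oracle equivalence; 100 replicate studies of 500
site-phases per proxy for boom-bust recovery (smoothed tree-ring SPD
peak within ±50 years of AD 1300, and negative smoothed radiocarbon
trend over AD 1300–1600); and exact-count filter audits. Every
stochastic step is seed-controlled; identical configurations reproduce
byte-identical outputs, and the pipeline itself is fully deterministic
given its inputs.

## Known limitations

Only single atmospheric-style curves are supported (no marine or mixed
curves, no reservoir corrections); no Bayesian sequence modelling; no
Monte-Carlo null-envelope testing of SPDs (deliberately — the
comparison here is descriptive); population periods are
piecewise-constant, so sub-period structure in a reference
reconstruction is invisible; and county-level region assignment cannot
represent sites near region boundaries better than its roster does.
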