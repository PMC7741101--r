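# chronospd

Summed probability distributions (SPDs) from radiocarbon and tree-ring
dates, as relative palaeodemographic proxies.

Under the "dates as data" premise, the density of dated archaeological
events through time tracks the relative direction of population change.
`chronospd` builds that proxy from two independent chronometric records
— radiocarbon determinations and dendrochronological cutting dates —
and compares both against period-resolved population reconstructions,
so that investigation bias in either record can be assessed. It
implements:

* **Calibration**: IntCal-style curve parsing and annual interpolation;
  posterior mass for a determination $(x,\sigma)$ at calendar year $t$
  proportional to the normal density of $x$ at mean $\mu(t)$ and
  standard deviation $\sqrt{\sigma^2+\sigma_c(t)^2}$; 95%
  highest-density regions with deterministic tie-breaking.
* **Cleaning**: ordered, auditable rules (non-archaeological flags,
  1σ errors above 300 ¹⁴C yr and/or 25% of age, duplicate laboratory
  numbers, county trimming, calibrated-window overlap with 1750–150
  cal BP), with per-rule removal counts that always reconcile with the
  input size. Tree-ring tables are restricted to cutting
  ('B','G','L','c','r', optional '+') and near-cutting ('v','v+')
  symbols.
* **Binning and SPDs**: same-site dates cluster into occupation phases
  by single-linkage agglomeration cut at h = 100 years (a gap of
  exactly h merges); each phase contributes the mean of its members'
  densities; the SPD is the annual pointwise sum, so total mass equals
  the number of site-phase bins. Tree-ring dates flow through the same
  machinery as degenerate (single-year) densities.
* **Post-processing**: 21-year / 5-sd Gaussian smoothing with
  truncated-renormalized edges; area-equalized scaling against a
  population series; descriptive comparison (peak years, decline
  onset, sign agreement of smoothed first differences).
* **Synthetic studies**: a generator with a boom-bust truth
  (exponential growth to a peak at AD 1300, then decline), inverse
  calibration, tree-ring symbol conventions, and exact known counts of
  injected contaminants, so the whole pipeline is testable offline.

See `vignettes/chronospd-methods.Rmd` for the model, parameter
rationale, and limitations.

## Worked example

```r
library(chronospd)

study <- generate_study(simulation_config(seed = 101))
report <- run_pipeline(run_config(
  curve = study$curve, radiocarbon = study$radiocarbon,
  treering = study$treering,
  population = list(CMV = study$population, NRG = study$population)))

report
#> <run_report> chronospd 0.1.0
#>   region rc_dates rc_sites tr_dates tr_sites rc_dates_per_site
#> 1   UUSW      500      144      500      146              3.47
#> 2    CMV       33        7       39        9              4.71
#> 3    NRG      157       40      129       40              3.92
#>   tr_dates_per_site rc_ratio tr_ratio
#> 1              3.42    3 : 1    3 : 1
#> ...

report$regions$UUSW$radiocarbon$report
#> <filter_report> input 536 -> retained 500
#>   removed by non_archaeological:    5
#>   removed by error_threshold:       10
#>   removed by duplicate_conflict:    8
#>   removed by out_of_area:           6
#>   removed by window_overlap:        4
#>   deduplicated:                  3

report$regions$UUSW$comparison_proxies
#> <spd_comparison>
#>   peak years (AD):      a = 1288, b = 1300 (|diff| = 12 yr)
#>   decline onset (AD):   a = 1289, b = 1301
#>   sign agreement:       0.373
```

The count matrix is the study's dates/sites table per region and proxy;
the filter report shows that every injected contaminant class was
removed by exactly the intended rule (the generator injected 5
non-archaeological records, 10 oversized errors, 4 conflicting
duplicate pairs, 3 exact duplicates, 6 out-of-area and 4 out-of-window
records around 500 clean events). The proxy comparison recovers the
simulated truth: both the radiocarbon (a) and tree-ring (b) series peak
within a few years of the true AD 1300 peak and begin a sustained
decline immediately after. The low year-scale sign agreement between
the two proxies is expected — the tree-ring series retains annual
noise that calibration smears out of the radiocarbon series — which is
precisely why comparisons should read centennial trends, not annual
wiggles.

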