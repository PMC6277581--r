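# fxscreen

Two-tier fragile X (*FMR1* CGG-repeat expansion) screening: triplet-primed
PCR **melt curve analysis** as a fast first tier, with reflex **capillary
electrophoresis sizing** of the screen positives — plus a synthetic-signal
generator and a packaged 151-sample reference cohort so the entire pipeline
runs and is testable without instrument data.

## The science

Fragile X syndrome is caused by expansion of the CGG repeat in the 5' UTR of
*FMR1*. Alleles fall into four classes by repeat count *n*: normal (`NL`,
5–44), intermediate/gray zone (`IM_GZ`, 45–54), premutation (`PM`, 55–199)
and full mutation (`FM`, ≥ 200). A population screen only needs to separate
*expanded* (`PM`/`FM`) from *non-expanded* samples quickly; exact sizing is
reserved for the few positives.

Tier 1 exploits the fact that the melting temperature of a triplet-primed
PCR product rises with the longest repeat tract present, saturating for very
long tracts:

```
Tm(n) = tm_sat − (tm_sat − tm_min) · exp(−n / tau)
```

with defaults `tm_min = 82.08 °C`, `tm_sat = 92 °C`, `tau = 55` repeats
(calibrated so an 8-repeat allele melts at 83.42 °C). Melt traces are
smoothed (Savitzky–Golay), differentiated to −dF/dT, and the **last** peak —
the longest tract melts last, so a normal co-allele can never mask an
expansion — is classified against a boundary calibrated in-run from four
46–54-repeat control DNAs, with a ±0.3 °C guard band and a
retest-at-higher-template policy for flat low-template profiles.

Tier 2 sizes the positives by counting the 3-bp rungs of the TP-PCR ladder
(one rung per repeat at 209 + 3k bp), flagging full mutations (≥ 200 rungs,
never reported as a point estimate) and size mosaicism, with a
repeat-spanning PCR cross-check that models the −12 bp GC mobility offset
(hence the +4-repeat size correction) and full-mutation amplicon dropout.

The methods vignette (`vignettes/fxs-screening.Rmd`) documents every model,
parameter, unit and design decision.

## Worked example

Screen the packaged 151-sample reference cohort end to end (boundary
calibration, melt screening with retests, reflex sizing of positives):

```r
library(fxscreen)

cohort <- fxs_cohort()
scr <- run_screen(cohort, seed = 17)
scr
#> Two-tier FMR1 expansion screen: 151 samples (75M, 76F)
#>   expansion-positive: 15 (3M, 12F)
#>   expansion-negative: 136 (72M, 64F)
#>   reflex-sized: 15 | MCA-indeterminate: 0 | QC fail: 0
#>   categories among positives: 7 PM (2M, 5F), 8 FM (1M, 7F)
#> IM/GZ boundary: 87.71 - 88.27 C (margin 0.30 C)
#>   controls: NA20230=87.71, NA20232=88.01, NA20234=88.27, NA20236=88.18
```

`tidy()` gives per-sample records, `glance()` the one-row summary
(broom-style), and `autoplot()` a Tm strip chart against the boundary band:

```r
tidy(scr)[1:4, c("sample_id", "sex", "mca_call", "tm", "final_call")]
#> # A tibble: 4 × 5
#>   sample_id sex   mca_call        tm final_call
#>   <chr>     <chr> <chr>        <dbl> <chr>
#> 1 001       M     non_expanded  86.3 non_expanded
#> 2 002       M     non_expanded  86.5 non_expanded
#> 3 003       M     non_expanded  86.0 non_expanded
#> 4 004       M     non_expanded  86.9 non_expanded

glance(scr)[, c("n_total", "n_positive", "n_negative", "n_pm", "n_fm", "n_concordant")]
#>   n_total n_positive n_negative n_pm n_fm n_concordant
#> 1     151         15        136    7    8          151
```

Size a single genotype — a heterozygous female carrying a 128-repeat
premutation — from its simulated CE ladder:

```r
g <- genotype_tbl("demo", "F", "29;128")
count_ladder(simulate_tppcr_trace(g, seed = 1))
#> # A tibble: 1 × 6  (selected columns)
#>   sample_id n_rungs allele_sizes category fm_flag mosaic_flag
#> 1 demo          128 29, 128      PM       FALSE   FALSE
```

Quantify run-to-run Tm reproducibility at low template (8 ng/µL):

```r
replicate_reproducibility(genotype_tbl("r", "M", "110"),
  dna_conc = 8, n_replicates = 10, seed = 5
)
#>   n_replicates n_ok n_flat mean_tm sd_tm
#> 1           10   10      0    90.6 0.475
```

Other entry points: `simulate_melt_curves()` / `melt_profile()` /
`plot_melt_profiles()` for tier 1 signals, `calibrate_boundary()` /
`classify_tm()` / `screen_with_retest()` for the screening logic,
`simulate_regular_trace()` / `regular_size()` / `sizing_concordance()` for
the sizing cross-check, and `count_homozygous_normal_females()` for the
workload argument in favour of melt-first screening. A thin command-line
wrapper lives at `inst/scripts/fxscreen.R`.

## Reproducibility by construction

Every stochastic function requires an explicit `seed`, never touches the
global RNG state, and `run_screen()` derives independent sub-seeds per
sample, so subsetting a cohort does not change per-sample results.
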