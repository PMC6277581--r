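---
title: "Two-tier fragile X screening: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier fragile X screening: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fxscreen)
```

## The screening problem

Fragile X syndrome is caused by expansion of the CGG trinucleotide repeat in
the 5' UTR of *FMR1*. Alleles are conventionally binned by repeat count:

| category | label | repeats |
|---|---|---|
| normal | `NL` | 5--44 |
| intermediate / gray zone | `IM_GZ` | 45--54 |
| premutation | `PM` | 55--199 |
| full mutation | `FM` | >= 200 |

A population screen does not need exact sizes for every sample. It needs a
fast, cheap first tier that separates *expanded* (`PM`/`FM`) from
*non-expanded* (`NL`/`IM_GZ`) samples, and a second tier that sizes only the
small minority the first tier flags. `fxscreen` implements such a two-tier
workflow end to end:

1. **Tier 1 -- melt curve analysis (MCA).** A triplet-primed PCR (TP-PCR)
   product is melted; the *last* peak of the negative derivative profile
   (-dF/dT) gives a melting temperature (Tm) that increases with the longest
   repeat tract present. Samples are classified against a boundary
   calibrated in-run from four intermediate/gray-zone control DNAs.
2. **Tier 2 -- reflex capillary electrophoresis (CE) sizing.** Screen-positive
   (and any indeterminate) samples are sized by counting TP-PCR ladder rungs,
   optionally cross-checked against a repeat-spanning ("regular") PCR
   amplicon.

Because real instrument traces are not needed to exercise the analysis code,
the package includes a synthetic-signal generator whose defaults emulate the
assay's documented operating characteristics, plus the 151-sample
previously genotyped reference cohort used to validate the screen
(`fxs_cohort()`).

## The Tm response model

`tm_model()` encodes the saturating response of the last-peak Tm to the
repeat count $n$:

$$\mathrm{Tm}(n) = T_{\mathrm{sat}} - (T_{\mathrm{sat}} - T_{\min})\, e^{-n/\tau}$$

| parameter | default | unit | meaning |
|---|---|---|---|
| `tm_min` | 82.08 | deg C | extrapolated Tm at zero repeats |
| `tm_sat` | 92 | deg C | saturation Tm for very long tracts |
| `tau` | 55 | repeats | e-folding scale of the approach to saturation |
| `transition_width` | 0.8 | deg C | FWHM of the -dF/dT peak of one transition |

`tm_min` is calibrated so that a short 8-repeat allele melts at 83.42 deg C,
the assay's low-end anchor; with `tau = 55` the model then places the
46- and 54-repeat boundary controls at 87.70 and 88.28 deg C and a
110-repeat premutation at 90.66 deg C, reproducing the observed ~5 deg C
dynamic range between short-normal and full-mutation alleles. Saturation is
the physically important property: beyond a few hundred repeats the product
is effectively pure CGG duplex and Tm no longer discriminates sizes, which
is exactly why tier 1 can only *screen* and tier 2 must *size*.

Each melt transition is a logistic step in fluorescence whose -dF/dT peak
has the configured FWHM. A female (or mosaic) sample is the
fraction-weighted superposition of its component transitions; superposition
is exact in the noiseless generator, which the test suite verifies to
`1e-10`.

## The noise model

`noise_model()` captures the two dominant template-dependent effects:

* **Tm jitter.** The run-to-run SD of a called Tm is 0.11 deg C at
  concentrations >= 25 ng/uL and 0.53 deg C at 8 ng/uL, interpolated
  linearly in 1/concentration between the two anchors and *capped* at
  0.53 deg C below the low anchor. The cap matters: uncapped 1/c
  extrapolation would assign multi-degree jitter to the rare ~1 ng/uL
  dried-blood-spot extract, which is not how the assay degrades -- low
  template flattens the profile rather than scattering its peak. Jitter is
  applied as a single per-curve temperature shift, so it moves all peaks of
  a profile together and preserves superposition.
* **Amplitude saturation and flat profiles.** Signal amplitude scales with
  template mass as $m/(m+10)$ (half-saturation at 10 ng). Below
  `flat_threshold_ng = 3` ng of template in the reaction the profile
  collapses to near-baseline (attenuation factor 0.02 plus drift), which the
  peak caller reports as `qc_flag == "flat"`.

A per-point baseline drift (SD 2 fluorescence units) completes the model.
`noise_none()` switches everything off for oracle tests.

## The melt analysis chain

`melt_profile()` runs, per sample:

1. **Derivative.** Savitzky--Golay smoothing (`signal::sgolayfilt`, window 7,
   order 2) on the uniform 65--95 deg C, 0.5 deg C grid, then central
   differences (one-sided at the ends) to get -dF/dT. The window spans
   3 deg C: wide enough to suppress drift, narrow enough to keep alleles
   >= 1 deg C apart resolvable.
2. **Peak calling.** `pracma::findpeaks` with a floor at
   `max(10, 0.10 * max(-dF/dT))` and a minimum separation of 1 deg C.
   Profiles with no peak are `flat`; profiles with more than 4 peaks are
   `noisy`.
3. **Sub-grid refinement.** A 3-point parabola through each peak refines the
   apex off the 0.5 deg C grid; on noiseless signals the recovered Tm is
   within ~0.002 deg C of the analytic model over 5--600 repeats.

The screening statistic is the **last** (hottest) surviving peak, because the
longest repeat tract melts last and a normal co-allele must never mask an
expansion. The test suite checks this "gender neutrality" directly: adding a
normal 30-repeat allele to an expanded one never demotes the call.

## Boundary calibration, classification and retest

`calibrate_boundary()` melts the four control DNAs (46, 49, 51 and
54 repeats, `boundary_controls()`, dosed by mass at 50 ng) in the same run
and takes the min and max of their last-peak Tms. `classify_tm()` then
calls:

* `expanded` above the upper control Tm + `margin`,
* `non_expanded` below the lower control Tm - `margin`,
* `indeterminate` inside the guard band.

`margin = 0.3` deg C is about 3 SD of high-template jitter: a sample must
clear the control interval by more than plausible run noise before it is
called. Calibration fails loudly -- fewer than four usable controls, or a
flat control profile, is an error naming the offending control, never a
silently narrowed boundary.

Flat profiles trigger the **retest policy** (`screen_with_retest()`): the
sample is re-amplified with increasing template volumes (2, 5, 7.5 uL) and
the first non-flat profile is classified; only if all volumes stay flat is
the sample a `qc_fail`. On the reference cohort this is exercised by the one
~1 ng/uL sample, which resolves at the second volume.

## Tier 2: ladder counting and amplicon sizing

`simulate_tppcr_trace()` produces the CE ladder: one rung per repeat at
$209 + 3k$ bp, Gaussian rungs (sigma 0.6 bp on a 0.25 bp grid), geometric
amplitude decay 0.995 per repeat, and a sustained drop at each allele end.
The decay constant is chosen so that a minority mosaic species carrying 30%
of the template still clears the 5% detection floor out to the 200-repeat
position -- with faster decay, mosaic full mutations would silently vanish
from their own ladders.

`count_ladder()` inverts the trace:

* rungs are counted on the 3-bp comb relative to the first detected rung;
* an **allele end** is a drop to <= 50% of the running amplitude sustained
  for >= 3 periods;
* species at or beyond 200 repeats set `fm_flag` and are *never* reported as
  point estimates -- "greater than 200" is the assay's honest resolution
  there;
* two or more expanded species set `mosaic_flag`.

`simulate_regular_trace()` / `regular_size()` model the repeat-spanning PCR
cross-check: an amplicon at $209 + 3n - 12$ bp. The -12 bp term is the
electrophoretic mobility offset of the GC-rich product, so the naive size
formula undercalls by 4 repeats; `regular_size()` reports both
`repeats_uncorrected = (bp - 209)/3` and
`repeats_corrected = round(uncorrected) + 4`. Alleles >= 200 repeats fail
to amplify (full-mutation dropout); a female with fewer than two distinct
amplicons (or a male with none) sets `dropout_suspected`, and
`sizing_concordance()` reconciles the two sizing dialects per allele.

## The pipeline and its accounting

`run_screen()` ties the tiers together per cohort: calibrate the boundary,
screen every sample with the retest policy, reflex every `expanded` or
`indeterminate` sample to ladder sizing, and form a **final call**:

* an `indeterminate` whose sized maximum allele is < 55 repeats becomes
  `non_expanded`; one sizing at `PM`/`FM` becomes `expanded`;
* summary counts (`glance()`) report final, post-reflex calls.

Two cohort records deserve comment:

* One male record carries two alleles (29 and 51 repeats). The package flags
  it (`qc_note == "sex_allele_mismatch"`) and retains it, treating the extra
  allele as a minority species rather than repairing the record. In the
  simulated melt its minor 51-repeat transition appears only as a shoulder
  on the dominant 29-repeat peak -- shoulder masking of a minor
  near-boundary species is a genuine MCA limitation -- so the sample screens
  negative, concordant with its recorded status.
* One mosaic female carries a normal, a premutation and a full-mutation
  smear; the ladder reports her normal allele, flags the full mutation and
  sets the mosaic flag without claiming a point size beyond 200.

`replicate_reproducibility()` quantifies run-to-run Tm spread for a genotype
at a given concentration, and `count_homozygous_normal_females()` computes
the tier-2 workload a *sizing-first* strategy would waste on homozygous
normal females -- the quantitative argument for melt-first screening.

## Seeds and reproducibility

Every stochastic function requires an explicit `seed` and is
seed-deterministic; none touches the global RNG state (the generator saves
and restores `.Random.seed`). `run_screen()` derives independent sub-seeds
for calibration, each sample and each retest, so per-sample results do not
shift when the cohort is subset.

## What the generator does and does not emulate

Emulated: repeat-dependent last-peak Tm with saturation, biallelic and
mosaic superposition, concentration-dependent jitter and amplitude, flat
low-template profiles, 3-bp TP-PCR ladders with decay and allele-end drops,
full-mutation ladder extension, regular-PCR mobility offset and
full-mutation dropout.

Not emulated: instrument-specific baseline optics, dye saturation,
inter-well crosstalk, stutter artifacts, heteroduplex melting, or AGG
interruptions within the repeat tract (which in real assays perturb TP-PCR
ladder amplitudes). Known analytic limitations: the >= 50%-drop allele-end
rule can merge *stacked* mosaic species of similar amplitude into one
ladder segment, and minor species melting close below a dominant peak can be
shoulder-masked in tier 1 (both are flagged-or-reflexed situations, not
silent errors).
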