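# Synthetic instrument signals: melt curves and CE electropherograms with the
# noise and artifact structure observed on dried-blood-spot TP-PCR assays.

#' Melting-temperature response model
#'
#' Saturating-exponential map from CGG repeat count to the melt peak
#' temperature of the corresponding TP-PCR product population:
#' `Tm(n) = tm_sat - (tm_sat - tm_min) * exp(-n / tau)`.
#' Tm increases strictly with repeat count and saturates for very long
#' alleles, reproducing the ordering Tm(normal) < Tm(premutation) <
#' Tm(full mutation). Defaults are calibrated so that Tm(8) = 83.42 C
#' (the documented low-Tm short allele) while the 46--54-repeat boundary
#' controls (87.7--88.3 C) stay clearly separated from 76+-repeat
#' expansions (>= 89.5 C).
#'
#' @param tm_min Asymptotic Tm for vanishingly short repeats, in C.
#' @param tm_sat Saturation Tm for very long repeats, in C.
#' @param tau Exponential scale, in repeats.
#' @param transition_width Full width at half maximum of a single
#'   transition's -dF/dT peak, in C.
#' @return An object of class `fxs_tm_model`.
#' @examples
#' m <- tm_model()
#' tm_of(m, c(8, 30, 110, 545))
#' @export
tm_model <- function(tm_min = 82.08, tm_sat = 92, tau = 55, transition_width = 0.8) {
  if (!(tm_min < tm_sat)) abort("tm_min must be below tm_sat")
  if (tau <= 0 || transition_width <= 0) abort("tau and transition_width must be positive")
  structure(
    list(
      tm_min = tm_min, tm_sat = tm_sat, tau = tau,
      transition_width = transition_width,
      # logistic scale such that the derivative peak FWHM equals
      # transition_width: FWHM = 2 * log(3 + 2*sqrt(2)) * scale
      scale = transition_width / (2 * log(3 + 2 * sqrt(2)))
    ),
    class = "fxs_tm_model"
  )
}

#' Analytic Tm of a repeat allele under a response model
#'
#' @param model An [tm_model()] object.
#' @param repeats Repeat counts.
#' @return Tm in C, same length as `repeats`.
#' @export
tm_of <- function(model, repeats) {
  stopifnot(inherits(model, "fxs_tm_model"))
  model$tm_sat - (model$tm_sat - model$tm_min) * exp(-repeats / model$tau)
}

#' @export
print.fxs_tm_model <- function(x, ...) {
  cat(sprintf(
    "Tm response model: Tm(n) = %.2f - (%.2f - %.2f) exp(-n/%g) C, width %.2f C\n",
    x$tm_sat, x$tm_sat, x$tm_min, x$tau, x$transition_width
  ))
  invisible(x)
}

#' Concentration-dependent noise model for melt curves
#'
#' Encodes the assay behaviours that degrade with template amount:
#' run-to-run Tm jitter rising as DNA concentration falls (piecewise linear
#' in 1/concentration between the high- and low-concentration anchors),
#' amplitude saturating with template mass, additive baseline drift, and a
#' near-flat profile when template mass drops below `flat_threshold_ng`
#' (the minimum input that still yields an analyzable melt peak).
#'
#' @param tm_jitter_high Tm jitter SD (C) at `conc_high` ng/uL and above.
#' @param tm_jitter_low Tm jitter SD (C) at `conc_low` ng/uL.
#' @param conc_high,conc_low Anchor concentrations, ng/uL.
#' @param baseline_drift_sd SD of additive baseline noise, signal units.
#' @param flat_threshold_ng Template mass (ng) below which profiles are
#'   near-flat.
#' @param amp_half_sat_ng Template mass at which amplitude reaches half its
#'   saturated value.
#' @param flat_atten Multiplicative attenuation applied below the flat
#'   threshold.
#' @return An object of class `fxs_noise_model`.
#' @seealso [noise_none()] for the noiseless variant used in oracle tests.
#' @export
noise_model <- function(tm_jitter_high = 0.11, tm_jitter_low = 0.53,
                        conc_high = 25, conc_low = 8,
                        baseline_drift_sd = 2, flat_threshold_ng = 3,
                        amp_half_sat_ng = 10, flat_atten = 0.02) {
  if (conc_low >= conc_high) abort("conc_low must be below conc_high")
  if (tm_jitter_low < tm_jitter_high) abort("jitter SD must be non-increasing in concentration")
  structure(
    list(
      tm_jitter_high = tm_jitter_high, tm_jitter_low = tm_jitter_low,
      conc_high = conc_high, conc_low = conc_low,
      baseline_drift_sd = baseline_drift_sd,
      flat_threshold_ng = flat_threshold_ng,
      amp_half_sat_ng = amp_half_sat_ng, flat_atten = flat_atten
    ),
    class = "fxs_noise_model"
  )
}

#' Noiseless melt model
#'
#' Zero Tm jitter and baseline noise; amplitude scaling and the flat-profile
#' threshold are retained (they are deterministic assay behaviours, not
#' noise).
#' @return An `fxs_noise_model` with all stochastic terms set to zero.
#' @export
noise_none <- function() {
  noise_model(tm_jitter_high = 0, tm_jitter_low = 0, baseline_drift_sd = 0)
}

#' Tm jitter SD at a given DNA concentration
#'
#' @param noise An [noise_model()] object.
#' @param conc DNA concentration, ng/uL.
#' @return SD in C (vectorized over `conc`).
#' @export
tm_jitter_sd <- function(noise, conc) {
  stopifnot(inherits(noise, "fxs_noise_model"))
  if (any(conc <= 0)) abort("concentration must be positive")
  slope <- (noise$tm_jitter_low - noise$tm_jitter_high) /
    (1 / noise$conc_low - 1 / noise$conc_high)
  sd <- noise$tm_jitter_high + slope * pmax(0, 1 / conc - 1 / noise$conc_high)
  # the jitter model is anchored between conc_high and conc_low; below the
  # low anchor the SD saturates rather than extrapolating without bound
  unname(pmin(sd, noise$tm_jitter_low))
}

amplitude_scale <- function(noise, template_ng) {
  template_ng / (template_ng + noise$amp_half_sat_ng)
}

#' Simulate TP-PCR melt curves for a genotype table
#'
#' Generates one fluorescence-versus-temperature melt trace per sample on
#' the standard 65--95 C grid in 0.5 C steps. Each allele or mosaic
#' component contributes one decreasing logistic transition centred at its
#' model Tm (plus a per-curve run jitter), with amplitude proportional to
#' its template fraction and to a saturating function of template mass;
#' the highest-temperature transition always corresponds to the largest
#' repeat species. Template masses below the flat threshold yield near-flat
#' profiles whose -dF/dT never clears the peak-calling floor.
#'
#' @param genotypes Cohort tibble (one or more rows).
#' @param dna_conc Optional ng/uL override; defaults to the cohort's
#'   `dna_conc` column (25 if absent).
#' @param template_volume Template volume per reaction, uL.
#' @param template_ng Optional direct template mass (ng), overriding
#'   `dna_conc * template_volume` (used for the control DNAs, which are
#'   dosed by mass).
#' @param model [tm_model()] object.
#' @param noise [noise_model()] object; use [noise_none()] for noiseless
#'   oracle curves.
#' @param seed Integer seed; required, every stochastic generator in this
#'   package takes an explicit seed.
#' @param grid Temperature grid, C.
#' @param base_amplitude Fluorescence amplitude of a full-template
#'   single-species transition, signal units.
#' @param baseline Constant fluorescence offset.
#' @return A long tibble `(sample_id, temperature, fluorescence)` with a
#'   `meta` attribute carrying per-sample preparation details.
#' @examples
#' g <- genotype_tbl("S1", "M", "110")
#' curves <- simulate_melt_curves(g, seed = 1)
#' @export
simulate_melt_curves <- function(genotypes, dna_conc = NULL, template_volume = 2,
                                 template_ng = NULL, model = tm_model(),
                                 noise = noise_model(), seed,
                                 grid = seq(65, 95, by = 0.5),
                                 base_amplitude = 1000, baseline = 100) {
  if (missing(seed)) abort("an explicit integer `seed` is required")
  genotypes <- ensure_cohort(genotypes)
  conc <- if (!is.null(dna_conc)) rep_len(dna_conc, nrow(genotypes)) else genotypes$dna_conc
  mass <- if (!is.null(template_ng)) {
    rep_len(template_ng, nrow(genotypes))
  } else {
    conc * template_volume
  }
  if (any(conc <= 0)) abort("dna_conc must be positive")
  with_seed_(seed, {
    curves <- pmap(
      list(genotypes$sample_id, genotypes$genotype, conc, mass),
      function(sid, geno, cc, mm) {
        amp <- base_amplitude * amplitude_scale(noise, mm)
        if (mm < noise$flat_threshold_ng) amp <- amp * noise$flat_atten
        jitter <- if (noise$tm_jitter_high > 0 || noise$tm_jitter_low > 0) {
          stats::rnorm(1, 0, tm_jitter_sd(noise, cc))
        } else {
          0
        }
        tms <- tm_of(model, geno$repeats) + jitter
        f <- rep(baseline, length(grid))
        for (k in seq_len(nrow(geno))) {
          f <- f + amp * geno$fraction[k] *
            stats::plogis(-(grid - tms[k]) / model$scale)
        }
        if (noise$baseline_drift_sd > 0) {
          slope <- stats::rnorm(1, 0, noise$baseline_drift_sd / 30)
          f <- f + slope * (grid - mean(grid)) +
            stats::rnorm(length(grid), 0, noise$baseline_drift_sd)
        }
        tibble(sample_id = sid, temperature = grid, fluorescence = pmax(f, 0))
      }
    )
    out <- bind_rows(curves)
    attr(out, "meta") <- tibble(
      sample_id = genotypes$sample_id, sex = genotypes$sex,
      dna_conc = conc, template_ng = mass
    )
    out
  })
}

#' Simulate a fluorescent TP-PCR CE electropherogram
#'
#' The triplet-primed primer anneals at every repeat position, so an allele
#' of n repeats yields a ladder of products at 3-bp periodicity covering
#' repeat positions 1..n with geometrically decaying amplitude. Female
#' traces superpose the two alleles' ladders; mosaic components add
#' partial-amplitude extensions. Full-mutation species (>= 200 repeats)
#' extend the ladder visibly beyond the 200-repeat position until the decay
#' meets the detection floor. The absolute base-pair register of the first
#' rung carries no information downstream (only the 3-bp spacing and rung
#' count do); it is anchored at `anchor_bp + 3` for convenience.
#'
#' @param genotypes Cohort tibble.
#' @param seed Integer seed (required).
#' @param decay Per-repeat geometric amplitude decay.
#' @param base_amp Amplitude of a full-template rung at repeat 1.
#' @param anchor_bp Flank-size anchor: rung k sits at `anchor_bp + 3 k` bp.
#' @param period_bp Ladder period, bp.
#' @param peak_sigma Gaussian peak SD, bp.
#' @param grid_step CE size-axis resolution, bp.
#' @param amp_noise_sd Multiplicative log-normal-ish rung amplitude noise SD
#'   (0 = noiseless).
#' @return A long tibble `(sample_id, size_bp, intensity)` with attributes
#'   `dialect = "tp_pcr"` and per-sample `meta`.
#' @export
simulate_tppcr_trace <- function(genotypes, seed, decay = 0.995, base_amp = 1000,
                                 anchor_bp = 209, period_bp = 3, peak_sigma = 0.6,
                                 grid_step = 0.25, amp_noise_sd = 0) {
  if (missing(seed)) abort("an explicit integer `seed` is required")
  genotypes <- ensure_cohort(genotypes)
  with_seed_(seed, {
    traces <- pmap(
      list(genotypes$sample_id, genotypes$genotype),
      function(sid, geno) {
        max_n <- max(geno$repeats)
        sizes <- seq(anchor_bp + period_bp - 6,
          anchor_bp + period_bp * max_n + 12,
          by = grid_step
        )
        heights <- numeric(max_n)
        for (k in seq_len(nrow(geno))) {
          n <- geno$repeats[k]
          heights[1:n] <- heights[1:n] +
            base_amp * geno$fraction[k] * decay^(1:n)
        }
        if (amp_noise_sd > 0) {
          heights <- heights * exp(stats::rnorm(max_n, 0, amp_noise_sd))
        }
        intensity <- gaussian_comb(sizes, anchor_bp + period_bp * seq_len(max_n),
          heights,
          sigma = peak_sigma
        )
        tibble(sample_id = sid, size_bp = sizes, intensity = intensity)
      }
    )
    out <- bind_rows(traces)
    attr(out, "dialect") <- "tp_pcr"
    attr(out, "meta") <- tibble(
      sample_id = genotypes$sample_id, sex = genotypes$sex,
      n_primary = map_int(genotypes$genotype, ~ sum(.x$role == "primary"))
    )
    out
  })
}

#' Simulate a fluorescent regular (repeat-spanning) PCR CE electropherogram
#'
#' One Gaussian amplicon peak per repeat species at observed size
#' `flank_bp + 3 n + mobility_offset_bp`; the default -12 bp offset models
#' the anomalous electrophoretic mobility of GC-rich amplicons that makes
#' formula-derived repeat sizes underestimate truth by ~4 repeats. Species
#' at or beyond `dropout_threshold` repeats fail to amplify and leave no
#' peak -- the full-mutation dropout that makes repeat-spanning PCR unable
#' to exclude large expansions.
#'
#' @param genotypes Cohort tibble.
#' @param mobility_offset_bp Observed-size shift, bp (default -12).
#' @param dropout_threshold Repeat count at and above which the amplicon
#'   drops out (default 200).
#' @param seed Integer seed (required).
#' @param flank_bp Flanking sequence size, bp: a 0-repeat amplicon would run
#'   at 209 bp.
#' @param period_bp Base pairs per repeat.
#' @param base_amp,peak_sigma,grid_step,amp_noise_sd As in
#'   [simulate_tppcr_trace()].
#' @return A long tibble `(sample_id, size_bp, intensity)` with attributes
#'   `dialect = "regular_pcr"` and per-sample `meta`.
#' @export
simulate_regular_trace <- function(genotypes, mobility_offset_bp = -12,
                                   dropout_threshold = 200, seed,
                                   flank_bp = 209, period_bp = 3, base_amp = 1000,
                                   peak_sigma = 0.6, grid_step = 0.25,
                                   amp_noise_sd = 0) {
  if (missing(seed)) abort("an explicit integer `seed` is required")
  genotypes <- ensure_cohort(genotypes)
  sizes <- seq(flank_bp - 30, flank_bp + period_bp * dropout_threshold + 30,
    by = grid_step
  )
  with_seed_(seed, {
    traces <- pmap(
      list(genotypes$sample_id, genotypes$genotype),
      function(sid, geno) {
        keep <- geno$repeats < dropout_threshold
        intensity <- numeric(length(sizes))
        if (any(keep)) {
          mu <- flank_bp + period_bp * geno$repeats[keep] + mobility_offset_bp
          h <- base_amp * geno$fraction[keep]
          if (amp_noise_sd > 0) h <- h * exp(stats::rnorm(length(h), 0, amp_noise_sd))
          intensity <- gaussian_comb(sizes, mu, h, sigma = peak_sigma)
        }
        tibble(sample_id = sid, size_bp = sizes, intensity = intensity)
      }
    )
    out <- bind_rows(traces)
    attr(out, "dialect") <- "regular_pcr"
    attr(out, "meta") <- tibble(
      sample_id = genotypes$sample_id, sex = genotypes$sex,
      n_primary = map_int(genotypes$genotype, ~ sum(.x$role == "primary"))
    )
    out
  })
}

# sum of Gaussian peaks on a size grid; positions within 4 sigma contribute
gaussian_comb <- function(grid, mu, height, sigma) {
  out <- numeric(length(grid))
  for (i in seq_along(mu)) {
    lo <- findInterval(mu[i] - 4 * sigma, grid)
    hi <- findInterval(mu[i] + 4 * sigma, grid) + 1
    idx <- max(1, lo):min(length(grid), hi)
    out[idx] <- out[idx] + height[i] * exp(-(grid[idx] - mu[i])^2 / (2 * sigma^2))
  }
  out
}
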