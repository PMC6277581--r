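# shared fixtures built in code

quiet_genotype <- function(...) suppressWarnings(genotype_tbl(...))

noiseless_curve <- function(sex, alleles, dna_conc = 25, volume = 2, seed = 1, ...) {
  simulate_melt_curves(quiet_genotype("q", sex, alleles, dna_conc = dna_conc),
    template_volume = volume, noise = noise_none(), seed = seed, ...
  )
}

noiseless_tm <- function(sex, alleles, ...) {
  melt_profile(noiseless_curve(sex, alleles, ...))$last_peak_tm
}

default_boundary <- function(margin = 0.3) {
  calibrate_boundary(
    simulate_melt_curves(boundary_controls(),
      template_ng = 50,
      noise = noise_none(), seed = 99
    ),
    margin = margin
  )
}

# hand-built electropherogram tibble with dialect attribute
manual_trace <- function(sizes, intensity, dialect, sample_id = "t") {
  out <- tibble::tibble(sample_id = sample_id, size_bp = sizes, intensity = intensity)
  attr(out, "dialect") <- dialect
  out
}
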