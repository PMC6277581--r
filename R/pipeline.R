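# Cohort-level orchestration of the two-tier screen: melt-curve screening of
# every sample, reflex CE sizing of positives and indeterminates, summary
# statistics and a reference-table-style report.

#' Run the two-tier expansion screen over a cohort
#'
#' For every sample: simulate (or in a wet lab, load) its melt curve at the
#' default template volume, apply the retest policy for flat profiles,
#' classify the last-peak Tm against an IM/GZ boundary calibrated from the
#' four control DNAs run alongside the batch, and reflex every `expanded`
#' or `indeterminate` call to TP-PCR CE ladder sizing. An indeterminate
#' screen call is resolved by its sizing result: expanded when the largest
#' sized species is premutation or larger, non-expanded otherwise; summary
#' counts report these final calls.
#'
#' @param cohort Cohort tibble (see [load_cohort()], [fxs_cohort()]).
#' @param controls Control cohort for boundary calibration
#'   ([boundary_controls()]).
#' @param model [tm_model()] object.
#' @param noise [noise_model()] object.
#' @param margin Classification guard band, C.
#' @param volumes Retest template volumes, uL.
#' @param control_template_ng Template mass used for the control reactions
#'   (controls are dosed by mass, 50 ng).
#' @param seed Integer seed driving every stochastic step (required).
#' @param sizing_noise_sd Rung amplitude noise for the reflex ladder
#'   simulation (0 = noiseless sizing traces).
#' @return An object of class `fxs_screen`: per-sample `records`, one-row
#'   `summary`, the `boundary` object and the parameters used. Methods:
#'   [tidy.fxs_screen()], [glance.fxs_screen()], `print`, `summary`,
#'   [autoplot.fxs_screen()].
#' @examples
#' scr <- run_screen(fxs_cohort(), seed = 17)
#' glance(scr)
#' @export
run_screen <- function(cohort, controls = boundary_controls(), model = tm_model(),
                       noise = noise_model(), margin = 0.3, volumes = c(2, 5, 7.5),
                       control_template_ng = 50, seed, sizing_noise_sd = 0) {
  if (missing(seed)) abort("an explicit integer `seed` is required")
  cohort <- ensure_cohort(cohort)
  n <- nrow(cohort)
  seeds <- derive_seeds(seed, 1L + 2L * max(n, 1L))
  control_curves <- simulate_melt_curves(controls,
    template_ng = control_template_ng,
    model = model, noise = noise, seed = seeds[1]
  )
  boundary <- calibrate_boundary(control_curves, margin = margin)
  if (n == 0) {
    return(new_fxs_screen(empty_records(), boundary, cohort, seed))
  }

  records <- purrr::map_dfr(seq_len(n), function(i) {
    row <- cohort[i, ]
    melt_seeds <- derive_seeds(seeds[1 + i], length(volumes))
    attempt <- 0L
    curve_fun <- function(v) {
      attempt <<- attempt + 1L
      simulate_melt_curves(row,
        template_volume = v, model = model,
        noise = noise, seed = melt_seeds[attempt]
      )
    }
    call <- screen_with_retest(curve_fun, boundary, volumes = volumes)
    rec <- tibble(
      sample_id = row$sample_id, sex = row$sex,
      known_alleles = row$alleles, known_status = row$status,
      qc_note = row$qc_note,
      mca_call = call$call, tm = call$tm, qc_flag = call$qc_flag,
      retest_count = call$retest_count
    )
    if (call$call %in% c("expanded", "indeterminate")) {
      trace <- simulate_tppcr_trace(row,
        seed = seeds[1 + n + i],
        amp_noise_sd = sizing_noise_sd
      )
      sizing <- count_ladder(trace)
      rec$sized <- TRUE
      rec$allele_sizes <- sizing$allele_sizes
      rec$fm_flag <- sizing$fm_flag
      rec$mosaic_flag <- sizing$mosaic_flag
      rec$final_category <- sizing$category
    } else {
      rec$sized <- FALSE
      rec$allele_sizes <- list(integer())
      rec$fm_flag <- NA
      rec$mosaic_flag <- NA
      rec$final_category <- factor(NA, levels = .category_levels)
    }
    rec
  })

  records <- records |>
    mutate(
      final_call = dplyr::case_when(
        .data$mca_call == "expanded" ~ "expanded",
        .data$mca_call == "non_expanded" ~ "non_expanded",
        .data$mca_call == "indeterminate" &
          .data$final_category %in% c("PM", "FM") ~ "expanded",
        .data$mca_call == "indeterminate" ~ "non_expanded",
        TRUE ~ "qc_fail"
      ),
      concordant_with_known = dplyr::case_when(
        is.na(.data$known_status) ~ NA,
        .data$known_status %in% c("PM", "FM") ~ .data$final_call == "expanded",
        TRUE ~ .data$final_call == "non_expanded"
      )
    )
  new_fxs_screen(records, boundary, cohort, seed)
}

empty_records <- function() {
  tibble(
    sample_id = character(), sex = character(), known_alleles = character(),
    known_status = character(), qc_note = character(), mca_call = character(),
    tm = numeric(), qc_flag = character(), retest_count = integer(),
    sized = logical(), allele_sizes = list(), fm_flag = logical(),
    mosaic_flag = logical(),
    final_category = factor(character(), levels = .category_levels),
    final_call = character(), concordant_with_known = logical()
  )
}

new_fxs_screen <- function(records, boundary, cohort, seed) {
  count_sex <- function(mask) {
    c(
      n = sum(mask, na.rm = TRUE),
      m = sum(mask & records$sex == "M", na.rm = TRUE),
      f = sum(mask & records$sex == "F", na.rm = TRUE)
    )
  }
  pos <- count_sex(records$final_call == "expanded")
  neg <- count_sex(records$final_call == "non_expanded")
  pm <- count_sex(records$final_call == "expanded" & records$final_category == "PM")
  fm <- count_sex(records$final_call == "expanded" & records$final_category == "FM")
  summary_tbl <- tibble(
    n_total = nrow(records),
    n_male = sum(records$sex == "M"),
    n_female = sum(records$sex == "F"),
    n_positive = pos[["n"]], n_positive_male = pos[["m"]], n_positive_female = pos[["f"]],
    n_negative = neg[["n"]], n_negative_male = neg[["m"]], n_negative_female = neg[["f"]],
    n_indeterminate_mca = sum(records$mca_call == "indeterminate"),
    n_qc_fail = sum(records$final_call == "qc_fail"),
    n_reflexed = sum(records$sized),
    n_pm = pm[["n"]], n_pm_male = pm[["m"]], n_pm_female = pm[["f"]],
    n_fm = fm[["n"]], n_fm_male = fm[["m"]], n_fm_female = fm[["f"]],
    n_concordant = sum(records$concordant_with_known, na.rm = TRUE),
    n_homozygous_normal_females = count_homozygous_normal_females(cohort)
  )
  structure(
    list(
      records = records, summary = summary_tbl, boundary = boundary,
      seed = seed
    ),
    class = "fxs_screen"
  )
}

#' @export
print.fxs_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "Two-tier FMR1 expansion screen: %d samples (%dM, %dF)\n",
      "  expansion-positive: %d (%dM, %dF)\n",
      "  expansion-negative: %d (%dM, %dF)\n",
      "  reflex-sized: %d | MCA-indeterminate: %d | QC fail: %d\n",
      "  categories among positives: %d PM (%dM, %dF), %d FM (%dM, %dF)\n"
    ),
    s$n_total, s$n_male, s$n_female,
    s$n_positive, s$n_positive_male, s$n_positive_female,
    s$n_negative, s$n_negative_male, s$n_negative_female,
    s$n_reflexed, s$n_indeterminate_mca, s$n_qc_fail,
    s$n_pm, s$n_pm_male, s$n_pm_female, s$n_fm, s$n_fm_male, s$n_fm_female
  ))
  print(x$boundary)
  invisible(x)
}

#' Per-sample screen records
#'
#' Broom-style accessor: one row per sample with the MCA call, Tm, QC
#' flags, reflex sizing results, final category and concordance with the
#' known genotype, in reference-table column order.
#'
#' @param x An `fxs_screen` object.
#' @param ... Unused.
#' @return A tibble of per-sample records.
#' @export
tidy.fxs_screen <- function(x, ...) x$records

#' One-row screen summary
#'
#' @param x An `fxs_screen` object.
#' @param ... Unused.
#' @return A one-row tibble of cohort-level counts.
#' @export
glance.fxs_screen <- function(x, ...) x$summary

#' @export
summary.fxs_screen <- function(object, ...) {
  object$records |>
    mutate(
      mca = dplyr::recode(.data$mca_call,
        expanded = "Pos", non_expanded = "Neg",
        indeterminate = "Indet", qc_fail = "QCfail"
      ),
      sizing = dplyr::if_else(
        .data$sized,
        paste0(
          map_chr(.data$allele_sizes, paste, collapse = "/"),
          dplyr::if_else(.data$fm_flag, "/>200", "")
        ),
        "n.d."
      )
    ) |>
    select(
      "sample_id", "sex", "known_status", "known_alleles", "mca", "tm",
      "sizing", "final_category", "concordant_with_known"
    )
}

#' Count homozygous normal females in a cohort
#'
#' Normal females are excluded by a repeat-spanning first-tier PCR only
#' when two distinct normal alleles are seen; females whose two alleles
#' have equal repeat counts cannot be distinguished from carriers of a
#' non-amplifiable full mutation and must be reflexed to sizing under that
#' strategy. This count is the workload the melt-curve screen avoids.
#'
#' @param cohort Cohort tibble.
#' @return Integer count.
#' @examples
#' count_homozygous_normal_females(fxs_cohort())
#' @export
count_homozygous_normal_females <- function(cohort) {
  cohort <- ensure_cohort(cohort)
  is_nl <- !is.na(cohort$status) & cohort$status == "NL"
  hom <- map_lgl(cohort$genotype, function(g) {
    prim <- g$repeats[g$role == "primary"]
    length(prim) == 2 && prim[1] == prim[2]
  })
  sum(cohort$sex == "F" & is_nl & hom)
}

#' Replicate reproducibility of the last-peak Tm
#'
#' Simulates independent replicate melt curves of one genotype at a given
#' DNA concentration, runs peak calling on each, and summarises the spread
#' of the recovered last-peak Tm. Flat replicates are reported but excluded
#' from the SD. When a boundary is supplied, `consistent_class` records
#' whether every analyzable replicate received the same classification.
#'
#' @param genotype One-row cohort tibble.
#' @param dna_conc DNA concentration, ng/uL.
#' @param template_volume Template volume, uL.
#' @param n_replicates Number of replicates (>= 2).
#' @param model,noise Signal models.
#' @param boundary Optional [calibrate_boundary()] object.
#' @param seed Integer seed (required).
#' @return One-row tibble: `sample_id`, `n_replicates`, `n_ok`, `n_flat`,
#'   `mean_tm`, `sd_tm`, `consistent_class`.
#' @export
replicate_reproducibility <- function(genotype, dna_conc = 25, template_volume = 2,
                                      n_replicates = 10, model = tm_model(),
                                      noise = noise_model(), boundary = NULL, seed) {
  if (missing(seed)) abort("an explicit integer `seed` is required")
  if (n_replicates < 2) abort("n_replicates must be at least 2")
  genotype <- ensure_cohort(genotype)
  if (nrow(genotype) != 1) abort("supply exactly one genotype row")
  seeds <- derive_seeds(seed, n_replicates)
  profs <- purrr::map_dfr(seeds, function(s) {
    melt_profile(simulate_melt_curves(genotype,
      dna_conc = dna_conc,
      template_volume = template_volume, model = model, noise = noise, seed = s
    ))
  })
  ok <- profs$qc_flag != "flat"
  tms <- profs$last_peak_tm[ok]
  consistent <- if (!is.null(boundary) && length(tms) > 0) {
    length(unique(classify_tm(tms, boundary))) == 1
  } else {
    NA
  }
  tibble(
    sample_id = genotype$sample_id, n_replicates = n_replicates,
    n_ok = sum(ok), n_flat = sum(!ok),
    mean_tm = if (length(tms) > 0) mean(tms) else NA_real_,
    sd_tm = if (length(tms) > 1) stats::sd(tms) else NA_real_,
    consistent_class = consistent
  )
}

#' Concordance of screen calls with known genotypes
#'
#' Checks every final call against the cohort's known-status column:
#' known premutation/full-mutation samples should screen expanded, normal
#' samples non-expanded. Category-level agreement (PM vs FM) among sized
#' positives is reported alongside.
#'
#' @param screen An `fxs_screen` object.
#' @return A per-sample tibble with an `aggregate` attribute (one-row
#'   tibble: `n`, `n_concordant`, `n_discordant`, `n_category_match`).
#' @export
concordance_report <- function(screen) {
  stopifnot(inherits(screen, "fxs_screen"))
  rec <- screen$records |>
    mutate(
      known_category = dplyr::if_else(
        .data$known_status %in% .category_levels, .data$known_status, NA_character_
      ),
      category_match = dplyr::if_else(
        .data$sized & !is.na(.data$known_category) &
          .data$known_category %in% c("PM", "FM"),
        as.character(.data$final_category) == .data$known_category,
        NA
      )
    ) |>
    select(
      "sample_id", "sex", "known_status", "mca_call", "final_call",
      "final_category", "concordant_with_known", "category_match"
    )
  attr(rec, "aggregate") <- tibble(
    n = nrow(rec),
    n_concordant = sum(rec$concordant_with_known, na.rm = TRUE),
    n_discordant = sum(!rec$concordant_with_known, na.rm = TRUE),
    n_category_match = sum(rec$category_match, na.rm = TRUE)
  )
  rec
}
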