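# Tier-2 reflex sizing: TP-PCR ladder peak counting (with full-mutation and
# mosaicism detection) and regular-PCR amplicon-to-repeat conversion with GC
# mobility correction.

# detect peaks on a CE trace; returns (size_bp, height) refined to sub-grid
trace_peaks <- function(sizes, intensity, peak_floor, min_dist_bp = 2) {
  mx <- max(intensity)
  if (mx <= 0) {
    return(tibble(size_bp = numeric(), height = numeric()))
  }
  step <- sizes[2] - sizes[1]
  pk <- pracma::findpeaks(intensity,
    minpeakheight = peak_floor * mx,
    minpeakdistance = max(1L, as.integer(round(min_dist_bp / step)))
  )
  if (is.null(pk)) {
    return(tibble(size_bp = numeric(), height = numeric()))
  }
  pk <- matrix(pk, ncol = 4)
  refined <- t(apply(pk, 1, function(row) refine_peak(sizes, intensity, row[2])))
  tibble(size_bp = refined[, 1], height = refined[, 2]) |>
    arrange(.data$size_bp)
}

# detect sustained amplitude steps marking where an allele's ladder ends:
# the mean rung height over the `run` periods after position j falls to
# <= (1 - drop) of the mean over the `run` periods up to j
ladder_ends <- function(idx, height, drop, run) {
  J <- length(idx)
  ends <- integer()
  for (j in seq_len(J - 1)) {
    before <- mean(height[max(1, j - run + 1):j])
    after <- mean(height[(j + 1):min(J, j + run)])
    if (after <= (1 - drop) * before) ends <- c(ends, idx[j])
  }
  sort(unique(c(ends, idx[J])))
}

#' Count TP-PCR ladder rungs and call repeat species
#'
#' Sizes a sample from its TP-PCR electropherogram by peak counting: rungs
#' at 3-bp periodicity are detected above a floor, indexed by repeat
#' position relative to the first rung (the absolute register carries no
#' information), and allele ends are called at sustained amplitude drops
#' (>= 50 percent over >= 3 periods by default), which deconvolves
#' biallelic female traces. A ladder whose qualifying rungs reach the
#' 200-repeat position marks a full-mutation species (`fm_flag`); such
#' species are reported as ">200" via the flag, never as a point estimate.
#' `mosaic_flag` is raised when two or more distinct expanded species are
#' present: a second expanded (55--199) allele end, an expanded end
#' together with a full-mutation continuation, or rung groups separated by
#' >= `mosaic_gap` silent periods.
#'
#' @param trace TP-PCR electropherogram tibble `(sample_id, size_bp,
#'   intensity)` (dialect `tp_pcr`).
#' @param period_bp Ladder period, bp.
#' @param peak_floor Detection floor as a fraction of the trace maximum.
#' @param end_drop Sustained relative amplitude drop that calls an allele
#'   end.
#' @param end_run Periods over which the drop must be sustained.
#' @param fm_repeats Repeat position at and beyond which rungs mark a full
#'   mutation.
#' @param mosaic_gap Silent periods splitting rung groups into separate
#'   species.
#' @return One row per sample: `allele_sizes` (list-column, ascending,
#'   species < `fm_repeats` only), `fm_flag`, `mosaic_flag`, `category`
#'   (class of the largest detected species) and `n_rungs`.
#' @export
count_ladder <- function(trace, period_bp = 3, peak_floor = 0.05,
                         end_drop = 0.5, end_run = 3, fm_repeats = 200,
                         mosaic_gap = 10) {
  dialect <- attr(trace, "dialect")
  if (!is.null(dialect) && dialect != "tp_pcr") {
    abort("count_ladder expects a tp_pcr-dialect trace")
  }
  res <- trace |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      pk <- trace_peaks(df$size_bp, df$intensity, peak_floor)
      if (nrow(pk) == 0) {
        return(tibble(
          allele_sizes = list(integer()), fm_flag = NA, mosaic_flag = NA,
          category = factor(NA, levels = .category_levels), n_rungs = 0L
        ))
      }
      idx <- as.integer(round((pk$size_bp - pk$size_bp[1]) / period_bp)) + 1L
      # split into species groups at silent gaps
      grp <- cumsum(c(1L, as.integer(diff(idx) >= mosaic_gap)))
      ends <- integer()
      for (g in unique(grp)) {
        sel <- grp == g
        ends <- c(ends, ladder_ends(idx[sel], pk$height[sel], end_drop, end_run))
      }
      ends <- sort(unique(ends))
      fm <- any(idx >= fm_repeats)
      sizes <- ends[ends < fm_repeats]
      expanded_species <- sum(sizes >= 55) + as.integer(fm) +
        max(0L, length(unique(grp)) - 1L)
      largest <- if (fm) fm_repeats else max(ends)
      tibble(
        allele_sizes = list(as.integer(sizes)),
        fm_flag = fm,
        mosaic_flag = expanded_species >= 2,
        category = suppressWarnings(repeat_category(largest)),
        n_rungs = nrow(pk)
      )
    }) |>
    ungroup()
  empty <- res$sample_id[res$n_rungs == 0]
  if (length(empty) > 0) {
    abort(paste(
      "no qualifying ladder peaks (failed CE) for sample(s):",
      paste(empty, collapse = ", ")
    ))
  }
  res
}

#' Convert regular-PCR amplicon sizes to repeat counts
#'
#' Applies the repeat-spanning PCR size conversion: uncorrected repeats =
#' (amplicon bp - 209) / 3. Because GC-rich amplicons migrate anomalously,
#' the formula underestimates true size by ~4 repeats; `repeats_corrected`
#' adds the integer mobility correction after rounding. Dropout is
#' suspected when a female trace shows fewer than two distinct amplicons or
#' a male trace none -- the signature of a non-amplifiable large expansion
#' (or, in females, of homozygosity, which this assay cannot distinguish).
#'
#' @param trace Regular-PCR electropherogram tibble (dialect
#'   `regular_pcr`).
#' @param flank_bp Flanking size constant of the conversion (209 bp).
#' @param period_bp Base pairs per repeat.
#' @param correction_repeats Mobility correction added to the rounded
#'   uncorrected size (default +4).
#' @param peak_floor Detection floor as a fraction of the trace maximum.
#' @param sex Optional named character vector (`M`/`F` by sample_id)
#'   overriding the trace's `meta` attribute.
#' @return One row per sample: `amplicon_bp`, `repeats_uncorrected` (real),
#'   `repeats_corrected` (integer) list-columns and `dropout_suspected`.
#' @export
regular_size <- function(trace, flank_bp = 209, period_bp = 3,
                         correction_repeats = 4, peak_floor = 0.05, sex = NULL) {
  dialect <- attr(trace, "dialect")
  if (!is.null(dialect) && dialect != "regular_pcr") {
    abort("regular_size expects a regular_pcr-dialect trace")
  }
  meta <- attr(trace, "meta")
  sex_of <- function(sid) {
    if (!is.null(sex) && sid %in% names(sex)) {
      return(sex[[sid]])
    }
    if (!is.null(meta) && sid %in% meta$sample_id) {
      return(meta$sex[meta$sample_id == sid])
    }
    NA_character_
  }
  trace |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      pk <- trace_peaks(df$size_bp, df$intensity, peak_floor)
      unc <- (pk$size_bp - flank_bp) / period_bp
      corr <- as.integer(round(unc)) + as.integer(correction_repeats)
      sx <- sex_of(key$sample_id)
      n_distinct_amp <- nrow(pk)
      dropout <- if (identical(sx, "F")) {
        n_distinct_amp < 2
      } else if (identical(sx, "M")) {
        n_distinct_amp < 1
      } else {
        n_distinct_amp < 1
      }
      tibble(
        amplicon_bp = list(pk$size_bp),
        repeats_uncorrected = list(unc),
        repeats_corrected = list(corr),
        n_amplicons = n_distinct_amp,
        dropout_suspected = dropout
      )
    }) |>
    ungroup()
}

#' Per-allele agreement between ladder counting and regular-PCR sizing
#'
#' Pairs each mobility-corrected regular-PCR size with the nearest ladder
#' allele size and reports the differences. Samples where the regular-PCR
#' trace lost a species that the ladder saw (full-mutation dropout, or a
#' second allele hidden by dropout) are `concordant_with_dropout` when the
#' remaining pairs agree.
#'
#' @param ladder Output of [count_ladder()].
#' @param regular Output of [regular_size()] for the same samples.
#' @param tol Maximum per-allele difference (repeats) still called
#'   concordant.
#' @return One row per sample: `n_ladder`, `n_regular`, `max_abs_diff`
#'   (`NA` when nothing to pair) and `status` in `c("concordant",
#'   "concordant_with_dropout", "discordant")`.
#' @export
sizing_concordance <- function(ladder, regular, tol = 1) {
  joined <- dplyr::inner_join(
    ladder |> select("sample_id", "allele_sizes", "fm_flag"),
    regular |> select("sample_id", "repeats_corrected", "dropout_suspected"),
    by = "sample_id"
  )
  joined |>
    mutate(pairing = map2(.data$allele_sizes, .data$repeats_corrected, function(ls, rs) {
      if (length(rs) == 0 || length(ls) == 0) {
        return(tibble(ladder = integer(), regular = integer(), diff = numeric()))
      }
      nearest <- vapply(rs, function(r) ls[which.min(abs(ls - r))], numeric(1))
      tibble(ladder = nearest, regular = rs, diff = rs - nearest)
    })) |>
    mutate(
      n_ladder = lengths(.data$allele_sizes) + as.integer(.data$fm_flag),
      n_regular = lengths(.data$repeats_corrected),
      max_abs_diff = map_dbl(.data$pairing, function(p) {
        if (nrow(p) == 0) NA_real_ else max(abs(p$diff))
      }),
      pairs_ok = is.na(.data$max_abs_diff) | .data$max_abs_diff <= tol,
      status = dplyr::case_when(
        .data$n_regular == .data$n_ladder & .data$pairs_ok ~ "concordant",
        .data$n_regular < .data$n_ladder & .data$pairs_ok &
          (.data$dropout_suspected | .data$fm_flag) ~ "concordant_with_dropout",
        TRUE ~ "discordant"
      )
    ) |>
    select(
      "sample_id", "n_ladder", "n_regular", "max_abs_diff", "status",
      "pairing"
    )
}
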