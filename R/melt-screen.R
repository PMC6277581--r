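# Tier-1 screen: -dF/dT transform, last-peak Tm calling, IM/GZ boundary
# calibration from control DNAs, expanded/non-expanded classification and the
# retest-with-more-template policy.

#' Negative first derivative of a melt curve
#'
#' Transforms fluorescence-versus-temperature traces to -dF/dT profiles,
#' the representation in which amplicon melting appears as peaks.
#' Fluorescence is first smoothed with a moving-window least-squares
#' polynomial (Savitzky--Golay) filter, then differentiated by central
#' differences at the grid points, with one-sided differences at the two
#' endpoints.
#'
#' @param curves Long tibble `(sample_id, temperature, fluorescence)`, one
#'   uniform temperature grid per sample with at least 7 points.
#' @param window Smoothing window length in grid points (odd; `1` disables
#'   smoothing). Default 7 points (3 C on the 0.5 C grid): wide enough to
#'   suppress grid noise, symmetric so a transition's peak position is
#'   preserved.
#' @param degree Polynomial order of the smoother.
#' @return Long tibble `(sample_id, temperature, neg_deriv)`; `meta`
#'   attribute is carried through.
#' @export
melt_derivative <- function(curves, window = 7, degree = 2) {
  stopifnot(all(c("sample_id", "temperature", "fluorescence") %in% names(curves)))
  if (window %% 2 == 0) abort("`window` must be odd")
  out <- curves |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      tt <- df$temperature
      if (length(tt) < 7) abort("melt curve needs at least 7 grid points")
      if (length(tt) < window) abort("fewer grid points than the smoothing window")
      steps <- diff(tt)
      if (any(steps <= 0) || max(steps) - min(steps) > 1e-6) {
        abort(paste0("non-uniform temperature grid for sample ", key$sample_id))
      }
      h <- steps[1]
      f <- df$fluorescence
      fs <- if (window > 1) signal::sgolayfilt(f, p = degree, n = window) else f
      m <- length(fs)
      d <- c(
        (fs[2] - fs[1]) / h,
        (fs[3:m] - fs[1:(m - 2)]) / (2 * h),
        (fs[m] - fs[m - 1]) / h
      )
      tibble(temperature = tt, neg_deriv = -d)
    }) |>
    ungroup()
  attr(out, "meta") <- attr(curves, "meta")
  out
}

# parabolic (3-point) sub-grid refinement around index i
refine_peak <- function(x, y, i) {
  if (i <= 1 || i >= length(y)) {
    return(c(x[i], y[i]))
  }
  y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < .Machine$double.eps) {
    return(c(x[i], y2))
  }
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(min(delta, 0.5), -0.5)
  h <- x[2] - x[1]
  c(x[i] + delta * h, y2 - 0.25 * (y1 - y3) * delta)
}

find_profile_peaks <- function(tt, nd, prominence_floor, abs_floor, min_separation) {
  h <- tt[2] - tt[1]
  floor_val <- max(abs_floor, prominence_floor * max(nd))
  pk <- pracma::findpeaks(nd,
    minpeakheight = floor_val,
    minpeakdistance = max(1L, as.integer(round(min_separation / h)))
  )
  if (is.null(pk)) {
    return(tibble(tm = numeric(), height = numeric(), prominence = numeric()))
  }
  pk <- matrix(pk, ncol = 4)
  refined <- t(apply(pk, 1, function(row) refine_peak(tt, nd, row[2])))
  prom <- pk[, 1] - pmax(nd[pk[, 3]], nd[pk[, 4]])
  tibble(tm = refined[, 1], height = refined[, 2], prominence = prom) |>
    arrange(.data$tm)
}

#' Call melt peaks and the last-peak Tm
#'
#' Detects local maxima of -dF/dT that clear a prominence floor (the larger
#' of a fraction of the profile maximum and an absolute floor tied to
#' baseline noise) and are separated by at least `min_separation`. The
#' melting temperature of each peak is refined below the 0.5 C grid by
#' parabolic interpolation through the peak and its two neighbours. The
#' sample's Tm is the last peak before the signal falls to baseline, i.e.
#' the highest-temperature qualifying peak. Profiles with no qualifying
#' peak are flagged `flat`; profiles with more than four are flagged
#' `noisy` (both still reported).
#'
#' @param deriv Output of [melt_derivative()].
#' @param prominence_floor Fraction of the per-profile maximum -dF/dT a
#'   peak must exceed (default 0.10).
#' @param abs_floor Absolute -dF/dT floor, signal units per C (default 10;
#'   keeps near-flat low-template profiles from yielding spurious peaks).
#' @param min_separation Minimum peak separation, C.
#' @return One row per sample: `sample_id`, `n_peaks`, `last_peak_tm`
#'   (`NA` when flat), `qc_flag` (`ok`/`flat`/`noisy`) and a `peaks`
#'   list-column of `(tm, height, prominence)`.
#' @export
call_melt_peaks <- function(deriv, prominence_floor = 0.10, abs_floor = 10,
                            min_separation = 1.0) {
  stopifnot(all(c("sample_id", "temperature", "neg_deriv") %in% names(deriv)))
  out <- deriv |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      pk <- find_profile_peaks(
        df$temperature, df$neg_deriv,
        prominence_floor, abs_floor, min_separation
      )
      tibble(
        n_peaks = nrow(pk),
        last_peak_tm = if (nrow(pk) > 0) max(pk$tm) else NA_real_,
        qc_flag = if (nrow(pk) == 0) "flat" else if (nrow(pk) > 4) "noisy" else "ok",
        peaks = list(pk)
      )
    }) |>
    ungroup()
  attr(out, "meta") <- attr(deriv, "meta")
  out
}

#' Derivative transform and peak calling in one step
#'
#' @inheritParams melt_derivative
#' @inheritParams call_melt_peaks
#' @return See [call_melt_peaks()].
#' @export
melt_profile <- function(curves, window = 7, degree = 2, prominence_floor = 0.10,
                         abs_floor = 10, min_separation = 1.0) {
  call_melt_peaks(melt_derivative(curves, window = window, degree = degree),
    prominence_floor = prominence_floor, abs_floor = abs_floor,
    min_separation = min_separation
  )
}

#' Calibrate the IM/GZ decision boundary from control melt curves
#'
#' The four 46--54-repeat reference DNAs are run alongside every batch;
#' their last-peak Tms bracket the intermediate/gray zone. The boundary is
#' the per-run minimum and maximum of the four control Tms, widened by a
#' fixed margin on each side when classifying (see [classify_tm()]).
#'
#' @param control_curves Melt curves for at least four boundary controls.
#' @param margin Guard band in C added beyond the control extremes before a
#'   call is made (default 0.3 C, the operational meaning of
#'   "significantly" beyond the boundary).
#' @param ... Passed to [melt_profile()].
#' @return An object of class `fxs_boundary` with `lower_tm`, `upper_tm`,
#'   `margin` and the named control Tms.
#' @export
calibrate_boundary <- function(control_curves, margin = 0.3, ...) {
  if (margin < 0) abort("margin must be non-negative")
  prof <- melt_profile(control_curves, ...)
  if (nrow(prof) < 4) {
    abort("boundary calibration requires all four IM/GZ control DNAs")
  }
  bad <- prof$sample_id[prof$qc_flag != "ok"]
  if (length(bad) > 0) {
    abort(paste(
      "control profile(s) failed QC:",
      paste(bad, collapse = ", ")
    ))
  }
  tms <- stats::setNames(prof$last_peak_tm, prof$sample_id)
  structure(
    list(
      lower_tm = min(tms), upper_tm = max(tms), margin = margin,
      control_tms = tms
    ),
    class = "fxs_boundary"
  )
}

#' @export
print.fxs_boundary <- function(x, ...) {
  cat(sprintf(
    "IM/GZ boundary: %.2f - %.2f C (margin %.2f C)\n  controls: %s\n",
    x$lower_tm, x$upper_tm, x$margin,
    paste(sprintf("%s=%.2f", names(x$control_tms), x$control_tms), collapse = ", ")
  ))
  invisible(x)
}

#' Classify a last-peak Tm against the IM/GZ boundary
#'
#' `expanded` when Tm lies more than `margin` above the upper control Tm,
#' `non_expanded` when more than `margin` below the lower control Tm, and
#' `indeterminate` inside the guarded band (indeterminate samples are
#' reflexed to CE sizing, like screen positives).
#'
#' @param tm Numeric vector of last-peak Tms (finite).
#' @param boundary An [calibrate_boundary()] object.
#' @return Character vector in
#'   `c("expanded", "non_expanded", "indeterminate")`.
#' @export
classify_tm <- function(tm, boundary) {
  stopifnot(inherits(boundary, "fxs_boundary"))
  if (any(!is.finite(tm))) abort("`tm` must be finite")
  dplyr::case_when(
    tm > boundary$upper_tm + boundary$margin ~ "expanded",
    tm < boundary$lower_tm - boundary$margin ~ "non_expanded",
    TRUE ~ "indeterminate"
  )
}

#' Screen one sample with the retest-at-higher-volume policy
#'
#' Reactions that fail to produce a melt peak (flat profile, usually low
#' DNA concentration) are repeated at increasing template volumes until a
#' non-flat profile is obtained; the first analyzable profile is classified
#' and returned with the number of retests consumed. If every volume is
#' flat the sample is a QC failure.
#'
#' @param curve_fun Function of one argument (template volume, uL)
#'   returning a one-sample melt-curve tibble.
#' @param boundary An [calibrate_boundary()] object.
#' @param volumes Increasing template volumes to attempt (uL).
#' @param ... Passed to [melt_profile()].
#' @return One-row tibble: `call`
#'   (`expanded`/`non_expanded`/`indeterminate`/`qc_fail`), `tm`,
#'   `qc_flag`, `retest_count`.
#' @export
screen_with_retest <- function(curve_fun, boundary, volumes = c(2, 5, 7.5), ...) {
  if (length(volumes) == 0 || is.unsorted(volumes, strictly = TRUE)) {
    abort("`volumes` must be a non-empty increasing vector")
  }
  for (i in seq_along(volumes)) {
    prof <- melt_profile(curve_fun(volumes[i]), ...)
    if (nrow(prof) != 1) abort("curve_fun must return a single-sample curve")
    if (prof$qc_flag != "flat") {
      return(tibble(
        call = classify_tm(prof$last_peak_tm, boundary),
        tm = prof$last_peak_tm, qc_flag = prof$qc_flag,
        retest_count = i - 1L
      ))
    }
  }
  tibble(
    call = "qc_fail", tm = NA_real_, qc_flag = "flat",
    retest_count = length(volumes) - 1L
  )
}
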