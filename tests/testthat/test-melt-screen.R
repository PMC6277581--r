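grid <- seq(65, 95, by = 0.5)

test_that("the derivative transform matches analytic derivatives", {
  const <- tibble::tibble(sample_id = "c", temperature = grid, fluorescence = 500)
  expect_true(all(abs(melt_derivative(const)$neg_deriv) < 1e-10))

  lin <- tibble::tibble(
    sample_id = "l", temperature = grid,
    fluorescence = 1000 - 2 * grid
  )
  d <- melt_derivative(lin)
  expect_equal(d$neg_deriv, rep(2, length(grid)), tolerance = 1e-8)
})

test_that("a noiseless sigmoid peak is located within a quarter grid step", {
  # oracle: dense analytic derivative of the same sigmoid peaks at its centre
  s <- 0.8 / (2 * log(3 + 2 * sqrt(2)))
  for (centre in c(85.0, 85.17, 85.33)) {
    f <- 100 + 1000 * plogis(-(grid - centre) / s)
    prof <- melt_profile(tibble::tibble(
      sample_id = "s", temperature = grid,
      fluorescence = f
    ))
    expect_equal(prof$n_peaks, 1L)
    expect_equal(prof$last_peak_tm, centre, tolerance = 0.25)
  }
})

test_that("derivative input validation rejects broken grids", {
  bad <- tibble::tibble(
    sample_id = "b", temperature = c(65, 65.5, 66.5, 67, 68, 69, 70),
    fluorescence = 1:7
  )
  expect_error(melt_derivative(bad), "non-uniform")
  short <- tibble::tibble(sample_id = "s", temperature = seq(65, 67, 0.5), fluorescence = 1:5)
  expect_error(melt_derivative(short), "at least 7")
  expect_error(
    melt_derivative(
      tibble::tibble(sample_id = "w", temperature = grid, fluorescence = 0),
      window = 63
    ),
    "window"
  )
})

test_that("biallelic expanded females show two peaks, the last at the expansion", {
  prof <- melt_profile(noiseless_curve("F", "29;128"))
  expect_equal(prof$n_peaks, 2L)
  pk <- prof$peaks[[1]]
  expect_equal(prof$last_peak_tm, max(pk$tm))
  expect_equal(prof$last_peak_tm, tm_of(tm_model(), 128), tolerance = 0.25)
  expect_equal(min(pk$tm), tm_of(tm_model(), 29), tolerance = 0.25)
})

test_that("boundary calibration brackets the controls and enforces QC", {
  b <- default_boundary()
  m <- tm_model()
  expect_equal(b$lower_tm, tm_of(m, 46), tolerance = 0.05)
  expect_equal(b$upper_tm, tm_of(m, 54), tolerance = 0.05)
  expect_lte(b$lower_tm, b$upper_tm)

  three <- boundary_controls()[1:3, ]
  expect_error(
    calibrate_boundary(
      simulate_melt_curves(three, template_ng = 50, noise = noise_none(), seed = 1)
    ),
    "four"
  )

  # a flat control aborts calibration, naming the control
  ctl <- boundary_controls()
  ctl$dna_conc <- c(25, 25, 25, 0.5)
  curves <- simulate_melt_curves(ctl, template_volume = 2, noise = noise_none(), seed = 1)
  expect_error(calibrate_boundary(curves), "NA20236")
})

test_that("jittered control runs always retain a positive boundary width", {
  ctl <- boundary_controls()
  widths <- vapply(1:100, function(i) {
    b <- calibrate_boundary(
      simulate_melt_curves(ctl, template_ng = 50, seed = 1000 + i)
    )
    b$upper_tm - b$lower_tm
  }, numeric(1))
  expect_true(all(widths > 0))
})

test_that("classification applies the guard band around the control extremes", {
  b <- default_boundary()
  eps <- 1e-6
  expect_equal(classify_tm(b$upper_tm, b), "indeterminate")
  expect_equal(classify_tm(b$upper_tm + b$margin + eps, b), "expanded")
  expect_equal(classify_tm(b$upper_tm + b$margin - eps, b), "indeterminate")
  expect_equal(classify_tm(b$lower_tm - b$margin - eps, b), "non_expanded")
  expect_equal(classify_tm(noiseless_tm("M", "110"), b), "expanded")
  expect_error(classify_tm(NA_real_, b), "finite")
})

test_that("raising the margin only moves calls into the indeterminate band", {
  b1 <- default_boundary(margin = 0.3)
  b2 <- default_boundary(margin = 1.2)
  tms <- seq(84, 92, by = 0.05)
  c1 <- classify_tm(tms, b1)
  c2 <- classify_tm(tms, b2)
  expect_false(any(c1 == "expanded" & c2 == "non_expanded"))
  expect_false(any(c1 == "non_expanded" & c2 == "expanded"))
  moved <- c1 != c2
  expect_true(all(c2[moved] == "indeterminate"))
})

test_that("the retest policy escalates template volume until analyzable", {
  b <- default_boundary()
  make_fun <- function(conc) {
    g <- quiet_genotype("r", "M", "30", dna_conc = conc)
    function(v) simulate_melt_curves(g, template_volume = v, noise = noise_none(), seed = 4)
  }
  # flat at 2 and 5 uL (0.9, 2.25 ng), analyzable at 7.5 uL (3.4 ng)
  res <- screen_with_retest(make_fun(0.45), b)
  expect_equal(res$call, "non_expanded")
  expect_equal(res$retest_count, 2L)

  res0 <- screen_with_retest(make_fun(25), b)
  expect_equal(res0$retest_count, 0L)
  expect_equal(res0$call, "non_expanded")

  res_fail <- screen_with_retest(make_fun(0.05), b)
  expect_equal(res_fail$call, "qc_fail")

  expect_error(screen_with_retest(make_fun(25), b, volumes = numeric()), "volumes")
})
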