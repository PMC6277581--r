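test_that("the Tm response model is anchored at the documented short allele", {
  m <- tm_model()
  expect_equal(tm_of(m, 8), 83.42, tolerance = 0.001)
  # recovered through the full simulate -> derivative -> peak-call path
  expect_equal(noiseless_tm("M", "8"), 83.42, tolerance = 0.25)
})

test_that("last-peak Tm is strictly increasing in repeat count", {
  ns <- c(10, 30, 54, 110, 545)
  tms <- vapply(ns, function(n) noiseless_tm("M", as.character(n)), numeric(1))
  expect_true(all(diff(tms) > 0))
  # oracle: the analytic Tm of the model evaluated directly
  expect_equal(tms, tm_of(tm_model(), ns), tolerance = 0.25)
})

test_that("template mass below the flat threshold gives a flat profile", {
  curves <- simulate_melt_curves(quiet_genotype("lo", "M", "110", dna_conc = 1),
    template_volume = 2, noise = noise_none(), seed = 3
  )
  prof <- melt_profile(curves)
  expect_equal(prof$qc_flag, "flat")
  expect_equal(prof$n_peaks, 0L)
  expect_true(is.na(prof$last_peak_tm))
})

test_that("female curves superpose the two allele transitions exactly", {
  fem <- noiseless_curve("F", "29;29")
  male <- noiseless_curve("M", "29")
  # identical alleles: same shape, amplitude only (here identical weights sum to 1)
  expect_equal(fem$fluorescence, male$fluorescence, tolerance = 1e-10)

  fem2 <- noiseless_curve("F", "29;128")
  m29 <- noiseless_curve("M", "29")$fluorescence - 100
  m128 <- noiseless_curve("M", "128")$fluorescence - 100
  expect_equal(fem2$fluorescence, 100 + 0.5 * m29 + 0.5 * m128, tolerance = 1e-10)
})

test_that("simulators require explicit seeds and are seed-deterministic", {
  g <- quiet_genotype("s", "M", "110")
  expect_error(simulate_melt_curves(g), "seed")
  expect_error(simulate_tppcr_trace(g), "seed")
  expect_error(simulate_regular_trace(g), "seed")
  a <- simulate_melt_curves(g, seed = 11)
  b <- simulate_melt_curves(g, seed = 11)
  d <- simulate_melt_curves(g, seed = 12)
  expect_identical(a$fluorescence, b$fluorescence)
  expect_false(identical(a$fluorescence, d$fluorescence))
})

test_that("Tm jitter SD reproduces its concentration anchors and saturates", {
  nm <- noise_model()
  expect_equal(tm_jitter_sd(nm, 25), 0.11)
  expect_equal(tm_jitter_sd(nm, 100), 0.11)
  expect_equal(tm_jitter_sd(nm, 8), 0.53)
  expect_equal(tm_jitter_sd(nm, 1), 0.53)
  conc <- c(100, 25, 16, 10, 8, 4)
  expect_true(all(diff(tm_jitter_sd(nm, conc)) >= 0))
})

test_that("injected Tm jitter is recovered by downstream peak calling", {
  n_rep <- 400
  g <- suppressWarnings(as.data.frame(quiet_genotype("r", "M", "110"))[rep(1, n_rep), ])
  g$sample_id <- sprintf("r%03d", seq_len(n_rep))
  curves <- simulate_melt_curves(tibble::as_tibble(g), dna_conc = 8, seed = 7)
  prof <- melt_profile(curves)
  expect_true(all(prof$qc_flag == "ok"))
  expect_equal(sd(prof$last_peak_tm), 0.53, tolerance = 0.10)
})

test_that("TP-PCR ladders carry exactly one rung per repeat", {
  for (n in c(1, 7, 36, 100, 250)) {
    trace <- simulate_tppcr_trace(quiet_genotype("l", "M", as.character(n)), seed = 1)
    lc <- count_ladder(trace)
    expect_equal(lc$n_rungs, n)
    if (n < 200) {
      expect_equal(lc$allele_sizes[[1]], n)
    } else {
      # at or beyond the full-mutation position the species is reported as
      # ">200" via the flag, never as a point estimate
      expect_true(lc$fm_flag)
      expect_length(lc$allele_sizes[[1]], 0)
    }
  }
})

test_that("full-mutation ladders extend beyond the 200-repeat position", {
  trace <- simulate_tppcr_trace(quiet_genotype("159", "F", "32;423"), seed = 1)
  lc <- count_ladder(trace)
  expect_equal(lc$allele_sizes[[1]], 32L)
  expect_true(lc$fm_flag)
  expect_equal(as.character(lc$category), "FM")
})

test_that("regular PCR places amplicons by the size formula and drops FM alleles", {
  tr <- simulate_regular_trace(quiet_genotype("a", "M", "28"), seed = 1)
  pk_bp <- tr$size_bp[which.max(tr$intensity)]
  expect_equal(pk_bp, 209 + 3 * 28 - 12, tolerance = 0.3) # 281 bp

  tr_fm <- simulate_regular_trace(quiet_genotype("b", "M", "545"), seed = 1)
  expect_equal(max(tr_fm$intensity), 0)

  tr_f <- simulate_regular_trace(quiet_genotype("c", "F", "29;288"), seed = 1)
  expect_equal(
    tr_f$size_bp[which.max(tr_f$intensity)], 209 + 3 * 29 - 12,
    tolerance = 0.3
  )
  # single amplicon: the expanded allele left no peak
  rs <- regular_size(tr_f)
  expect_equal(rs$n_amplicons, 1L)
  expect_true(rs$dropout_suspected)
})
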