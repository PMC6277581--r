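test_that("ladder counting inverts the generator across the sizing range", {
  for (n in c(5, 29, 36, 54, 55, 110, 150, 199)) {
    lc <- count_ladder(
      simulate_tppcr_trace(quiet_genotype("m", "M", as.character(n)), seed = 1)
    )
    expect_equal(lc$allele_sizes[[1]], n)
    expect_false(lc$fm_flag)
  }
})

test_that("biallelic female ladders are deconvolved at the amplitude step", {
  lc <- count_ladder(
    simulate_tppcr_trace(quiet_genotype("f", "F", "29;128"), seed = 1)
  )
  expect_equal(lc$allele_sizes[[1]], c(29L, 128L))
  expect_false(lc$fm_flag)
  expect_false(lc$mosaic_flag)
  expect_equal(as.character(lc$category), "PM")
})

test_that("premutation/full-mutation mosaics raise the mosaic flag", {
  lc <- count_ladder(
    simulate_tppcr_trace(quiet_genotype("152x", "F", "29;130;250"), seed = 1)
  )
  expect_true(lc$fm_flag)
  expect_true(lc$mosaic_flag)
  expect_equal(as.character(lc$category), "FM")
})

test_that("a single-rung trace and a silent trace behave as specified", {
  lc <- count_ladder(simulate_tppcr_trace(quiet_genotype("one", "M", "1"), seed = 1))
  expect_equal(lc$allele_sizes[[1]], 1L)
  expect_equal(lc$n_rungs, 1L)

  silent <- manual_trace(seq(200, 400, 0.25), 0, dialect = "tp_pcr", sample_id = "145")
  expect_error(count_ladder(silent), "145")
  expect_error(count_ladder(silent), "failed CE")
})

test_that("ladder full-mutation flags match genotype truth across the cohort", {
  co <- max_allele(fxs_cohort())
  traces <- simulate_tppcr_trace(co, seed = 2)
  lc <- count_ladder(traces)
  lc <- lc[match(co$sample_id, lc$sample_id), ]
  expect_equal(lc$fm_flag, co$max_allele >= 200)
})

test_that("the size conversion formula and mobility correction are exact", {
  # 281 bp -> 24 repeats uncorrected, 28 corrected
  rs <- regular_size(simulate_regular_trace(quiet_genotype("145x", "M", "28"), seed = 1))
  expect_equal(rs$repeats_uncorrected[[1]], 24, tolerance = 1e-3)
  expect_equal(rs$repeats_corrected[[1]], 28L)

  # formula identity at the flank size
  flat209 <- manual_trace(
    seq(180, 320, 0.25),
    1000 * exp(-(seq(180, 320, 0.25) - 209)^2 / (2 * 0.6^2)),
    dialect = "regular_pcr"
  )
  rs0 <- regular_size(flat209, sex = c(t = "M"))
  expect_equal(rs0$repeats_uncorrected[[1]], 0, tolerance = 1e-3)

  # full-mutation male: no amplicon, dropout suspected
  rs_fm <- regular_size(simulate_regular_trace(quiet_genotype("044x", "M", "545"), seed = 1))
  expect_equal(rs_fm$n_amplicons, 0L)
  expect_true(rs_fm$dropout_suspected)
})

test_that("regular sizing inverts the generator under the default offset", {
  for (n in c(5, 20, 75, 150)) {
    rs <- regular_size(
      simulate_regular_trace(quiet_genotype("m", "M", as.character(n)), seed = 1)
    )
    expect_equal(rs$repeats_corrected[[1]], n)
  }
})

test_that("ladder and corrected regular sizes agree; dropout is tolerated", {
  g <- quiet_genotype("145x", "M", "28")
  conc <- sizing_concordance(
    count_ladder(simulate_tppcr_trace(g, seed = 1)),
    regular_size(simulate_regular_trace(g, seed = 1))
  )
  expect_equal(conc$status, "concordant")
  expect_equal(conc$max_abs_diff, 0)

  gf <- quiet_genotype("166x", "F", "29;288")
  conc2 <- sizing_concordance(
    count_ladder(simulate_tppcr_trace(gf, seed = 1)),
    regular_size(simulate_regular_trace(gf, seed = 1))
  )
  expect_equal(conc2$status, "concordant_with_dropout")

  # empty against empty is trivially concordant
  empty_l <- tibble::tibble(
    sample_id = "e", allele_sizes = list(integer()), fm_flag = FALSE
  )
  empty_r <- tibble::tibble(
    sample_id = "e", repeats_corrected = list(integer()), dropout_suspected = FALSE
  )
  expect_equal(sizing_concordance(empty_l, empty_r)$status, "concordant")
})
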