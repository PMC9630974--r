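test_that("sperm fraction follows from the coverage-peak ratio", {
  # worked ratios: algebra of fh = (2r - 1)/r
  expect_equal(sperm_fraction_from_ratio(0.607), (2 * 0.607 - 1) / 0.607)
  expect_equal(round(100 * sperm_fraction_from_ratio(0.607), 1), 35.3)
  expect_equal(sperm_fraction_from_ratio(0.5), 0)
  expect_equal(sperm_fraction_from_ratio(2 / 3), 0.5)
  expect_equal(sperm_fraction_from_peaks(17.4, 28.7),
               sperm_fraction_from_ratio(17.4 / 28.7))
  # noisy ratio below 0.5 clips to zero with a warning
  expect_warning(fh <- sperm_fraction_from_ratio(0.49), "clipping")
  expect_equal(fh, 0)
  # no valid mixture when the 1n peak reaches the 2n peak
  expect_error(sperm_fraction_from_peaks(30, 30), "no valid")
  expect_error(sperm_fraction_from_ratio(1.2), "below 1")
})

test_that("parental coverage expectations split c_AA exactly", {
  fh <- sperm_fraction_from_ratio(0.607)
  par <- expected_parental_coverages(28.73, fh)
  expect_equal(round(unname(par), 2), c(17.44, 11.29))
  expect_equal(sum(par), 28.73)
  expect_equal(unname(expected_parental_coverages(30, 0)), c(15, 15))
  # near-pure haploid tissue: paternal coverage vanishes
  par <- expected_parental_coverages(20, 1 - 1e-9)
  expect_equal(unname(par[["maternal"]]), 20, tolerance = 1e-8)
  expect_error(expected_parental_coverages(20, 1), "fh")
  expect_error(expected_parental_coverages(-1, 0.3), "positive")
})

test_that("minor-ratio estimator and its inverse agree", {
  expect_equal(sperm_fraction_from_minor_ratio(0.5), 0)
  expect_equal(sperm_fraction_from_minor_ratio(1 / 3), 0.5)
  expect_equal(sperm_fraction_from_minor_ratio(0.406), 0.3165, tolerance = 1e-4)
  expect_equal(paternal_ratio_from_sperm_fraction(0), 0.5)
  expect_equal(paternal_ratio_from_sperm_fraction(0.5), 1 / 3)
  expect_equal(paternal_ratio_from_sperm_fraction(0.3525), 0.393, tolerance = 1e-3)
  expect_error(sperm_fraction_from_minor_ratio(0.6), "0.5")
  expect_error(sperm_fraction_from_minor_ratio(0), "positive")
})

test_that("estimator round-trips are identities to machine precision", {
  r <- seq(0.5, 0.999, by = 1e-4)
  fh <- suppressWarnings(sperm_fraction_from_ratio(r))
  r_back <- 1 / (2 - fh)
  expect_lt(max(abs(r_back - r)), 1e-12)

  pp <- seq(1e-4, 0.5, by = 1e-4)
  fh <- sperm_fraction_from_minor_ratio(pp)
  pp_back <- paternal_ratio_from_sperm_fraction(fh)
  expect_lt(max(abs(pp_back - pp)), 1e-12)

  # monotonicity: fh increases in r, decreases in p_p
  expect_true(all(diff(suppressWarnings(sperm_fraction_from_ratio(r))) > 0))
  expect_true(all(diff(sperm_fraction_from_minor_ratio(pp)) < 0))
})

test_that("estimators are mutually consistent: c_maternal equals the X coverage", {
  # when c_AA = c_A, the maternal autosomal coverage equals c_X = c_A/(2-fh)
  for (fh in c(0, 0.2, 0.35, 0.6)) {
    c_A <- 28.7
    par <- expected_parental_coverages(c_A, fh)
    expect_equal(unname(par[["maternal"]]), c_A / (2 - fh))
  }
})

test_that("c_AA is the mean total depth of homozygous autosomal variants", {
  df <- data.frame(genotype_class = c("homozygous_alt", "homozygous_alt",
                                      "heterozygous", "homozygous_alt"),
                   chrom_class = c("autosome", "autosome", "autosome", "X"),
                   depth_ref = c(0L, 2L, 10L, 0L),
                   depth_alt = c(28L, 30L, 12L, 17L))
  class(df) <- c("allele_depths", "data.frame")
  expect_equal(estimate_c_aa(df), mean(c(28, 32)))
  df$chrom_class <- "X"
  expect_error(estimate_c_aa(df), "no homozygous autosomal")
})

test_that("tissue_mixture assembles a coherent report", {
  tm <- tissue_mixture(ratio = 0.607, c_AA = 28.73)
  expect_s3_class(tm, "tissue_mixture")
  expect_equal(tm$c_maternal + tm$c_paternal, tm$c_AA)
  expect_equal(tm$p_p, paternal_ratio_from_sperm_fraction(tm$fh))
  expect_output(print(tm), "sperm fraction")
  tm2 <- tissue_mixture(c_X = 17.4, c_A = 28.7)
  expect_equal(tm2$ratio, 17.4 / 28.7)
  expect_error(tissue_mixture(), "supply")
})
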