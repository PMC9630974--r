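test_that("major/minor decomposition is the per-site max/min", {
  df <- data.frame(depth_ref = c(10L, 3L, 7L), depth_alt = c(5L, 9L, 7L))
  dec <- decompose_heterozygous(df)
  expect_equal(dec$major, c(10, 9, 7))
  expect_equal(dec$minor, c(5, 3, 7))
  # a fully tied input collapses both components
  tied <- data.frame(depth_ref = c(4L, 6L), depth_alt = c(4L, 6L))
  dtie <- decompose_heterozygous(tied)
  expect_equal(dtie$major, dtie$minor)
  # swapping ref/alt labels at any site changes nothing
  swapped <- data.frame(depth_ref = df$depth_alt, depth_alt = df$depth_ref)
  expect_equal(decompose_heterozygous(swapped), dec)
  expect_error(decompose_heterozygous(df[0, ]), "no heterozygous")
})

test_that("decomposition selects het autosomal records from allele_depths", {
  sim <- pge_sim()
  dec <- decompose_heterozygous(
    structure(sim$variants, class = c("allele_depths", "data.frame")))
  hv <- het_variants(sim)
  expect_equal(length(dec$major), nrow(hv))
  expect_true(all(dec$major >= dec$minor))
})

test_that("expected misassignment matches a Monte-Carlo oracle", {
  # independent oracle: a large simulation of the same two NB draws
  set.seed(77)
  n <- 1e6
  mat <- rnbinom(n, mu = 17.44, size = 15)
  pat <- rnbinom(n, mu = 11.29, size = 15)
  mc <- mean(pat > mat) + 0.5 * mean(pat == mat)
  se <- sqrt(mc * (1 - mc) / n)
  exact <- expected_misassignment(17.44, 11.29, 15)
  expect_lt(abs(exact - mc), 3 * se)
})

test_that("misassignment obeys symmetry, limits and monotonicity", {
  expect_equal(expected_misassignment(10, 10, 15), 0.5)
  expect_equal(expected_misassignment(10, 0, 15), 0)
  # increasing in c_pat/c_mat
  probs <- vapply(c(5, 8, 11, 14, 17), function(cp)
    expected_misassignment(17.44, cp, 15), 0)
  expect_true(all(diff(probs) > 0))
  # increasing in overdispersion (1/size)
  probs <- vapply(c(100, 30, 15, 5), function(s)
    expected_misassignment(17.44, 11.29, s), 0)
  expect_true(all(diff(probs) > 0))
  expect_error(expected_misassignment(10, 12, 15), "exceed")
  expect_error(expected_misassignment(0, 0, 15), "positive")
})

test_that("decomposing equal-coverage alleles misassigns half the sites", {
  # regular X0 male: maternal and paternal autosomal coverages are equal,
  # so coverage ranking is uninformative by construction
  sim <- x0_sim()
  hv <- het_variants(sim)
  expect_gte(nrow(hv), 1e4)
  mis <- mean(hv$pat_depth > hv$mat_depth) +
    0.5 * mean(hv$pat_depth == hv$mat_depth)
  expect_lt(abs(mis - 0.5), 0.02)
})

test_that("misassignment on PGE data matches its realized fraction", {
  sim <- pge_sim()
  hv <- het_variants(sim)
  realized <- mean(hv$pat_depth > hv$mat_depth) +
    0.5 * mean(hv$pat_depth == hv$mat_depth)
  expected <- expected_misassignment(sim$truth$c_maternal,
                                     sim$truth$c_paternal, 15)
  expect_lt(abs(realized - expected), 3 * sqrt(0.25 / nrow(hv)) + 0.01)
})

test_that("wasserstein distance behaves on known cases", {
  expect_equal(wasserstein1(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein1(c(0, 0), c(1, 1)), 1)
  expect_equal(wasserstein1(0:10, 0:10 + 2.5), 2.5)
  expect_equal(wasserstein1(5, 5), 0)
})

test_that("pge_test separates the PGE and X0 regimes", {
  set.seed(42)
  mat <- rnbinom(5000, mu = 17.44, size = 15)
  pat <- rnbinom(5000, mu = 11.29, size = 15)
  major <- pmax(mat, pat); minor <- pmin(mat, pat)
  # X drawn from the same distribution as the maternal component
  x_pge <- rnbinom(2000, mu = 17.44, size = 15)
  res <- pge_test(major, minor, x_pge)
  expect_equal(res$verdict, "PGE-like")
  expect_lte(res$position_index, 0.25)
  expect_lt(res$d_major_X, res$d_minor_X)

  # X centred midway between the major and minor medians
  x_mid <- rnbinom(2000, mu = (median(major) + median(minor)) / 2, size = 15)
  res_mid <- pge_test(major, minor, x_mid)
  expect_equal(res_mid$verdict, "non-PGE-like")
  expect_gt(res_mid$position_index, 0.35)

  # undersized samples and degenerate ties
  expect_error(pge_test(major[1:50], minor[1:50], x_pge), "at least")
  res_tie <- pge_test(rep(10, 200), rep(10, 200), rep(10, 200))
  expect_equal(res_tie$verdict, "non-PGE-like")
  expect_true(is.na(res_tie$position_index))
})

test_that("full simulated PGE and X0 samples get opposite verdicts", {
  for (case in list(list(sim = pge_sim(), verdict = "PGE-like"),
                    list(sim = x0_sim(), verdict = "non-PGE-like"))) {
    dec <- decompose_heterozygous(
      structure(case$sim$variants, class = c("allele_depths", "data.frame")))
    res <- pge_test(dec$major, dec$minor, xhom_depths(case$sim))
    expect_equal(res$verdict, case$verdict)
  }
})

test_that("verdicts are stable under bootstrap resampling of sites", {
  sim <- pge_sim()
  dec <- decompose_heterozygous(
    structure(sim$variants, class = c("allele_depths", "data.frame")))
  xh <- xhom_depths(sim)
  n <- length(dec$major)
  set.seed(7)
  verdicts <- vapply(1:100, function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    xi <- sample(xh, length(xh), replace = TRUE)
    pge_test(dec$major[idx], dec$minor[idx], xi)$verdict
  }, "")
  expect_gte(mean(verdicts == "PGE-like"), 0.9)
})
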