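# Build a noiseless histogram directly from the two-component model, so the
# self-consistency checks do not depend on the simulator module.
model_histogram <- function(ratio, c2n, amp1 = 2e6, amp2 = 1e7, size = 15,
                            mmax = ceiling(3.5 * c2n)) {
  m <- seq_len(mmax)
  y <- round(amp1 * dnbinom(m, mu = ratio * c2n, size = size) +
               amp2 * dnbinom(m, mu = c2n, size = size))
  kmer_histogram(m, y)
}

test_that("the fitter recovers its own model without noise", {
  fit <- fit_two_peak_model(model_histogram(0.5, 30))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)[["ratio_r"]]), 0.5, tolerance = 1e-3)
  expect_equal(unname(coef(fit)[["c2n"]]), 30, tolerance = 0.05)

  fit <- fit_two_peak_model(model_histogram(0.607, 28.7))
  expect_equal(unname(coef(fit)[["ratio_r"]]), 0.607, tolerance = 1e-3)
  # a mixture this strong is unambiguous: the CI excludes the naive 1:2
  expect_gt(fit$ratio_ci[1L], 0.5)
  expect_true(test_ratio_deviation(fit)$deviates)
})

test_that("a single-peak histogram is rejected with advice", {
  m <- 1:80
  y <- round(1e7 * dnbinom(m, mu = 30, size = 15))
  expect_error(fit_two_peak_model(kmer_histogram(m, y)),
               "single detectable peak")
  cfg <- simulation_config(x_fraction = 0, het_rate = 0, seed = 4)
  expect_error(fit_two_peak_model(simulate_kmer_histogram(cfg)),
               "single detectable peak|fit_range")
})

test_that("count scaling leaves peak positions invariant and scales amplitudes", {
  h <- simulate_kmer_histogram(simulation_config(seed = 12))
  f1 <- fit_two_peak_model(h)
  h7 <- kmer_histogram(h$multiplicity, h$count * 7)
  f7 <- fit_two_peak_model(h7)
  expect_equal(coef(f7)[["ratio_r"]], coef(f1)[["ratio_r"]], tolerance = 1e-6)
  expect_equal(coef(f7)[["c2n"]], coef(f1)[["c2n"]], tolerance = 1e-6)
  expect_equal(coef(f7)[["amp_2n"]] / coef(f1)[["amp_2n"]], 7, tolerance = 1e-4)
})

test_that("deviation test reads the confidence interval correctly", {
  stub <- function(ci, se = diff(ci) / (2 * 1.96)) {
    structure(list(coefficients = c(c2n = 28.7, ratio_r = mean(ci),
                                    amp_1n = 1, amp_2n = 1,
                                    disp_1n = 15, disp_2n = 15),
                   ratio_se = se, ratio_ci = ci, converged = TRUE),
              class = "two_peak_fit")
  }
  expect_true(test_ratio_deviation(stub(c(0.582, 0.633)))$deviates)
  res <- test_ratio_deviation(stub(c(0.499, 0.503)))
  expect_false(res$deviates)
  expect_true(res$consistent_with_half)
  # degenerate zero-width interval at exactly 0.5 is not a deviation
  expect_false(test_ratio_deviation(stub(c(0.5, 0.5), se = 0))$deviates)
  bad <- stub(c(0.4, 0.6)); bad$converged <- FALSE
  expect_error(test_ratio_deviation(bad), "unconverged")
})

test_that("fit methods expose curve, residuals and summary", {
  fit <- fit_two_peak_model(model_histogram(0.6, 30))
  expect_equal(length(predict(fit)), nrow(fit$data))
  expect_equal(predict(fit), predict(fit, component = "1n") +
                 predict(fit, component = "2n"))
  expect_lt(sum(residuals(fit)^2) / sum(fit$data$y^2), 1e-6)
  s <- summary(fit)
  expect_s3_class(s, "summary.two_peak_fit")
  expect_output(print(s), "ratio")
  expect_output(print(fit), "2n peak coverage")
})

test_that("sampling-noise CIs behave like 0.95 intervals", {
  # 60 seeded replicates at the default study conditions; the narrower
  # 200-replicate calibration lives with the acceptance checks
  true_r <- 1 / (2 - 0.35)
  hits <- vapply(1:60, function(i) {
    cfg <- simulation_config(fh_true = 0.35, depth_2n = 28.7, seed = 3000 + i)
    f <- fit_two_peak_model(simulate_kmer_histogram(cfg))
    f$converged && f$ratio_ci[1L] <= true_r && f$ratio_ci[2L] >= true_r
  }, NA)
  expect_gte(mean(hits), 0.85)
})
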