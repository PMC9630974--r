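# Two-peak coverage-spectrum model.
#
# A whole-body male library from a species with a substantial haploid
# germline fraction shows two coverage peaks: a monoploid (1n) peak from the
# X chromosome(s) and heterozygous k-mers, and a diploid (2n) peak from
# homozygous autosomal sequence. Under a two-tissue soma+sperm mixture the 1n
# peak sits at a ratio r = c1n/c2n > 1/2 of the diploid peak, so the model
# below estimates r directly and tests its deviation from 1/2.

#' Fit the two-peak negative-binomial coverage model
#'
#' Fits, by nonlinear least squares, the mixture
#' \deqn{h(m) = a_{1n}\,\mathrm{NB}(m;\ \mu = r\,c_{2n},\ s_{1n}) +
#'              a_{2n}\,\mathrm{NB}(m;\ \mu = c_{2n},\ s_{2n})}
#' to a coverage histogram, where `m` is multiplicity, the two components are
#' negative-binomial densities in the mean/size parameterisation, and the
#' parameter of interest is the peak-position ratio `r = c1n/c2n`. Fitting is
#' two-stage: an unweighted pass (with a small multi-start when the 1n peak
#' is only a shoulder) locates the peaks, then a pass weighted by the inverse
#' fitted counts — bin counts at genome scale are close to Poisson, so the
#' variance tracks the mean — delivers the estimates. The standard error of
#' `r` comes from the Jacobian-based asymptotic covariance of the weighted
#' fit (dispersion estimated from the weighted residual sum of squares) and
#' the reported confidence interval is `r +- 1.96 * se` (0.95 asymptotic CI).
#'
#' If no fit range is given, the low-multiplicity error peak is truncated at
#' the first local minimum of the smoothed histogram (running mean, window 3)
#' and the fit extends to 3 times the initial diploid-peak guess. The diploid
#' peak is initialised at the tallest smoothed local maximum in range, the
#' ratio at the position of the second detectable peak (0.5 if ambiguous) and
#' both dispersions at 15.
#'
#' @param hist A [kmer_histogram()] (k-mer multiplicity or per-base mapping
#'   coverage histogram).
#' @param fit_range Optional numeric `c(m_lo, m_hi)` multiplicity window.
#' @param init_size Initial negative-binomial size for both peaks. Default 15.
#' @return An object of class `two_peak_fit` with components `coefficients`
#'   (`c2n`, `ratio_r`, `amp_1n`, `amp_2n`, `disp_1n`, `disp_2n`),
#'   `ratio_se`, `ratio_ci`, `fit_range`, `converged`, `data` (the fitted
#'   bins) and the underlying `nls` object (`fit`).
#' @seealso [test_ratio_deviation()], [sperm_fraction_from_ratio()]
#' @examples
#' h <- simulate_kmer_histogram(simulation_config(seed = 1), sampled = FALSE)
#' fit <- fit_two_peak_model(h)
#' coef(fit)["ratio_r"]
#' @export
fit_two_peak_model <- function(hist, fit_range = NULL, init_size = 15) {
  stopifnot(inherits(hist, "kmer_histogram"))
  m <- hist$multiplicity
  y <- hist$count
  sm <- running_mean(y, 3L)

  if (is.null(fit_range)) {
    # error-peak truncation: first local minimum of the smoothed histogram,
    # searched only below the tallest peak (the tail decays to zero and
    # would otherwise masquerade as a minimum)
    lmax <- local_maxima(sm)
    peak_idx <- if (length(lmax)) lmax[which.max(sm[lmax])] else which.max(sm)
    mins <- local_minima(sm)
    mins <- mins[mins < peak_idx]
    m_lo <- if (length(mins)) m[mins[1L]] else m[1L]
  } else {
    m_lo <- fit_range[1L]
  }
  in_lo <- m >= m_lo
  if (!any(in_lo)) stop("fit range excludes every histogram bin")

  # peak detection on the smoothed histogram above the error-peak truncation
  maxs <- local_maxima(sm)
  maxs <- maxs[m[maxs] >= m_lo]
  if (length(maxs) == 0L)  # plateau or monotone shape: take the global max
    maxs <- which(m >= m_lo)[which.max(sm[m >= m_lo])]
  tallest <- maxs[which.max(sm[maxs])]
  p1 <- m[tallest]
  # second peak: the tallest well-separated maximum of non-negligible
  # height (>= 2% of the main peak, screening out count noise in the tail);
  # when the 1n component is only a shoulder of the 2n peak, fall back to a
  # small multi-start around the main peak instead
  others <- maxs[(m[maxs] < 0.8 * p1 | m[maxs] > 1.25 * p1) &
                   sm[maxs] >= 0.02 * sm[tallest]]
  if (length(others) > 0L) {
    p2 <- m[others[which.max(sm[others])]]
    c2_init <- max(p1, p2)
    r_init <- min(p1, p2) / c2_init
    if (r_init < 0.1 || r_init > 0.95) r_init <- 0.5
    starts <- list(c(c2 = c2_init, r = r_init))
  } else {
    c2_init <- p1
    starts <- list(c(c2 = p1, r = 0.5), c(c2 = 1.3 * p1, r = 0.6),
                   c(c2 = 1.45 * p1, r = 0.55), c(c2 = p1, r = 0.75))
  }

  m_hi <- if (is.null(fit_range)) 3 * c2_init else fit_range[2L]
  sel <- m >= m_lo & m <= m_hi
  if (sum(sel) < 10L)
    stop("fewer than 10 histogram bins in fit range [", m_lo, ", ", m_hi, "]")
  dat <- data.frame(m = m[sel], y = y[sel])

  amp_at <- function(pos, size) {
    h <- sm[which.min(abs(m - pos))]
    max(h, 1) / stats::dnbinom(round(pos), mu = pos, size = size)
  }
  one_fit <- function(st) {
    start <- list(a1 = amp_at(st[["r"]] * st[["c2"]], init_size),
                  a2 = amp_at(st[["c2"]], init_size),
                  c2 = st[["c2"]], r = st[["r"]],
                  s1 = init_size, s2 = init_size)
    tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * dnbinom(m, mu = r * c2, size = s1) +
            a2 * dnbinom(m, mu = c2, size = s2),
        data = dat, start = start,
        lower = c(a1 = 0, a2 = 0, c2 = m_lo, r = 0.05, s1 = 0.1, s2 = 0.1),
        upper = c(a1 = Inf, a2 = Inf, c2 = Inf, r = 1.8, s1 = 1e4, s2 = 1e4),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }
  fits <- lapply(starts, one_fit)
  fits <- Filter(Negate(is.null), fits)
  fit <- NULL
  if (length(fits)) {
    rss <- vapply(fits, function(f) sum(residuals(f)^2), 0)
    conv <- vapply(fits, function(f) isTRUE(f$convInfo$isConv), NA)
    ord <- order(!conv, rss)  # converged fits first, then best RSS
    fit <- fits[[ord[1L]]]
  }
  # second stage: reweight by the fitted counts (bin counts are close to
  # Poisson at genome scale, so Var ~ mean); the first, unweighted pass only
  # locates the peaks, the weighted pass delivers the estimate and a
  # correctly calibrated asymptotic covariance
  if (!is.null(fit)) {
    w <- 1 / pmax(fitted(fit), 1)
    refit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * dnbinom(m, mu = r * c2, size = s1) +
            a2 * dnbinom(m, mu = c2, size = s2),
        data = dat, start = as.list(coef(fit)), weights = w,
        lower = c(a1 = 0, a2 = 0, c2 = m_lo, r = 0.05, s1 = 0.1, s2 = 0.1),
        upper = c(a1 = Inf, a2 = Inf, c2 = Inf, r = 1.8, s1 = 1e4, s2 = 1e4),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(refit) && refit$convInfo$isConv) fit <- refit
  }
  converged <- !is.null(fit) && fit$convInfo$isConv
  co <- if (!is.null(fit)) coef(fit) else unlist(start)

  # if the optimiser labelled the peaks in reverse (r > 1), swap them
  if (co[["r"]] > 1) {
    co <- c(a1 = co[["a2"]], a2 = co[["a1"]],
            c2 = co[["r"]] * co[["c2"]], r = 1 / co[["r"]],
            s1 = co[["s2"]], s2 = co[["s1"]])
    swapped <- TRUE
  } else swapped <- FALSE

  # degenerate outcomes: essentially all mass in one component, or the two
  # peak positions collapsed — the histogram has no resolvable second peak
  rel_amp <- min(co[["a1"]], co[["a2"]]) / (co[["a1"]] + co[["a2"]])
  if (converged && (rel_amp < 0.01 || co[["r"]] > 0.97))
    stop("single detectable peak in histogram (no distinct 1n component); ",
         "supply fit_range manually bracketing both the 1n and 2n peaks")

  ratio_se <- NA_real_
  if (converged && !swapped) {
    vc <- tryCatch(vcov(fit), error = function(e) NULL)
    if (!is.null(vc) && is.finite(vc["r", "r"]) && vc["r", "r"] >= 0)
      ratio_se <- sqrt(vc["r", "r"])
  } else if (converged && swapped) {
    # delta method for r' = 1/r
    vc <- tryCatch(vcov(fit), error = function(e) NULL)
    if (!is.null(vc) && is.finite(vc["r", "r"]) && vc["r", "r"] >= 0)
      ratio_se <- sqrt(vc["r", "r"]) * co[["r"]]^2
  }
  ratio_ci <- if (converged && is.finite(ratio_se))
    c(co[["r"]] - 1.96 * ratio_se, co[["r"]] + 1.96 * ratio_se)
  else c(NA_real_, NA_real_)

  structure(list(
    coefficients = c(c2n = unname(co[["c2"]]), ratio_r = unname(co[["r"]]),
                     amp_1n = unname(co[["a1"]]), amp_2n = unname(co[["a2"]]),
                     disp_1n = unname(co[["s1"]]), disp_2n = unname(co[["s2"]])),
    ratio_se = ratio_se,
    ratio_ci = ratio_ci,
    fit_range = c(m_lo = m_lo, m_hi = m_hi),
    converged = converged,
    data = dat,
    fit = fit
  ), class = "two_peak_fit")
}

#' @export
coef.two_peak_fit <- function(object, ...) object$coefficients

#' Model curve of a fitted two-peak spectrum
#'
#' @param object A `two_peak_fit`.
#' @param newdata Optional data frame with a column `m` (multiplicities);
#'   default the fitted bins.
#' @param component `"both"` for the full mixture, `"1n"` or `"2n"` for a
#'   single peak.
#' @param ... Unused.
#' @return Numeric vector of expected counts.
#' @export
predict.two_peak_fit <- function(object, newdata = NULL,
                                 component = c("both", "1n", "2n"), ...) {
  component <- match.arg(component)
  m <- if (is.null(newdata)) object$data$m else newdata$m
  co <- object$coefficients
  p1 <- co[["amp_1n"]] *
    stats::dnbinom(m, mu = co[["ratio_r"]] * co[["c2n"]], size = co[["disp_1n"]])
  p2 <- co[["amp_2n"]] *
    stats::dnbinom(m, mu = co[["c2n"]], size = co[["disp_2n"]])
  switch(component, both = p1 + p2, `1n` = p1, `2n` = p2)
}

#' @export
residuals.two_peak_fit <- function(object, ...)
  object$data$y - predict(object)

#' @export
print.two_peak_fit <- function(x, ...) {
  co <- x$coefficients
  cat("Two-peak negative-binomial coverage model\n")
  cat(sprintf("  2n peak coverage : %.3f\n", co[["c2n"]]))
  cat(sprintf("  1n peak coverage : %.3f\n", co[["ratio_r"]] * co[["c2n"]]))
  cat(sprintf("  ratio r = c1n/c2n: %.4f", co[["ratio_r"]]))
  if (is.finite(x$ratio_se))
    cat(sprintf("  (0.95 CI [%.4f, %.4f])", x$ratio_ci[1L], x$ratio_ci[2L]))
  cat("\n")
  cat(sprintf("  fit range [%g, %g], %d bins, converged: %s\n",
              x$fit_range[1L], x$fit_range[2L], nrow(x$data),
              ifelse(x$converged, "yes", "no")))
  invisible(x)
}

#' @export
summary.two_peak_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              ratio_se = object$ratio_se, ratio_ci = object$ratio_ci,
              fit_range = object$fit_range, converged = object$converged,
              rss = sum(residuals(object)^2), nbins = nrow(object$data))
  if (object$converged) {
    dev <- tryCatch(test_ratio_deviation(object), error = function(e) NULL)
    out$deviates_from_half <- if (is.null(dev)) NA else dev$deviates
  }
  class(out) <- "summary.two_peak_fit"
  out
}

#' @export
print.summary.two_peak_fit <- function(x, ...) {
  cat("Two-peak model summary\n")
  print(round(x$coefficients, 4))
  if (is.finite(x$ratio_se))
    cat(sprintf("ratio SE %.4g, 0.95 CI [%.4f, %.4f]\n",
                x$ratio_se, x$ratio_ci[1L], x$ratio_ci[2L]))
  if (!is.null(x$deviates_from_half) && !is.na(x$deviates_from_half))
    cat("deviates from the 1:2 peak spacing:",
        ifelse(x$deviates_from_half, "yes", "no"), "\n")
  cat(sprintf("RSS %.4g over %d bins\n", x$rss, x$nbins))
  invisible(x)
}

#' @export
plot.two_peak_fit <- function(x, ...) {
  dat <- x$data
  plot(dat$m, dat$y, type = "h", col = "grey70",
       xlab = "coverage (multiplicity)", ylab = "count",
       main = "Two-peak coverage model", ...)
  mm <- data.frame(m = seq(min(dat$m), max(dat$m), by = 1))
  lines(mm$m, predict(x, mm), col = "black", lwd = 2)
  lines(mm$m, predict(x, mm, component = "1n"), col = "firebrick", lty = 2)
  lines(mm$m, predict(x, mm, component = "2n"), col = "steelblue", lty = 2)
  legend("topright", c("fit", "1n", "2n"),
         col = c("black", "firebrick", "steelblue"),
         lty = c(1, 2, 2), lwd = c(2, 1, 1), bty = "n")
  invisible(x)
}

#' Test whether the peak ratio deviates from the naive 1:2 spacing
#'
#' In a pure diploid-soma male (X0 and no germline contribution) the 1n peak
#' sits at exactly half the 2n peak. A 0.95 asymptotic confidence interval
#' for the fitted ratio that excludes 0.5 indicates a tissue mixture.
#'
#' @param fit A converged `two_peak_fit`.
#' @return List with `deviates` (logical), `consistent_with_half` (its
#'   negation), `ratio_r` and `ratio_ci`.
#' @export
test_ratio_deviation <- function(fit) {
  stopifnot(inherits(fit, "two_peak_fit"))
  if (!fit$converged)
    stop("cannot test an unconverged fit")
  if (!is.finite(fit$ratio_se))
    stop("fit has no finite ratio standard error")
  dev <- fit$ratio_ci[1L] > 0.5 || fit$ratio_ci[2L] < 0.5
  list(deviates = dev, consistent_with_half = !dev,
       ratio_r = unname(fit$coefficients[["ratio_r"]]),
       ratio_ci = fit$ratio_ci)
}
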