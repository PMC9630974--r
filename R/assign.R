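# Coverage-based sample sexing and scaffold chromosome assignment.
#
# In an X0 male, X-linked scaffolds sequence at roughly half (or, with a
# haploid germline fraction, somewhat above half) the autosomal depth, so the
# male coverage distribution is bimodal while a female's is unimodal. Scaffold
# class follows from where a scaffold's normalised male and female coverages
# fall relative to the two male modes.

#' Infer the sex of a sample from its coverage modality
#'
#' Fits 1- and 2-component Gaussian mixtures (unequal variances) to the log2
#' per-scaffold coverages, weighting scaffolds by length (each scaffold is
#' replicated proportionally to its length). The sample is called male when
#' the 2-component model wins by BIC and the lower-mean component sits about
#' one log2 unit below the dominant one (within `half_tol`); the tolerance
#' accommodates PGE males, whose X peak is shifted above half coverage.
#'
#' @param cov Per-scaffold coverage data frame (columns `scaffold`, `length`,
#'   `coverage`).
#' @param min_length Minimum scaffold length used. Default 20000 (short
#'   scaffolds have noisy medians).
#' @param min_scaffolds Minimum usable scaffolds. Default 50.
#' @param half_tol Allowed deviation, in log2 units, of the minor-component
#'   mean from half the major. Default 0.35.
#' @return List with `sex` (`"male"`/`"female"`), the BICs of the two models
#'   and the fitted component means (log2 scale).
#' @export
infer_sex <- function(cov, min_length = 20000, min_scaffolds = 50L,
                      half_tol = 0.35) {
  stopifnot(all(c("scaffold", "length", "coverage") %in% names(cov)))
  use <- cov$length >= min_length & cov$coverage > 0
  if (sum(use) < min_scaffolds)
    stop("fewer than ", min_scaffolds, " scaffolds of length >= ", min_length)
  lg <- log2(cov$coverage[use])
  w <- pmin(pmax(1L, round(cov$length[use] / min_length)), 25L)
  x <- rep(lg, w)
  if (length(unique(x)) == 1L)
    return(list(sex = "female", bic = c(G1 = NA, G2 = NA),
                means = mean(x), proportions = 1))
  if (length(unique(x)) == 2L) {
    # two exact coverage levels: degenerate for a mixture fit; decide directly
    tab <- sort(table(x), decreasing = TRUE)
    mu_major <- as.numeric(names(tab)[1L])
    mu_minor <- as.numeric(names(tab)[2L])
    male <- mu_minor < mu_major && abs((mu_minor - mu_major) + 1) <= half_tol
    return(list(sex = if (male) "male" else "female",
                bic = c(G1 = NA, G2 = NA),
                means = c(major = mu_major, minor = mu_minor),
                proportions = as.numeric(tab) / length(x)))
  }
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  fit <- tryCatch(mclust::Mclust(x, G = 1:2, modelNames = "V",
                                 verbose = FALSE),
                  error = function(e) NULL)
  if (is.null(fit))
    return(list(sex = "female", bic = c(G1 = NA, G2 = NA),
                means = mean(x), proportions = 1))
  bics <- c(G1 = fit$BIC[1, "V"], G2 = fit$BIC[2, "V"])
  if (fit$G == 2L) {
    mu <- fit$parameters$mean
    pro <- fit$parameters$pro
    major <- which.max(pro)
    minor <- 3L - major
    male <- mu[minor] < mu[major] &&
      abs((mu[minor] - mu[major]) + 1) <= half_tol
  } else male <- FALSE
  list(sex = if (male) "male" else "female", bic = bics,
       means = if (fit$G == 2L) c(major = unname(fit$parameters$mean[major]),
                                  minor = unname(fit$parameters$mean[minor]))
               else unname(fit$parameters$mean),
       proportions = fit$parameters$pro)
}

# Locate the (up to two) dominant modes of a log2 coverage sample by KDE.
# Returns linear-scale mode positions sorted decreasing by height.
coverage_modes <- function(lg, min_sep = 0.25, min_peak_frac = 0.05) {
  d <- stats::density(lg, bw = "nrd0", n = 512L)
  idx <- local_maxima(d$y)
  if (length(idx) == 0L) idx <- which.max(d$y)
  idx <- idx[order(d$y[idx], decreasing = TRUE)]
  main <- idx[1L]
  rest <- idx[-1L]
  rest <- rest[abs(d$x[rest] - d$x[main]) >= min_sep &
                 d$y[rest] >= min_peak_frac * d$y[main]]
  picks <- c(main, if (length(rest)) rest[1L])
  2^d$x[picks]
}

#' Classify scaffolds as autosomal or X-linked from male and female coverage
#'
#' Each sample's coverages are normalised by its autosomal mode (the taller
#' coverage mode). The male sample must be bimodal; the boundary between the
#' X and autosome acceptance windows is the midpoint between the two male
#' modes, and each window extends symmetrically by half the mode separation.
#' A scaffold is `X` when its normalised male coverage lies in the 1n window
#' while the female coverage is diploid-like; `autosome` when both normalised
#' coverages are diploid-like; otherwise (e.g. collapsed duplications at
#' twice the depth) `unassigned`.
#'
#' @param male_cov,female_cov Per-scaffold coverage data frames (columns
#'   `scaffold`, `length`, `coverage`).
#' @param min_length Scaffolds shorter than this stay `unassigned`. Default
#'   20000.
#' @param min_scaffolds Minimum shared scaffolds required. Default 50.
#' @return Data frame of class `scaffold_assignment` with columns `scaffold`,
#'   `length`, `class`, `male_norm_cov`, `female_norm_cov`.
#' @export
classify_scaffolds <- function(male_cov, female_cov, min_length = 20000,
                               min_scaffolds = 50L) {
  shared <- intersect(male_cov$scaffold, female_cov$scaffold)
  if (length(shared) < min_scaffolds)
    stop("fewer than ", min_scaffolds, " shared scaffolds")
  mi <- match(shared, male_cov$scaffold)
  fi <- match(shared, female_cov$scaffold)
  len <- male_cov$length[mi]
  mcov <- male_cov$coverage[mi]
  fcov <- female_cov$coverage[fi]
  usable <- len >= min_length & mcov > 0 & fcov > 0

  m_modes <- coverage_modes(log2(mcov[usable]))
  f_mode <- coverage_modes(log2(fcov[usable]))[1L]
  res <- data.frame(scaffold = shared, length = len,
                    class = "unassigned",
                    male_norm_cov = mcov / m_modes[1L],
                    female_norm_cov = fcov / f_mode,
                    stringsAsFactors = FALSE)
  if (length(m_modes) < 2L) {
    warning("male coverage distribution is unimodal; no X/autosome ",
            "separation possible — all scaffolds unassigned")
    class(res) <- c("scaffold_assignment", "data.frame")
    return(res)
  }
  mode_1n <- min(m_modes[2L] / m_modes[1L], 1)  # normalised X mode
  halfw <- (1 - mode_1n) / 2                    # window half-width
  is_x <- abs(res$male_norm_cov - mode_1n) <= halfw &
    abs(res$female_norm_cov - 1) <= halfw
  is_a <- abs(res$male_norm_cov - 1) <= halfw &
    abs(res$female_norm_cov - 1) <= halfw
  res$class[usable & is_x] <- "X"
  res$class[usable & is_a] <- "autosome"
  class(res) <- c("scaffold_assignment", "data.frame")
  res
}
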