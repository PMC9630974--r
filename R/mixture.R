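# Two-tissue mixture algebra.
#
# A male body is modelled as a mixture of diploid soma (autosomes 2n, X 1n)
# and a haploid germline fraction fh (sperm: one autosome set plus X). With
# cX and cA the 1n and 2n coverage-peak positions, fh = 1 - (cA - cX)/cX,
# equivalently fh = 2 - cA/cX = (2r - 1)/r for r = cX/cA. Under paternal
# genome elimination the sperm haplotype is the maternal one, which fixes the
# expected maternal/paternal autosomal allele coverages and the expected
# minor-allele ratio p_p = (1 - fh)/(2 - fh).

#' Haploid (sperm) fraction from the two coverage peaks
#'
#' @param c_X 1n (X-chromosome) coverage-peak position, > 0.
#' @param c_A 2n (autosomal) coverage-peak position, > 0.
#' @return The haploid-tissue fraction `fh = 1 - (c_A - c_X)/c_X` in `[0, 1)`.
#'   A ratio `c_X/c_A` slightly below 0.5 (sampling noise) is clipped to
#'   `fh = 0` with a warning; `c_X >= c_A` is an error (no valid mixture).
#' @examples
#' sperm_fraction_from_peaks(17.4, 28.7)
#' @export
sperm_fraction_from_peaks <- function(c_X, c_A) {
  stopifnot(is.numeric(c_X), is.numeric(c_A))
  if (any(c_X <= 0) || any(c_A <= 0)) stop("coverages must be positive")
  if (any(c_X >= c_A))
    stop("c_X >= c_A: 1n peak at or above the 2n peak has no valid ",
         "two-tissue interpretation")
  sperm_fraction_from_ratio(c_X / c_A)
}

#' Haploid (sperm) fraction from the peak-position ratio
#'
#' @param ratio The ratio `r = c1n/c2n` of the two coverage peaks,
#'   in `(0, 1)`.
#' @return `fh = (2 r - 1)/r`, clipped to 0 with a warning when `r < 0.5`.
#' @examples
#' sperm_fraction_from_ratio(0.607)  # 0.3526
#' @export
sperm_fraction_from_ratio <- function(ratio) {
  stopifnot(is.numeric(ratio))
  if (any(ratio <= 0)) stop("ratio must be positive")
  if (any(ratio >= 1)) stop("ratio must be below 1")
  fh <- (2 * ratio - 1) / ratio
  if (any(fh < 0)) {
    warning("peak ratio below 0.5; clipping sperm fraction to 0 ",
            "(consistent with a pure diploid soma up to sampling noise)")
    fh <- pmax(fh, 0)
  }
  fh
}

#' Expected maternal and paternal autosomal allele coverages under PGE
#'
#' Under paternal genome elimination the haploid germline carries the
#' maternal haplotype only, so of the total autosomal allele coverage `c_AA`
#' the maternal allele receives `c_AA/(2 - fh)` and the paternal allele the
#' remainder.
#'
#' @param c_AA Mean total allele coverage of homozygous autosomal variants
#'   (read-depth units), > 0.
#' @param fh Haploid-tissue fraction in `[0, 1)`.
#' @return Named numeric vector `c(maternal =, paternal =)`; the two values
#'   sum exactly to `c_AA`.
#' @examples
#' expected_parental_coverages(28.73, 0.3525)
#' @export
expected_parental_coverages <- function(c_AA, fh) {
  stopifnot(is.numeric(c_AA), is.numeric(fh), length(fh) == 1L)
  if (c_AA <= 0) stop("c_AA must be positive")
  if (fh < 0 || fh >= 1) stop("fh must be in [0, 1)")
  maternal <- c_AA / (2 - fh)
  c(maternal = maternal, paternal = c_AA - maternal)
}

#' Expected paternal minor-allele ratio from the sperm fraction
#'
#' The expected proportion of reads carrying the paternal allele at an
#' autosomal heterozygous site, `p_p = (1 - fh)/(2 - fh)`; the exact inverse
#' of [sperm_fraction_from_minor_ratio()].
#'
#' @param fh Haploid-tissue fraction in `[0, 1)`.
#' @return `p_p` in `(0, 0.5]`.
#' @export
paternal_ratio_from_sperm_fraction <- function(fh) {
  stopifnot(is.numeric(fh))
  if (any(fh < 0) || any(fh >= 1)) stop("fh must be in [0, 1)")
  (1 - fh) / (2 - fh)
}

#' Sperm fraction from the minor-allele coverage ratio
#'
#' @param p_p Minor (paternal) allele-coverage ratio in `(0, 0.5]`.
#' @return `fh = (1 - 2 p_p)/(1 - p_p)` in `[0, 1)`.
#' @examples
#' sperm_fraction_from_minor_ratio(1/3)  # 0.5
#' @export
sperm_fraction_from_minor_ratio <- function(p_p) {
  stopifnot(is.numeric(p_p))
  if (any(p_p <= 0)) stop("p_p must be positive")
  if (any(p_p > 0.5)) stop("p_p must not exceed 0.5 (minor allele by definition)")
  (1 - 2 * p_p) / (1 - p_p)
}

#' Mean allele coverage of homozygous autosomal variants (c_AA)
#'
#' Estimated as the mean of `depth_ref + depth_alt` over homozygous-alternate
#' autosomal records (the mean, not the mode, of the coverage distribution).
#'
#' @param records An `allele_depths` data frame from [read_allele_depths()].
#' @return Scalar estimate of `c_AA`.
#' @export
estimate_c_aa <- function(records) {
  sel <- records$genotype_class == "homozygous_alt" &
    records$chrom_class == "autosome"
  if (!any(sel)) stop("no homozygous autosomal variants to estimate c_AA from")
  mean(records$depth_ref[sel] + records$depth_alt[sel])
}

#' Assemble the full two-tissue mixture report
#'
#' Links every coverage quantity of the two-tissue PGE model from the
#' available inputs: the 1n/2n peak coverages (or their ratio) and,
#' optionally, the homozygous autosomal allele coverage `c_AA`.
#'
#' @param c_X,c_A 1n and 2n coverage-peak positions (both or neither).
#' @param ratio Peak ratio `c_X/c_A`; ignored when `c_X` and `c_A` are given.
#' @param c_AA Optional mean homozygous autosomal allele coverage; enables
#'   the maternal/paternal expectations.
#' @return Object of class `tissue_mixture`: list with `fh`, `c_X`, `c_A`,
#'   `ratio`, `p_p`, and (when `c_AA` is supplied) `c_AA`, `c_maternal`,
#'   `c_paternal`.
#' @examples
#' tissue_mixture(ratio = 0.607, c_AA = 28.73)
#' @export
tissue_mixture <- function(c_X = NULL, c_A = NULL, ratio = NULL, c_AA = NULL) {
  if (!is.null(c_X) && !is.null(c_A)) {
    fh <- sperm_fraction_from_peaks(c_X, c_A)
    ratio <- c_X / c_A
  } else if (!is.null(ratio)) {
    fh <- sperm_fraction_from_ratio(ratio)
    c_X <- NA_real_; c_A <- NA_real_
  } else {
    stop("supply either c_X and c_A, or ratio")
  }
  out <- list(fh = fh, c_X = c_X, c_A = c_A, ratio = ratio,
              p_p = paternal_ratio_from_sperm_fraction(fh))
  if (!is.null(c_AA)) {
    par <- expected_parental_coverages(c_AA, fh)
    out$c_AA <- c_AA
    out$c_maternal <- unname(par[["maternal"]])
    out$c_paternal <- unname(par[["paternal"]])
  }
  structure(out, class = "tissue_mixture")
}

#' @export
print.tissue_mixture <- function(x, ...) {
  cat("Two-tissue mixture model\n")
  cat(sprintf("  peak ratio r       : %.4f\n", x$ratio))
  cat(sprintf("  sperm fraction fh  : %.4f (%.1f%%)\n", x$fh, 100 * x$fh))
  cat(sprintf("  expected minor p_p : %.4f\n", x$p_p))
  if (!is.null(x$c_AA)) {
    cat(sprintf("  c_AA               : %.2f\n", x$c_AA))
    cat(sprintf("  expected maternal  : %.2fx\n", x$c_maternal))
    cat(sprintf("  expected paternal  : %.2fx\n", x$c_paternal))
  }
  invisible(x)
}
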