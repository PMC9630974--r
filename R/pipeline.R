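# End-to-end orchestration: spectrum fit -> two-tissue mixture -> PGE
# decomposition test -> (optional) pileup bistate replication, with a
# cross-estimator consistency block. Each stage is isolated: a failing stage
# is recorded and the remaining stages still run where their inputs allow.

#' Run the full PGE detection workflow
#'
#' @param histogram Path to a k-mer histogram file, or a [kmer_histogram()].
#' @param vcf Path to a VCF of variant calls (or an `allele_depths` data
#'   frame from [read_allele_depths()]).
#' @param assignment Scaffold assignment table (path or data frame); passed
#'   to [read_allele_depths()].
#' @param sync Optional sync pileup (path or `pileup_sites` data frame)
#'   enabling the SNP-call-free bistate estimate.
#' @param cov_a,cov_b Optional per-scaffold coverage tables of the two males
#'   for CNV-scaffold exclusion before the bistate analysis.
#' @param config Named list of stage options: `fit_range`, `min_qual`,
#'   `min_sites`, `pge_threshold`, `non_pge_threshold`, `min_depth`,
#'   `cnv_threshold`, `sample`. All thresholds used are echoed into the
#'   report.
#' @return Object of class `pge_analysis`: list with `spectra` (two-peak
#'   fit), `deviation`, `mixture` (tissue-mixture report), `pge`
#'   (decomposition test), `bistate` (if `sync` given), `consistency`
#'   (fh estimates from every route and their spread), `errors` (named list
#'   of failed stages) and `config`.
#' @export
run_full_analysis <- function(histogram, vcf = NULL, assignment = NULL,
                              sync = NULL, cov_a = NULL, cov_b = NULL,
                              config = list()) {
  defaults <- list(fit_range = NULL, min_qual = 20, min_sites = 100L,
                   pge_threshold = 0.25, non_pge_threshold = 0.4,
                   min_depth = 10L, cnv_threshold = 0.25, sample = 1L)
  config <- utils::modifyList(defaults, config)
  errors <- list()
  res <- list(config = config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  # spectra + mixture
  res$spectra <- stage("spectra", {
    h <- if (inherits(histogram, "kmer_histogram")) histogram
         else read_kmer_histogram(histogram)
    fit_two_peak_model(h, fit_range = config$fit_range)
  })
  res$deviation <- if (!is.null(res$spectra))
    stage("deviation", test_ratio_deviation(res$spectra)) else NULL

  depths <- if (!is.null(vcf)) stage("variants", {
    if (inherits(vcf, "allele_depths")) vcf
    else read_allele_depths(vcf, assignment, sample = config$sample,
                            min_qual = config$min_qual)
  }) else NULL

  res$mixture <- if (!is.null(res$spectra)) stage("mixture", {
    r <- unname(res$spectra$coefficients[["ratio_r"]])
    c_aa <- if (!is.null(depths))
      tryCatch(estimate_c_aa(depths), error = function(e) NULL) else NULL
    tissue_mixture(ratio = r, c_AA = c_aa)
  }) else NULL

  res$pge <- if (!is.null(depths)) stage("pge", {
    dec <- decompose_heterozygous(depths)
    xh <- depths[depths$genotype_class == "homozygous_alt" &
                   depths$chrom_class == "X", , drop = FALSE]
    pge_test(dec$major, dec$minor, xh$depth_alt,
             min_sites = config$min_sites,
             pge_threshold = config$pge_threshold,
             non_pge_threshold = config$non_pge_threshold)
  }) else NULL

  res$bistate <- if (!is.null(sync)) stage("bistate", {
    sites <- if (inherits(sync, "pileup_sites")) sync
             else read_sync(sync, sample = config$sample)
    kept <- NULL
    if (!is.null(cov_a) && !is.null(cov_b)) {
      ca <- if (is.character(cov_a)) read_coverage_table(cov_a) else cov_a
      cb <- if (is.character(cov_b)) read_coverage_table(cov_b) else cov_b
      kept <- filter_cnv_scaffolds(ca, cb, threshold = config$cnv_threshold)
    }
    bistate_minor_frequencies(sites, kept_scaffolds = kept,
                              min_depth = config$min_depth)
  }) else NULL

  # cross-estimator consistency: fh from each available route
  fh <- c(
    spectra = if (!is.null(res$mixture)) res$mixture$fh else NA_real_,
    pileup = if (!is.null(res$bistate)) res$bistate$fh_estimate else NA_real_)
  res$consistency <- list(
    fh_estimates = fh,
    max_spread = if (sum(!is.na(fh)) >= 2L)
      diff(range(fh, na.rm = TRUE)) else NA_real_)
  res$errors <- errors
  res$ok <- length(errors) == 0L
  class(res) <- "pge_analysis"
  res
}

#' @export
print.pge_analysis <- function(x, ...) {
  cat("PGE detection workflow report\n")
  cat("=============================\n")
  if (!is.null(x$spectra)) {
    print(x$spectra)
    if (!is.null(x$deviation))
      cat("  deviation from 1:2 spacing:",
          ifelse(x$deviation$deviates, "yes", "no"), "\n")
  }
  if (!is.null(x$mixture)) print(x$mixture)
  if (!is.null(x$pge)) print(x$pge)
  if (!is.null(x$bistate)) print(x$bistate)
  if (!is.na(x$consistency$max_spread))
    cat(sprintf("fh estimates spread across estimators: %.4f\n",
                x$consistency$max_spread))
  if (length(x$errors)) {
    cat("failed stages:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n",
                                    sep = "")
  }
  invisible(x)
}
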