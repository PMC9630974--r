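# SNP-call-free replication estimate: bistate minor-frequency analysis of
# raw pileups, restricted to scaffolds without copy-number differences
# between samples. Avoids any bias a variant caller's priors might introduce.

#' Filter scaffolds with copy-number variation between two samples
#'
#' Normalises each sample's per-scaffold coverage by its own median and keeps
#' scaffolds whose between-sample log2 normalised coverage ratio is within
#' the threshold.
#'
#' @param cov_a,cov_b Per-scaffold coverage data frames (columns `scaffold`,
#'   `coverage`, e.g. from [read_coverage_table()]) for the two samples.
#' @param threshold Maximum `|log2|` normalised ratio. Default 0.25 (halfway,
#'   in log2, to a single-copy change).
#' @return Character vector of retained scaffold identifiers.
#' @export
filter_cnv_scaffolds <- function(cov_a, cov_b, threshold = 0.25) {
  stopifnot(all(c("scaffold", "coverage") %in% names(cov_a)),
            all(c("scaffold", "coverage") %in% names(cov_b)))
  shared <- intersect(cov_a$scaffold, cov_b$scaffold)
  if (length(shared) == 0L) stop("no shared scaffolds between the samples")
  a <- cov_a$coverage[match(shared, cov_a$scaffold)]
  b <- cov_b$coverage[match(shared, cov_b$scaffold)]
  if (any(a <= 0) || any(b <= 0)) stop("coverages must be positive")
  ratio <- log2((a / stats::median(a)) / (b / stats::median(b)))
  shared[abs(ratio) <= threshold]
}

#' Bistate minor-frequency analysis of pileup sites
#'
#' A genomic position qualifies as a bistate when exactly 2 of its 4
#' nucleotide counts exceed 1 (N and deletion counts are ignored); its minor
#' frequency is the smaller of the two counts over their sum, hence in
#' `(0, 0.5]`. In a PGE male the bistates of heterozygous positions
#' concentrate around the paternal ratio `p_p = (1 - fh)/(2 - fh)`, so the
#' location of that concentration yields an estimate of the sperm fraction
#' that is fully independent of SNP calling.
#'
#' Because the minor count folds the allele ratio at 0.5, the location
#' `mode_pp` is estimated by maximum likelihood under a folded binomial:
#' each qualifying site contributes `log(dbinom(k, n, p) + dbinom(n-k, n,
#' p))` with `n` the two-state depth and `k` the minor count, maximised over
#' `p` on `(0, 0.5]`. (A kernel-density mode of the raw frequencies is also
#' reported for inspection, but the discrete ratio lattice at typical depths
#' makes it jittery, and the fold biases it toward 0.5.)
#'
#' @param sites A `pileup_sites` data frame from [read_sync()].
#' @param kept_scaffolds Optional scaffold whitelist (e.g. from
#'   [filter_cnv_scaffolds()]); `NULL` keeps all.
#' @param min_depth Minimum total nucleotide depth at a site; sites below are
#'   discarded because sequencing errors create spurious low-frequency
#'   bistates at shallow depth. Default 10.
#' @return Object of class `bistate_summary`: `frequencies`, `mode_pp` (the
#'   folded-binomial location), `kde_mode_pp` (descriptive kernel-density
#'   mode), `fh_estimate`, `n_sites`.
#' @export
bistate_minor_frequencies <- function(sites, kept_scaffolds = NULL,
                                      min_depth = 10L) {
  stopifnot(all(c("scaffold", "A", "T", "C", "G") %in% names(sites)))
  if (!is.null(kept_scaffolds)) {
    if (length(kept_scaffolds) == 0L) stop("kept scaffold set is empty")
    sites <- sites[sites$scaffold %in% kept_scaffolds, , drop = FALSE]
  }
  if (nrow(sites) == 0L) stop("no pileup sites after scaffold filtering")
  cnt <- as.matrix(sites[, c("A", "T", "C", "G")])
  total <- rowSums(cnt)
  nstates <- rowSums(cnt > 1L)
  ok <- nstates == 2L & total >= min_depth
  if (!any(ok)) stop("no qualifying bistate sites")
  cnt <- cnt[ok, , drop = FALSE]
  # counts of the two states with coverage > 1, smallest over sum
  top2 <- t(apply(cnt, 1L, function(z) sort(z, decreasing = TRUE)[1:2]))
  n2 <- top2[, 1L] + top2[, 2L]
  k2 <- top2[, 2L]
  freq <- k2 / n2
  negll <- function(p)
    -sum(log(stats::dbinom(k2, n2, p) +
               stats::dbinom(n2 - k2, n2, p) * (k2 != n2 - k2)))
  mode_pp <- stats::optimize(negll, c(1e-3, 0.5))$minimum
  structure(list(frequencies = freq,
                 mode_pp = mode_pp,
                 kde_mode_pp = kde_mode(freq, from = 1e-3, to = 0.5),
                 fh_estimate = sperm_fraction_from_minor_ratio(mode_pp),
                 n_sites = length(freq)),
            class = "bistate_summary")
}

#' @export
print.bistate_summary <- function(x, ...) {
  cat("Pileup bistate minor-frequency summary\n")
  cat(sprintf("  qualifying bistate sites : %d\n", x$n_sites))
  cat(sprintf("  modal minor ratio p_p    : %.4f\n", x$mode_pp))
  cat(sprintf("  implied sperm fraction   : %.4f (%.1f%%)\n",
              x$fh_estimate, 100 * x$fh_estimate))
  invisible(x)
}
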