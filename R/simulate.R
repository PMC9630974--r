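# Synthetic two-tissue sequencing data with known ground truth.
#
# Emulates a whole-body male library: a diploid soma (autosomes 2n, X 1n)
# mixed with a haploid sperm fraction fh carrying one autosomal haplotype
# (the maternal one, under PGE) plus the X. Read depths are drawn
# negative-binomially; the k-mer histogram analogue has error, 1n and 2n
# components. Everything the pipeline consumes can be generated with a known
# fh, which makes end-to-end parameter-recovery and power analyses possible.

#' Configuration for the two-tissue simulator
#'
#' Defaults describe a springtail-like whole-body male library: diploid
#' coverage around 28.7x, sperm fraction 0.35, negative-binomial size 15,
#' X chromosomes spanning 40% of the genome, and autosomal heterozygosity of
#' 2 variants per kb.
#'
#' @param genome_size Genome span in bp. Default 2e7 (a desk-scale stand-in
#'   for a fragmented arthropod assembly).
#' @param n_scaffolds Number of scaffolds. Default 200.
#' @param x_fraction Proportion of the genome on the X chromosome(s), in
#'   `[0, 1)`. Default 0.4 (globular springtails carry two non-homologous X
#'   chromosomes that together span nearly half of the chromosome-assigned
#'   sequence).
#' @param het_rate Autosomal heterozygous sites per bp. Default 0.002.
#' @param hom_rate Homozygous-alternate variant sites per bp (divergence from
#'   the reference; applies to autosomes and X). Default 0.001.
#' @param depth_2n Mean diploid (autosomal) coverage. Default 28.7.
#' @param fh_true True haploid (sperm) fraction in `[0, 1)`. Default 0.35.
#' @param nb_size Negative-binomial size (dispersion) parameter. Default 15.
#' @param cnv_fraction Proportion of scaffolds carrying a copy-number change
#'   in the second male. Default 0.05.
#' @param cnv_ratio Coverage ratio of CNV scaffolds in the second male.
#'   Default 1.5.
#' @param error_rate Per-read sequencing-error rate used for spurious
#'   pileup states. Default 0.002.
#' @param seed Integer seed; the whole fixture bundle is reproducible given
#'   the seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(genome_size = 2e7, n_scaffolds = 200L,
                              x_fraction = 0.4, het_rate = 0.002,
                              hom_rate = 0.001, depth_2n = 28.7,
                              fh_true = 0.35, nb_size = 15,
                              cnv_fraction = 0.05, cnv_ratio = 1.5,
                              error_rate = 0.002, seed = 1L) {
  cfg <- list(genome_size = genome_size, n_scaffolds = as.integer(n_scaffolds),
              x_fraction = x_fraction, het_rate = het_rate,
              hom_rate = hom_rate, depth_2n = depth_2n, fh_true = fh_true,
              nb_size = nb_size, cnv_fraction = cnv_fraction,
              cnv_ratio = cnv_ratio, error_rate = error_rate,
              seed = as.integer(seed))
  if (cfg$genome_size <= 0 || cfg$n_scaffolds < 1L)
    stop("genome_size and n_scaffolds must be positive")
  if (cfg$x_fraction < 0 || cfg$x_fraction >= 1)
    stop("x_fraction must be in [0, 1)")
  if (cfg$fh_true < 0 || cfg$fh_true >= 1)
    stop("fh_true must be in [0, 1)")
  if (cfg$depth_2n <= 0) stop("depth_2n must be positive")
  if (cfg$nb_size <= 0) stop("nb_size must be positive")
  if (cfg$het_rate < 0 || cfg$hom_rate < 0 || cfg$error_rate < 0 ||
      cfg$cnv_fraction < 0 || cfg$cnv_fraction > 1)
    stop("rates must be non-negative (cnv_fraction in [0, 1])")
  if (is.na(cfg$seed)) stop("seed must be an integer")
  structure(cfg, class = "simulation_config")
}

# Expected coverage quantities implied by a config.
config_truth <- function(cfg) {
  fh <- cfg$fh_true
  c_A <- cfg$depth_2n
  c_X <- c_A / (2 - fh)
  list(fh_true = fh, c_A = c_A, c_X = c_X, ratio = c_X / c_A,
       c_maternal = c_A / (2 - fh), c_paternal = c_A * (1 - fh) / (2 - fh),
       p_p = (1 - fh) / (2 - fh))
}

# Scaffold table: log-normal lengths rescaled to the genome span, X-linked
# scaffolds accumulated until x_fraction of the span is reached.
simulate_scaffolds <- function(cfg) {
  len <- stats::rlnorm(cfg$n_scaffolds, meanlog = log(cfg$genome_size /
                                                        cfg$n_scaffolds) - 0.32,
                       sdlog = 0.8)
  len <- pmax(round(len * cfg$genome_size / sum(len)), 1000L)
  ord <- sample.int(cfg$n_scaffolds)
  cls <- rep("autosome", cfg$n_scaffolds)
  if (cfg$x_fraction > 0) {
    target <- cfg$x_fraction * sum(len)
    cum <- cumsum(len[ord])
    n_x <- which(cum >= target)[1L]
    if (is.na(n_x)) n_x <- cfg$n_scaffolds
    cls[ord[seq_len(n_x)]] <- "X"
  }
  data.frame(scaffold = sprintf("scf%04d", seq_len(cfg$n_scaffolds)),
             length = len, class = cls, stringsAsFactors = FALSE)
}

#' Simulate a complete two-tissue fixture bundle
#'
#' Generates, from one seed, every input the pipeline consumes: a variant
#' table (optionally written as a VCF), a single-sample sync pileup with
#' sequencing-error bistates, per-scaffold coverage tables for the male, a
#' female (all-diploid) and a second male carrying CNV scaffolds, the true
#' scaffold assignment, and a ground-truth record.
#'
#' Per autosomal heterozygous site the maternal allele depth is drawn
#' `NB(mu = depth_2n/(2 - fh), size)` and the paternal depth
#' `NB(mu = depth_2n (1 - fh)/(2 - fh), size)`; homozygous X-linked variants
#' are drawn at the X coverage `depth_2n/(2 - fh)`. Heterozygous draws where
#' either allele received zero reads are dropped (a caller would not emit a
#' heterozygous genotype there); the count is recorded in the truth block.
#'
#' @param cfg A [simulation_config()].
#' @param outdir Optional directory; when given, writes `sim.vcf`,
#'   `sim.sync`, `cov_male.tsv`, `cov_female.tsv`, `cov_male2.tsv`,
#'   `assignment.tsv`, `histogram.histo` and `truth.json` there.
#' @return List of class `two_tissue_sim`: `scaffolds`, `variants` (with the
#'   true maternal/paternal depths alongside the observable fields), `sync`,
#'   `cov_male`, `cov_female`, `cov_male2`, `histogram`, `truth`, `paths`
#'   (when written).
#' @export
simulate_two_tissue_sample <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  tr <- config_truth(cfg)
  scf <- simulate_scaffolds(cfg)
  bases <- c("A", "T", "C", "G")

  sim_sites <- function(scaffold, length, rate) {
    n <- min(stats::rpois(1L, length * rate), length)
    if (n == 0L) return(NULL)
    data.frame(scaffold = scaffold, position = sort(sample.int(length, n)),
               stringsAsFactors = FALSE)
  }
  collect <- function(sub, rate) {
    out <- mapply(sim_sites, sub$scaffold, sub$length,
                  MoreArgs = list(rate = rate), SIMPLIFY = FALSE)
    do.call(rbind, out)
  }

  auto <- scf[scf$class == "autosome", ]
  xscf <- scf[scf$class == "X", ]

  # autosomal heterozygous sites: one maternal + one paternal allele
  het <- collect(auto, cfg$het_rate)
  variants <- NULL
  n_zero_het <- 0L
  if (!is.null(het)) {
    n <- nrow(het)
    mat <- stats::rnbinom(n, mu = tr$c_maternal, size = cfg$nb_size)
    pat <- stats::rnbinom(n, mu = tr$c_paternal, size = cfg$nb_size)
    keep <- mat > 0L & pat > 0L
    n_zero_het <- sum(!keep)
    het <- het[keep, , drop = FALSE]
    mat <- mat[keep]; pat <- pat[keep]
    n <- nrow(het)
    mat_is_ref <- stats::runif(n) < 0.5
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    variants <- data.frame(
      scaffold = het$scaffold, position = het$position,
      ref = ref, alt = alt, genotype_class = "heterozygous",
      chrom_class = "autosome",
      depth_ref = ifelse(mat_is_ref, mat, pat),
      depth_alt = ifelse(mat_is_ref, pat, mat),
      mat_depth = mat, pat_depth = pat,
      quality = round(stats::runif(n, 30, 2000), 1),
      stringsAsFactors = FALSE)
  }

  # homozygous-alternate variants: autosomes (both haplotypes alt) and X
  mk_hom <- function(sub, mu_total, chrom_class) {
    hom <- collect(sub, cfg$hom_rate)
    if (is.null(hom)) return(NULL)
    n <- nrow(hom)
    depth <- if (chrom_class == "autosome")
      stats::rnbinom(n, mu = tr$c_maternal, size = cfg$nb_size) +
        stats::rnbinom(n, mu = tr$c_paternal, size = cfg$nb_size)
    else stats::rnbinom(n, mu = mu_total, size = cfg$nb_size)
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    data.frame(scaffold = hom$scaffold, position = hom$position,
               ref = ref, alt = alt, genotype_class = "homozygous_alt",
               chrom_class = chrom_class,
               depth_ref = 0L, depth_alt = depth,
               mat_depth = NA_integer_, pat_depth = NA_integer_,
               quality = round(stats::runif(n, 30, 2000), 1),
               stringsAsFactors = FALSE)
  }
  hom_a <- mk_hom(auto, tr$c_A, "autosome")
  hom_x <- if (nrow(xscf)) mk_hom(xscf, tr$c_X, "X") else NULL
  variants <- rbind(variants, hom_a, hom_x)
  variants <- variants[variants$depth_alt > 0L | variants$depth_ref > 0L, ,
                       drop = FALSE]
  variants <- variants[!duplicated(variants[, c("scaffold", "position")]), ,
                       drop = FALSE]
  variants <- variants[order(variants$scaffold, variants$position), ]
  rownames(variants) <- NULL

  # sync pileup: heterozygous sites plus homozygous-reference background,
  # both with sequencing-error states. At the pileup level the two allele
  # counts of a site come from a single read pool, so the site's total depth
  # (the same mat+pat draw as the variant table) is split binomially at the
  # paternal ratio p_p rather than re-drawn as independent counts.
  hetv <- variants[variants$genotype_class == "heterozygous", , drop = FALSE]
  sync_het <- NULL
  if (nrow(hetv)) {
    sync_het <- data.frame(scaffold = hetv$scaffold, position = hetv$position,
                           ref = hetv$ref, stringsAsFactors = FALSE)
    total <- hetv$mat_depth + hetv$pat_depth
    pat_cnt <- stats::rbinom(nrow(hetv), total, tr$p_p)
    mat_cnt <- total - pat_cnt
    mat_ref <- hetv$depth_ref == hetv$mat_depth
    cnt <- matrix(0L, nrow(hetv), 6L,
                  dimnames = list(NULL, c("A", "T", "C", "G", "N", "del")))
    for (i in seq_len(nrow(hetv))) {
      if (mat_ref[i]) {
        cnt[i, hetv$ref[i]] <- mat_cnt[i]
        cnt[i, hetv$alt[i]] <- pat_cnt[i]
      } else {
        cnt[i, hetv$ref[i]] <- pat_cnt[i]
        cnt[i, hetv$alt[i]] <- mat_cnt[i]
      }
    }
    sync_het <- cbind(sync_het, as.data.frame(cnt))
  }
  ref_bg <- collect(scf, cfg$het_rate)  # background density matches het sites
  sync_ref <- NULL
  if (!is.null(ref_bg)) {
    n <- nrow(ref_bg)
    is_x <- ref_bg$scaffold %in% xscf$scaffold
    depth <- stats::rnbinom(n, mu = ifelse(is_x, tr$c_X, tr$c_A),
                            size = cfg$nb_size)
    ref <- sample(bases, n, replace = TRUE)
    sync_ref <- data.frame(scaffold = ref_bg$scaffold,
                           position = ref_bg$position, ref = ref,
                           stringsAsFactors = FALSE)
    cnt <- matrix(0L, n, 6L,
                  dimnames = list(NULL, c("A", "T", "C", "G", "N", "del")))
    err <- stats::rbinom(n, depth, cfg$error_rate)
    for (i in seq_len(n)) {
      cnt[i, ref[i]] <- depth[i] - err[i]
      if (err[i] > 0L)
        cnt[i, sample(setdiff(bases, ref[i]), 1L)] <- err[i]
    }
    sync_ref <- cbind(sync_ref, as.data.frame(cnt))
  }
  sync <- rbind(sync_het, sync_ref)
  sync <- sync[!duplicated(sync[, c("scaffold", "position")]), , drop = FALSE]
  sync <- sync[order(sync$scaffold, sync$position), ]
  rownames(sync) <- NULL
  for (cn in c("A", "T", "C", "G", "N", "del"))
    sync[[cn]] <- as.integer(sync[[cn]])
  class(sync) <- c("pileup_sites", "data.frame")

  # per-scaffold coverage tables: noise shrinks with scaffold length
  scaffold_cov <- function(mu) {
    nwin <- pmax(1, round(scf$length / 1000))
    sd <- sqrt((mu + mu^2 / cfg$nb_size) / nwin)
    pmax(stats::rnorm(nrow(scf), mu, sd), 0.1)
  }
  mu_male <- ifelse(scf$class == "X", tr$c_X, tr$c_A)
  cov_male <- data.frame(scaffold = scf$scaffold, length = scf$length,
                         coverage = scaffold_cov(mu_male))
  cov_female <- data.frame(scaffold = scf$scaffold, length = scf$length,
                           coverage = scaffold_cov(rep(cfg$depth_2n,
                                                       nrow(scf))))
  cnv <- stats::runif(nrow(scf)) < cfg$cnv_fraction
  cov_male2 <- data.frame(scaffold = scf$scaffold, length = scf$length,
                          coverage = scaffold_cov(mu_male *
                                                    ifelse(cnv, cfg$cnv_ratio, 1)))

  histogram <- simulate_kmer_histogram(cfg, reseed = FALSE)

  truth <- c(tr, list(
    n_het_autosomal = sum(variants$genotype_class == "heterozygous"),
    n_hom_autosomal = sum(variants$genotype_class == "homozygous_alt" &
                            variants$chrom_class == "autosome"),
    n_hom_x = sum(variants$genotype_class == "homozygous_alt" &
                    variants$chrom_class == "X"),
    n_zero_depth_het_dropped = n_zero_het,
    cnv_scaffolds = scf$scaffold[cnv],
    seed = cfg$seed))

  res <- structure(list(scaffolds = scf, variants = variants, sync = sync,
                        cov_male = cov_male, cov_female = cov_female,
                        cov_male2 = cov_male2, histogram = histogram,
                        truth = truth, config = cfg),
                   class = "two_tissue_sim")
  if (!is.null(outdir)) res$paths <- write_sim_bundle(res, outdir)
  res
}

# Write the fixture bundle as plain-text files.
write_sim_bundle <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(outdir, "sim.vcf"),
    sync = file.path(outdir, "sim.sync"),
    cov_male = file.path(outdir, "cov_male.tsv"),
    cov_female = file.path(outdir, "cov_female.tsv"),
    cov_male2 = file.path(outdir, "cov_male2.tsv"),
    assignment = file.path(outdir, "assignment.tsv"),
    histogram = file.path(outdir, "histogram.histo"),
    truth = file.path(outdir, "truth.json"))
  write_sim_vcf(sim$variants, paths$vcf)
  write_sync(sim$sync, paths$sync)
  write_coverage_table(sim$cov_male, paths$cov_male)
  write_coverage_table(sim$cov_female, paths$cov_female)
  write_coverage_table(sim$cov_male2, paths$cov_male2)
  write_assignment(data.frame(scaffold = sim$scaffolds$scaffold,
                              class = sim$scaffolds$class),
                   paths$assignment)
  write_kmer_histogram(sim$histogram, paths$histogram)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE, digits = NA)
  paths
}

# Minimal single-sample VCF with freebayes-style RO/AO depth fields.
write_sim_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tissuemix-simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=RO,Number=1,Type=Integer,Description=\"Reference allele observation count\">",
    "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observation count\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsim")
  gt <- ifelse(variants$genotype_class == "heterozygous", "0/1", "1/1")
  dp <- variants$depth_ref + variants$depth_alt
  body <- paste(variants$scaffold, variants$position, ".", variants$ref,
                variants$alt, variants$quality, ".", ".", "GT:DP:RO:AO",
                paste(gt, dp, variants$depth_ref, variants$depth_alt,
                      sep = ":"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a k-mer multiplicity histogram with known peak ratio
#'
#' Builds the expected spectrum of a two-tissue male library as an error
#' component (exponential decay over multiplicities 1-3), a 1n component
#' centred at `depth_2n/(2 - fh_true)` whose weight combines the X span and
#' the heterozygous k-mers (2k per site, k = 21), and a 2n component centred
#' at `depth_2n`; counts are then multinomially sampled at genome scale
#' (or returned as the rounded expectation when `sampled = FALSE`).
#'
#' @param cfg A [simulation_config()].
#' @param sampled Draw multinomial counts (`TRUE`, default) or return the
#'   noiseless expected histogram.
#' @param reseed Set the RNG to `cfg$seed` first (default `TRUE`; the
#'   bundle generator passes `FALSE` to keep one stream).
#' @return A [kmer_histogram()].
#' @export
simulate_kmer_histogram <- function(cfg, sampled = TRUE, reseed = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (reseed) set.seed(cfg$seed)
  tr <- config_truth(cfg)
  k <- 21
  w_het <- min(2 * k * cfg$het_rate, 1)
  w_1n <- cfg$x_fraction + w_het * (1 - cfg$x_fraction)
  w_2n <- (1 - w_het) * (1 - cfg$x_fraction)
  w_err <- 0.1
  m <- seq_len(ceiling(3.5 * cfg$depth_2n))
  expected <- w_1n * stats::dnbinom(m, mu = tr$c_X, size = cfg$nb_size) +
    w_2n * stats::dnbinom(m, mu = tr$c_A, size = cfg$nb_size)
  err <- numeric(length(m))
  err[1:3] <- exp(-2 * (0:2))
  expected <- expected + w_err * err / sum(err)
  n_total <- round(cfg$genome_size * (w_1n + w_2n + w_err))
  if (sampled) {
    counts <- as.vector(stats::rmultinom(1L, size = n_total,
                                         prob = expected))
  } else {
    counts <- round(cfg$genome_size * expected)
  }
  kmer_histogram(m, counts)
}

#' Default power-analysis grid
#'
#' A factorial grid of simulation conditions: 3 X-chromosome spans, 2
#' heterozygosity levels, 3 diploid coverages, 4 sperm fractions and 2
#' replicates (144 cells).
#'
#' @param x_fraction,het_rate,depth_2n,fh_true,replicates Factor levels.
#' @return Data frame with one row per grid cell.
#' @export
default_power_grid <- function(x_fraction = c(0.05, 0.1, 0.2),
                               het_rate = c(0.001, 0.005),
                               depth_2n = c(15, 25, 40),
                               fh_true = c(0.1, 0.2, 0.35, 0.45),
                               replicates = 2L) {
  expand.grid(x_fraction = x_fraction, het_rate = het_rate,
              depth_2n = depth_2n, fh_true = fh_true,
              rep = seq_len(replicates), KEEP.OUT.ATTRS = FALSE)
}

#' Run the coverage-peak power analysis over a grid of conditions
#'
#' For each grid cell, simulates a k-mer histogram, fits the two-peak model
#' and records whether the fit converged and whether the 0.95 confidence
#' interval of the peak ratio excludes 0.5 (a detected deviation from the
#' naive 1:2 spacing). Per-cell failures are recorded, not fatal.
#'
#' @param grid Data frame with columns `x_fraction`, `het_rate`, `depth_2n`,
#'   `fh_true` (see [default_power_grid()]); extra columns are carried
#'   through.
#' @param seed Base seed; cell `i` uses `seed + i`.
#' @param genome_size Genome span passed to each cell's config. Default 2e7.
#' @return The grid with columns `converged`, `deviation_detected`,
#'   `ratio_hat`, `fh_hat` and `error` appended.
#' @export
run_power_grid <- function(grid, seed = 1L, genome_size = 2e7) {
  stopifnot(nrow(grid) > 0L,
            all(c("x_fraction", "het_rate", "depth_2n", "fh_true")
                %in% names(grid)))
  out <- grid
  out$converged <- FALSE
  out$deviation_detected <- NA
  out$ratio_hat <- NA_real_
  out$fh_hat <- NA_real_
  out$error <- NA_character_
  for (i in seq_len(nrow(grid))) {
    cfg <- simulation_config(genome_size = genome_size,
                             x_fraction = grid$x_fraction[i],
                             het_rate = grid$het_rate[i],
                             depth_2n = grid$depth_2n[i],
                             fh_true = grid$fh_true[i],
                             seed = seed + i)
    res <- tryCatch({
      h <- simulate_kmer_histogram(cfg)
      fit <- fit_two_peak_model(h)
      list(fit = fit, err = NA_character_)
    }, error = function(e) list(fit = NULL, err = conditionMessage(e)))
    if (is.null(res$fit)) {
      out$error[i] <- res$err
      next
    }
    fit <- res$fit
    out$converged[i] <- fit$converged
    out$ratio_hat[i] <- unname(fit$coefficients[["ratio_r"]])
    if (fit$converged && is.finite(fit$ratio_se)) {
      out$deviation_detected[i] <- fit$ratio_ci[1L] > 0.5 ||
        fit$ratio_ci[2L] < 0.5
      r <- out$ratio_hat[i]
      if (r > 0 && r < 1)
        out$fh_hat[i] <- suppressWarnings(sperm_fraction_from_ratio(r))
    }
  }
  out
}
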