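# Readers and writers for the external representations the pipeline touches:
# k-mer multiplicity histograms, VCF allele depths, popoolation2-style sync
# pileups, per-scaffold coverage tables and scaffold assignment tables.
# Coordinates are 1-based inclusive throughout (VCF/sync convention).

#' Construct a k-mer multiplicity histogram
#'
#' A k-mer histogram maps k-mer multiplicity (coverage) to the number of
#' distinct k-mers observed at that multiplicity, as emitted by k-mer counters
#' such as KMC or jellyfish. The same container also holds per-base mapping
#' coverage histograms; the fitting functions do not care about the source.
#'
#' @param multiplicity Strictly increasing vector of positive integers.
#' @param count Non-negative integer counts, same length, not all zero.
#' @return A `kmer_histogram`: a data frame with columns `multiplicity` and
#'   `count`.
#' @export
kmer_histogram <- function(multiplicity, count) {
  multiplicity <- as.numeric(multiplicity)
  count <- as.numeric(count)
  if (length(multiplicity) != length(count))
    stop("multiplicity and count must have the same length")
  if (length(multiplicity) < 2L)
    stop("a k-mer histogram needs at least 2 entries")
  if (anyNA(multiplicity) || anyNA(count))
    stop("NA values are not allowed in a k-mer histogram")
  if (any(multiplicity < 1) || any(multiplicity != round(multiplicity)))
    stop("multiplicities must be positive integers")
  if (any(diff(multiplicity) <= 0))
    stop("multiplicities must be strictly increasing")
  if (any(count < 0) || any(count != round(count)))
    stop("counts must be non-negative integers")
  if (all(count == 0))
    stop("counts must not be all zero")
  structure(data.frame(multiplicity = multiplicity, count = count),
            class = c("kmer_histogram", "data.frame"))
}

#' Read a two-column k-mer histogram file
#'
#' Parses the whitespace-separated `multiplicity count` format written by
#' common k-mer counters.
#'
#' @param path Path to the histogram file.
#' @return A [kmer_histogram()].
#' @export
read_kmer_histogram <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty histogram file: ", path)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stop("malformed histogram line ", bad[1L], " in ", path,
         ": expected 2 whitespace-separated fields")
  m <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  k <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(m) | is.na(k))
  if (length(bad))
    stop("malformed histogram line ", bad[1L], " in ", path,
         ": non-numeric field")
  kmer_histogram(m, k)
}

#' Write a k-mer histogram file
#'
#' @param hist A [kmer_histogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "kmer_histogram"))
  writeLines(paste(format(hist$multiplicity, scientific = FALSE, trim = TRUE),
                   format(hist$count, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Read a scaffold chromosome-assignment table
#'
#' Two-column TSV: scaffold identifier and class (`autosome`, `X` or
#' `unassigned`). A header line is detected and skipped.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `scaffold`, `class`.
#' @export
read_assignment <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("scaffold", "class"),
                          colClasses = "character")
  if (nrow(df) && tolower(df$class[1L]) == "class") df <- df[-1L, , drop = FALSE]
  ok <- df$class %in% c("autosome", "X", "unassigned")
  if (!all(ok))
    stop("unknown assignment class: ", paste(unique(df$class[!ok]), collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Write a scaffold chromosome-assignment table
#'
#' @param assignment Data frame with columns `scaffold` and `class` (e.g. from
#'   [classify_scaffolds()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  stopifnot(all(c("scaffold", "class") %in% names(assignment)))
  utils::write.table(assignment[, c("scaffold", "class")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-allele depths of biallelic SNPs from a VCF
#'
#' Retains biallelic SNP records with `QUAL > 20` and a called diploid
#' genotype that is either heterozygous (ref/alt) or homozygous-alternate.
#' Per-allele depths are taken from the caller's dedicated
#' reference/alternate observation-count fields (`RO`/`AO`, as written by
#' freebayes), falling back to the combined allele-depth field `AD`.
#' Indels, multiallelic records, missing and half genotype calls, and records
#' without usable depth fields are dropped; the number of dropped records is
#' reported in the `dropped` attribute and via a message.
#'
#' @param vcf_path Path to a plain or bgzipped VCF.
#' @param assignment Optional scaffold assignment: a data frame with columns
#'   `scaffold`, `class` or a path readable by [read_assignment()]. Scaffolds
#'   absent from the table get `chrom_class = "unknown"`.
#' @param sample Column of the genotype matrix to read (index or name);
#'   default the first sample.
#' @param min_qual Quality threshold; records are kept if `QUAL > min_qual`
#'   (strictly greater). Default 20.
#' @return Data frame of class `allele_depths` with columns `scaffold`,
#'   `position`, `genotype_class` (`"heterozygous"`/`"homozygous_alt"`),
#'   `depth_ref`, `depth_alt`, `quality`, `chrom_class`
#'   (`"autosome"`/`"X"`/`"unknown"`).
#' @export
read_allele_depths <- function(vcf_path, assignment = NULL, sample = 1L,
                               min_qual = 20) {
  if (!file.exists(vcf_path)) stop("file does not exist: ", vcf_path)
  vcf <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                  error = function(e) stop("unreadable VCF: ", conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    res <- empty_allele_depths()
    return(res)
  }
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  bases <- c("A", "C", "G", "T")
  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% bases & fix$ALT %in% bases & !grepl(",", fix$ALT)
  n_nonsnp <- sum(!snp)
  pass_q <- !is.na(qual) & qual > min_qual
  keep <- snp & pass_q

  gt_all <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt_all[, sample]
  het <- gt %in% c("0/1", "1/0", "0|1", "1|0")
  hom <- gt %in% c("1/1", "1|1")
  n_nocall <- sum(keep & !(het | hom), na.rm = TRUE)
  keep <- keep & (het | hom) & !is.na(gt)

  fmt <- strsplit(vcf@gt[1L, "FORMAT"], ":", fixed = TRUE)[[1L]]
  if (all(c("RO", "AO") %in% fmt)) {
    dr <- suppressWarnings(as.numeric(vcfR::extract.gt(vcf, "RO")[, sample]))
    da <- suppressWarnings(as.numeric(vcfR::extract.gt(vcf, "AO")[, sample]))
  } else if ("AD" %in% fmt) {
    ad <- vcfR::extract.gt(vcf, "AD")[, sample]
    sp <- strsplit(ad, ",", fixed = TRUE)
    dr <- suppressWarnings(as.numeric(vapply(sp, function(x) x[1L] %||% NA_character_, "")))
    da <- suppressWarnings(as.numeric(vapply(sp, function(x) if (length(x) >= 2L) x[2L] else NA_character_, "")))
  } else {
    stop("VCF has neither RO/AO nor AD depth fields")
  }
  n_nodepth <- sum(keep & (is.na(dr) | is.na(da)), na.rm = TRUE)
  keep <- keep & !is.na(dr) & !is.na(da)
  # heterozygous calls must be supported by both alleles
  badhet <- keep & het & (dr <= 0 | da <= 0)
  n_badhet <- sum(badhet)
  keep <- keep & !badhet

  res <- data.frame(
    scaffold = fix$CHROM[keep],
    position = as.integer(fix$POS[keep]),
    genotype_class = ifelse(het[keep], "heterozygous", "homozygous_alt"),
    depth_ref = as.integer(dr[keep]),
    depth_alt = as.integer(da[keep]),
    quality = qual[keep],
    stringsAsFactors = FALSE
  )
  res$chrom_class <- "unknown"
  if (!is.null(assignment)) {
    if (is.character(assignment) && length(assignment) == 1L)
      assignment <- read_assignment(assignment)
    idx <- match(res$scaffold, assignment$scaffold)
    cls <- assignment$class[idx]
    res$chrom_class[!is.na(cls) & cls == "autosome"] <- "autosome"
    res$chrom_class[!is.na(cls) & cls == "X"] <- "X"
  }
  dropped <- c(non_snp = n_nonsnp, low_qual = sum(snp & !pass_q),
               no_genotype = n_nocall, no_depth = n_nodepth,
               unsupported_het = n_badhet)
  if (sum(dropped) > 0)
    message("read_allele_depths: dropped ", sum(dropped), " records (",
            paste(names(dropped), dropped, sep = "=", collapse = ", "), ")")
  attr(res, "dropped") <- dropped
  class(res) <- c("allele_depths", "data.frame")
  res
}

empty_allele_depths <- function() {
  res <- data.frame(scaffold = character(), position = integer(),
                    genotype_class = character(), depth_ref = integer(),
                    depth_alt = integer(), quality = numeric(),
                    chrom_class = character(), stringsAsFactors = FALSE)
  class(res) <- c("allele_depths", "data.frame")
  res
}

#' Read one sample column of a sync pileup file
#'
#' The sync format (popoolation2 `mpileup2sync`) is tab-separated with columns
#' scaffold, position, reference base, then one colon-delimited
#' `A:T:C:G:N:del` count field per sample.
#'
#' @param path Path to the sync file.
#' @param sample Which sample column to read (1-based among the count
#'   columns). Default 1.
#' @return Data frame of class `pileup_sites` with columns `scaffold`,
#'   `position`, `ref` and integer count columns `A`, `T`, `C`, `G`, `N`,
#'   `del`.
#' @export
read_sync <- function(path, sample = 1L) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 3L + sample)
    stop("sync file has no sample column ", sample,
         " (found ", ncol(df) - 3L, " sample column(s))")
  counts <- strsplit(df[[3L + sample]], ":", fixed = TRUE)
  bad <- which(vapply(counts, length, 1L) != 6L)
  if (length(bad))
    stop("malformed sync count field at line ", bad[1L],
         ": expected 6 colon-delimited parts")
  mat <- suppressWarnings(matrix(as.numeric(unlist(counts)), ncol = 6L,
                                 byrow = TRUE))
  if (anyNA(mat))
    stop("malformed sync count field at line ",
         which(rowSums(is.na(mat)) > 0)[1L], ": non-numeric count")
  if (any(mat < 0)) stop("negative counts in sync file")
  res <- data.frame(scaffold = df[[1L]],
                    position = as.integer(df[[2L]]),
                    ref = df[[3L]],
                    A = as.integer(mat[, 1L]), T = as.integer(mat[, 2L]),
                    C = as.integer(mat[, 3L]), G = as.integer(mat[, 4L]),
                    N = as.integer(mat[, 5L]), del = as.integer(mat[, 6L]),
                    stringsAsFactors = FALSE)
  class(res) <- c("pileup_sites", "data.frame")
  res
}

#' Write a single-sample sync pileup file
#'
#' @param sites A `pileup_sites` data frame as returned by [read_sync()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sites, path) {
  stopifnot(all(c("scaffold", "position", "ref", "A", "T", "C", "G", "N", "del")
                %in% names(sites)))
  field <- paste(sites$A, sites$T, sites$C, sites$G, sites$N, sites$del,
                 sep = ":")
  writeLines(paste(sites$scaffold, sites$position, sites$ref, field,
                   sep = "\t"), path)
  invisible(path)
}

#' Read a per-scaffold coverage table
#'
#' Three-column TSV: scaffold identifier, scaffold length (bp) and
#' median/mean sequencing depth. A header line is detected and skipped.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `scaffold`, `length`, `coverage`.
#' @export
read_coverage_table <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", strsplit(first, "\t")[[1L]][2L])
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          col.names = c("scaffold", "length", "coverage"),
                          colClasses = c("character", "numeric", "numeric"))
  if (any(df$coverage < 0)) stop("negative coverage values in ", path)
  df
}

#' Write a per-scaffold coverage table
#'
#' @param cov Data frame with columns `scaffold`, `length`, `coverage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(cov, path) {
  stopifnot(all(c("scaffold", "length", "coverage") %in% names(cov)))
  utils::write.table(cov[, c("scaffold", "length", "coverage")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
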