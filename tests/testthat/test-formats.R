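test_that("k-mer histograms parse, validate and round-trip", {
  f <- withr::local_tempfile()
  writeLines(c("1 100", "2 50"), f)
  h <- read_kmer_histogram(f)
  expect_s3_class(h, "kmer_histogram")
  expect_equal(h$multiplicity, c(1, 2))
  expect_equal(h$count, c(100, 50))

  writeLines(c("2 50", "1 100"), f)
  expect_error(read_kmer_histogram(f), "strictly increasing")

  writeLines(c("1 100", "2"), f)
  expect_error(read_kmer_histogram(f), "line 2")

  writeLines(character(), f)
  expect_error(read_kmer_histogram(f), "empty")

  expect_error(kmer_histogram(1:3, c(0, 0, 0)), "all zero")
  expect_error(kmer_histogram(1, 5), "at least 2")

  # writer -> reader identity on simulated data
  h0 <- simulate_kmer_histogram(simulation_config(seed = 11))
  write_kmer_histogram(h0, f)
  expect_identical(as.data.frame(read_kmer_histogram(f)), as.data.frame(h0))
})

test_that("VCF reader applies the quality, biallelic-SNP and genotype filters", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(f)
  ad <- suppressMessages(read_allele_depths(f, toy_assignment))
  # of 8 records: QUAL 15 and QUAL 20 dropped (strict > 20), multiallelic,
  # indel and uncalled dropped -> 3 remain
  expect_equal(nrow(ad), 3L)
  expect_equal(sort(ad$position), c(100, 150, 300))
  expect_equal(ad$genotype_class[ad$position == 300], "homozygous_alt")
  expect_equal(ad$depth_ref[ad$position == 100], 12L)
  expect_equal(ad$depth_alt[ad$position == 100], 9L)
  expect_equal(ad$chrom_class[ad$scaffold == "scf2"], "X")
  expect_equal(sum(attr(ad, "dropped")), 5L)
  expect_equal(unname(attr(ad, "dropped")["low_qual"]), 2L)
})

test_that("VCF reader falls back to the combined AD depth field", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(f, format = "AD")
  ad <- suppressMessages(read_allele_depths(f))
  expect_equal(nrow(ad), 3L)
  expect_equal(ad$depth_ref[ad$position == 150], 14L)
  expect_equal(ad$depth_alt[ad$position == 150], 13L)
  expect_true(all(ad$chrom_class == "unknown"))  # no assignment given
})

test_that("simulator-written VCF depths are recovered exactly", {
  sim <- simulate_two_tissue_sample(
    simulation_config(genome_size = 1e6, seed = 31), outdir = withr::local_tempdir())
  ad <- suppressMessages(read_allele_depths(sim$paths$vcf, sim$paths$assignment))
  expect_equal(nrow(ad), nrow(sim$variants))
  m <- merge(sim$variants, ad, by = c("scaffold", "position"))
  expect_true(all(m$depth_ref.x == m$depth_ref.y))
  expect_true(all(m$depth_alt.x == m$depth_alt.y))
  expect_true(all(m$chrom_class.x == m$chrom_class.y))
  expect_true(all(m$genotype_class.x == m$genotype_class.y))
})

test_that("sync files parse, reject malformed fields and round-trip", {
  f <- withr::local_tempfile(fileext = ".sync")
  writeLines("scf1\t10\tA\t20:11:0:0:0:0", f)
  s <- read_sync(f)
  expect_equal(unlist(s[1, c("A", "T", "C", "G", "N", "del")], use.names = FALSE),
               c(20L, 11L, 0L, 0L, 0L, 0L))
  expect_equal(s$position, 10L)

  writeLines("scf1\t10\tA", f)
  expect_error(read_sync(f), "no sample column")

  writeLines("scf1\t10\tA\t20:11:0:0:0", f)
  expect_error(read_sync(f), "6 colon-delimited")

  sim <- x0_sim()
  write_sync(sim$sync, f)
  expect_identical(as.data.frame(read_sync(f)), as.data.frame(sim$sync))
})

test_that("record filters are order-independent", {
  f <- withr::local_tempfile(fileext = ".sync")
  sim <- x0_sim()
  sync <- sim$sync[1:200, ]
  set.seed(5)
  perm <- sample.int(nrow(sync))
  write_sync(sync[perm, ], f)
  reread <- read_sync(f)
  orig <- as.data.frame(sync[perm, ])
  rownames(orig) <- NULL
  expect_identical(as.data.frame(reread), orig)
})

test_that("coverage and assignment tables round-trip", {
  sim <- x0_sim()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_coverage_table(sim$cov_male, f)
  expect_equal(read_coverage_table(f)$coverage, sim$cov_male$coverage)
  write_assignment(data.frame(scaffold = sim$scaffolds$scaffold,
                              class = sim$scaffolds$class), f)
  asg <- read_assignment(f)
  expect_equal(asg$class, sim$scaffolds$class)
  writeLines("s1\tweird", f)
  expect_error(read_assignment(f), "unknown assignment class")
})
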