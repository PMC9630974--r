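# Small hand-built fixtures used across test files. Everything is generated
# in code at test time; nothing binary is stored.

# A toy VCF exercising the record filters: SNPs above/below the quality
# threshold, a multiallelic record, an indel, a missing genotype and a
# homozygous-alternate call.
write_toy_vcf <- function(path, format = c("RO_AO", "AD")) {
  format <- match.arg(format)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=RO,Number=1,Type=Integer,Description=\"Ref obs count\">",
    "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alt obs count\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample1")
  recs <- if (format == "RO_AO") c(
    "scf1\t100\t.\tA\tG\t50\t.\t.\tGT:RO:AO\t0/1:12:9",
    "scf1\t200\t.\tC\tT\t15\t.\t.\tGT:RO:AO\t0/1:10:11",   # low qual
    "scf1\t300\t.\tG\tA\t90\t.\t.\tGT:RO:AO\t1/1:0:25",
    "scf1\t400\t.\tT\tC\t20\t.\t.\tGT:RO:AO\t0/1:8:9",     # qual == 20: dropped
    "scf2\t150\t.\tA\tC\t80\t.\t.\tGT:RO:AO\t0/1:14:13",
    "scf2\t250\t.\tA\tC,G\t99\t.\t.\tGT:RO:AO\t1/2:5:6",   # multiallelic
    "scf2\t350\t.\tAT\tA\t99\t.\t.\tGT:RO:AO\t0/1:7:8",    # indel
    "scf2\t450\t.\tG\tT\t99\t.\t.\tGT:RO:AO\t./.:3:4"      # no call
  ) else c(
    "scf1\t100\t.\tA\tG\t50\t.\t.\tGT:AD\t0/1:12,9",
    "scf1\t300\t.\tG\tA\t90\t.\t.\tGT:AD\t1/1:0,25",
    "scf2\t150\t.\tA\tC\t80\t.\t.\tGT:AD\t0/1:14,13")
  writeLines(c(header, recs), path)
  path
}

toy_assignment <- data.frame(scaffold = c("scf1", "scf2"),
                             class = c("autosome", "X"),
                             stringsAsFactors = FALSE)

# Coverage table of n scaffolds at a fixed coverage with optional noise.
toy_cov <- function(n = 100, coverage = 30, length = 50000, sd = 0,
                    prefix = "s") {
  set.seed(99)
  data.frame(scaffold = paste0(prefix, seq_len(n)), length = length,
             coverage = coverage + if (sd > 0) rnorm(n, 0, sd) else 0,
             stringsAsFactors = FALSE)
}

# Standard simulated fixtures shared by several test files (cached per run).
pge_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_two_tissue_sample(
      simulation_config(fh_true = 0.35, depth_2n = 28.7, seed = 101))
    val
  }
})

x0_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_two_tissue_sample(
      simulation_config(fh_true = 0, depth_2n = 28.7, seed = 202))
    val
  }
})

het_variants <- function(sim)
  sim$variants[sim$variants$genotype_class == "heterozygous", , drop = FALSE]

xhom_depths <- function(sim) {
  v <- sim$variants
  v$depth_alt[v$genotype_class == "homozygous_alt" & v$chrom_class == "X"]
}
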