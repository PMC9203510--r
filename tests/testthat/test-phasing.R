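test_that("phased VCF round-trips and GT|PS semantics are honoured", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t150\t.\tA\tG\t.\tPASS\t.\tGT:PS\t0|1:100",
    "chr1\t250\t.\tC\tT\t.\tPASS\t.\tGT:PS\t1|0:100",
    "chr1\t900\t.\tG\tA\t.\tPASS\t.\tGT:PS\t0|1:800",
    "chr1\t950\t.\tT\tC\t.\tPASS\t.\tGT:PS\t1|0:800",
    "chr2\t100\t.\tA\tC\t.\tPASS\t.\tGT:PS\t0|1:100",
    "chr2\t200\t.\tA\tC\t.\tPASS\t.\tGT\t0/1",     # unphased: dropped
    "chr2\t300\t.\tA\tC\t.\tPASS\t.\tGT:PS\t1|1:100"), vcf) # hom: dropped
  s <- read_phased_vcf(vcf)
  expect_equal(nrow(s), 5L)
  # 0|1 -> haplotype 1 carries REF; 1|0 -> haplotype 1 carries ALT
  expect_equal(s[s$pos == 150, ]$hp1_allele, "A")
  expect_equal(s[s$pos == 150, ]$hp2_allele, "G")
  expect_equal(s[s$pos == 250, ]$hp1_allele, "T")
  # blocks keyed by (chrom, PS): sizes sum to record count
  expect_equal(length(unique(s$block_id[s$chrom == "chr1"])), 2L)
  expect_setequal(as.integer(table(s$block_id)), c(2L, 2L, 1L))

  out <- tempfile(fileext = ".vcf")
  write_phased_vcf(s, out)
  s2 <- read_phased_vcf(out)
  expect_equal(s2$hp1_allele, s$hp1_allele)
  expect_equal(s2$pos, s$pos)

  # unphased-only file: empty with warning
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chr1\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"), vcf)
  expect_warning(e <- read_phased_vcf(vcf), "no phased")
  expect_equal(nrow(e), 0L)

  # malformed record: error naming the line
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chr1\t10\t.\tA\tG"), vcf)
  expect_error(read_phased_vcf(vcf), "line 1")
})

test_that("the built-in VCF parser agrees with vcfR on a simulated file", {
  cfg <- sim_config(genome_length = 1e5, n_chroms = 2, seed = 17)
  g <- simulate_diploid_genome(cfg)
  vcf <- tempfile(fileext = ".vcf")
  write_phased_vcf(g$snps, vcf)
  mine <- read_phased_vcf(vcf)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  gt <- vcfR::extract.gt(v, "GT")[, 1]
  expect_equal(nrow(mine), length(gt))
  expect_equal(mine$pos, as.integer(vcfR::getPOS(v)))
  # haplotype-1 allele from the left of the | separator, via vcfR
  a1 <- as.integer(sub("\\|.*", "", gt))
  vcfr_hp1 <- ifelse(a1 == 1L, vcfR::getALT(v), vcfR::getREF(v))
  expect_equal(mine$hp1_allele, unname(vcfr_hp1))
})

test_that("block statistics match their definitions and a naive oracle", {
  lens <- c(1, 1, 1, 1, 1, 1, 1, 1, 2, 10) * 1000
  blocks <- data.frame(chrom = "chr1", block_id = paste0("b", 1:10),
                       start = 1, end = lens, n_snps = 2L,
                       length_bp = lens)
  st <- block_stats(blocks)
  expect_equal(st$n50_length, 10000)

  one <- blocks[10, ]
  st1 <- block_stats(one)
  expect_equal(st1$n50_length, 10000)
  expect_equal(st1$median_length, 10000)
  expect_equal(st1$max_length, 10000)

  # N50/median/max vs naive reference on random block sets
  set.seed(42)
  for (k in 1:1000) {
    lens <- sample.int(1e5, sample(1:30, 1), replace = TRUE)
    st <- block_stats(data.frame(chrom = "chr1",
                                 block_id = seq_along(lens), start = 1,
                                 end = lens, n_snps = 2L,
                                 length_bp = lens))
    expect_identical(st$n50_length, oracle_n50(lens))
    expect_identical(st$max_length, max(lens))
    expect_identical(st$median_length, median(lens))
  }

  # all het SNPs phased: fraction 1, every window high-coverage
  het <- data.frame(chrom = "chr1", pos = seq(1, 3e6, by = 1500),
                    phased = TRUE)
  stw <- block_stats(blocks, het_snps = het)
  expect_equal(stw$phased_fraction, 1.0)
  expect_equal(stw$genome_coverage, 1.0)
  expect_true(all(stw$windows$class == "high"))

  # empty block set: zeros
  st0 <- block_stats(blocks[0, ])
  expect_equal(st0$n_blocks, 0L)
  expect_equal(st0$n50_length, 0)
})

test_that("singleton blocks are excluded from the block table", {
  snps <- data.frame(chrom = "chr1", pos = c(100, 200, 5000),
                     ref = "A", alt = "G", hp1_allele = "A",
                     hp2_allele = "G",
                     block_id = c("b1", "b1", "b2"))
  b <- phased_blocks(snps)
  expect_equal(nrow(b), 1L)
  expect_equal(attr(b, "n_singletons"), 1L)
})

test_that("switch/flip comparison: identity, orientation and examples", {
  p <- make_phasing_pair(rep(FALSE, 5))
  r <- compare_phasings(p$a, p$b)
  expect_equal(r$total$n_switch + r$total$n_flip, 0L)
  expect_equal(r$total$discrepancy_rate, 0)

  # swapping every SNP's haplotype is pure orientation: 0 errors
  r2 <- compare_phasings(p$a, swap_haplotypes(p$a))
  expect_equal(r2$total$n_switch + r2$total$n_flip, 0L)

  # SNP 3 alone flipped: 1 flip; SNPs 4-5 flipped: 1 switch
  p3 <- make_phasing_pair(c(FALSE, FALSE, TRUE, FALSE, FALSE))
  r3 <- compare_phasings(p3$a, p3$b)
  expect_equal(r3$total$n_flip, 1L)
  expect_equal(r3$total$n_switch, 0L)
  p45 <- make_phasing_pair(c(FALSE, FALSE, FALSE, TRUE, TRUE))
  r45 <- compare_phasings(p45$a, p45$b)
  expect_equal(r45$total$n_switch, 1L)
  expect_equal(r45$total$n_flip, 0L)
  expect_equal(r45$total$discrepancy_rate, 1 / 5)

  # no shared phased SNPs: zero counts, NaN rate
  q <- p$a; q$pos <- q$pos + 7L
  r0 <- compare_phasings(p$a, q)
  expect_equal(r0$total$n_compared_snps, 0L)
  expect_true(is.nan(r0$total$discrepancy_rate))
})

test_that("switch/flip decomposition equals the exhaustive oracle and is symmetric", {
  set.seed(7)
  for (n in 2:6) {
    for (mask in 0:(2^n - 1)) {
      d <- as.logical(bitwAnd(mask, 2^(0:(n - 1))) > 0)
      p <- make_phasing_pair(d)
      r <- compare_phasings(p$a, p$b)
      o <- oracle_switch_flip(d)
      expect_equal(c(r$total$n_switch, r$total$n_flip), unname(o),
                   info = paste("pattern", mask, "n", n))
      rswap <- compare_phasings(p$b, p$a)
      expect_equal(rswap$total$n_switch, r$total$n_switch)
      expect_equal(rswap$total$n_flip, r$total$n_flip)
    }
  }
})

test_that("comparison respects block segmentation and chromosomes", {
  # same positions, but b splits the block in two: the orientation of
  # each b-block is independent, so a whole-segment swap costs nothing
  p <- make_phasing_pair(c(FALSE, FALSE, FALSE, TRUE, TRUE))
  b <- p$b
  b$block_id <- c("x", "x", "x", "y", "y")
  r <- compare_phasings(p$a, b)
  expect_equal(r$total$n_switch + r$total$n_flip, 0L)
})

test_that("panel concordance counts consecutive-pair phase relations", {
  set.seed(1)
  n <- 11
  q <- data.frame(chrom = "chr1", pos = seq_len(n) * 50L, ref = "A",
                  alt = "G",
                  hp1_allele = sample(c("A", "G"), n, replace = TRUE),
                  block_id = "b1", stringsAsFactors = FALSE)
  q$hp2_allele <- ifelse(q$hp1_allele == "A", "G", "A")
  # identical panel: concordance 1 over 10 pairs
  r <- panel_concordance(q, q)
  expect_equal(r$n_pairs, 10L)
  expect_equal(r$concordance, 1.0)
  # invert the relation of exactly one pair by flipping one terminal SNP
  p2 <- q
  p2[n, c("hp1_allele", "hp2_allele")] <- p2[n, c("hp2_allele", "hp1_allele")]
  r2 <- panel_concordance(q, p2)
  expect_equal(r2$concordance, 0.9)
  expect_equal(nrow(r2$mismatches), 1L)
  # panel orientation is irrelevant
  r3 <- panel_concordance(q, swap_haplotypes(q))
  expect_equal(r3$concordance, 1.0)
  # random panel relations converge to 0.5 (binomial corridor)
  set.seed(2)
  n <- 2001
  q <- data.frame(chrom = "chr1", pos = seq_len(n) * 50L, ref = "A",
                  alt = "G",
                  hp1_allele = sample(c("A", "G"), n, replace = TRUE),
                  block_id = "b1", stringsAsFactors = FALSE)
  q$hp2_allele <- ifelse(q$hp1_allele == "A", "G", "A")
  p4 <- q
  p4$hp1_allele <- sample(c("A", "G"), n, replace = TRUE)
  p4$hp2_allele <- ifelse(p4$hp1_allele == "A", "G", "A")
  r4 <- panel_concordance(q, p4)
  expect_lt(abs(r4$concordance - 0.5), 3 * sqrt(0.25 / r4$n_pairs))
  # zero comparable pairs flagged undefined
  r0 <- panel_concordance(q[1, ], q[1, ])
  expect_true(r0$undefined)
})
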