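mk_counts <- function(t1, t2, n1, n2, gene = "g1") rbind(
  data.frame(gene_id = gene, tissue = "tumor", chrom = "chr1", pos = 100L,
             hp1_reads = t1, hp2_reads = t2),
  data.frame(gene_id = gene, tissue = "normal", chrom = "chr1", pos = 100L,
             hp1_reads = n1, hp2_reads = n2))

test_that("RNA read tagging uses the genomic rule", {
  snps <- data.frame(chrom = "chr1", pos = c(100, 200, 300), ref = "A",
                     alt = "G", hp1_allele = c("A", "A", "A"),
                     hp2_allele = c("G", "G", "G"), block_id = "b1")
  obs3 <- data.frame(read_id = "r1", chrom = "chr1", pos = c(100, 200, 300),
                     allele = c("G", "G", "G"))
  expect_equal(tag_rna_reads(obs3, snps)$label, "HP2")
  obs1 <- data.frame(read_id = "r1", chrom = "chr1", pos = 100,
                     allele = "A")
  expect_equal(tag_rna_reads(obs1, snps)$label, "untagged")
  obs10 <- data.frame(read_id = rep("r1", 10), chrom = "chr1",
                      pos = rep(c(100, 200), 5),
                      allele = c(rep("A", 7), rep("G", 3)))
  expect_equal(tag_rna_reads(obs10, snps)$label, "HP1")  # 7:3 boundary
})

test_that("allele-specific expression verdicts match the examples", {
  # extreme tumour bias with balanced normal: tumour-specific
  r <- allelic_expression_test(mk_counts(40, 2, 21, 19))
  expect_equal(r$snps$tumor_biased_hap, "HP1")
  expect_true(is.na(r$snps$normal_biased_hap))
  expect_true(r$snps$tumor_specific)
  # 12:10 is far from significant; exact binomial oracle agrees
  r2 <- allelic_expression_test(mk_counts(12, 10, 11, 11))
  expect_true(is.na(r2$snps$tumor_biased_hap))
  expect_equal(r2$snps$p_tumor, oracle_binom_two_sided(12, 22),
               tolerance = 1e-9)
  # biased the same way in both tissues: not tumour-specific
  r3 <- allelic_expression_test(mk_counts(30, 0, 28, 0))
  expect_equal(r3$snps$tumor_biased_hap, "HP1")
  expect_equal(r3$snps$normal_biased_hap, "HP1")
  expect_false(r3$snps$tumor_specific)
  # low coverage is reported untested
  r4 <- allelic_expression_test(mk_counts(4, 2, 3, 3))
  expect_equal(r4$snps$status, "low_coverage")
})

test_that("swapping haplotype labels flips directions, not p-values", {
  x <- mk_counts(35, 8, 20, 22)
  sw <- x
  sw$hp1_reads <- x$hp2_reads
  sw$hp2_reads <- x$hp1_reads
  r <- allelic_expression_test(x)
  rs <- allelic_expression_test(sw)
  expect_equal(r$snps$p_tumor, rs$snps$p_tumor)
  expect_equal(r$snps$q_tumor, rs$snps$q_tumor)
  expect_equal(r$snps$tumor_biased_hap, "HP1")
  expect_equal(rs$snps$tumor_biased_hap, "HP2")
  expect_equal(r$snps$tumor_specific, rs$snps$tumor_specific)
})

test_that("gene verdicts aggregate SNPs by majority direction", {
  x <- rbind(mk_counts(40, 2, 20, 20),
             transform(mk_counts(38, 3, 19, 21), pos = 200L),
             transform(mk_counts(2, 40, 20, 20), pos = 300L,
                       gene_id = "g2"))
  r <- allelic_expression_test(x)
  expect_equal(r$genes[r$genes$gene_id == "g1", ]$biased_hap, "HP1")
  expect_equal(r$genes[r$genes$gene_id == "g2", ]$biased_hap, "HP2")
  # discordant significant SNPs flag the gene mixed
  x2 <- rbind(mk_counts(40, 2, 20, 20),
              transform(mk_counts(2, 40, 20, 20), pos = 200L))
  r2 <- allelic_expression_test(x2)
  expect_equal(r2$genes$biased_hap, "mixed")
})

test_that("simulated allelic skew is recovered from tagged RNA reads", {
  cfg <- sim_config(genome_length = 1e6, n_chroms = 1, seed = 71,
                    with_sequence = FALSE,
                    expression_spec = data.frame(
                      gene_id = c("skewed", "balanced"), chrom = "chr1",
                      start = c(1e5, 6e5), end = c(1.5e5, 6.5e5),
                      tss = c(1e5, 6e5),
                      tumor_hp1_rate = c(40, 25), tumor_hp2_rate = c(10, 25),
                      normal_hp1_rate = 25, normal_hp2_rate = 25))
  sim <- simulate_tumor(cfg)
  tags <- tag_rna_reads(sim$rna, sim$genome$snps)
  cnts <- allelic_counts(sim$rna, tags)
  r <- allelic_expression_test(cnts)
  g <- r$genes
  expect_equal(g[g$gene_id == "skewed", ]$biased_hap, "HP1")
  expect_true(g[g$gene_id == "skewed", ]$tumor_specific)
  expect_equal(g[g$gene_id == "balanced", ]$biased_hap, "unbiased")
})

test_that("regulatory candidates respect promoter windows and exclusions", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(10000L, 50000L))
  enh <- data.frame(chrom = "chr1", start = 30000L, end = 31000L)
  v <- data.frame(chrom = "chr1",
                  pos = c(9200L,    # 800 bp upstream of g1 TSS: promoter
                          30500L,   # inside enhancer
                          9500L,    # promoter window but exonic: excluded
                          20000L),  # nothing
                  hap = c("HP2", "HP1", "HP1", "HP1"),
                  annotation = c("intergenic", "intergenic", "exonic",
                                 "intergenic"))
  cand <- annotate_regulatory(v, genes, enh)
  expect_equal(nrow(cand), 2L)
  pr <- cand[cand$element == "promoter", ]
  expect_equal(pr$pos, 9200L)
  expect_equal(pr$gene_id, "g1")
  expect_equal(pr$hap, "HP2")
  expect_equal(cand[cand$element == "enhancer", ]$pos, 30500L)
  expect_error(annotate_regulatory(v, NULL), "gene_model")
})

test_that("bias-to-regulation linking flags haplotype concordance", {
  genes <- data.frame(gene_id = "CLN5like", n_snps = 6L, n_sig_tumor = 6L,
                      biased_hap = "HP2", tumor_specific = TRUE)
  cand <- data.frame(chrom = "chr1", pos = 9200L, hap = "HP2",
                     gene_id = "CLN5like", element = "promoter")
  dmrb <- data.frame(block_id = "b1", block_length = 1e6L,
                     n_dmrs_total = 4L, n_dmrs_major_direction = 4L,
                     major_direction = "hp2_hypo", dmrs_per_mb = 4)
  gb <- data.frame(gene_id = "CLN5like", block_id = "b1")
  r <- link_bias_to_regulation(genes, cand, dmrb, gb)
  expect_true(r$regulatory_concordant)
  expect_true(r$dmr_concordant)   # hypomethylated on the expressed hap
  # discordant candidate haplotype
  cand$hap <- "HP1"
  expect_false(link_bias_to_regulation(genes, cand)$regulatory_concordant)
  # gene without candidate: empty regulatory fields
  r3 <- link_bias_to_regulation(genes, cand[0, ])
  expect_true(is.na(r3$regulatory_hap))
})

test_that("RNA-editing overlap fraction is exact by construction", {
  snps <- data.frame(chrom = "chr1", pos = seq_len(400) * 10L,
                     ref = "A", alt = "G")
  expect_warning(r0 <- rna_editing_overlap(snps,
                                           data.frame(chrom = character(),
                                                      pos = integer())),
                 "empty")
  expect_equal(r0$fraction, 0)
  cat2 <- data.frame(chrom = "chr1", pos = c(10L, 20L))
  r <- rna_editing_overlap(snps, cat2)
  expect_equal(r$fraction, 2 / 400)
  expect_equal(r$n_overlap, 2L)
  # non-A/G SNPs are excluded from the denominator
  snps2 <- rbind(snps, data.frame(chrom = "chr1", pos = 99999L,
                                  ref = "C", alt = "T"))
  expect_equal(rna_editing_overlap(snps2, cat2)$n_ag_snps, 400L)
})
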