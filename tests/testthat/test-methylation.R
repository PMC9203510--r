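mk_tags <- function(ids, labels) data.frame(
  read_id = ids, block_id = "b1", hp1_count = 5L, hp2_count = 0L,
  n_obs = 5L, label = labels)

test_that("per-haplotype methylation frequencies respect min_reads", {
  calls <- data.frame(
    read_id = c("r1", "r2", "r3", "r4", "r5"),
    chrom = "chr1", cpg_pos = 100L,
    methylated = c(1L, 1L, 0L, 1L, 0L))
  tags <- mk_tags(paste0("r", 1:5),
                  c("HP1", "HP1", "HP1", "HP2", "HP2"))
  f <- haplotype_methylation_frequency(calls, tags)
  expect_equal(f$freq_hp1, 2 / 3)
  expect_true(is.na(f$freq_hp2))        # 2 reads < min_reads
  f2 <- haplotype_methylation_frequency(calls, tags, min_reads = 2)
  expect_equal(f2$freq_hp2, 0.5)
  # untagged reads never enter a frequency
  tags$label[1] <- "untagged"
  f3 <- haplotype_methylation_frequency(calls, tags, min_reads = 2)
  expect_equal(f3$freq_hp1, 0.5)
})

test_that("synthetic methylation frequencies match their generating probabilities", {
  cfg <- sim_config(genome_length = 5e5, n_chroms = 1, depth = 30,
                    per_base_error = 0, seed = 13, with_sequence = FALSE,
                    methylation_spec = list(regions = data.frame(
                      chrom = "chr1", start = 1e5, end = 2e5,
                      hp1_prob = 0.8, hp2_prob = 0.1)))
  sim <- simulate_tumor(cfg)
  tags <- tag_reads(sim$reads$observations, sim$genome$snps)
  f <- haplotype_methylation_frequency(sim$methylation, tags)
  expect_lt(abs(mean(f$freq_hp1, na.rm = TRUE) - 0.8), 0.05)
  expect_lt(abs(mean(f$freq_hp2, na.rm = TRUE) - 0.1), 0.05)
})

test_that("DMR caller finds constructed runs and nothing in identity", {
  pos <- seq(1000L, by = 100L, length.out = 10L)
  same <- data.frame(chrom = "chr1", cpg_pos = pos, freq_hp1 = 0.5,
                     freq_hp2 = 0.5, n_hp1 = 10L, n_hp2 = 10L)
  expect_equal(nrow(call_dmrs(same)), 0L)
  dm <- data.frame(chrom = "chr1", cpg_pos = pos, freq_hp1 = 0.9,
                   freq_hp2 = 0.1, n_hp1 = 10L, n_hp2 = 10L)
  d <- call_dmrs(dm)
  expect_equal(nrow(d), 1L)
  expect_equal(d$direction, "hp2_hypo")
  expect_equal(d$n_cpgs, 10L)
  expect_equal(d$start, 1000L)
  # direction flips under haplotype relabelling
  dm_sw <- dm; dm_sw$freq_hp1 <- dm$freq_hp2; dm_sw$freq_hp2 <- dm$freq_hp1
  expect_equal(call_dmrs(dm_sw)$direction, "hp1_hypo")
})

test_that("injected DMRs are recovered with the right direction", {
  regions <- data.frame(chrom = "chr1",
                        start = seq(1e5, 5e5, 1e5),
                        end = seq(1e5, 5e5, 1e5) + 2e4,
                        hp1_prob = c(0.9, 0.1, 0.9, 0.1, 0.9),
                        hp2_prob = c(0.1, 0.9, 0.1, 0.9, 0.1))
  cfg <- sim_config(genome_length = 6e5, n_chroms = 1, depth = 30,
                    per_base_error = 0, seed = 23, with_sequence = FALSE,
                    methylation_spec = list(regions = regions))
  sim <- simulate_tumor(cfg)
  tags <- tag_reads(sim$reads$observations, sim$genome$snps)
  f <- haplotype_methylation_frequency(sim$methylation, tags)
  d <- call_dmrs(f)
  for (j in seq_len(5)) {
    hit <- d[d$start <= regions$end[j] & d$end >= regions$start[j], ]
    expect_gte(nrow(hit), 1L)
    want <- if (regions$hp1_prob[j] < regions$hp2_prob[j]) "hp1_hypo"
            else "hp2_hypo"
    expect_true(all(hit$direction == want))
  }
})

test_that("DMR-bias blocks apply the three conditions and normal exclusion", {
  blocks <- data.frame(chrom = "chr1", block_id = c("b1", "b2"),
                       start = c(1L, 2000001L),
                       end = c(1000001L, 4000001L), n_snps = 100L,
                       length_bp = c(1e6, 2e6))
  mk_dmrs <- function(n_hp2hypo, n_hp1hypo, offset = 0L) {
    n <- n_hp2hypo + n_hp1hypo
    data.frame(chrom = "chr1",
               start = offset + seq_len(n) * 10000L,
               end = offset + seq_len(n) * 10000L + 500L,
               n_cpgs = 10L, mean_freq_hp1 = 0.8, mean_freq_hp2 = 0.2,
               direction = c(rep("hp2_hypo", n_hp2hypo),
                             rep("hp1_hypo", n_hp1hypo)),
               p_value = 1e-5, q_value = 1e-4)
  }
  # block b1 (1 Mb): 4 hp2_hypo + 1 hp1_hypo -> 4>=3, 0.8>=0.7, 4/Mb>=3
  d1 <- mk_dmrs(4, 1)
  r1 <- dmr_bias_blocks(d1, NULL, blocks)
  expect_equal(r1$block_id, "b1")
  expect_equal(r1$n_dmrs_major_direction, 4L)
  expect_equal(r1$major_direction, "hp2_hypo")
  # same DMRs on a 2-Mb block: 4/2 = 2 per Mb < 3 -> not reported
  d2 <- mk_dmrs(4, 0, offset = 2000001L)
  expect_equal(nrow(dmr_bias_blocks(d2, NULL, blocks)), 0L)
  # ratio condition: 3 hp2 + 2 hp1 = 0.6 < 0.7 -> not reported
  d3 <- mk_dmrs(3, 2)
  expect_equal(nrow(dmr_bias_blocks(d3, NULL, blocks)), 0L)
  # a tumour DMR overlapped 30% by a normal DMR is excluded before
  # counting (the major-direction count drops from 4 to 3), while an
  # overlap of 10% keeps it
  d4 <- mk_dmrs(4, 1)
  normal30 <- data.frame(chrom = "chr1", start = d4$start[1],
                         end = d4$start[1] + 150L)  # 151/501 = 30%
  r4 <- dmr_bias_blocks(d4, normal30, blocks)
  expect_equal(r4$n_dmrs_major_direction, 3L)
  expect_equal(r4$n_dmrs_total, 4L)
  normal10 <- data.frame(chrom = "chr1", start = d4$start[1],
                         end = d4$start[1] + 49L)   # 50/501 = 10%
  expect_equal(dmr_bias_blocks(d4, normal10, blocks)$n_dmrs_major_direction,
               4L)
})

test_that("DMR-bias conditions agree with a brute-force re-count", {
  set.seed(99)
  blocks <- data.frame(chrom = "chr1", block_id = paste0("b", 1:5),
                       start = (0:4) * 2e6 + 1, end = (1:5) * 2e6,
                       n_snps = 10L, length_bp = 2e6)
  for (trial in 1:20) {
    n <- sample(0:12, 5, replace = TRUE)
    dmrs <- do.call(rbind, lapply(1:5, function(j) {
      if (n[j] == 0) return(NULL)
      data.frame(chrom = "chr1",
                 start = (j - 1) * 2e6 + seq_len(n[j]) * 1e5,
                 end = (j - 1) * 2e6 + seq_len(n[j]) * 1e5 + 400L,
                 n_cpgs = 8L, mean_freq_hp1 = 0.8, mean_freq_hp2 = 0.2,
                 direction = sample(c("hp1_hypo", "hp2_hypo"), n[j],
                                    replace = TRUE),
                 p_value = 1e-4, q_value = 1e-3)
    }))
    if (is.null(dmrs)) next
    rep_blocks <- dmr_bias_blocks(dmrs, NULL, blocks)
    # independent re-count per block
    for (j in 1:5) {
      d <- dmrs[dmrs$start >= blocks$start[j] & dmrs$end <= blocks$end[j], ]
      n1 <- sum(d$direction == "hp1_hypo")
      n2 <- sum(d$direction == "hp2_hypo")
      nmax <- max(n1, n2)
      len_mb <- (blocks$end[j] - blocks$start[j]) / 1e6
      want <- nrow(d) > 0 && nmax >= 3 && nmax / nrow(d) >= 0.7 &&
        nmax / len_mb >= 3
      expect_equal(blocks$block_id[j] %in% rep_blocks$block_id, want,
                   info = paste("trial", trial, "block", j))
    }
  }
})

test_that("no-difference methylation yields (almost) no DMR-bias blocks", {
  hits <- 0L
  for (k in 1:10) {
    cfg <- sim_config(genome_length = 4e5, n_chroms = 1, depth = 20,
                      per_base_error = 0, seed = 400 + k,
                      with_sequence = FALSE,
                      methylation_spec = list(regions = data.frame(
                        chrom = "chr1", start = 1e5, end = 3e5,
                        hp1_prob = 0.5, hp2_prob = 0.5)))
    sim <- simulate_tumor(cfg)
    tags <- tag_reads(sim$reads$observations, sim$genome$snps)
    f <- haplotype_methylation_frequency(sim$methylation, tags)
    d <- call_dmrs(f)
    blocks <- phased_blocks(sim$genome$snps)
    hits <- hits + nrow(dmr_bias_blocks(d, NULL, blocks))
  }
  expect_lte(hits, 1L)
})
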