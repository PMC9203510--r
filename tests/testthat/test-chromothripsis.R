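mk_sv <- function(p1, p2, chrom = "chr1", hap = "HP1") data.frame(
  sv_id = sprintf("sv%02d", seq_along(p1)), chrom1 = chrom, pos1 = p1,
  dir1 = "+", chrom2 = chrom, pos2 = p2, dir2 = "-", type = "deletion",
  read_ids = "", hap = hap, stringsAsFactors = FALSE)

test_that("interleaved SV clustering connects by interval intersection", {
  sv <- mk_sv(c(1000, 5000, 12000), c(10000, 15000, 20000))
  cl <- cluster_interleaved_svs(sv)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_svs, 3L)
  expect_equal(cl$start, 1000L)
  expect_equal(cl$end, 20000L)
  # far-apart singletons produce no cluster
  sv2 <- mk_sv(c(1000, 100000), c(2000, 101000))
  expect_equal(nrow(cluster_interleaved_svs(sv2)), 0L)
  # max_gap bridges a gap
  expect_equal(nrow(cluster_interleaved_svs(sv2, max_gap = 98000)), 1L)
})

test_that("injected interleaved clusters are recovered whole", {
  cfg <- sim_config(genome_length = 5e6, n_chroms = 1, seed = 8,
                    with_sequence = FALSE,
                    sv_cluster_spec = data.frame(chrom = "chr1",
                      start = 1e6, end = 4e6, hap = 2, n_svs = 15,
                      n_cn_oscillations = 6))
  g <- simulate_diploid_genome(cfg)
  ev <- inject_somatic_events(g, cfg)
  cl <- cluster_interleaved_svs(ev$svs)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_svs, 15L)
  expect_setequal(strsplit(cl$sv_ids, ",")[[1]], ev$svs$sv_id)
})

test_that("CN oscillation counting matches the brute-force oracle", {
  mk_cn <- function(states) data.frame(
    chrom = "chr1", start = seq_along(states) * 1000L - 999L,
    end = seq_along(states) * 1000L, cn = states)
  o <- count_cn_oscillations(mk_cn(c(2, 1, 2, 1, 2)), "chr1", 1, 5000)
  expect_equal(o$n_2state_segments, 5L)
  expect_equal(o$n_2state_transitions, 4L)
  o2 <- count_cn_oscillations(mk_cn(c(2, 2, 2)), "chr1", 1, 3000)
  expect_equal(o2$n_2state_segments, 0L)
  o3 <- count_cn_oscillations(mk_cn(c(3, 1, 2, 1, 3, 1)), "chr1", 1, 6000)
  expect_equal(o3$n_3state_segments,
               oracle_longest_alternating(c(3, 1, 2, 1, 3, 1), 3))
  expect_equal(o3$n_2state_segments,
               oracle_longest_alternating(c(3, 1, 2, 1, 3, 1), 2))
  # random state sequences against the oracle
  set.seed(5)
  for (k in 1:200) {
    states <- sample(1:4, sample(2:12, 1), replace = TRUE)
    o <- count_cn_oscillations(mk_cn(states), "chr1", 1,
                               length(states) * 1000)
    expect_equal(o$n_2state_segments,
                 oracle_longest_alternating(states, 2), info = k)
    expect_equal(o$n_3state_segments,
                 oracle_longest_alternating(states, 3), info = k)
    expect_equal(o$n_state_changes, sum(diff(states) != 0))
  }
})

test_that("the four chromothripsis criteria are applied conjunctively", {
  # 12 SVs over ~4 Mb with 5 oscillating segments: all criteria pass
  cl <- data.frame(cluster = 1L, chrom = "chr1", start = 1L, end = 4e6L,
                   n_svs = 12L, span_mb = 4, svs_per_mb = 3,
                   sv_ids = "", n_hp1 = 12L, n_hp2 = 0L)
  cn5 <- data.frame(chrom = "chr1", start = (0:4) * 8e5 + 1,
                    end = (1:5) * 8e5, cn = c(2, 1, 2, 1, 2))
  call <- call_chromothripsis(cl, cn5)
  expect_true(call$passed)
  expect_true(all(unlist(call[c("c1", "c2", "c3", "c4")])))
  # 9 SVs: fails (i) only
  cl9 <- cl; cl9$n_svs <- 9L
  call9 <- call_chromothripsis(cl9, cn5)
  expect_false(call9$passed)
  expect_false(call9$c1)
  expect_true(call9$c2 && call9$c3 && call9$c4)
  # 2-state run of 3 segments and 3-state of 5: fails (ii)
  cn_bad <- data.frame(chrom = "chr1", start = (0:4) * 8e5 + 1,
                       end = (1:5) * 8e5, cn = c(2, 1, 3, 1, 1))
  call_bad <- call_chromothripsis(cl, cn_bad)
  expect_false(call_bad$c2)
  expect_false(call_bad$passed)
  # criteria re-checked independently on every call of a random batch
  set.seed(31)
  for (k in 1:50) {
    n_svs <- sample(5:20, 1)
    span <- sample(c(2e6, 5e6, 4e7), 1)
    states <- sample(1:3, sample(2:9, 1), replace = TRUE)
    cn <- data.frame(chrom = "chr1",
                     start = round(seq(1, span, length.out =
                                         length(states) + 1))[-(length(states) + 1)],
                     end = round(seq(1, span, length.out =
                                       length(states) + 1))[-1], cn = states)
    clk <- data.frame(cluster = 1L, chrom = "chr1", start = 1L,
                      end = span, n_svs = n_svs, span_mb = span / 1e6,
                      svs_per_mb = n_svs / (span / 1e6), sv_ids = "",
                      n_hp1 = n_svs, n_hp2 = 0L)
    call <- call_chromothripsis(clk, cn)
    o2 <- oracle_longest_alternating(states, 2)
    o3 <- oracle_longest_alternating(states, 3)
    want <- (n_svs >= 10) && (o2 >= 4 || o3 >= 6) &&
      (n_svs / (span / 1e6) >= 0.2) &&
      (sum(diff(states) != 0) / (span / 1e6) >= 0.2)
    expect_equal(call$passed, want, info = k)
  }
})

test_that("trinucleotide categories follow pyrimidine-strand convention", {
  ref <- c(chr1 = "ATCAGTGACT")
  #             TCA        -> C>T at T[C>T]A
  v1 <- data.frame(chrom = "chr1", pos = 3L, ref = "C", alt = "T")
  s1 <- trinucleotide_spectrum(v1, ref)
  expect_equal(sum(s1), 1L)
  expect_equal(unname(s1["T[C>T]A"]), 1L)
  #             TGA (pos 5-7 GTG? use pos 6: T G A) -> G>A == C>T at T[C>T]A
  ref2 <- c(chr1 = "ATTGACT")
  v2 <- data.frame(chrom = "chr1", pos = 4L, ref = "G", alt = "A")
  s2 <- trinucleotide_spectrum(v2, ref2)
  expect_equal(unname(s2["T[C>T]A"]), 1L)
  # SNV at a contig edge is skipped and counted
  v3 <- data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "G")
  s3 <- trinucleotide_spectrum(v3, ref)
  expect_equal(sum(s3), 0L)
  expect_equal(attr(s3, "n_skipped"), 1L)
  # conservation: counts sum to processed minus skipped
  v_all <- rbind(v1, v3)
  s_all <- trinucleotide_spectrum(v_all, ref)
  expect_equal(sum(s_all) + attr(s_all, "n_skipped"), nrow(v_all))
})

test_that("cosine similarity: identity, orthogonality, hand-computed case", {
  sig <- builtin_signatures()[, "APOBEC-like"]
  expect_equal(cosine_similarity(sig * 17, sig), 1.0)
  a <- c(1, 0, 1, 0, rep(0, 92))
  b <- c(0, 1, 0, 1, rep(0, 92))
  expect_equal(cosine_similarity(a, b), 0.0)
  # (1,0,1,0,...) vs (1,1,0,0,...): 1 / (sqrt(2) * sqrt(2)) = 0.5
  m <- c(1, 1, 0, 0, rep(0, 92))
  expect_equal(cosine_similarity(a, m), 0.5)
  expect_warning(z <- cosine_similarity(rep(0, 96), sig), "zero")
  expect_true(is.nan(z))
  # scale invariance
  expect_equal(cosine_similarity(a * 1000, m / 7),
               cosine_similarity(a, m))
  # best_matches ranks above-threshold signatures
  bm <- best_matches(sig, builtin_signatures())
  expect_equal(bm$signature[1], "APOBEC-like")
  expect_true(all(bm$cosine > 0.7))
})

test_that("kataegis scan flags APOBEC-like clusters, not flat ones", {
  base <- list(genome_length = 2e6, n_chroms = 1, somatic_rate = 2,
               with_sequence = TRUE, seed = 67)
  mk <- function(spectrum) {
    cfg <- do.call(sim_config, c(base, list(bias_regions = data.frame(
      chrom = "chr1", start = 5e5, end = 6e5, hap = 1,
      fraction_on_hap = 1, n_snvs = 25, spectrum = spectrum))))
    g <- simulate_diploid_genome(cfg)
    ev <- inject_somatic_events(g, cfg)
    snvs <- ev$snvs
    snvs$hap <- paste0("HP", snvs$hap_truth)
    kataegis_scan(snvs, g$chrom_lengths, reference = g$reference)
  }
  hit <- mk("APOBEC-like")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$dominant_hap, "HP1")
  expect_gt(hit$cosine, 0.7)
  # a flat-spectrum cluster is enriched but not kataegis
  expect_equal(nrow(mk("flat")), 0L)
})
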