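# Shared demo-study configuration for the analysis scripts.
# One synthetic tumour/normal case: two 2-Mb chromosomes, 30x long reads
# (N50 16 kb, 10% SNP-site error), a haplotype-biased APOBEC-context SNV
# region, an interleaved SV cluster with oscillating CN on one
# haplotype, a haplotype-specific hypomethylated region, and one gene
# with tumour-specific 4:1 allelic skew. Everything downstream is
# deterministic given DEMO_SEED.

library(hapcontext)

DEMO_SEED <- 2024L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

demo_config <- function(seed = DEMO_SEED) {
  sim_config(
    genome_length = 2e6, n_chroms = 2, depth = 30, read_n50 = 16000,
    per_base_error = 0.10, somatic_rate = 10, seed = seed,
    with_sequence = TRUE,
    bias_regions = data.frame(
      chrom = "chr1", start = 4e5, end = 6e5, hap = 1,
      fraction_on_hap = 0.95, n_snvs = 30, spectrum = "APOBEC-like"),
    sv_cluster_spec = data.frame(
      chrom = "chr2", start = 2e5, end = 1.6e6, hap = 1, n_svs = 15,
      n_cn_oscillations = 6),
    methylation_spec = list(regions = data.frame(
      chrom = "chr1", start = 1.2e6, end = 1.3e6,
      hp1_prob = 0.15, hp2_prob = 0.85)),
    expression_spec = data.frame(
      gene_id = c("GENE_A", "GENE_B"), chrom = "chr1",
      start = c(1.5e6, 1.7e6), end = c(1.55e6, 1.75e6),
      tss = c(1.5e6, 1.7e6),
      tumor_hp1_rate = c(40, 25), tumor_hp2_rate = c(10, 25),
      normal_hp1_rate = c(25, 25), normal_hp2_rate = c(25, 25)))
}

demo_dataset <- function() simulate_tumor(demo_config())
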