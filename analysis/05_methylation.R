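#!/usr/bin/env Rscript
# Allele-specific methylation: per-haplotype CpG frequencies, DMRs
# between haplotypes, and phase blocks with directionally biased DMRs.
# A matched-normal with no haplotype difference provides the exclusion
# set.

source("analysis/00_config.R")

sim <- demo_dataset()
tags <- tag_reads(sim$reads$observations, sim$genome$snps)
freqs <- haplotype_methylation_frequency(sim$methylation, tags)
cat(sprintf("CpG sites with frequencies on both haplotypes: %d\n",
            sum(!is.na(freqs$freq_hp1) & !is.na(freqs$freq_hp2))))

dmrs <- call_dmrs(freqs)
cat(sprintf("DMRs called: %d (%d hp1_hypo / %d hp2_hypo)\n", nrow(dmrs),
            sum(dmrs$direction == "hp1_hypo"),
            sum(dmrs$direction == "hp2_hypo")))
write_tsv(dmrs, file.path(RESULTS_DIR, "dmrs.tsv"))

# matched normal: same regions, no haplotype difference
normal_cfg <- demo_config(seed = DEMO_SEED + 500L)
normal_cfg$methylation_spec$regions$hp1_prob <- 0.5
normal_cfg$methylation_spec$regions$hp2_prob <- 0.5
nsim <- simulate_tumor(normal_cfg)
ntags <- tag_reads(nsim$reads$observations, nsim$genome$snps)
nfreqs <- haplotype_methylation_frequency(nsim$methylation, ntags)
ndmrs <- call_dmrs(nfreqs)
cat(sprintf("matched-normal DMRs: %d\n", nrow(ndmrs)))

blocks <- phased_blocks(connectivity_blocks(sim$genome$snps,
                                            sim$reads$reads))
bias <- dmr_bias_blocks(dmrs, ndmrs, blocks)
print(bias)
write_tsv(bias, file.path(RESULTS_DIR, "dmr_bias_blocks.tsv"))
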