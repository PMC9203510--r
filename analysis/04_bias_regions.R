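#!/usr/bin/env Rscript
# Mutation-enriched 100-kb windows, haplotype-biased regions (>80% of
# phased mutations on one haplotype) and SV-concentrated phase blocks.

source("analysis/00_config.R")

sim <- demo_dataset()
tags <- tag_reads(sim$reads$observations, sim$genome$snps)
ph <- phase_snvs(sim$snvs, sim$mutant_reads, tags)

enr <- find_enriched_windows(ph, sim$genome$chrom_lengths)
cat(sprintf("enriched 100-kb windows (BH < 0.05): %d\n", nrow(enr)))

regions <- call_biased_regions(enr, ph)
print(regions[, c("chrom", "start", "end", "n_hp1", "n_hp2",
                  "bias_fraction", "biased_hap", "p_binomial")])
write_tsv(regions, file.path(RESULTS_DIR, "biased_regions.tsv"))

psv <- phase_svs(sim$svs, tags)
svb <- sv_concentrated_blocks(psv)
print(svb)
write_tsv(svb, file.path(RESULTS_DIR, "sv_concentrated_blocks.tsv"))
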