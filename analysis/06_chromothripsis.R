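#!/usr/bin/env Rscript
# Chromothripsis-like event calling: interleaved SV clusters, CN
# oscillations, the four criteria, and the local mutational signature
# (kataegis scan) of the biased SNV region.

source("analysis/00_config.R")

sim <- demo_dataset()
tags <- tag_reads(sim$reads$observations, sim$genome$snps)
psv <- phase_svs(sim$svs, tags)

calls <- chromothripsis_calls(psv, sim$cn)
print(calls[, c("chrom", "start", "end", "n_svs", "n_2state_segments",
                "svs_per_mb", "cn_states_per_mb", "c1", "c2", "c3", "c4",
                "passed", "dominant_hap")])
write_tsv(calls, file.path(RESULTS_DIR, "chromothripsis_calls.tsv"))

# spectrum of the haplotype-biased SNV region vs the signature catalogue
ph <- phase_snvs(sim$snvs, sim$mutant_reads, tags)
br <- sim$truth$bias_regions
in_region <- ph$chrom == br$chrom & ph$pos >= br$start & ph$pos <= br$end
spec <- trinucleotide_spectrum(ph[in_region, ], sim$genome$reference)
m <- best_matches(spec, builtin_signatures())
cat("signature matches (cosine > 0.7) of the biased region:\n")
print(m)
write_tsv(data.frame(category = names(spec), count = as.integer(spec)),
          file.path(RESULTS_DIR, "biased_region_spectrum.tsv"))

kat <- kataegis_scan(ph, sim$genome$chrom_lengths,
                     reference = sim$genome$reference)
cat("kataegis candidates:\n")
print(kat)
write_tsv(kat, file.path(RESULTS_DIR, "kataegis_candidates.tsv"))
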