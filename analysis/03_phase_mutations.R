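#!/usr/bin/env Rscript
# Haplotype assignment of somatic SNVs and SVs from haplotagged reads,
# accuracy against the simulation truth, and temporal ordering of
# co-spanned mutation pairs.

source("analysis/00_config.R")

sim <- demo_dataset()
tags <- tag_reads(sim$reads$observations, sim$genome$snps)
cat(sprintf("reads tagged: %d HP1, %d HP2, %d untagged\n",
            sum(tags$label == "HP1"), sum(tags$label == "HP2"),
            sum(tags$label == "untagged")))

ph <- phase_snvs(sim$snvs, sim$mutant_reads, tags)
cat(sprintf("SNVs haplotype-resolved: %d of %d (%.0f%%)\n",
            sum(ph$hap != "unknown"), nrow(ph),
            100 * mean(ph$hap != "unknown")))
truth <- merge(ph[ph$hap != "unknown", c("id", "hap")],
               sim$truth$snvs[, c("id", "hap_truth")], by = "id")
cat(sprintf("assignment accuracy vs truth: %.3f\n",
            mean(truth$hap == paste0("HP", truth$hap_truth))))
write_somatic_vcf(ph, file.path(RESULTS_DIR, "somatic_phased.vcf"))

psv <- phase_svs(sim$svs, tags)
cat(sprintf("SVs phased: %d of %d\n", sum(psv$hap != "unknown"),
            nrow(psv)))
write_tsv(psv, file.path(RESULTS_DIR, "svs_phased.tsv"))

ord <- order_mutation_pairs(sim$snvs, sim$mutant_reads,
                            sim$reads$reads)
cat(sprintf("mutation pairs co-spanned by reads: %d (%d ordered, %d co-occurring, %d conflicting)\n",
            nrow(ord),
            sum(ord$verdict %in% c("A_before_B", "B_before_A")),
            sum(ord$verdict == "co_occurring"),
            sum(ord$verdict == "conflicting")))
write_tsv(ord, file.path(RESULTS_DIR, "mutation_pair_order.tsv"))
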