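#!/usr/bin/env Rscript
# Generate the demo synthetic tumour/normal dataset and export it in the
# standard interchange formats (FASTA reference, phased VCF, read/SV/CN
# TSVs, methylation calls, truth BED).

source("analysis/00_config.R")

sim <- demo_dataset()
out <- file.path(RESULTS_DIR, "demo_data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

write_fasta(sim$genome$reference, file.path(out, "reference.fa"))
write_phased_vcf(sim$genome$snps, file.path(out, "germline_phased.vcf"))
write_tsv(sim$reads$reads, file.path(out, "reads.tsv"))
write_tsv(sim$reads$observations, file.path(out, "read_snp_observations.tsv"))
write_tsv(sim$snvs, file.path(out, "somatic_snvs.tsv"))
write_tsv(sim$svs, file.path(out, "somatic_svs.tsv"))
write_tsv(sim$cn, file.path(out, "cn_segments.tsv"))
write_tsv(sim$methylation, file.path(out, "methylation_calls.tsv"))
write_tsv(sim$rna, file.path(out, "rna_observations.tsv"))
write_bed(sim$truth$bias_regions[, c("chrom", "start", "end")],
          file.path(out, "truth_bias_regions.bed"))

tags <- tag_reads(sim$reads$observations, sim$genome$snps)
write_sam(sim$reads$reads, sim$genome$chrom_lengths,
          file.path(out, "reads.sam"), tags)

cat(sprintf(
  "demo dataset: %d het SNPs, %d reads (%.0fx), %d somatic SNVs, %d SVs\n",
  nrow(sim$genome$snps), nrow(sim$reads$reads),
  sum(sim$reads$reads$end - sim$reads$reads$start + 1) /
    sum(sim$genome$chrom_lengths),
  nrow(sim$snvs), nrow(sim$svs)))
cat("written to", out, "\n")
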