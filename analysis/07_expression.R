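#!/usr/bin/env Rscript
# Allele-specific expression and its regulatory context: per-SNP and
# per-gene haplotype bias, tumour specificity, promoter/enhancer
# candidate mutations, RNA-editing confounder check, and the join of
# expression bias with regulatory variants and DMR-biased blocks.

source("analysis/00_config.R")

sim <- demo_dataset()
rna_tags <- tag_rna_reads(sim$rna, sim$genome$snps)
cnts <- allelic_counts(sim$rna, rna_tags)
ase <- allelic_expression_test(cnts)
print(ase$genes)
write_tsv(ase$snps, file.path(RESULTS_DIR, "ase_snps.tsv"))
write_tsv(ase$genes, file.path(RESULTS_DIR, "ase_genes.tsv"))

# regulatory candidates among phased somatic SNVs around gene TSSs
tags <- tag_reads(sim$reads$observations, sim$genome$snps)
ph <- phase_snvs(sim$snvs, sim$mutant_reads, tags)
genes <- as.data.frame(sim$truth$expression)
gene_model <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                         tss = c(1.5e6, 1.7e6))
cand <- annotate_regulatory(ph, gene_model)
cat(sprintf("regulatory candidates near TSSs: %d\n", nrow(cand)))

link <- link_bias_to_regulation(ase$genes, cand)
print(link)
write_tsv(link, file.path(RESULTS_DIR, "bias_regulation_links.tsv"))

# RNA-editing overlap of A/G phasing SNPs with a synthetic catalogue
set.seed(DEMO_SEED)
ag <- sim$genome$snps[(sim$genome$snps$ref == "A" &
                         sim$genome$snps$alt == "G") |
                        (sim$genome$snps$ref == "T" &
                           sim$genome$snps$alt == "C"), ]
catalog <- data.frame(chrom = ag$chrom[1], pos = ag$pos[1:3])
ov <- rna_editing_overlap(sim$genome$snps, catalog)
cat(sprintf("A/G SNPs overlapping editing catalogue: %d of %d (%.2f%%)\n",
            ov$n_overlap, ov$n_ag_snps, 100 * ov$fraction))
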