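Package: hapcontext
Title: Haplotype Context of Somatic Mutations from Long-Read Phasing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the chromosomal (haplotype) context of
    somatic alterations in paired tumour/normal genomes phased with long
    sequencing reads. Implements haplotagging of reads from phased
    heterozygous SNPs, haplotype assignment of somatic SNVs/indels and
    structural variants from tagged read support, switch/flip phasing
    concordance and panel concordance metrics, phased-block statistics,
    detection of mutation-enriched and haplotype-biased regions,
    allele-specific methylation (differentially methylated regions between
    haplotypes and DMR-biased phase blocks), chromothripsis-like event
    calling from interleaved SV clusters with oscillating copy number,
    trinucleotide mutational spectra with cosine similarity to reference
    signatures, and allele-specific expression tests. A synthetic diploid
    tumour generator with a full truth set supports end-to-end testing and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
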