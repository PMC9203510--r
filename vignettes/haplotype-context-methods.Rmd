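---
title: "Methods: haplotype-context analysis of somatic mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-context analysis of somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapcontext)
```

# Overview

`hapcontext` analyses the chromosomal context of somatic alterations in a
diploid tumour genome whose germline heterozygous SNPs have been phased
into blocks (a phased VCF with `GT|PS`) and sequenced with long reads.
The package assumes exactly two haplotypes per block (HP1/HP2), takes
upstream phasing, alignment and variant calling as given, and implements
everything downstream of them: haplotagging reads, assigning somatic
SNVs/indels and SVs to haplotypes, quantifying phasing quality, and
detecting regions where mutation, methylation or expression differ
between the two parental chromosome copies.

All operations are exercised end-to-end on a bundled synthetic diploid
tumour generator with a complete truth set, so every detector in the
package has a parameter-recovery test against known ground truth.

# Read haplotagging and somatic-variant assignment

A read is compared with the phased SNPs of a block it overlaps. An
observation is *informative* when it equals one of the two haplotype
alleles. The read is labelled `HPk` when it has at least 2 informative
observations and the majority haplotype holds at least 70% of them
(boundary inclusive); otherwise it is untagged. The same rule tags
genomic and transcript reads.

A somatic SNV/indel is assigned to a haplotype when **3 or more** mutant
(alt-carrying) reads are tagged to one haplotype and **at most 1** to
the other; anything else stays `unknown`. An SV is *phased* when at
least 3 of its supporting reads are tagged and the majority haplotype
holds at least 70% of them; SV phasing is restricted to autosomes
(chr1–22). A read supporting an SV through several alignment segments
is counted once, with its observations pooled before the 2-SNP rule —
the natural reading when primary and supplementary alignments carry
complementary SNP information.

An optional VAF filter (`min_vaf`, default off) reproduces the common
practice of restricting haplotype assignment to mutations with VAF
≥ 0.2, where read support is usually sufficient.

For mutation pairs co-spanned by at least one read, spanning reads are
classified into `neither` / `A-only` / `B-only` / `both`. "A before B"
requires `both` and `A-only` each supported by at least `min_reads`
(default 2) reads and `B-only` empty; both single-mutant patterns
supported means parallel clones (`conflicting`). The support threshold
is a package choice exposed in the interface: one read of a rare
pattern is too easily a chimera or mis-tag, two independent molecules
are already strong evidence at typical long-read error rates. Pairs
farther apart than the longest read are never interrogated.

# Phasing concordance metrics

`compare_phasings()` restricts to SNPs phased in both inputs with
identical ref/alt, groups them into segments by the pair of block
identifiers, and works per chromosome. Within a segment, the
per-SNP agreement sequence is explained by two operations: a **flip**
(one SNP on the wrong haplotype, toggles one position) and a **switch**
(the haplotype identity inverts from some SNP onward, toggles a
suffix). The global orientation of a segment carries no information and
is free. The reported counts are the *minimum-cost* explanation
(switches + flips), computed by a small dynamic program over positions
with the suffix-toggle parity as state; ties between equal-cost
explanations are broken toward fewer flips, and then toward the
HP1↔HP1 orientation. Consequences worth knowing:

* an isolated wrong SNP strictly inside a segment is one flip (cost 1
  beats two switches);
* a disagreement run of length ≥ 2 bounded by agreement is two
  switches (ties at length 2 go to switches by the tie-break);
* a run touching a segment end is one switch — including a single
  terminal SNP, where one switch and one flip tie and the tie-break
  favours the switch.

An exhaustive test enumerates every orientation pattern on segments of
up to 8 SNPs and checks the decomposition against brute-force
enumeration of all flip/switch subsets.

Because no denominator convention is universal, the discrepancy rate is
reported both per compared SNP and per consecutive compared pair.

`panel_concordance()` compares only the *relative phase of consecutive
phased heterozygous SNP pairs* (alt alleles cis or trans) between the
query blocks and a chromosome-scale panel. Cross-block comparisons are
never made: block-local haplotype numbering is arbitrary, so only
within-block pair relations are meaningful.

# Mutation-enriched and haplotype-biased regions

The genome is partitioned into fixed 100-kb windows. Each window's
somatic mutation count is tested against the genome-wide rate with a
one-sided Poisson upper-tail test, λ scaled by window length over the
callable length, and BH-adjusted across all windows (an exact binomial
alternative is provided; at these rates the two are nearly identical).
The callable length defaults to the supplied chromosome total; passing
the phased-block span restricts the background rate to phaseable
sequence. Adjacent significant windows are merged before bias calling,
since a single event frequently spills across window boundaries.

A merged region is **haplotype-biased** when it carries at least
`min_phased = 5` haplotype-resolved mutations and more than 80% of them
lie on one haplotype. Unknown-haplotype mutations are counted but
excluded from the denominator: including them would make the fraction
depend on coverage rather than biology. The `min_phased` floor guards
against degenerate "100% of 1 mutation" regions. An exact two-sided
binomial p-value against an even split is reported alongside the
fraction so regions can be ranked rather than merely flagged.

Phase blocks holding ≥ 3 phased SVs are reported with the maximum
per-haplotype SV proportion.

# Chromothripsis-like events and signatures

Intrachromosomal SVs are represented as breakpoint-to-breakpoint
intervals; two SVs are connected when their intervals intersect
(`max_gap = 0`, i.e. strict overlap, configurable), and connected
components of at least two SVs form clusters. Interval-intersection
connectivity is the operational meaning of "interleaved": the shattered
fragments of one event produce mutually overlapping rearrangement
intervals, while independent distant SVs do not chain.

Copy-number segments clipped to the cluster span yield the longest run
of consecutive segments alternating between two CN values, and the
longest run using at most three values with every adjacent pair
differing. A cluster is called chromothripsis-like when all four hold:

1. ≥ 10 SVs in the cluster;
2. ≥ 4 oscillating CN segments between two states, or ≥ 6 among three;
3. ≥ 0.2 SVs per Mb of cluster span;
4. ≥ 0.2 CN state changes per Mb.

Criterion 2 is applied to *segment counts* (with transition counts also
reported and selectable via `oscillation_metric`), and criterion 4
counts adjacent state changes — the stricter and more common reading of
"states per Mb". All four thresholds are exposed.

Spectra use the standard 96 pyrimidine-centric trinucleotide
categories; purine-reference SNVs are reverse-complemented. Cosine
similarity against a signature catalogue flags matches above 0.7. The
shipped catalogue (`builtin_signatures()`) is **synthetic** — an
APOBEC-like TpC-focused profile, a CpG-deamination "aging-like"
profile and a flat profile — sufficient for tests and simulation;
analyses of real data should supply a COSMIC-format matrix. The
kataegis scan flags mutation-enriched windows whose local spectrum has
cosine > 0.7 to the APOBEC-class profile, with haplotype composition.

# Allele-specific methylation

Per-read CpG calls are aggregated per (site, haplotype); a frequency is
emitted only with ≥ 3 tagged reads on that haplotype. The internal DMR
caller is deliberately minimal plumbing — maximal runs of ≥ 5
consecutive CpGs with a per-site between-haplotype difference ≥ 0.3 in
a consistent direction, a Mann–Whitney test per run and BH adjustment —
so that the pipeline is end-to-end on synthetic data; DMR tables from a
dedicated caller can be substituted anywhere a DMR table is accepted.

A phase block has **DMR bias** when (i) the maximum number of
same-direction DMRs is ≥ 3, (ii) that count is ≥ 70% of the block's
DMRs, and (iii) it is ≥ 3 per Mb of block span. "Same direction" means
hypomethylated on the same haplotype. Tumour DMRs overlapped by a
matched-normal DMR over more than 20% of the *tumour DMR's* length are
removed first (the overlap base is a package choice; the tumour DMR is
the object being classified, so its length is the natural denominator).

# Allele-specific expression

Per SNP and tissue, the HP1 read count is tested against an even split
with an exact two-sided binomial test, BH-adjusted across SNPs; SNPs
under 10 tagged reads are reported untested. The per-tissue binomial
(rather than a tumour-versus-normal contingency test) matches how
haplotype ratios are reported per tissue; a Fisher option is provided.
A SNP is *tumour-specific* when significant in tumour and the normal is
not significantly biased toward the same haplotype. Genes aggregate
their SNPs by majority direction; discordant significant SNPs flag the
gene `mixed` rather than letting opposite exons cancel.

Promoter candidates are variants within ±1.5 kb of a TSS, enhancer
candidates fall in supplied enhancer intervals; variants annotated
exonic/5'UTR/3'UTR are excluded from regulatory candidacy. The linking
step joins per-gene expression bias, regulatory candidates and
DMR-biased blocks, flagging haplotype concordance (e.g. promoter
mutation and over-expression on the same haplotype, hypomethylation of
the expressed haplotype). Haplotype-specific copy number is annotated,
not corrected for: a CN-driven expression skew is a real skew with a
different cause.

# The synthetic generator

`sim_config()` fixes the study conditions: heterozygous SNPs as a
Poisson process at 1/1500 bp (human-typical density); log-normal read
lengths with σ = 0.85 and log-mean `log(N50) − σ²`, which makes the
length-weighted median of the law equal the target N50 (16 kb by
default, the scale of nanopore WGS runs; σ = 0.85 puts the mean/N50
ratio near 0.7, typical of long-read length distributions); 30×
default depth; a 10% chance per covered SNP of reporting the other
haplotype's allele, matching single-pass long-read accuracy at the
sites that matter for phasing. Somatic SNVs arise at 10/Mb in the
background plus configurable biased regions, with VAFs from a
Beta(8, 12) (mean 0.4); a read from the mutant haplotype carries the
mutation with probability `min(1, 2·VAF)`. SV clusters place 2n sorted
breakpoints and pair point *i* with point *i + n*, which makes every
pair of intervals intersect — an explicitly interleaved architecture —
with alternating two-state CN segments (three-state configurable)
confined to one haplotype. Methylation and expression follow the
per-region/per-gene per-haplotype probabilities given in the
configuration.

When a reference sequence is generated, SNV positions are placed only
where the reference trinucleotide equals the drawn category's context,
so spectra recomputed from the sequence agree exactly with the
generator's truth; for large genomes the generator runs without a
sequence and records contexts in the truth table instead.

The generator emulates the *statistical* structure the detectors
assume, not sequencing physics: errors exist only as SNP-site flips
(no indel errors, no quality scores), reads are single contiguous
segments (no chimeras or supplementary splits), tumours are pure and
clonally homogeneous, and CpG sites in no-sequence mode sit on a
regular grid. Passing parameter-recovery tests therefore demonstrates
the correctness of the decision rules under their stated model — not
robustness to alignment artefacts, subclonality or impure samples.

Phase blocks on synthetic data come from *read connectivity*
(consecutive SNPs share a block iff a read spans both). This is not a
phasing algorithm — alleles are taken from truth — but it reproduces
the real dependence of block length on depth and read length: under
nested subsampling the block partition can only coarsen as reads are
added, so block N50 is non-decreasing in depth, the qualitative
saturation behaviour expected of long-read phasing.

Determinism: one integer seed fully determines a dataset; each
generator stage derives a fixed sub-seed so stages are independently
reproducible.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive internally and in VCF; BED output
  is 0-based half-open.
* Empty inputs return typed empty tables; undefined rates (no
  compared SNPs, no comparable pairs) are `NaN` with an explicit flag,
  never silently 0 or 1.
* At a tagging ratio of exactly 0.5 there is no majority haplotype and
  the read stays untagged regardless of thresholds.
* A zero spectrum has no cosine; the function warns and returns `NaN`.
* BH adjustment is `stats::p.adjust(method = "BH")` throughout.

# Problem sizes in the test-suite

The recovery suites run at sizes chosen to give stable Monte-Carlo
estimates while keeping the whole suite fast on one CPU: 20 seeds of
50-Mb genomes (five 10-Mb chromosomes) at 30× for biased-region
recovery; 20 seeds of 5-Mb genomes for chromothripsis recovery with a
50-Mb scattered negative control; 20 seeds for the methylation null
and the allele-specific expression power/false-positive suite (15
skewed + 15 balanced genes per seed at ~50× transcript coverage).
`scripts/acceptance.R` recomputes the same quantities at 10 seeds per
suite.

# Known limitations

* The DMR caller is plumbing, not a replacement for a dedicated
  caller; its run-splitting under sampling noise can fragment one true
  region into several DMRs (recovery is therefore judged by overlap
  and direction, not region counts).
* Mutation-pair ordering assumes the mutant-read sets are reliable;
  it does not model sequencing errors at the mutation site itself.
* Enrichment testing treats the callable length as uniformly mutable;
  no covariate correction (replication timing, chromatin) is applied.
* The two-haplotype assumption breaks in aneuploid or heavily
  rearranged regions; calls there inherit whatever the upstream CN
  segmentation says.
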