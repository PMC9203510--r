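#' Haplotag RNA reads
#'
#' Applies the same rule as genomic read tagging (at least 2 informative
#' SNP observations and a majority-haplotype ratio of at least 0.7) to
#' transcript reads.
#'
#' @param observations RNA read observations (`read_id`, `chrom`, `pos`,
#'   `allele`; extra columns such as `gene_id`, `tissue` are carried
#'   through per read).
#' @param snps phased SNP table.
#' @param min_snps,min_ratio see [tag_read()].
#' @return data.table as [tag_reads()].
#' @export
tag_rna_reads <- function(observations, snps, min_snps = 2L,
                          min_ratio = 0.7) {
  tag_reads(observations, snps, min_snps = min_snps,
            min_ratio = min_ratio)
}

#' Per-SNP allelic read counts from tagged RNA reads
#'
#' @param observations RNA observations with `read_id`, `gene_id`,
#'   `tissue`, `chrom`, `pos`.
#' @param tags output of [tag_rna_reads()].
#' @return data.table: `gene_id`, `tissue`, `chrom`, `pos`,
#'   `hp1_reads`, `hp2_reads` (one row per SNP per tissue).
#' @export
allelic_counts <- function(observations, tags) {
  obs <- as.data.table(observations)
  tg <- as.data.table(tags)[label %in% c("HP1", "HP2")]
  tg <- tg[order(read_id, -n_obs)][!duplicated(read_id)]
  m <- merge(obs, tg[, .(read_id, label)], by = "read_id")
  if (nrow(m) == 0L)
    return(data.table(gene_id = character(), tissue = character(),
                      chrom = character(), pos = integer(),
                      hp1_reads = integer(), hp2_reads = integer()))
  m[, .(hp1_reads = sum(label == "HP1"),
        hp2_reads = sum(label == "HP2")),
    by = .(gene_id, tissue, chrom, pos)]
}

#' Allele-specific expression tests at phased SNPs
#'
#' Per tissue, each SNP's haplotype-1 read count is tested against an
#' even 0.5 split with an exact two-sided binomial test, BH-adjusted
#' across SNPs of the tissue. A SNP is tumour-specific biased when it is
#' significant in the tumour and the normal tissue does not show a
#' significant bias toward the same haplotype. SNPs with fewer than
#' `min_total` tagged reads in a tissue are reported untested
#' (`low_coverage`). A per-gene verdict aggregates its SNPs by majority
#' direction (discordant significant SNPs flag the gene `mixed`). A
#' Fisher tumour-versus-normal contingency alternative is available.
#'
#' @param counts output of [allelic_counts()] for tumour and normal
#'   (rows distinguished by `tissue` in `{"tumor", "normal"}`).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param min_total minimum reads per SNP per tissue (default 10).
#' @param test `"binomial"` (per tissue versus 0.5, default) or
#'   `"fisher"` (tumour counts versus normal counts).
#' @return list with `snps` (per-SNP table: counts, `q_tumor`,
#'   `q_normal`, `tumor_biased_hap`, `normal_biased_hap`,
#'   `tumor_specific`, `status`) and `genes` (per-gene verdicts).
#' @export
allelic_expression_test <- function(counts, alpha = 0.05,
                                    min_total = 10L,
                                    test = c("binomial", "fisher")) {
  test <- match.arg(test)
  x <- dcast(as.data.table(counts), gene_id + chrom + pos ~ tissue,
             value.var = c("hp1_reads", "hp2_reads"), fill = 0L)
  for (col in c("hp1_reads_tumor", "hp2_reads_tumor",
                "hp1_reads_normal", "hp2_reads_normal"))
    if (!col %in% names(x)) x[, (col) := 0L]
  x[, `:=`(tot_tumor = hp1_reads_tumor + hp2_reads_tumor,
           tot_normal = hp1_reads_normal + hp2_reads_normal)]
  btest <- function(k, n) {
    if (n < min_total) return(NA_real_)
    binom.test(k, n, 0.5)$p.value
  }
  if (test == "binomial") {
    x[, p_tumor := mapply(btest, hp1_reads_tumor, tot_tumor)]
    x[, p_normal := mapply(btest, hp1_reads_normal, tot_normal)]
  } else {
    x[, p_tumor := mapply(function(a, b, c, d) {
      if (a + b < min_total || c + d < min_total) return(NA_real_)
      stats::fisher.test(matrix(c(a, b, c, d), 2L))$p.value
    }, hp1_reads_tumor, hp2_reads_tumor, hp1_reads_normal,
       hp2_reads_normal)]
    x[, p_normal := mapply(btest, hp1_reads_normal, tot_normal)]
  }
  x[, q_tumor := p.adjust(p_tumor, method = "BH")]
  x[, q_normal := p.adjust(p_normal, method = "BH")]
  dirn <- function(h1, tot) ifelse(h1 * 2L > tot, "HP1", "HP2")
  x[, tumor_biased_hap := ifelse(!is.na(q_tumor) & q_tumor < alpha,
                                 dirn(hp1_reads_tumor, tot_tumor),
                                 NA_character_)]
  x[, normal_biased_hap := ifelse(!is.na(q_normal) & q_normal < alpha,
                                  dirn(hp1_reads_normal, tot_normal),
                                  NA_character_)]
  x[, tumor_specific := !is.na(tumor_biased_hap) &
      (is.na(normal_biased_hap) | normal_biased_hap != tumor_biased_hap)]
  x[, status := ifelse(is.na(p_tumor), "low_coverage", "tested")]
  genes <- x[status == "tested",
             {
               sig <- !is.na(tumor_biased_hap)
               d <- tumor_biased_hap[sig]
               n1 <- sum(d == "HP1"); n2 <- sum(d == "HP2")
               verdict <- if (n1 + n2 == 0L) "unbiased"
                 else if (n1 > 0L && n2 > 0L) "mixed"
                 else if (n1 > 0L) "HP1" else "HP2"
               list(n_snps = .N, n_sig_tumor = sum(sig),
                    biased_hap = verdict,
                    tumor_specific = any(tumor_specific[sig]))
             }, by = gene_id]
  list(snps = x[], genes = genes)
}

#' Annotate regulatory candidate mutations
#'
#' A variant is a promoter candidate when it lies within `promoter_pad`
#' bp (default 1500) of a transcription start site, and an enhancer
#' candidate when it falls in a supplied enhancer interval — in both
#' cases only if its functional annotation is not exonic or UTR.
#'
#' @param variants variant table (`chrom`, `pos`, optionally `hap` and
#'   `annotation` — variants annotated `"exonic"`, `"5UTR"` or `"3UTR"`
#'   are excluded).
#' @param gene_model data.frame with `gene_id`, `chrom`, `tss`.
#' @param enhancers optional interval table (`chrom`, `start`, `end`).
#' @param promoter_pad promoter half-width in bp (default 1500).
#' @return data.table of candidates: variant columns plus `element`
#'   (`"promoter"`/`"enhancer"`) and `gene_id` (`NA` for enhancers not
#'   tied to a gene).
#' @export
annotate_regulatory <- function(variants, gene_model, enhancers = NULL,
                                promoter_pad = 1500L) {
  if (is.null(gene_model)) stop("gene_model is required", call. = FALSE)
  v <- as.data.table(variants)
  g <- as.data.table(gene_model)
  if (!"annotation" %in% names(v)) v[, annotation := NA_character_]
  excluded <- v$annotation %in% c("exonic", "5UTR", "3UTR")
  v_ok <- v[!excluded]
  out <- list()
  if (nrow(v_ok)) {
    pm <- g[, .(chrom, start = tss - promoter_pad, end = tss + promoter_pad,
                gene_id)]
    setkey(pm, chrom, start, end)
    q <- v_ok[, .(chrom, start = pos, end = pos, pos,
                  hap = if ("hap" %in% names(v_ok)) hap else NA_character_)]
    setkey(q, chrom, start, end)
    hits <- foverlaps(q, pm, nomatch = NULL)
    if (nrow(hits))
      out$promoter <- hits[, .(chrom, pos, hap, gene_id,
                               element = "promoter")]
    if (!is.null(enhancers)) {
      en <- as.data.table(enhancers)[, .(chrom, start, end)]
      setkey(en, chrom, start, end)
      ehits <- foverlaps(q, en, nomatch = NULL)
      # promoter assignment wins for a variant in both element types
      if (nrow(hits))
        ehits <- ehits[!paste(chrom, pos) %in%
                         hits[, paste(chrom, pos)]]
      if (nrow(ehits))
        out$enhancer <- ehits[, .(chrom, pos, hap,
                                  gene_id = NA_character_,
                                  element = "enhancer")]
    }
  }
  if (length(out) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      hap = character(), gene_id = character(),
                      element = character()))
  rbindlist(out, use.names = TRUE)
}

#' Link expression bias to regulatory mutations and DMR-biased blocks
#'
#' Joins per-gene expression-bias verdicts with regulatory candidate
#' mutations (on gene identity) and DMR-biased phase blocks (on block
#' identity when supplied), flagging haplotype concordance — e.g. a
#' promoter mutation on the same haplotype that is over-expressed.
#'
#' @param gene_bias per-gene table from [allelic_expression_test()].
#' @param candidates output of [annotate_regulatory()].
#' @param dmr_blocks optional [dmr_bias_blocks()] output.
#' @param gene_blocks optional data.frame mapping `gene_id` to
#'   `block_id` (needed for the DMR join).
#' @return data.table: one row per biased gene with `regulatory_hap`,
#'   `regulatory_concordant`, `dmr_direction`, `dmr_concordant`.
#' @export
link_bias_to_regulation <- function(gene_bias, candidates,
                                    dmr_blocks = NULL,
                                    gene_blocks = NULL) {
  gb <- as.data.table(gene_bias)[biased_hap %in% c("HP1", "HP2")]
  if (nrow(gb) == 0L)
    return(data.table(gene_id = character(), biased_hap = character(),
                      element = character(), regulatory_hap = character(),
                      regulatory_concordant = logical(),
                      dmr_direction = character(),
                      dmr_concordant = logical()))
  cand <- as.data.table(candidates)
  res <- lapply(seq_len(nrow(gb)), function(i) {
    g <- gb[i]
    cg <- if (nrow(cand)) cand[gene_id == g$gene_id] else cand
    element <- if (nrow(cg)) cg$element[1] else NA_character_
    rhap <- if (nrow(cg)) cg$hap[1] else NA_character_
    dmr_dir <- NA_character_
    if (!is.null(dmr_blocks) && !is.null(gene_blocks)) {
      blk <- as.data.table(gene_blocks)[gene_id == g$gene_id]
      if (nrow(blk)) {
        db <- as.data.table(dmr_blocks)[block_id %in% blk$block_id]
        if (nrow(db)) dmr_dir <- db$major_direction[1]
      }
    }
    # hypomethylation on the over-expressed haplotype is concordant
    dmr_conc <- if (is.na(dmr_dir)) NA else
      (dmr_dir == "hp1_hypo") == (g$biased_hap == "HP1")
    data.table(gene_id = g$gene_id, biased_hap = g$biased_hap,
               element = element, regulatory_hap = rhap,
               regulatory_concordant = if (is.na(rhap)) NA
                 else rhap == g$biased_hap,
               dmr_direction = dmr_dir, dmr_concordant = dmr_conc)
  })
  rbindlist(res)
}

#' Overlap of phasing A/G SNPs with an RNA-editing catalogue
#'
#' Fraction of A/G (or T/C, the reverse-strand equivalent)
#' heterozygous SNPs that coincide with catalogued A-to-I editing
#' positions — a check that editing sites are not confounding
#' RNA-based haplotype assignment.
#'
#' @param snps phased SNP table (`chrom`, `pos`, `ref`, `alt`).
#' @param catalog editing-site table (`chrom`, `pos`).
#' @return list: `fraction`, `n_ag_snps`, `n_overlap`.
#' @export
rna_editing_overlap <- function(snps, catalog) {
  s <- as.data.table(snps)
  ag <- s[(ref == "A" & alt == "G") | (ref == "T" & alt == "C")]
  cat_dt <- as.data.table(catalog)
  if (nrow(cat_dt) == 0L) {
    warning("empty editing catalogue")
    return(list(fraction = 0, n_ag_snps = nrow(ag), n_overlap = 0L))
  }
  n_ov <- nrow(merge(ag[, .(chrom, pos)], unique(cat_dt[, .(chrom, pos)]),
                     by = c("chrom", "pos")))
  list(fraction = if (nrow(ag)) n_ov / nrow(ag) else 0,
       n_ag_snps = nrow(ag), n_overlap = n_ov)
}
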