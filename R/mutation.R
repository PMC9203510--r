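#' Haplotype assignment of a somatic SNV/indel from mutant-read counts
#'
#' A haplotype is assigned when `min_mut` (default 3) or more mutant
#' reads are tagged to one haplotype and at most `max_other` (default 1)
#' to the other; otherwise the variant stays `"unknown"`.
#'
#' @param hp1_mut,hp2_mut numbers of mutant (alt-carrying) reads tagged
#'   HP1 / HP2. Vectorised.
#' @param min_mut,max_other rule thresholds.
#' @return character vector: `"HP1"`, `"HP2"` or `"unknown"`.
#' @export
assign_snv_haplotype <- function(hp1_mut, hp2_mut, min_mut = 3L,
                                 max_other = 1L) {
  out <- rep("unknown", length(hp1_mut))
  out[hp1_mut >= min_mut & hp2_mut <= max_other] <- "HP1"
  out[hp2_mut >= min_mut & hp1_mut <= max_other] <- "HP2"
  out
}

#' Phase somatic SNVs from haplotagged mutant reads
#'
#' Joins each variant's mutant reads to the read haplotags and applies
#' the assignment rule of [assign_snv_haplotype()]. Variants with no
#' covering mutant read are reported `"unknown"` with reason
#' `"no_coverage"`.
#'
#' @param variants data.frame of somatic variants (`id`, `chrom`, `pos`,
#'   `ref`, `alt`, `vaf`, ...).
#' @param mutant_reads data.frame linking variants to the reads carrying
#'   the mutant allele (`snv_id`, `read_id`).
#' @param tags haplotag table from [tag_reads()].
#' @param min_mut,max_other rule thresholds (defaults 3 and 1).
#' @param min_vaf optional VAF filter: variants below it are not
#'   assigned (default `NULL`, no filter).
#' @return the variant table with `mut_hp1`, `mut_hp2`, `hap`,
#'   `block_id` and `reason` columns added.
#' @export
phase_snvs <- function(variants, mutant_reads, tags, min_mut = 3L,
                       max_other = 1L, min_vaf = NULL) {
  v <- as.data.table(variants)
  mr <- as.data.table(mutant_reads)
  tg <- as.data.table(tags)[label %in% c("HP1", "HP2")]
  if (nrow(mr) && nrow(tg)) {
    j <- merge(mr, tg[, .(read_id, block_id, label)], by = "read_id",
               allow.cartesian = TRUE)
    cnt <- j[, .(mut_hp1 = sum(label == "HP1"),
                 mut_hp2 = sum(label == "HP2"),
                 block_id = block_id[1]), by = snv_id]
  } else {
    cnt <- data.table(snv_id = character(), mut_hp1 = integer(),
                      mut_hp2 = integer(), block_id = character())
  }
  out <- merge(v, cnt, by.x = "id", by.y = "snv_id", all.x = TRUE)
  covered <- out$id %in% mr$snv_id
  out[is.na(mut_hp1), `:=`(mut_hp1 = 0L, mut_hp2 = 0L)]
  out[, hap := assign_snv_haplotype(mut_hp1, mut_hp2, min_mut, max_other)]
  if (!is.null(min_vaf)) out[vaf < min_vaf, hap := "unknown"]
  out[, reason := ifelse(hap != "unknown", "",
                         ifelse(covered, "rule_not_met", "no_coverage"))]
  out[hap == "unknown", block_id := NA_character_]
  setkey(out, chrom, pos)
  out[]
}

#' Phase a structural variant from its tagged supporting reads
#'
#' A "phased SV" requires at least `min_reads` (default 3) supporting
#' reads that are themselves haplotagged, with the majority haplotype
#' holding at least `min_ratio` (default 0.7, boundary inclusive) of
#' them. SVs outside chromosomes chr1-chr22 are excluded from phasing.
#' A read is counted once even when several alignment segments of it
#' support the SV.
#'
#' @param svs data.frame of SV calls with `sv_id`, `chrom1`, `pos1`,
#'   `dir1`, `chrom2`, `pos2`, `dir2`, `type` and comma-separated
#'   `read_ids` of supporting reads.
#' @param tags haplotag table from [tag_reads()].
#' @param min_reads,min_ratio rule thresholds.
#' @return the SV table with `n_hp1`, `n_hp2`, `hap` and `block_id`
#'   columns added.
#' @export
phase_svs <- function(svs, tags, min_reads = 3L, min_ratio = 0.7) {
  s <- as.data.table(svs)
  tg <- as.data.table(tags)[label %in% c("HP1", "HP2")]
  # one label per read: a read spanning two blocks keeps the block with
  # most observations
  tg <- tg[order(read_id, -n_obs)][!duplicated(read_id)]
  autosomes <- paste0("chr", 1:22)
  res <- lapply(seq_len(nrow(s)), function(i) {
    ids <- unique(strsplit(s$read_ids[i] %||% "", ",", fixed = TRUE)[[1]])
    ids <- ids[nzchar(ids)]
    t <- tg[read_id %in% ids]
    h1 <- sum(t$label == "HP1"); h2 <- sum(t$label == "HP2")
    hap <- "unknown"
    if (s$chrom1[i] %in% autosomes && s$chrom2[i] %in% autosomes &&
        (h1 + h2) >= min_reads && h1 != h2 &&
        max(h1, h2) / (h1 + h2) >= min_ratio)
      hap <- if (h1 > h2) "HP1" else "HP2"
    blk <- if (hap != "unknown") t$block_id[t$label == hap][1]
           else NA_character_
    data.table(n_hp1 = h1, n_hp2 = h2, hap = hap, block_id = blk)
  })
  cbind(s, rbindlist(res))
}

#' Temporal ordering of somatic mutation pairs from co-spanning reads
#'
#' For every pair of variants co-spanned by at least one read, spanning
#' reads are classified into the four patterns `neither`, `A_only`,
#' `B_only`, `both`. A pair is ordered "A before B" when the `both` and
#' `A_only` patterns each have at least `min_reads` supporting reads and
#' `B_only` has none (the mutation observed alone must be the earlier
#' one). Pairs with both single-mutant patterns supported are flagged
#' `conflicting` (parallel clones); pairs with only `neither`/`both`
#' are `co_occurring` (unordered). Pairs farther apart than the reads
#' never enter the analysis (no spanning read exists).
#'
#' @param variants somatic variant table (`id`, `chrom`, `pos`).
#' @param mutant_reads table of (`snv_id`, `read_id`) for reads carrying
#'   each variant's mutant allele.
#' @param reads read table (`read_id`, `chrom`, `start`, `end`) used to
#'   find reads spanning both positions of a pair.
#' @param min_reads support threshold per pattern (default 2).
#' @return data.table with one row per co-spanned pair: positions,
#'   pattern counts, and `verdict` in
#'   `{"A_before_B", "B_before_A", "co_occurring", "conflicting",
#'   "unresolved"}`.
#' @export
order_mutation_pairs <- function(variants, mutant_reads, reads,
                                 min_reads = 2L) {
  v <- as.data.table(variants)
  mr <- as.data.table(mutant_reads)
  rd <- as.data.table(reads)
  out <- list()
  for (ch in unique(v$chrom)) {
    vc <- v[chrom == ch][order(pos)]
    if (nrow(vc) < 2L) next
    rc <- rd[chrom == ch]
    if (nrow(rc) == 0L) next
    max_len <- max(rc$end - rc$start + 1L)
    for (i in seq_len(nrow(vc) - 1L)) for (j in (i + 1L):nrow(vc)) {
      if (vc$pos[j] - vc$pos[i] + 1L > max_len) break
      span <- rc[start <= vc$pos[i] & end >= vc$pos[j]]
      if (nrow(span) == 0L) next
      a_ids <- mr[snv_id == vc$id[i], read_id]
      b_ids <- mr[snv_id == vc$id[j], read_id]
      has_a <- span$read_id %in% a_ids
      has_b <- span$read_id %in% b_ids
      n <- c(neither = sum(!has_a & !has_b),
             a_only = sum(has_a & !has_b),
             b_only = sum(!has_a & has_b),
             both = sum(has_a & has_b))
      verdict <- if (n["a_only"] >= min_reads && n["b_only"] >= min_reads)
        "conflicting"
      else if (n["both"] >= min_reads && n["a_only"] >= min_reads &&
               n["b_only"] == 0L) "A_before_B"
      else if (n["both"] >= min_reads && n["b_only"] >= min_reads &&
               n["a_only"] == 0L) "B_before_A"
      else if (n["both"] >= min_reads && n["a_only"] == 0L &&
               n["b_only"] == 0L) "co_occurring"
      else "unresolved"
      out[[length(out) + 1L]] <- data.table(
        chrom = ch, id_a = vc$id[i], pos_a = vc$pos[i],
        id_b = vc$id[j], pos_b = vc$pos[j],
        n_neither = n[["neither"]], n_a_only = n[["a_only"]],
        n_b_only = n[["b_only"]], n_both = n[["both"]],
        verdict = verdict)
    }
  }
  if (length(out) == 0L)
    return(data.table(chrom = character(), id_a = character(),
                      pos_a = integer(), id_b = character(),
                      pos_b = integer(), n_neither = integer(),
                      n_a_only = integer(), n_b_only = integer(),
                      n_both = integer(), verdict = character()))
  rbindlist(out)
}
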