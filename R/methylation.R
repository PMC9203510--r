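#' Per-site, per-haplotype CpG methylation frequencies
#'
#' Aggregates per-read CpG calls by haplotype. A site reports a
#' frequency for a haplotype only when covered by at least `min_reads`
#' tagged reads of that haplotype; calls on untagged reads are retained
#' in the input but never enter a frequency.
#'
#' @param calls data.frame of per-read calls: `read_id`, `chrom`,
#'   `cpg_pos`, `methylated` (0/1).
#' @param tags haplotag table from [tag_reads()] (or any table with
#'   `read_id`, `label`).
#' @param min_reads minimum reads per (site, haplotype) (default 3).
#' @return data.table: `chrom`, `cpg_pos`, `freq_hp1`, `freq_hp2`,
#'   `n_hp1`, `n_hp2` (frequencies `NA` where coverage is insufficient).
#' @export
haplotype_methylation_frequency <- function(calls, tags, min_reads = 3L) {
  cl <- as.data.table(calls)
  tg <- as.data.table(tags)[label %in% c("HP1", "HP2")]
  tg <- tg[order(read_id, -n_obs)][!duplicated(read_id)]
  m <- merge(cl, tg[, .(read_id, label)], by = "read_id")
  if (nrow(m) == 0L)
    return(data.table(chrom = character(), cpg_pos = integer(),
                      freq_hp1 = numeric(), freq_hp2 = numeric(),
                      n_hp1 = integer(), n_hp2 = integer()))
  agg <- m[, .(n_meth = sum(methylated), n_total = .N),
           by = .(chrom, cpg_pos, label)]
  wide <- dcast(agg, chrom + cpg_pos ~ label,
                value.var = c("n_meth", "n_total"), fill = 0L)
  for (col in c("n_meth_HP1", "n_meth_HP2", "n_total_HP1", "n_total_HP2"))
    if (!col %in% names(wide)) wide[, (col) := 0L]
  wide[, freq_hp1 := ifelse(n_total_HP1 >= min_reads,
                            n_meth_HP1 / n_total_HP1, NA_real_)]
  wide[, freq_hp2 := ifelse(n_total_HP2 >= min_reads,
                            n_meth_HP2 / n_total_HP2, NA_real_)]
  out <- wide[, .(chrom, cpg_pos, freq_hp1, freq_hp2,
                  n_hp1 = n_total_HP1, n_hp2 = n_total_HP2)]
  setorder(out, chrom, cpg_pos)
  out[]
}

#' Call differentially methylated regions between haplotypes
#'
#' A deliberately minimal DMR caller: maximal runs of at least
#' `min_cpgs` consecutive CpG sites (sites where both haplotypes have a
#' frequency) with a per-site between-haplotype difference of at least
#' `min_diff` in a consistent direction. Each run is tested with a
#' Mann-Whitney test of the per-site frequencies of the two haplotypes,
#' BH-adjusted across runs. Externally produced DMR tables (e.g. from a
#' dedicated caller such as metilene) with columns `chrom`, `start`,
#' `end`, `direction` can be used anywhere a DMR table is accepted.
#'
#' @param freqs frequency table from [haplotype_methylation_frequency()].
#' @param min_cpgs minimum consecutive CpGs (default 5).
#' @param min_diff minimum absolute per-site frequency difference
#'   (default 0.3).
#' @param q_alpha BH-adjusted significance threshold (default 0.05).
#' @return data.table of DMRs: `chrom`, `start`, `end`, `n_cpgs`,
#'   `mean_freq_hp1`, `mean_freq_hp2`, `direction`
#'   (`"hp1_hypo"`/`"hp2_hypo"`), `p_value`, `q_value`.
#' @export
call_dmrs <- function(freqs, min_cpgs = 5L, min_diff = 0.3,
                      q_alpha = 0.05) {
  f <- as.data.table(freqs)
  f <- f[!is.na(freq_hp1) & !is.na(freq_hp2)]
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      mean_freq_hp1 = numeric(), mean_freq_hp2 = numeric(),
                      direction = character(), p_value = numeric(),
                      q_value = numeric())
  if (nrow(f) == 0L) return(empty)
  setorder(f, chrom, cpg_pos)
  f[, diffsign := sign(freq_hp1 - freq_hp2) *
      as.integer(abs(freq_hp1 - freq_hp2) >= min_diff)]
  runs <- list()
  for (ch in unique(f$chrom)) {
    fc <- f[chrom == ch]
    r <- rle(fc$diffsign)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (r$values[k] == 0 || r$lengths[k] < min_cpgs) next
      i <- starts[k]:ends[k]
      pv <- suppressWarnings(
        wilcox.test(fc$freq_hp1[i], fc$freq_hp2[i], exact = FALSE)$p.value)
      runs[[length(runs) + 1L]] <- data.table(
        chrom = ch, start = fc$cpg_pos[starts[k]],
        end = fc$cpg_pos[ends[k]], n_cpgs = r$lengths[k],
        mean_freq_hp1 = mean(fc$freq_hp1[i]),
        mean_freq_hp2 = mean(fc$freq_hp2[i]),
        direction = if (r$values[k] < 0) "hp1_hypo" else "hp2_hypo",
        p_value = pv)
    }
  }
  if (length(runs) == 0L) return(empty)
  d <- rbindlist(runs)
  d[, q_value := p.adjust(p_value, method = "BH")]
  d[q_value < q_alpha][]
}

#' Phase blocks with haplotype-biased DMRs
#'
#' Flags phase blocks in which the between-haplotype DMRs pile up in one
#' direction. Tumour DMRs whose overlap with any matched-normal DMR
#' exceeds `normal_overlap` of the tumour DMR's length are excluded
#' first. A block is reported when all three conditions hold: (i) the
#' maximum number of DMRs in the same direction is at least `min_dmrs`;
#' (ii) that count is at least `min_ratio` of the block's DMRs; (iii)
#' that count per Mb of block length is at least `min_per_mb`.
#'
#' @param dmrs tumour DMR table ([call_dmrs()] output or equivalent).
#' @param normal_dmrs matched-normal DMR table (may be empty/`NULL`).
#' @param blocks phase block table from [phased_blocks()].
#' @param min_dmrs,min_ratio,min_per_mb the three conditions
#'   (defaults 3, 0.7, 3).
#' @param normal_overlap overlap fraction (of the tumour DMR) above
#'   which a tumour DMR is discarded (default 0.2).
#' @return data.table of reported blocks: `block_id`, `block_length`,
#'   `n_dmrs_total`, `n_dmrs_major_direction`, `major_direction`,
#'   `dmrs_per_mb`.
#' @export
dmr_bias_blocks <- function(dmrs, normal_dmrs, blocks, min_dmrs = 3L,
                            min_ratio = 0.7, min_per_mb = 3,
                            normal_overlap = 0.2) {
  d <- as.data.table(dmrs)
  b <- as.data.table(blocks)
  empty <- data.table(block_id = character(), block_length = integer(),
                      n_dmrs_total = integer(),
                      n_dmrs_major_direction = integer(),
                      major_direction = character(),
                      dmrs_per_mb = numeric())
  if (nrow(d) == 0L || nrow(b) == 0L) return(empty)
  if (!is.null(normal_dmrs) && nrow(as.data.table(normal_dmrs))) {
    nd <- as.data.table(normal_dmrs)[, .(chrom, start, end)]
    setkey(nd, chrom, start, end)
    dk <- copy(d); setkey(dk, chrom, start, end)
    ov <- foverlaps(dk, nd, nomatch = NULL)
    if (nrow(ov)) {
      ov[, overlap_bp := pmin(i.end, end) - pmax(i.start, start) + 1L]
      drop <- ov[overlap_bp / (i.end - i.start + 1L) > normal_overlap,
                 unique(paste(chrom, i.start, i.end))]
      d <- d[!paste(chrom, start, end) %in% drop]
    }
  }
  if (nrow(d) == 0L) return(empty)
  # assign each DMR to the phase block it overlaps most
  bk <- b[, .(chrom, start, end, block_id)]
  setkey(bk, chrom, start, end)
  dk <- copy(d); setkey(dk, chrom, start, end)
  ov <- foverlaps(dk, bk, nomatch = NULL)
  if (nrow(ov) == 0L) return(empty)
  ov[, overlap_bp := pmin(i.end, end) - pmax(i.start, start) + 1L]
  setorder(ov, chrom, i.start, -overlap_bp)
  ov <- ov[!duplicated(paste(chrom, i.start, i.end))]
  res <- ov[, {
    n1 <- sum(direction == "hp1_hypo"); n2 <- sum(direction == "hp2_hypo")
    nmax <- max(n1, n2)
    len <- b[block_id == .BY[[1]], end - start][1]
    list(block_length = len, n_dmrs_total = .N,
         n_dmrs_major_direction = nmax,
         major_direction = if (n1 >= n2) "hp1_hypo" else "hp2_hypo",
         dmrs_per_mb = nmax / (len / 1e6))
  }, by = block_id]
  res[n_dmrs_major_direction >= min_dmrs &
        n_dmrs_major_direction / n_dmrs_total >= min_ratio &
        dmrs_per_mb >= min_per_mb][]
}
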