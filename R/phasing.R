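#' Read phased heterozygous SNPs from a VCF
#'
#' Parses a VCF 4.x file with phased genotypes (`GT` like `0|1`) and
#' phase-set (`PS`) FORMAT fields, keeping only phased heterozygous SNPs.
#' Blocks are keyed by `(chrom, PS)`. When the `vcfR` package is
#' installed it is used for parsing; a built-in parser of the same
#' dialect is the fallback.
#'
#' @param path VCF file (plain text).
#' @param sample sample column index to use (default first).
#' @return data.table with columns `chrom`, `pos`, `ref`, `alt`,
#'   `hp1_allele`, `hp2_allele`, `block_id`. Haplotype 1 is the allele
#'   left of the `|` separator. An empty table (with a warning) results
#'   when no phased heterozygous SNP is present.
#' @export
read_phased_vcf <- function(path, sample = 1L) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    warning("no records in VCF: ", path)
    return(empty_snp_table())
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  ncol_min <- 9L + sample
  rec <- lapply(seq_along(f), function(i) {
    x <- f[[i]]
    if (length(x) < ncol_min)
      stop("malformed VCF record at data line ", i, ": fewer than ",
           ncol_min, " columns", call. = FALSE)
    fmt <- strsplit(x[9L], ":", fixed = TRUE)[[1]]
    smp <- strsplit(x[9L + sample], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i) || gt_i > length(smp))
      stop("malformed VCF record at data line ", i, ": no GT field",
           call. = FALSE)
    gt <- smp[gt_i]
    ps_i <- match("PS", fmt)
    ps <- if (!is.na(ps_i) && ps_i <= length(smp)) smp[ps_i] else NA
    list(chrom = x[1L], pos = as.integer(x[2L]), ref = x[4L],
         alt = x[5L], gt = gt, ps = ps)
  })
  d <- rbindlist(rec)
  # phased het SNPs only: single-base ref/alt, GT a|b with a != b
  phased <- grepl("^[0-9]+\\|[0-9]+$", d$gt)
  keep <- phased & nchar(d$ref) == 1L & nchar(d$alt) == 1L
  a1 <- suppressWarnings(as.integer(sub("\\|.*", "", d$gt)))
  a2 <- suppressWarnings(as.integer(sub(".*\\|", "", d$gt)))
  keep <- keep & !is.na(a1) & !is.na(a2) & (a1 != a2) &
    (a1 <= 1L) & (a2 <= 1L)
  if (!any(keep)) {
    warning("no phased heterozygous SNPs in VCF: ", path)
    return(empty_snp_table())
  }
  d <- d[keep]; a1 <- a1[keep]; a2 <- a2[keep]
  out <- d[, .(chrom, pos, ref, alt)]
  out[, hp1_allele := ifelse(a1 == 1L, alt, ref)]
  out[, hp2_allele := ifelse(a2 == 1L, alt, ref)]
  out[, block_id := ifelse(is.na(d$ps), paste0(chrom, "_nops"),
                           paste0(chrom, "_", d$ps))]
  setkey(out, chrom, pos)
  out[]
}

empty_snp_table <- function() {
  data.table(chrom = character(), pos = integer(), ref = character(),
             alt = character(), hp1_allele = character(),
             hp2_allele = character(), block_id = character())
}

#' Write phased SNPs to a VCF
#'
#' Emits a minimal VCF 4.2 with phased `GT` and integer `PS` fields
#' (phase set = smallest SNP position of the block), the dialect
#' [read_phased_vcf()] consumes.
#'
#' @param snps phased SNP table.
#' @param path output file.
#' @param sample_name sample column header.
#' @export
write_phased_vcf <- function(snps, path, sample_name = "SAMPLE") {
  snps <- as.data.table(snps)
  setorder(snps, chrom, pos)
  gt <- ifelse(snps$hp1_allele == snps$alt, "1|0", "0|1")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_name))
  ps_by_block <- snps[, .(ps = min(pos)), by = block_id]
  ps_val <- ps_by_block[match(snps$block_id, block_id), ps]
  rows <- paste(snps$chrom, snps$pos, ".", snps$ref, snps$alt, ".",
                "PASS", ".", "GT:PS", paste0(gt, ":", ps_val), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Summarise phased blocks
#'
#' Groups a phased SNP table into blocks. Blocks with a single SNP are
#' counted separately (attribute `n_singletons`), matching the convention
#' that singletons are not phase blocks.
#'
#' @param snps phased SNP table (as from [read_phased_vcf()]).
#' @return data.table with `chrom`, `block_id`, `start`, `end`,
#'   `length_bp`, `n_snps`, sorted by position.
#' @export
phased_blocks <- function(snps) {
  snps <- as.data.table(snps)
  b <- snps[, .(chrom = chrom[1], start = min(pos), end = max(pos),
                n_snps = .N), by = block_id]
  n_singletons <- sum(b$n_snps < 2L)
  b <- b[n_snps >= 2L]
  b[, length_bp := end - start]
  setorder(b, chrom, start)
  setattr(b, "n_singletons", n_singletons)
  b[]
}

#' Phasing block statistics
#'
#' Computes block count, N50/median/maximum block length, the number and
#' fraction of phased heterozygous SNPs, and window-level phasing
#' coverage: per `window` bp the fraction of heterozygous SNPs that are
#' phased, with windows classified as high (`> hi`) or low (`< lo`)
#' coverage. `genome_coverage` is the fraction of windows (containing at
#' least one het SNP) in the high class.
#'
#' @param blocks block table from [phased_blocks()].
#' @param het_snps optional table of all heterozygous SNPs with columns
#'   `chrom`, `pos`, `phased` (logical); enables `phased_fraction` and
#'   window coverage.
#' @param window window size in bp (default 1 Mb).
#' @param hi,lo coverage classification thresholds (defaults 0.75 / 0.25).
#' @return list of class `block_stats`: `n_blocks`, `n50_length`,
#'   `median_length`, `max_length`, `n_phased_snps`, `phased_fraction`,
#'   `genome_coverage`, and the per-window table `windows`.
#' @export
block_stats <- function(blocks, het_snps = NULL, window = 1e6,
                        hi = 0.75, lo = 0.25) {
  blocks <- as.data.table(blocks)
  out <- list(
    n_blocks = nrow(blocks),
    n50_length = if (nrow(blocks)) n50(blocks$length_bp) else 0,
    median_length = if (nrow(blocks)) median(blocks$length_bp) else 0,
    max_length = if (nrow(blocks)) max(blocks$length_bp) else 0,
    n_phased_snps = sum(blocks$n_snps),
    phased_fraction = NA_real_, genome_coverage = NA_real_,
    windows = NULL)
  if (!is.null(het_snps)) {
    h <- as.data.table(het_snps)
    out$phased_fraction <- mean(h$phased)
    w <- h[, .(n_het = .N, n_phased = sum(phased)),
           by = .(chrom, window_start = (pos - 1L) %/% window * window + 1L)]
    w[, `:=`(window_end = window_start + window - 1L,
             coverage = n_phased / n_het)]
    w[, class := ifelse(coverage > hi, "high",
                        ifelse(coverage < lo, "low", "mid"))]
    out$genome_coverage <- mean(w$coverage > hi)
    out$windows <- w[]
  }
  class(out) <- "block_stats"
  out
}

#' @export
print.block_stats <- function(x, ...) {
  cat("Phased block statistics\n")
  cat(sprintf("  blocks: %d  (N50 %s bp, median %s, max %s)\n",
              x$n_blocks, format(x$n50_length, big.mark = ","),
              format(x$median_length, big.mark = ","),
              format(x$max_length, big.mark = ",")))
  cat(sprintf("  phased SNPs: %d", x$n_phased_snps))
  if (!is.na(x$phased_fraction))
    cat(sprintf("  (%.1f%% of het SNPs)", 100 * x$phased_fraction))
  cat("\n")
  if (!is.na(x$genome_coverage))
    cat(sprintf("  high-coverage windows: %.2f\n", x$genome_coverage))
  invisible(x)
}

# Minimal-cost switch/flip decomposition of one compared segment.
# `agree` is the per-SNP agreement vector under the HP1<->HP1 pairing.
# Operations: a flip toggles one SNP; a switch toggles the suffix from
# some SNP >= 2 onwards; the global orientation (suffix from SNP 1) is
# free. Minimises (switches + flips), ties broken toward fewer flips,
# then toward the identity orientation. Dynamic program over positions
# with the current suffix-toggle parity as state.
decompose_segment <- function(agree) {
  d <- as.integer(!agree)
  n <- length(d)
  if (n == 0L) return(c(n_switch = 0L, n_flip = 0L))
  INF <- c(1e9, 1e9)
  better <- function(a, b) {
    # lexicographic on (total cost, flips)
    if (sum(a) != sum(b)) sum(a) < sum(b) else a[2] < b[2]
  }
  run_dp <- function(p0) {
    best <- list(INF, INF)          # best[[parity + 1]] = c(sw, fl)
    best[[p0 + 1L]] <- c(0, 0)
    for (j in seq_len(n)) {
      if (j > 1L) {                 # optional switch before SNP j
        for (p in 0:1) {
          cand <- best[[(1L - p) + 1L]] + c(1, 0)
          if (better(cand, best[[p + 1L]])) best[[p + 1L]] <- cand
        }
      }
      for (p in 0:1)                # flip if still discordant
        if (d[j] != p)
          best[[p + 1L]] <- best[[p + 1L]] + c(0, 1)
    }
    if (better(best[[1]], best[[2]])) best[[1]] else best[[2]]
  }
  r0 <- run_dp(0L)
  r1 <- run_dp(1L)
  r <- if (better(r1, r0)) r1 else r0   # tie -> identity orientation
  c(n_switch = as.integer(r[1]), n_flip = as.integer(r[2]))
}

#' Compare two phasings of the same SNPs (switch/flip discrepancies)
#'
#' Restricted to SNPs phased in both inputs with the same ref/alt pair,
#' grouped into segments by the pair of block identifiers, and computed
#' per chromosome. Within each segment the relative orientation sequence
#' is decomposed into the minimal-cost explanation by flip errors (one
#' SNP assigned to the other haplotype) and switch errors (the haplotype
#' switches to the other from some SNP onward); the global orientation of
#' a segment is arbitrary and chosen to minimise the cost. Ties between
#' equal-cost explanations are broken toward fewer flips.
#'
#' @param a,b phased SNP tables (as from [read_phased_vcf()]).
#' @return list of class `discrepancy_report` with `total` (a one-row
#'   data.table: `n_compared_snps`, `n_compared_pairs`, `n_switch`,
#'   `n_flip`, `discrepancy_rate` over compared SNPs, and
#'   `discrepancy_rate_pairs` over consecutive pairs) and `by_chrom`.
#'   With no shared phased SNPs the counts are zero and the rates `NaN`.
#' @export
compare_phasings <- function(a, b) {
  a <- as.data.table(a); b <- as.data.table(b)
  m <- merge(a, b, by = c("chrom", "pos"), suffixes = c("_a", "_b"))
  m <- m[ref_a == ref_b & alt_a == alt_b]
  res <- if (nrow(m) == 0L) {
    data.table(chrom = character(), n_compared_snps = integer(),
               n_compared_pairs = integer(), n_switch = integer(),
               n_flip = integer())
  } else {
    setorder(m, chrom, pos)
    m[, segment_id := paste(block_id_a, block_id_b, sep = "~")]
    segs <- m[, {
      if (.N < 2L) {
        list(n_compared_snps = 0L, n_compared_pairs = 0L,
             n_switch = 0L, n_flip = 0L)
      } else {
        dec <- decompose_segment(hp1_allele_a == hp1_allele_b)
        list(n_compared_snps = .N, n_compared_pairs = .N - 1L,
             n_switch = dec[["n_switch"]], n_flip = dec[["n_flip"]])
      }
    }, by = .(chrom, segment_id)]
    segs[, .(n_compared_snps = sum(n_compared_snps),
             n_compared_pairs = sum(n_compared_pairs),
             n_switch = sum(n_switch), n_flip = sum(n_flip)),
         by = chrom]
  }
  tot <- res[, .(n_compared_snps = sum(n_compared_snps),
                 n_compared_pairs = sum(n_compared_pairs),
                 n_switch = sum(n_switch), n_flip = sum(n_flip))]
  if (nrow(tot) == 0L)
    tot <- data.table(n_compared_snps = 0L, n_compared_pairs = 0L,
                      n_switch = 0L, n_flip = 0L)
  add_rates <- function(x) {
    x[, discrepancy_rate := (n_switch + n_flip) / n_compared_snps]
    x[, discrepancy_rate_pairs := (n_switch + n_flip) / n_compared_pairs]
    x[]
  }
  out <- list(total = add_rates(tot), by_chrom = add_rates(res))
  class(out) <- "discrepancy_report"
  out
}

#' @export
print.discrepancy_report <- function(x, ...) {
  t <- x$total
  cat(sprintf(
    "Phasing comparison: %d SNPs compared, %d switch + %d flip errors\n",
    t$n_compared_snps, t$n_switch, t$n_flip))
  if (is.finite(t$discrepancy_rate))
    cat(sprintf("  discrepancy rate: %.3f%% (per SNP), %.3f%% (per pair)\n",
                100 * t$discrepancy_rate, 100 * t$discrepancy_rate_pairs))
  else cat("  discrepancy rate undefined (no shared phased SNPs)\n")
  invisible(x)
}

#' Concordance of consecutive-SNP phase relations against a panel
#'
#' For every pair of consecutive phased heterozygous SNPs that lie in the
#' same block of `query` and are both phased in `panel`, the relative
#' phase (whether the alternate alleles are cis or trans) is compared.
#' Only consecutive-pair relations are used: with chromosome-scale panel
#' haplotypes (e.g. from statistical phasing of a cohort) but block-wise
#' query haplotypes, the haplotype numbering is only meaningful within a
#' block.
#'
#' @param query phased SNP table.
#' @param panel phased SNP table (block structure of the panel is
#'   ignored; typically one block per chromosome).
#' @return list with `concordance` (fraction of consistent pairs; `NaN`
#'   and a flag when no pair is comparable), `n_pairs`, `n_consistent`,
#'   and `mismatches` (positions of inconsistent pairs).
#' @export
panel_concordance <- function(query, panel) {
  q <- as.data.table(query); p <- as.data.table(panel)
  m <- merge(q, p[, .(chrom, pos, panel_hp1 = hp1_allele)],
             by = c("chrom", "pos"))
  setorder(m, chrom, pos)
  # code each SNP by whether the alt allele sits on haplotype 1
  m[, q_alt1 := hp1_allele == alt]
  m[, p_alt1 := panel_hp1 == alt]
  pairs <- m[, {
    if (.N < 2L) NULL else {
      i <- seq_len(.N - 1L)
      same <- block_id[i] == block_id[i + 1L]
      list(pos1 = pos[i][same], pos2 = pos[i + 1L][same],
           consistent = ((q_alt1[i] == q_alt1[i + 1L]) ==
                           (p_alt1[i] == p_alt1[i + 1L]))[same])
    }
  }, by = chrom]
  n_pairs <- nrow(pairs)
  n_consistent <- if (n_pairs) sum(pairs$consistent) else 0L
  list(concordance = if (n_pairs) n_consistent / n_pairs else NaN,
       undefined = n_pairs == 0L,
       n_pairs = n_pairs, n_consistent = n_consistent,
       mismatches = if (n_pairs) pairs[consistent == FALSE,
                                       .(chrom, pos1, pos2)] else NULL)
}
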