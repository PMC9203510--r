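#' Haplotag one read from its SNP observations
#'
#' Counts how many of the read's observations match the haplotype-1 and
#' haplotype-2 alleles of one phase block. The read is labelled `"HP1"`
#' or `"HP2"` when it carries at least `min_snps` informative
#' observations and the majority haplotype accounts for at least
#' `min_ratio` of them (boundary inclusive); otherwise `"untagged"`.
#' Observations matching neither allele (sequencing errors, third
#' alleles) are non-informative.
#'
#' @param observations data.frame with `chrom`, `pos`, `allele`.
#' @param phased_block phased SNP table of one block.
#' @param min_snps minimum informative observations (default 2).
#' @param min_ratio majority ratio threshold (default 0.7).
#' @return list with `hp1_count`, `hp2_count`, `label`.
#' @export
tag_read <- function(observations, phased_block, min_snps = 2L,
                     min_ratio = 0.7) {
  obs <- as.data.table(observations)
  blk <- as.data.table(phased_block)
  m <- merge(obs, blk[, .(chrom, pos, hp1_allele, hp2_allele)],
             by = c("chrom", "pos"))
  h1 <- sum(m$allele == m$hp1_allele)
  h2 <- sum(m$allele == m$hp2_allele)
  list(hp1_count = h1, hp2_count = h2,
       label = tag_label(h1, h2, min_snps, min_ratio))
}

#' Haplotype label from informative observation counts
#'
#' The bare labelling rule behind [tag_read()], vectorised over counts:
#' `HPk` iff `h1 + h2 >= min_snps` and the majority haplotype holds at
#' least `min_ratio` of the informative observations.
#'
#' @param h1,h2 counts of observations matching haplotype 1 / 2.
#' @param min_snps,min_ratio rule thresholds (defaults 2 and 0.7).
#' @return character vector in `{"HP1", "HP2", "untagged"}`.
#' @export
tag_label <- function(h1, h2, min_snps = 2L, min_ratio = 0.7) {
  n <- h1 + h2
  lab <- rep("untagged", length(n))
  ok <- n >= min_snps & pmax(h1, h2) / n >= min_ratio
  # at ratio exactly 0.5 (h1 == h2) there is no majority haplotype
  ok <- ok & (h1 != h2)
  lab[ok & h1 > h2] <- "HP1"
  lab[ok & h2 > h1] <- "HP2"
  lab
}

#' Haplotag a read table against phased blocks
#'
#' Vectorised version of [tag_read()]: every read is tagged per phase
#' block it overlaps (a read spanning two blocks gets one row per
#' block).
#'
#' @param observations data.frame with `read_id`, `chrom`, `pos`,
#'   `allele`.
#' @param snps phased SNP table.
#' @param min_snps,min_ratio see [tag_read()].
#' @return data.table with `read_id`, `block_id`, `hp1_count`,
#'   `hp2_count`, `n_obs`, `label`.
#' @export
tag_reads <- function(observations, snps, min_snps = 2L, min_ratio = 0.7) {
  obs <- as.data.table(observations)
  s <- as.data.table(snps)
  m <- merge(obs, s[, .(chrom, pos, hp1_allele, hp2_allele, block_id)],
             by = c("chrom", "pos"))
  if (nrow(m) == 0L)
    return(data.table(read_id = character(), block_id = character(),
                      hp1_count = integer(), hp2_count = integer(),
                      n_obs = integer(), label = character()))
  tags <- m[, .(hp1_count = sum(allele == hp1_allele),
                hp2_count = sum(allele == hp2_allele), n_obs = .N),
            by = .(read_id, block_id)]
  tags[, label := tag_label(hp1_count, hp2_count, min_snps, min_ratio)]
  setkey(tags, read_id)
  tags[]
}
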