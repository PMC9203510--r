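#' Mutation-enriched genomic windows
#'
#' Partitions each chromosome into fixed non-overlapping windows
#' (default 100 kb), counts somatic variants per window, and tests each
#' window's count against the genome-wide mutation rate with a one-sided
#' Poisson upper-tail test (`lambda = total_mutations * window /
#' callable_length`), Benjamini-Hochberg adjusted across all windows.
#' An exact binomial alternative is available.
#'
#' @param variants somatic variant table (`chrom`, `pos`).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param callable_length denominator of the genome-wide rate; defaults
#'   to `sum(chrom_lengths)`. Pass the total phased-block span to
#'   restrict the rate to phaseable regions.
#' @param window window size in bp (default 1e5).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param test `"poisson"` (default) or `"binomial"`.
#' @param all_windows return all windows instead of significant only.
#' @return data.table of windows: `chrom`, `window_start`, `window_end`,
#'   `n_mutations`, `expected_mutations`, `p_raw`, `p_adjusted`.
#' @export
find_enriched_windows <- function(variants, chrom_lengths,
                                  callable_length = sum(chrom_lengths),
                                  window = 1e5, alpha = 0.05,
                                  test = c("poisson", "binomial"),
                                  all_windows = FALSE) {
  test <- match.arg(test)
  v <- as.data.table(variants)
  empty <- data.table(chrom = character(), window_start = integer(),
                      window_end = integer(), n_mutations = integer(),
                      expected_mutations = numeric(), p_raw = numeric(),
                      p_adjusted = numeric())
  if (nrow(v) == 0L) return(empty)
  # every window of every chromosome enters the test (zero counts too)
  grid <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    starts <- seq.int(1L, chrom_lengths[[ch]], by = window)
    data.table(chrom = ch, window_start = as.integer(starts),
               window_end = as.integer(pmin(starts + window - 1L,
                                            chrom_lengths[[ch]])))
  }))
  cnt <- v[, .(n_mutations = .N),
           by = .(chrom, window_start = (pos - 1L) %/% as.integer(window) *
                    as.integer(window) + 1L)]
  w <- merge(grid, cnt, by = c("chrom", "window_start"), all.x = TRUE)
  w[is.na(n_mutations), n_mutations := 0L]
  total <- nrow(v)
  w[, expected_mutations := total *
      (window_end - window_start + 1) / callable_length]
  if (test == "poisson") {
    w[, p_raw := ppois(n_mutations - 1L, expected_mutations,
                       lower.tail = FALSE)]
  } else {
    size <- (w$window_end - w$window_start + 1) / callable_length
    w[, p_raw := mapply(function(k, p) {
      if (k == 0L) 1 else stats::pbinom(k - 1L, total, p,
                                        lower.tail = FALSE)
    }, n_mutations, size)]
  }
  w[, p_adjusted := p.adjust(p_raw, method = "BH")]
  setorder(w, chrom, window_start)
  if (all_windows) w[] else w[p_adjusted < alpha]
}

# union of adjacent/overlapping significant windows into regions
merge_windows <- function(windows) {
  w <- as.data.table(windows)
  if (nrow(w) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      p_adjusted = numeric()))
  setorder(w, chrom, window_start)
  w[, grp := cumsum(c(1L, as.integer(
    chrom[-1L] != chrom[-.N] | window_start[-1L] > window_end[-.N] + 1L)))]
  w[, .(chrom = chrom[1], start = min(window_start),
        end = max(window_end), n_windows = .N,
        p_adjusted = min(p_adjusted)), by = grp][, grp := NULL][]
}

#' Haplotype-biased mutation regions
#'
#' Merges adjacent mutation-enriched windows into regions and calls a
#' region haplotype-biased when it holds at least `min_phased`
#' haplotype-resolved variants and more than `threshold` (default 0.8)
#' of them lie on one haplotype. Variants with unknown haplotype are
#' counted but excluded from the bias fraction. An exact two-sided
#' binomial p-value against an even 0.5 split is reported alongside.
#'
#' @param enriched output of [find_enriched_windows()].
#' @param variants phased somatic variants (`chrom`, `pos`, `hap` in
#'   `{"HP1","HP2","unknown"}`).
#' @param min_phased minimum haplotype-resolved variants (default 5).
#' @param threshold bias fraction threshold, exclusive (default 0.8).
#' @return data.table of regions with `n_hp1`, `n_hp2`, `n_unknown`,
#'   `bias_fraction`, `biased_hap` (`NA` when not biased), `p_binomial`,
#'   `reason` for unflagged regions.
#' @export
call_biased_regions <- function(enriched, variants, min_phased = 5L,
                                threshold = 0.8) {
  regions <- merge_windows(enriched)
  v <- as.data.table(variants)
  if (nrow(regions) == 0L) {
    regions[, `:=`(n_hp1 = integer(), n_hp2 = integer(),
                   n_unknown = integer(), bias_fraction = numeric(),
                   biased_hap = character(), p_binomial = numeric(),
                   reason = character())]
    return(regions[])
  }
  res <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i]
    vr <- v[chrom == r$chrom & pos >= r$start & pos <= r$end]
    n1 <- sum(vr$hap == "HP1"); n2 <- sum(vr$hap == "HP2")
    nu <- sum(vr$hap == "unknown")
    np <- n1 + n2
    bf <- if (np > 0L) max(n1, n2) / np else NA_real_
    pb <- if (np > 0L) binom.test(n1, np, 0.5)$p.value else NA_real_
    biased <- !is.na(bf) && np >= min_phased && bf > threshold
    data.table(n_hp1 = n1, n_hp2 = n2, n_unknown = nu,
               bias_fraction = bf,
               biased_hap = if (biased) c("HP1", "HP2")[which.max(c(n1, n2))]
                            else NA_character_,
               p_binomial = pb,
               reason = if (biased) "" else if (np < min_phased)
                 "too_few_phased" else "below_threshold")
  })
  cbind(regions, rbindlist(res))
}

#' Phased blocks concentrating structural variants
#'
#' Reports, per phase block holding at least `min_svs` phased SVs, the
#' SV count and the maximum proportion of SVs on one haplotype.
#'
#' @param phased_svs SV table from [phase_svs()] (rows with
#'   `hap != "unknown"` are used).
#' @param min_svs minimum phased SVs per block (default 3).
#' @return data.table: `block_id`, `n_phased_svs`, `n_hp1`, `n_hp2`,
#'   `max_hap_proportion`.
#' @export
sv_concentrated_blocks <- function(phased_svs, min_svs = 3L) {
  s <- as.data.table(phased_svs)[hap %in% c("HP1", "HP2") &
                                   !is.na(block_id)]
  if (nrow(s) == 0L)
    return(data.table(block_id = character(), n_phased_svs = integer(),
                      n_hp1 = integer(), n_hp2 = integer(),
                      max_hap_proportion = numeric()))
  b <- s[, .(n_phased_svs = .N, n_hp1 = sum(hap == "HP1"),
             n_hp2 = sum(hap == "HP2")), by = block_id]
  b <- b[n_phased_svs >= min_svs]
  b[, max_hap_proportion := pmax(n_hp1, n_hp2) / n_phased_svs]
  setorder(b, -n_phased_svs)
  b[]
}
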