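#' Cluster interleaved structural variants
#'
#' Represents each intrachromosomal SV as the interval between its
#' breakpoints and connects two SVs when their intervals intersect
#' (within `max_gap` bp; default 0, strict overlap). Connected
#' components with at least two members form clusters; singletons are
#' discarded. Interchromosomal SVs attach to a chromosome's graph by
#' their local breakpoint (a zero-length interval).
#'
#' @param svs SV table (`sv_id`, `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   optionally `hap`).
#' @param max_gap maximum gap between intervals still counted as
#'   connected (default 0).
#' @return data.table of clusters: `cluster`, `chrom`, `start`, `end`,
#'   `n_svs`, `span_mb`, `svs_per_mb`, `sv_ids` (comma-separated),
#'   `n_hp1`, `n_hp2` (0 when no `hap` column is present).
#' @export
cluster_interleaved_svs <- function(svs, max_gap = 0L) {
  s <- as.data.table(svs)
  empty <- data.table(cluster = integer(), chrom = character(),
                      start = integer(), end = integer(), n_svs = integer(),
                      span_mb = numeric(), svs_per_mb = numeric(),
                      sv_ids = character(), n_hp1 = integer(),
                      n_hp2 = integer())
  if (nrow(s) == 0L) return(empty)
  # local interval per (sv, chromosome)
  intra <- s[chrom1 == chrom2,
             .(sv_id, chrom = chrom1, start = pmin(pos1, pos2),
               end = pmax(pos1, pos2))]
  inter <- s[chrom1 != chrom2]
  iv <- rbind(intra,
              if (nrow(inter)) rbind(
                inter[, .(sv_id, chrom = chrom1, start = pos1, end = pos1)],
                inter[, .(sv_id, chrom = chrom2, start = pos2, end = pos2)])
              else NULL)
  out <- list()
  cl_id <- 0L
  for (ch in unique(iv$chrom)) {
    x <- iv[chrom == ch][order(start, end)]
    if (nrow(x) == 0L) next
    # single sweep over start-sorted intervals: a new component opens
    # when an interval starts beyond the running maximum end (+ gap)
    comp <- if (nrow(x) == 1L) 1L else
      cumsum(c(1L, as.integer(
        x$start[-1L] > cummax(x$end)[-nrow(x)] + max_gap)))
    x[, comp := comp]
    for (g in unique(comp)) {
      xg <- x[comp == g]
      members <- unique(xg$sv_id)
      if (length(members) < 2L) next
      cl_id <- cl_id + 1L
      haps <- if ("hap" %in% names(s))
        s[sv_id %in% members, hap] else character(0)
      out[[cl_id]] <- data.table(
        cluster = cl_id, chrom = ch, start = min(xg$start),
        end = max(xg$end), n_svs = length(members),
        span_mb = (max(xg$end) - min(xg$start)) / 1e6,
        svs_per_mb = length(members) /
          ((max(xg$end) - min(xg$start)) / 1e6),
        sv_ids = paste(members, collapse = ","),
        n_hp1 = sum(haps %in% c("HP1", 1L)),
        n_hp2 = sum(haps %in% c("HP2", 2L)))
    }
  }
  if (length(out) == 0L) return(empty)
  rbindlist(out)
}

#' Count oscillating copy-number states within an interval
#'
#' Clips CN segments to `[start, end]` on `chrom` and finds the longest
#' run of consecutive segments alternating between exactly two CN values
#' and the longest run whose consecutive segments differ while using at
#' most three distinct recurring values. Both the number of segments in
#' the run and the number of state transitions are returned, together
#' with the density of CN state changes per Mb.
#'
#' @param cn CN segment table (`chrom`, `start`, `end`, `cn`).
#' @param chrom,start,end the interval (typically a cluster span).
#' @return list: `n_2state_segments`, `n_2state_transitions`,
#'   `n_3state_segments`, `n_3state_transitions`, `n_state_changes`,
#'   `cn_states_per_mb`.
#' @export
count_cn_oscillations <- function(cn, chrom, start, end) {
  ch <- chrom; lo <- start; hi <- end
  x <- as.data.table(cn)
  x <- x[x$chrom == ch & x$end >= lo & x$start <= hi]
  setorder(x, start)
  states <- x$cn
  span_mb <- (hi - lo) / 1e6
  if (length(states) < 2L)
    return(list(n_2state_segments = 0L, n_2state_transitions = 0L,
                n_3state_segments = 0L, n_3state_transitions = 0L,
                n_state_changes = 0L, cn_states_per_mb = 0))
  n_changes <- sum(diff(states) != 0)
  r2 <- longest_alternating_run(states, 2L)
  r3 <- longest_alternating_run(states, 3L)
  list(n_2state_segments = r2, n_2state_transitions = max(0L, r2 - 1L),
       n_3state_segments = r3, n_3state_transitions = max(0L, r3 - 1L),
       n_state_changes = n_changes,
       cn_states_per_mb = if (span_mb > 0) n_changes / span_mb else 0)
}

# longest contiguous run of segments whose consecutive values differ,
# using at most k distinct values within the run
longest_alternating_run <- function(states, k) {
  n <- length(states)
  best <- 0L
  for (i in seq_len(n)) {
    vals <- states[i]
    j <- i
    while (j < n && states[j + 1L] != states[j]) {
      nv <- union(vals, states[j + 1L])
      if (length(nv) > k) break
      vals <- nv
      j <- j + 1L
    }
    best <- max(best, j - i + 1L)
  }
  # a single segment is not an oscillation
  if (best < 2L) 0L else best
}

#' Apply the four chromothripsis criteria to an SV cluster
#'
#' A cluster is called a chromothripsis-like region when all four hold:
#' (i) at least `min_svs` SVs in the cluster; (ii) at least
#' `min_osc2` oscillating CN segments between two states, or at least
#' `min_osc3` among three states; (iii) at least `min_sv_density` SVs
#' per Mb; (iv) at least `min_cn_density` CN state changes per Mb.
#' Criterion (ii) is applied to segment counts by default; set
#' `oscillation_metric = "transitions"` to use transition counts.
#'
#' @param cluster one row of [cluster_interleaved_svs()] output.
#' @param cn CN segment table.
#' @param min_svs,min_osc2,min_osc3,min_sv_density,min_cn_density
#'   thresholds (defaults 10, 4, 6, 0.2, 0.2).
#' @param oscillation_metric `"segments"` (default) or `"transitions"`.
#' @return list with `passed`, per-criterion logicals `c1`..`c4`, the
#'   oscillation counts, and the cluster row.
#' @export
call_chromothripsis <- function(cluster, cn, min_svs = 10L,
                                min_osc2 = 4L, min_osc3 = 6L,
                                min_sv_density = 0.2,
                                min_cn_density = 0.2,
                                oscillation_metric = c("segments",
                                                       "transitions")) {
  oscillation_metric <- match.arg(oscillation_metric)
  cl <- as.data.table(cluster)
  osc <- count_cn_oscillations(cn, cl$chrom, cl$start, cl$end)
  o2 <- if (oscillation_metric == "segments") osc$n_2state_segments
        else osc$n_2state_transitions
  o3 <- if (oscillation_metric == "segments") osc$n_3state_segments
        else osc$n_3state_transitions
  c1 <- cl$n_svs >= min_svs
  c2 <- (o2 >= min_osc2) || (o3 >= min_osc3)
  c3 <- cl$svs_per_mb >= min_sv_density
  c4 <- osc$cn_states_per_mb >= min_cn_density
  list(passed = c1 && c2 && c3 && c4, c1 = c1, c2 = c2, c3 = c3, c4 = c4,
       oscillations = osc, cluster = cl)
}

#' Chromothripsis calls for every cluster in an SV set
#'
#' @param svs phased SV table.
#' @param cn CN segment table.
#' @param max_gap see [cluster_interleaved_svs()].
#' @param ... thresholds passed to [call_chromothripsis()].
#' @return data.table: one row per cluster with criteria flags,
#'   oscillation counts and the dominant haplotype of member SVs.
#' @export
chromothripsis_calls <- function(svs, cn, max_gap = 0L, ...) {
  clusters <- cluster_interleaved_svs(svs, max_gap = max_gap)
  empty <- data.table(cluster = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      n_svs = integer(), svs_per_mb = numeric(),
                      n_2state_segments = integer(),
                      n_3state_segments = integer(),
                      cn_states_per_mb = numeric(), c1 = logical(),
                      c2 = logical(), c3 = logical(), c4 = logical(),
                      passed = logical(), dominant_hap = character())
  if (nrow(clusters) == 0L) return(empty)
  res <- lapply(seq_len(nrow(clusters)), function(i) {
    call <- call_chromothripsis(clusters[i], cn, ...)
    o <- call$oscillations
    dom <- if (clusters$n_hp1[i] + clusters$n_hp2[i] == 0L) NA_character_
           else c("HP1", "HP2")[which.max(c(clusters$n_hp1[i],
                                            clusters$n_hp2[i]))]
    data.table(cluster = clusters$cluster[i], chrom = clusters$chrom[i],
               start = clusters$start[i], end = clusters$end[i],
               n_svs = clusters$n_svs[i],
               svs_per_mb = clusters$svs_per_mb[i],
               n_2state_segments = o$n_2state_segments,
               n_3state_segments = o$n_3state_segments,
               cn_states_per_mb = o$cn_states_per_mb,
               c1 = call$c1, c2 = call$c2, c3 = call$c3, c4 = call$c4,
               passed = call$passed, dominant_hap = dom)
  })
  rbindlist(res)
}

#' Trinucleotide mutational spectrum of SNVs
#'
#' Maps each SNV to one of the 96 pyrimidine-centric substitution
#' categories using the reference context at position +/- 1. SNVs whose
#' reference base is a purine are reverse-complemented (e.g. G>A at
#' 5'-TGA-3' becomes C>T at T[C>T]A). SNVs at contig edges or whose
#' stated reference allele disagrees with the sequence are skipped and
#' counted.
#'
#' @param snvs SNV table (`chrom`, `pos`, `ref`, `alt`).
#' @param reference named character vector of chromosome sequences.
#' @return named integer vector of length 96 (attribute `n_skipped`).
#' @export
trinucleotide_spectrum <- function(snvs, reference) {
  v <- as.data.table(snvs)
  cats <- sbs_categories()
  counts <- setNames(integer(96L), cats)
  skipped <- 0L
  if (nrow(v) == 0L) {
    attr(counts, "n_skipped") <- 0L
    return(counts)
  }
  for (i in seq_len(nrow(v))) {
    ch <- v$chrom[i]; p <- v$pos[i]
    seq_ch <- reference[[ch]]
    if (is.null(seq_ch) || is.na(seq_ch) || p < 2L ||
        p > nchar(seq_ch) - 1L) { skipped <- skipped + 1L; next }
    ctx <- substring(seq_ch, p - 1L, p + 1L)
    ref <- substring(ctx, 2L, 2L)
    alt <- v$alt[i]
    if (ref != v$ref[i]) { skipped <- skipped + 1L; next }
    if (ref %in% c("G", "A")) {
      ctx <- revcomp(ctx)
      ref <- unname(comp_base[ref])
      alt <- unname(comp_base[alt])
    }
    cat96 <- paste0(substring(ctx, 1L, 1L), "[", ref, ">", alt, "]",
                    substring(ctx, 3L, 3L))
    if (!cat96 %in% cats) { skipped <- skipped + 1L; next }
    counts[cat96] <- counts[cat96] + 1L
  }
  attr(counts, "n_skipped") <- skipped
  counts
}

#' Spectrum from generator-recorded contexts
#'
#' Builds the 96-category spectrum directly from a variant table that
#' carries its trinucleotide `context` (pyrimidine-centric) — the form
#' the synthetic generator emits — without needing a reference sequence.
#'
#' @param snvs SNV table with `ref`, `alt`, `context` columns.
#' @return named integer vector of length 96.
#' @export
spectrum_from_contexts <- function(snvs) {
  v <- as.data.table(snvs)
  cats <- sbs_categories()
  lab <- paste0(substring(v$context, 1, 1), "[", v$ref, ">", v$alt, "]",
                substring(v$context, 3, 3))
  tab <- table(factor(lab, levels = cats))
  counts <- setNames(as.integer(tab), cats)
  attr(counts, "n_skipped") <- sum(!lab %in% cats)
  counts
}

#' Cosine similarity between a spectrum and a signature
#'
#' Standard cosine of two non-negative 96-vectors; invariant to scaling
#' either vector. A zero vector yields `NaN` with a warning.
#'
#' @param spectrum,signature numeric vectors of equal length.
#' @return number in `[0, 1]` (or `NaN` for a zero vector).
#' @export
cosine_similarity <- function(spectrum, signature) {
  x <- as.numeric(spectrum); y <- as.numeric(signature)
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("cosine similarity undefined for a zero vector")
    return(NaN)
  }
  sum(x * y) / (nx * ny)
}

#' Best-matching signatures for a spectrum
#'
#' @param spectrum 96-vector of counts.
#' @param catalog signature matrix (96 rows, one column per signature),
#'   e.g. [builtin_signatures()] or a COSMIC-format table.
#' @param threshold minimum cosine to report (default 0.7).
#' @return data.table of matches ordered by decreasing cosine.
#' @export
best_matches <- function(spectrum, catalog, threshold = 0.7) {
  cs <- vapply(seq_len(ncol(catalog)), function(j)
    cosine_similarity(spectrum, catalog[, j]), numeric(1))
  out <- data.table(signature = colnames(catalog), cosine = cs)
  setorder(out, -cosine)
  out[cosine > threshold][]
}

#' Scan for kataegis-like local hypermutation
#'
#' Flags mutation-enriched windows (via [find_enriched_windows()]) whose
#' local spectrum exceeds `cosine_threshold` against an APOBEC-class
#' signature, reporting the haplotype composition of each candidate.
#'
#' @param snvs phased SNV table (`chrom`, `pos`, `ref`, `alt`,
#'   `context` and/or with `reference` supplied, `hap` optional).
#' @param chrom_lengths named chromosome lengths.
#' @param signature APOBEC-class 96-vector (default the built-in
#'   APOBEC-like profile).
#' @param reference optional named reference sequences; when absent the
#'   `context` column is used.
#' @param window,alpha enrichment parameters (defaults 1e5, 0.05).
#' @param cosine_threshold minimum cosine (default 0.7).
#' @return data.table of candidate regions with `cosine`, `n_snvs`,
#'   `n_hp1`, `n_hp2`, `dominant_hap`.
#' @export
kataegis_scan <- function(snvs, chrom_lengths,
                          signature = builtin_signatures()[, "APOBEC-like"],
                          reference = NULL, window = 1e5, alpha = 0.05,
                          cosine_threshold = 0.7) {
  v <- as.data.table(snvs)
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), n_snvs = integer(),
                      cosine = numeric(), n_hp1 = integer(),
                      n_hp2 = integer(), dominant_hap = character())
  enriched <- find_enriched_windows(v, chrom_lengths, window = window,
                                    alpha = alpha)
  regions <- merge_windows(enriched)
  if (nrow(regions) == 0L) return(empty)
  res <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i]
    vr <- v[chrom == r$chrom & pos >= r$start & pos <= r$end]
    spec <- if (!is.null(reference)) trinucleotide_spectrum(vr, reference)
            else spectrum_from_contexts(vr)
    cs <- suppressWarnings(cosine_similarity(spec, signature))
    n1 <- if ("hap" %in% names(vr)) sum(vr$hap == "HP1") else 0L
    n2 <- if ("hap" %in% names(vr)) sum(vr$hap == "HP2") else 0L
    data.table(chrom = r$chrom, start = r$start, end = r$end,
               n_snvs = nrow(vr), cosine = cs, n_hp1 = n1, n_hp2 = n2,
               dominant_hap = if (n1 + n2 == 0L) NA_character_
                              else c("HP1", "HP2")[which.max(c(n1, n2))])
  })
  out <- rbindlist(res)
  out[!is.nan(cosine) & cosine > cosine_threshold][]
}
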