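#' Configuration for the synthetic diploid tumour generator
#'
#' Builds and validates the parameter set that fully determines a synthetic
#' paired tumour/normal dataset: a diploid genome with heterozygous SNPs,
#' log-normally distributed long reads with SNP-site errors, somatic SNVs
#' with configurable haplotype bias and trinucleotide spectrum, clusters of
#' interleaved SVs with oscillating copy number confined to one haplotype,
#' haplotype-specific CpG methylation, and haplotype-skewed transcript
#' counts. The same seed always yields byte-identical output.
#'
#' @param genome_length bases per chromosome.
#' @param n_chroms number of chromosomes (named `chr1`, `chr2`, ...).
#' @param snp_rate heterozygous SNPs per base (default 1/1500, the density
#'   typical of a human genome).
#' @param read_n50 target N50 read length in bp (default 16000, the scale
#'   of nanopore whole-genome runs).
#' @param read_length_sigma log-scale standard deviation of the log-normal
#'   read-length law. The log-mean is set to `log(read_n50) - sigma^2` so
#'   the length-weighted median (N50) of the law equals `read_n50`.
#' @param depth haploid fold-coverage in read bases per genome base.
#' @param per_base_error probability that a read's observation of a SNP
#'   site reports the allele of the other haplotype.
#' @param somatic_rate background somatic SNVs per Mb.
#' @param vaf_shape two-parameter beta shape for somatic VAFs
#'   (default `c(8, 12)`, mean 0.4).
#' @param bias_regions `NULL` or a data.frame with columns `chrom`,
#'   `start`, `end`, `hap` (1 or 2), `fraction_on_hap`, `n_snvs`,
#'   `spectrum` (a name in [builtin_signatures()]).
#' @param sv_cluster_spec `NULL` or a data.frame with columns `chrom`,
#'   `start`, `end`, `hap`, `n_svs`, `n_cn_oscillations`.
#' @param methylation_spec `NULL` or a list with elements `regions` (a
#'   data.frame `chrom`, `start`, `end`, `hp1_prob`, `hp2_prob`) and
#'   optionally `cpg_spacing` (bp between synthetic CpG sites when no
#'   reference sequence is generated; default 100).
#' @param expression_spec `NULL` or a data.frame with columns `gene_id`,
#'   `chrom`, `start`, `end`, `tss`, `tumor_hp1_rate`, `tumor_hp2_rate`,
#'   `normal_hp1_rate`, `normal_hp2_rate` (expected read counts).
#' @param with_sequence generate an explicit random reference sequence
#'   (needed for trinucleotide-context placement of SNVs and CpG-site
#'   detection). Disable for large genomes where only positional
#'   statistics are exercised.
#' @param seed integer seed that fully determines the simulation.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e6,
                       n_chroms = 2,
                       snp_rate = 1 / 1500,
                       read_n50 = 16000,
                       read_length_sigma = 0.85,
                       depth = 30,
                       per_base_error = 0.10,
                       somatic_rate = 10,
                       vaf_shape = c(8, 12),
                       bias_regions = NULL,
                       sv_cluster_spec = NULL,
                       methylation_spec = NULL,
                       expression_spec = NULL,
                       with_sequence = genome_length * n_chroms <= 5e6,
                       seed = 1L) {
  cfg <- list(genome_length = genome_length, n_chroms = as.integer(n_chroms),
              snp_rate = snp_rate, read_n50 = read_n50,
              read_length_sigma = read_length_sigma, depth = depth,
              per_base_error = per_base_error, somatic_rate = somatic_rate,
              vaf_shape = vaf_shape, bias_regions = bias_regions,
              sv_cluster_spec = sv_cluster_spec,
              methylation_spec = methylation_spec,
              expression_spec = expression_spec,
              with_sequence = isTRUE(with_sequence), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$genome_length) || cfg$genome_length < 1000)
    stop_config("genome_length", "must be numeric and >= 1000 bp")
  if (cfg$n_chroms < 1 || cfg$n_chroms > 22)
    stop_config("n_chroms", "must be between 1 and 22")
  if (cfg$snp_rate < 0 || cfg$snp_rate > 1)
    stop_config("snp_rate", "must be a probability per bp in [0, 1]")
  if (cfg$read_n50 <= 0) stop_config("read_n50", "must be positive")
  if (cfg$read_length_sigma <= 0)
    stop_config("read_length_sigma", "must be positive")
  if (cfg$depth <= 0) stop_config("depth", "must be positive")
  if (cfg$per_base_error < 0 || cfg$per_base_error > 1)
    stop_config("per_base_error", "must be in [0, 1]")
  if (cfg$somatic_rate < 0) stop_config("somatic_rate", "must be >= 0")
  check_regions <- function(df, field, cols) {
    if (is.null(df)) return(invisible())
    df <- as.data.frame(df)
    if (!all(cols %in% names(df)))
      stop_config(field, paste("missing column(s):",
                               paste(setdiff(cols, names(df)), collapse = ", ")))
    if (any(df$start < 1) || any(df$end > cfg$genome_length) ||
        any(df$start >= df$end))
      stop_config(field, "intervals must lie within genome bounds")
    if ("hap" %in% cols && !all(df$hap %in% c(1, 2)))
      stop_config(field, "hap must be 1 or 2")
    invisible()
  }
  check_regions(cfg$bias_regions, "bias_regions",
                c("chrom", "start", "end", "hap", "fraction_on_hap",
                  "n_snvs", "spectrum"))
  if (!is.null(cfg$bias_regions)) {
    f <- cfg$bias_regions$fraction_on_hap
    if (any(f < 0 | f > 1))
      stop_config("bias_regions", "fraction_on_hap must be in [0, 1]")
  }
  check_regions(cfg$sv_cluster_spec, "sv_cluster_spec",
                c("chrom", "start", "end", "hap", "n_svs",
                  "n_cn_oscillations"))
  if (!is.null(cfg$methylation_spec)) {
    check_regions(cfg$methylation_spec$regions, "methylation_spec",
                  c("chrom", "start", "end", "hp1_prob", "hp2_prob"))
    p <- cfg$methylation_spec$regions
    if (!is.null(p) && any(c(p$hp1_prob, p$hp2_prob) < 0 |
                           c(p$hp1_prob, p$hp2_prob) > 1))
      stop_config("methylation_spec", "probabilities must be in [0, 1]")
  }
  if (!is.null(cfg$expression_spec)) {
    check_regions(cfg$expression_spec, "expression_spec",
                  c("gene_id", "chrom", "start", "end"))
    r <- as.data.frame(cfg$expression_spec)
    rates <- unlist(r[intersect(names(r), c("tumor_hp1_rate",
      "tumor_hp2_rate", "normal_hp1_rate", "normal_hp2_rate"))])
    if (any(rates < 0)) stop_config("expression_spec", "rates must be >= 0")
  }
  invisible(cfg)
}

#' Simulate a diploid genome with phased heterozygous SNPs
#'
#' Heterozygous SNP positions are drawn as a Poisson process at
#' `config$snp_rate` per bp; each SNP receives a reference and alternate
#' allele and a random assignment of the two alleles to haplotypes 1 and 2.
#' All SNPs of a chromosome share one truth phase block.
#'
#' @param config a [sim_config()].
#' @return a list with `chrom_lengths` (named), `reference` (named
#'   character vector of chromosome sequences, or `NULL` when
#'   `with_sequence = FALSE`) and `snps`, a data.table with columns
#'   `chrom`, `pos`, `ref`, `alt`, `hp1_allele`, `hp2_allele`, `block_id`.
#' @export
simulate_diploid_genome <- function(config) {
  validate_sim_config(config)
  set.seed(sub_seed(config$seed, 1L))
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_lengths <- setNames(rep(as.integer(config$genome_length),
                                config$n_chroms), chroms)
  bases <- c("A", "C", "G", "T")

  reference <- NULL
  if (config$with_sequence) {
    reference <- setNames(vapply(chroms, function(ch)
      paste(sample(bases, config$genome_length, replace = TRUE),
            collapse = ""), character(1)), chroms)
  }

  snp_list <- lapply(chroms, function(ch) {
    n <- rpois(1L, config$genome_length * config$snp_rate)
    if (n == 0L) return(NULL)
    pos <- sort(sample.int(config$genome_length - 2L, n) + 1L)
    if (!is.null(reference)) {
      ref <- substring(reference[[ch]], pos, pos)
    } else {
      ref <- sample(bases, n, replace = TRUE)
    }
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                  character(1), USE.NAMES = FALSE)
    alt_on_hp1 <- runif(n) < 0.5
    data.table(chrom = ch, pos = pos, ref = ref, alt = alt,
               hp1_allele = ifelse(alt_on_hp1, alt, ref),
               hp2_allele = ifelse(alt_on_hp1, ref, alt),
               block_id = paste0(ch, "_b1"))
  })
  snps <- rbindlist(snp_list)
  if (nrow(snps) == 0L)
    snps <- data.table(chrom = character(), pos = integer(),
                       ref = character(), alt = character(),
                       hp1_allele = character(), hp2_allele = character(),
                       block_id = character())
  setkey(snps, chrom, pos)
  list(chrom_lengths = chrom_lengths, reference = reference, snps = snps)
}

#' Simulate haplotagged long reads over a diploid genome
#'
#' Read lengths are log-normal with log-mean `log(read_n50) - sigma^2`,
#' which makes the length-weighted median of the law equal `read_n50`.
#' Each read originates from one haplotype; every heterozygous SNP it
#' covers is reported with the true allele of that haplotype, flipped to
#' the other haplotype's allele with probability `per_base_error`.
#'
#' @param genome output of [simulate_diploid_genome()].
#' @param config a [sim_config()].
#' @return list with `reads` (data.table: `read_id`, `chrom`, `start`,
#'   `end`, `hap_truth`) and `observations` (data.table: `read_id`,
#'   `chrom`, `pos`, `allele`).
#' @export
simulate_long_reads <- function(genome, config) {
  if (config$depth <= 0) stop_config("depth", "must be positive")
  set.seed(sub_seed(config$seed, 2L))
  sigma <- config$read_length_sigma
  mu <- log(config$read_n50) - sigma^2
  mean_len <- exp(mu + sigma^2 / 2)
  total_bases <- config$depth * sum(genome$chrom_lengths)
  n_reads <- max(1L, round(total_bases / mean_len))

  chroms <- names(genome$chrom_lengths)
  chrom <- sample(chroms, n_reads, replace = TRUE,
                  prob = genome$chrom_lengths / sum(genome$chrom_lengths))
  len <- pmax(200L, pmin(round(rlnorm(n_reads, mu, sigma)),
                         genome$chrom_lengths[chrom]))
  start <- floor(runif(n_reads) *
                   (genome$chrom_lengths[chrom] - len + 1)) + 1L
  reads <- data.table(read_id = sprintf("r%06d", seq_len(n_reads)),
                      chrom = chrom, start = as.integer(start),
                      end = as.integer(start + len - 1L),
                      hap_truth = sample(1:2, n_reads, replace = TRUE))
  setkey(reads, chrom, start, end)
  obs <- observe_snps(reads, genome$snps, config$per_base_error)
  list(reads = reads, observations = obs)
}

# Vectorised extraction of SNP observations for a read table; err is the
# probability of reporting the other haplotype's allele.
observe_snps <- function(reads, snps, err) {
  if (nrow(snps) == 0L || nrow(reads) == 0L)
    return(data.table(read_id = character(), chrom = character(),
                      pos = integer(), allele = character()))
  out <- vector("list", length(unique(reads$chrom)))
  i <- 0L
  for (ch in unique(reads$chrom)) {
    rs <- reads[chrom == ch]
    sp <- snps[chrom == ch]
    if (nrow(sp) == 0L) next
    i1 <- findInterval(rs$start - 1L, sp$pos) + 1L
    i2 <- findInterval(rs$end, sp$pos)
    nobs <- pmax(0L, i2 - i1 + 1L)
    keep <- nobs > 0L
    if (!any(keep)) next
    idx <- sequence(nobs[keep]) + rep(i1[keep] - 1L, nobs[keep])
    rid <- rep(rs$read_id[keep], nobs[keep])
    hap <- rep(rs$hap_truth[keep], nobs[keep])
    true_allele <- ifelse(hap == 1L, sp$hp1_allele[idx], sp$hp2_allele[idx])
    other_allele <- ifelse(hap == 1L, sp$hp2_allele[idx], sp$hp1_allele[idx])
    flip <- runif(length(idx)) < err
    i <- i + 1L
    out[[i]] <- data.table(read_id = rid, chrom = ch, pos = sp$pos[idx],
                           allele = ifelse(flip, other_allele, true_allele))
  }
  obs <- rbindlist(out[seq_len(i)])
  setkey(obs, read_id, chrom, pos)
  obs
}

#' Inject somatic events into a simulated genome
#'
#' Adds (i) background somatic SNVs at `somatic_rate` per Mb with a flat
#' trinucleotide spectrum and random haplotype, (ii) haplotype-biased SNV
#' regions where each SNV falls on the designated haplotype with
#' probability `fraction_on_hap` and draws its substitution category from
#' the named spectrum, (iii) clusters of mutually interleaved SV
#' breakpoint pairs on one haplotype with alternating copy-number
#' segments, (iv) per-read CpG methylation calls with per-haplotype
#' probabilities, and (v) haplotype-skewed RNA read counts. A truth set
#' records the generating haplotype and region of every emitted record.
#'
#' @param genome output of [simulate_diploid_genome()].
#' @param config a [sim_config()].
#' @param reads optional output of [simulate_long_reads()]; when supplied,
#'   mutant reads, SV-supporting reads and methylation calls are linked to
#'   actual simulated reads (required for read-based haplotype recovery).
#' @return list with `snvs`, `mutant_reads`, `svs`, `cn`, `methylation`,
#'   `rna`, and `truth` (a list of truth tables; every emitted somatic
#'   record appears exactly once).
#' @export
inject_somatic_events <- function(genome, config, reads = NULL) {
  validate_sim_config(config)
  check_region_overlaps(config)
  set.seed(sub_seed(config$seed, 3L))
  snvs <- make_somatic_snvs(genome, config)
  set.seed(sub_seed(config$seed, 4L))
  svres <- make_sv_clusters(genome, config, reads)
  set.seed(sub_seed(config$seed, 5L))
  mutant_reads <- link_mutant_reads(snvs, reads)
  set.seed(sub_seed(config$seed, 6L))
  meth <- make_methylation(genome, config, reads)
  set.seed(sub_seed(config$seed, 7L))
  rna <- make_rna(genome, config)

  truth <- list(
    snvs = if (nrow(snvs)) snvs[, .(id, chrom, pos, hap_truth, region_id,
                                    category)] else NULL,
    bias_regions = if (!is.null(config$bias_regions))
      as.data.table(config$bias_regions) else NULL,
    sv_clusters = svres$truth,
    svs = if (nrow(svres$svs)) svres$svs[, .(sv_id, hap_truth, cluster_id)]
      else NULL,
    dmrs = meth$truth,
    expression = rna$truth
  )
  list(snvs = snvs, mutant_reads = mutant_reads, svs = svres$svs,
       cn = svres$cn, methylation = meth$calls, rna = rna$observations,
       rna_reads = rna$reads, truth = truth)
}

check_region_overlaps <- function(config) {
  br <- config$bias_regions
  if (is.null(br) || nrow(as.data.frame(br)) < 2) return(invisible())
  br <- as.data.table(br)
  setkey(br, chrom, start, end)
  ov <- foverlaps(br, br, which = TRUE)
  ov <- ov[ov$xid != ov$yid, ]
  if (nrow(ov)) {
    a <- br[ov$xid[1]]; b <- br[ov$yid[1]]
    if (a$hap != b$hap || a$spectrum != b$spectrum)
      stop("overlapping bias_regions with contradictory haplotype or ",
           "spectrum: ", a$chrom, ":", a$start, "-", a$end, call. = FALSE)
  }
  invisible()
}

make_somatic_snvs <- function(genome, config) {
  sig <- builtin_signatures()
  cats <- rownames(sig)
  pieces <- list()
  # background: uniform positions, flat spectrum, random haplotype
  n_bg <- rpois(1L, config$somatic_rate * sum(genome$chrom_lengths) / 1e6)
  if (n_bg > 0) {
    ch <- sample(names(genome$chrom_lengths), n_bg, replace = TRUE,
                 prob = genome$chrom_lengths / sum(genome$chrom_lengths))
    cat_bg <- sample(cats, n_bg, replace = TRUE)
    pieces$bg <- data.table(chrom = ch, category = cat_bg,
                            hap_truth = sample(1:2, n_bg, replace = TRUE),
                            region_id = NA_character_,
                            lo = 1L,
                            hi = genome$chrom_lengths[ch])
  }
  br <- if (is.null(config$bias_regions)) NULL else
    as.data.table(config$bias_regions)
  if (!is.null(br)) for (j in seq_len(nrow(br))) {
    n <- br$n_snvs[j]
    if (n == 0) next
    p <- sig[, br$spectrum[j]]
    pieces[[paste0("bias", j)]] <- data.table(
      chrom = br$chrom[j],
      category = sample(cats, n, replace = TRUE, prob = p),
      hap_truth = ifelse(runif(n) < br$fraction_on_hap[j],
                         br$hap[j], 3L - br$hap[j]),
      region_id = sprintf("bias_%d", j),
      lo = as.integer(br$start[j]), hi = as.integer(br$end[j]))
  }
  tab <- rbindlist(pieces)
  if (is.null(tab) || nrow(tab) == 0L)
    return(data.table(id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      context = character(), vaf = numeric(),
                      hap_truth = integer(), region_id = character(),
                      category = character()))
  # decode category "A[C>T]G" -> context ACG, ref C, alt T
  ref <- substring(tab$category, 3, 3)
  alt <- substring(tab$category, 5, 5)
  ctx <- paste0(substring(tab$category, 1, 1), ref,
                substring(tab$category, 7, 7))
  tab[, `:=`(ref = ref, alt = alt, context = ctx)]
  tab[, pos := place_snv_positions(.SD, genome, .BY$chrom), by = chrom]
  tab <- tab[!is.na(pos)]
  tab[, vaf := rbeta(.N, config$vaf_shape[1], config$vaf_shape[2])]
  tab[, id := sprintf("snv%05d", seq_len(.N))]
  out <- tab[, .(id, chrom, pos, ref, alt, context, vaf, hap_truth,
                 region_id, category)]
  setkey(out, chrom, pos)
  out
}

# choose positions for SNVs of one chromosome; with a reference sequence
# the position's trinucleotide must equal the requested context, so that
# spectra recomputed from the reference agree with the generator.
place_snv_positions <- function(sd, genome, ch) {
  L <- genome$chrom_lengths[[ch]]
  if (is.null(genome$reference)) {
    return(as.integer(floor(runif(nrow(sd)) * (sd$hi - sd$lo + 1)) + sd$lo))
  }
  seq_ch <- genome$reference[[ch]]
  tri <- substring(seq_ch, seq_len(L - 2L), seq_len(L - 2L) + 2L)
  idx <- split(seq_len(L - 2L) + 1L, tri)  # centre position by context
  pos <- integer(nrow(sd))
  used <- integer(0)
  for (k in seq_len(nrow(sd))) {
    cand <- idx[[sd$context[k]]]
    cand <- cand[cand >= sd$lo[k] & cand <= sd$hi[k]]
    cand <- setdiff(cand, used)
    if (length(cand) == 0L) { pos[k] <- NA_integer_; next }
    pos[k] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    used <- c(used, pos[k])
  }
  pos
}

make_sv_clusters <- function(genome, config, reads) {
  spec <- config$sv_cluster_spec
  empty_sv <- data.table(sv_id = character(), chrom1 = character(),
                         pos1 = integer(), dir1 = character(),
                         chrom2 = character(), pos2 = integer(),
                         dir2 = character(), type = character(),
                         read_ids = character(), hap_truth = integer(),
                         cluster_id = character())
  cn_default <- data.table(chrom = names(genome$chrom_lengths),
                           start = 1L,
                           end = as.integer(genome$chrom_lengths),
                           cn = 2L)
  if (is.null(spec))
    return(list(svs = empty_sv, cn = cn_default, truth = NULL))
  spec <- as.data.table(spec)
  sv_list <- list(); cn_list <- list(); truth_list <- list()
  types <- c("deletion", "duplication", "inversion")
  for (j in seq_len(nrow(spec))) {
    n <- spec$n_svs[j]
    ch <- spec$chrom[j]
    lo <- spec$start[j]; hi <- spec$end[j]
    # breakpoints as an interleaved bracket sequence: sort 2n points and
    # pair point i with point i+n, which makes every pair of intervals
    # mutually intersect (one connected cluster).
    pts <- sort(as.integer(sort(sample(seq.int(lo, hi), 2L * n))))
    bp1 <- pts[seq_len(n)]
    bp2 <- pts[seq_len(n) + n]
    svs <- data.table(
      sv_id = sprintf("sv_c%d_%02d", j, seq_len(n)),
      chrom1 = ch, pos1 = bp1, dir1 = sample(c("+", "-"), n, TRUE),
      chrom2 = ch, pos2 = bp2, dir2 = sample(c("+", "-"), n, TRUE),
      type = sample(types, n, TRUE), read_ids = "",
      hap_truth = as.integer(spec$hap[j]),
      cluster_id = sprintf("cluster_%d", j))
    if (!is.null(reads)) {
      svs[, read_ids := vapply(seq_len(.N), function(k)
        supporting_read_ids(reads$reads, ch, bp1[k], bp2[k],
                            spec$hap[j]), character(1))]
    }
    sv_list[[j]] <- svs
    # oscillating copy number: n_osc transitions between states 2 and 1
    n_osc <- spec$n_cn_oscillations[j]
    if (n_osc > 0) {
      cuts <- sort(sample(seq.int(lo + 1L, hi - 1L), n_osc))
      starts <- c(lo, cuts)
      ends <- c(cuts - 1L, hi)
      states <- rep_len(c(2L, 1L), n_osc + 1L)
      cn_list[[j]] <- data.table(chrom = ch, start = as.integer(starts),
                                 end = as.integer(ends), cn = states)
    }
    truth_list[[j]] <- data.table(cluster_id = sprintf("cluster_%d", j),
                                  chrom = ch, start = lo, end = hi,
                                  hap = spec$hap[j], n_svs = n,
                                  n_cn_oscillations = n_osc)
  }
  svs <- rbindlist(sv_list)
  cn <- build_cn_table(cn_list, genome)
  list(svs = svs, cn = cn, truth = rbindlist(truth_list))
}

# flat CN 2 everywhere except the injected oscillating intervals
build_cn_table <- function(cn_list, genome) {
  osc <- rbindlist(cn_list)
  out <- list()
  for (ch in names(genome$chrom_lengths)) {
    L <- genome$chrom_lengths[[ch]]
    o <- if (nrow(osc)) osc[chrom == ch][order(start)] else osc[0]
    if (nrow(o) == 0L) {
      out[[ch]] <- data.table(chrom = ch, start = 1L, end = as.integer(L),
                              cn = 2L)
      next
    }
    segs <- list()
    cursor <- 1L
    for (k in seq_len(nrow(o))) {
      if (o$start[k] > cursor)
        segs[[length(segs) + 1L]] <- data.table(chrom = ch, start = cursor,
                                                end = o$start[k] - 1L,
                                                cn = 2L)
      segs[[length(segs) + 1L]] <- o[k, .(chrom, start, end, cn)]
      cursor <- o$end[k] + 1L
    }
    if (cursor <= L)
      segs[[length(segs) + 1L]] <- data.table(chrom = ch, start = cursor,
                                              end = as.integer(L), cn = 2L)
    out[[ch]] <- rbindlist(segs)
  }
  rbindlist(out)
}

supporting_read_ids <- function(reads, ch, p1, p2, hap, max_n = 30L) {
  sup <- reads[chrom == ch & hap_truth == hap &
                 ((start <= p1 & end >= p1) | (start <= p2 & end >= p2))]
  ids <- head(sup$read_id, max_n)
  paste(ids, collapse = ",")
}

# each read of the SNV's haplotype covering the site carries the mutant
# allele with probability min(1, 2*vaf) (VAF is measured over both
# haplotypes, the mutation sits on one).
link_mutant_reads <- function(snvs, reads) {
  empty <- data.table(snv_id = character(), read_id = character())
  if (is.null(reads) || nrow(snvs) == 0L) return(empty)
  rd <- reads$reads
  out <- vector("list", length(unique(snvs$chrom)))
  i <- 0L
  for (ch in unique(snvs$chrom)) {
    sv <- snvs[chrom == ch]
    rc <- rd[chrom == ch]
    if (nrow(rc) == 0L) next
    setkey(rc, start, end)
    q <- data.table(start = sv$pos, end = sv$pos, snv_id = sv$id,
                    hap = sv$hap_truth, vaf = sv$vaf)
    hits <- foverlaps(q, rc, type = "any", nomatch = NULL)
    hits <- hits[hap_truth == hap]
    if (nrow(hits) == 0L) next
    hits <- hits[runif(.N) < pmin(1, 2 * vaf)]
    if (nrow(hits) == 0L) next
    i <- i + 1L
    out[[i]] <- hits[, .(snv_id, read_id)]
  }
  res <- rbindlist(out[seq_len(i)])
  if (nrow(res) == 0L) return(empty)
  setkey(res, snv_id, read_id)
  res
}

make_methylation <- function(genome, config, reads) {
  spec <- config$methylation_spec
  empty <- data.table(read_id = character(), chrom = character(),
                      cpg_pos = integer(), methylated = integer(),
                      hap_truth = integer())
  if (is.null(spec) || is.null(spec$regions) || is.null(reads))
    return(list(calls = empty, truth = NULL))
  regions <- as.data.table(spec$regions)
  spacing <- spec$cpg_spacing %||% 100L
  rd <- reads$reads
  calls <- list(); truth <- list()
  for (j in seq_len(nrow(regions))) {
    ch <- regions$chrom[j]
    sites <- cpg_sites(genome, ch, regions$start[j], regions$end[j], spacing)
    if (length(sites) == 0L) next
    rc <- rd[chrom == ch & start <= regions$end[j] & end >= regions$start[j]]
    if (nrow(rc) == 0L) next
    i1 <- findInterval(rc$start - 1L, sites) + 1L
    i2 <- findInterval(rc$end, sites)
    nobs <- pmax(0L, i2 - i1 + 1L)
    keep <- nobs > 0L
    if (!any(keep)) next
    idx <- sequence(nobs[keep]) + rep(i1[keep] - 1L, nobs[keep])
    hap <- rep(rc$hap_truth[keep], nobs[keep])
    p <- ifelse(hap == 1L, regions$hp1_prob[j], regions$hp2_prob[j])
    calls[[j]] <- data.table(read_id = rep(rc$read_id[keep], nobs[keep]),
                             chrom = ch, cpg_pos = sites[idx],
                             methylated = as.integer(runif(length(idx)) < p),
                             hap_truth = hap)
    dir <- if (regions$hp1_prob[j] < regions$hp2_prob[j]) "hp1_hypo"
           else if (regions$hp2_prob[j] < regions$hp1_prob[j]) "hp2_hypo"
           else "none"
    truth[[j]] <- data.table(chrom = ch, start = regions$start[j],
                             end = regions$end[j],
                             hp1_prob = regions$hp1_prob[j],
                             hp2_prob = regions$hp2_prob[j],
                             direction = dir, n_cpgs = length(sites))
  }
  list(calls = rbindlist(calls), truth = rbindlist(truth))
}

cpg_sites <- function(genome, ch, lo, hi, spacing) {
  if (!is.null(genome$reference)) {
    seg <- substring(genome$reference[[ch]], lo, hi)
    rel <- gregexpr("CG", seg, fixed = TRUE)[[1]]
    if (rel[1] == -1L) return(integer(0))
    return(as.integer(rel) + lo - 1L)
  }
  as.integer(seq.int(lo, hi, by = spacing))
}

make_rna <- function(genome, config) {
  spec <- config$expression_spec
  empty_obs <- data.table(read_id = character(), gene_id = character(),
                          tissue = character(), chrom = character(),
                          pos = integer(), allele = character())
  empty_reads <- data.table(read_id = character(), gene_id = character(),
                            tissue = character(), hap_truth = integer())
  if (is.null(spec))
    return(list(observations = empty_obs, reads = empty_reads,
                truth = NULL))
  spec <- as.data.table(spec)
  obs <- list(); rmeta <- list(); truth <- list()
  for (j in seq_len(nrow(spec))) {
    g <- spec[j]
    gsnps <- genome$snps[chrom == g$chrom & pos >= g$start & pos <= g$end]
    for (tis in c("tumor", "normal")) {
      r1 <- if (tis == "tumor") g$tumor_hp1_rate else g$normal_hp1_rate
      r2 <- if (tis == "tumor") g$tumor_hp2_rate else g$normal_hp2_rate
      counts <- c(rpois(1L, r1), rpois(1L, r2))
      for (h in 1:2) {
        if (counts[h] == 0L) next
        rid <- sprintf("rna_%s_%s_h%d_%03d", tis, g$gene_id, h,
                       seq_len(counts[h]))
        rmeta[[length(rmeta) + 1L]] <-
          data.table(read_id = rid, gene_id = g$gene_id, tissue = tis,
                     hap_truth = h)
        if (nrow(gsnps) == 0L) next
        # a transcript read reports every exonic het SNP of the gene,
        # with the same SNP-site error model as genomic reads
        true_a <- if (h == 1L) gsnps$hp1_allele else gsnps$hp2_allele
        other_a <- if (h == 1L) gsnps$hp2_allele else gsnps$hp1_allele
        for (r in rid) {
          flip <- runif(nrow(gsnps)) < config$per_base_error
          obs[[length(obs) + 1L]] <-
            data.table(read_id = r, gene_id = g$gene_id, tissue = tis,
                       chrom = g$chrom, pos = gsnps$pos,
                       allele = ifelse(flip, other_a, true_a))
        }
      }
    }
    truth[[j]] <- data.table(gene_id = g$gene_id, chrom = g$chrom,
                             tumor_skew = g$tumor_hp1_rate /
                               (g$tumor_hp1_rate + g$tumor_hp2_rate),
                             normal_skew = g$normal_hp1_rate /
                               (g$normal_hp1_rate + g$normal_hp2_rate))
  }
  list(observations = rbindlist(obs), reads = rbindlist(rmeta),
       truth = rbindlist(truth))
}

#' Simulate a complete synthetic tumour/normal dataset
#'
#' Convenience wrapper running [simulate_diploid_genome()],
#' [simulate_long_reads()] and [inject_somatic_events()] under one seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `reads` (reads + observations), and all
#'   components of [inject_somatic_events()].
#' @export
simulate_tumor <- function(config) {
  genome <- simulate_diploid_genome(config)
  reads <- simulate_long_reads(genome, config)
  events <- inject_somatic_events(genome, config, reads)
  c(list(genome = genome, reads = reads), events)
}

#' Phase blocks from read connectivity
#'
#' Partitions the heterozygous SNPs of each chromosome into blocks by read
#' support: two consecutive SNPs share a block iff at least `min_links`
#' reads cover both positions. This mirrors how long-read depth and
#' length limit attainable block size (more or longer reads can only
#' merge blocks, never split them). It is not a phasing algorithm: the
#' alleles are left untouched; only the block partition is derived.
#'
#' @param snps phased SNP table (`chrom`, `pos`, ... as from
#'   [simulate_diploid_genome()]).
#' @param reads read table (`chrom`, `start`, `end`).
#' @return the SNP table with `block_id` replaced by connectivity blocks.
#' @export
connectivity_blocks <- function(snps, reads) {
  snps <- as.data.table(snps)
  reads <- as.data.table(reads)
  out <- copy(snps)
  setorder(out, chrom, pos)
  out[, block_id := {
    p <- pos
    n <- length(p)
    if (n <= 1L) rep(paste0(.BY[[1]], "_cb1"), n) else {
      rc <- reads[chrom == .BY[[1]]]
      if (nrow(rc) == 0L) {
        paste0(.BY[[1]], "_cb", seq_len(n))
      } else {
        setorder(rc, start)
        # farthest read end among reads starting at or before p_k; the
        # consecutive pair (p_k, p_{k+1}) is linked iff that end reaches
        # p_{k+1}
        run_max <- cummax(rc$end)
        j <- findInterval(p[-n], rc$start)
        reach <- ifelse(j == 0L, -Inf, run_max[pmax(j, 1L)])
        grp <- cumsum(c(1L, as.integer(reach < p[-1L])))
        paste0(.BY[[1]], "_cb", grp)
      }
    }
  }, by = chrom]
  out
}
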