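#' Pipeline configuration
#'
#' Bundles the simulation configuration, stage toggles and every
#' analysis threshold (at its default from the corresponding module)
#' into one validated object consumed by [run_pipeline()].
#'
#' @param sim a [sim_config()].
#' @param out_dir optional output directory for report files.
#' @param stages character vector of stages to run, a subset of
#'   `c("phasing", "snv", "sv", "bias", "chromothripsis",
#'   "methylation", "expression")`.
#' @param min_tag_snps,min_tag_ratio read-tagging rule (2, 0.7).
#' @param min_mut_reads,max_other_reads SNV assignment rule (3, 1).
#' @param min_sv_reads,min_sv_ratio SV phasing rule (3, 0.7).
#' @param min_vaf optional VAF filter for SNV assignment.
#' @param enrich_window,enrich_alpha enrichment windows (1e5, 0.05).
#' @param bias_min_phased,bias_threshold biased-region rule (5, 0.8).
#' @param dmr_min_cpgs,dmr_min_diff,dmr_q_alpha DMR caller (5, 0.3,
#'   0.05).
#' @param dmr_bias_min,dmr_bias_ratio,dmr_bias_per_mb DMR-bias block
#'   rule (3, 0.7, 3).
#' @param ct_min_svs,ct_min_osc2,ct_min_osc3,ct_min_sv_density,ct_min_cn_density
#'   chromothripsis criteria (10, 4, 6, 0.2, 0.2).
#' @param ase_alpha,ase_min_total allele-specific expression test
#'   (0.05, 10).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            out_dir = NULL,
                            stages = c("phasing", "snv", "sv", "bias",
                                       "chromothripsis", "methylation",
                                       "expression"),
                            min_tag_snps = 2L, min_tag_ratio = 0.7,
                            min_mut_reads = 3L, max_other_reads = 1L,
                            min_sv_reads = 3L, min_sv_ratio = 0.7,
                            min_vaf = NULL,
                            enrich_window = 1e5, enrich_alpha = 0.05,
                            bias_min_phased = 5L, bias_threshold = 0.8,
                            dmr_min_cpgs = 5L, dmr_min_diff = 0.3,
                            dmr_q_alpha = 0.05,
                            dmr_bias_min = 3L, dmr_bias_ratio = 0.7,
                            dmr_bias_per_mb = 3,
                            ct_min_svs = 10L, ct_min_osc2 = 4L,
                            ct_min_osc3 = 6L, ct_min_sv_density = 0.2,
                            ct_min_cn_density = 0.2,
                            ase_alpha = 0.05, ase_min_total = 10L) {
  known <- c("phasing", "snv", "sv", "bias", "chromothripsis",
             "methylation", "expression")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop_config("stages", paste("unknown stage(s):",
                                paste(bad, collapse = ", ")))
  ratios <- c(min_tag_ratio, min_sv_ratio, bias_threshold, dmr_bias_ratio)
  if (any(ratios < 0 | ratios > 1))
    stop_config("ratios", "thresholds expressed as ratios must be in [0,1]")
  cfg <- as.list(environment())
  cfg$known <- NULL
  cfg$bad <- NULL
  cfg$ratios <- NULL
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Simulates a tumour/normal dataset, tags reads, phases somatic SNVs
#' and SVs, and runs the enabled downstream analyses (biased regions,
#' chromothripsis calling, methylation DMR bias, allele-specific
#' expression). Deterministic given the simulation seed.
#'
#' @param config a [pipeline_config()].
#' @return list with the intermediate tables and `summary`, a
#'   machine-readable list of per-stage record counts and headline
#'   calls. When `config$out_dir` is set, report TSVs and
#'   `summary.json` are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  need <- function(stage, dependent) {
    if (!stage %in% stages)
      stop(sprintf("stage '%s' requires disabled stage '%s'",
                   dependent, stage), call. = FALSE)
  }
  sim <- simulate_tumor(config$sim)
  res <- list(sim = sim)
  summary <- list(seed = config$sim$seed,
                  n_snps = nrow(sim$genome$snps),
                  n_reads = nrow(sim$reads$reads),
                  n_somatic_snvs = nrow(sim$snvs),
                  n_svs = nrow(sim$svs))

  if ("phasing" %in% stages) {
    res$tags <- tag_reads(sim$reads$observations, sim$genome$snps,
                          config$min_tag_snps, config$min_tag_ratio)
    res$blocks <- phased_blocks(sim$genome$snps)
    summary$n_tagged_reads <-
      sum(res$tags$label != "untagged")
    summary$n_blocks <- nrow(res$blocks)
  }
  if ("snv" %in% stages) {
    need("phasing", "snv")
    res$phased_snvs <- phase_snvs(sim$snvs, sim$mutant_reads, res$tags,
                                  config$min_mut_reads,
                                  config$max_other_reads, config$min_vaf)
    summary$n_snvs_phased <- sum(res$phased_snvs$hap != "unknown")
  }
  if ("sv" %in% stages) {
    need("phasing", "sv")
    res$phased_svs <- phase_svs(sim$svs, res$tags,
                                config$min_sv_reads, config$min_sv_ratio)
    summary$n_svs_phased <- sum(res$phased_svs$hap != "unknown")
  }
  if ("bias" %in% stages) {
    need("snv", "bias")
    enriched <- find_enriched_windows(
      res$phased_snvs, sim$genome$chrom_lengths,
      window = config$enrich_window, alpha = config$enrich_alpha)
    res$biased_regions <- call_biased_regions(
      enriched, res$phased_snvs, config$bias_min_phased,
      config$bias_threshold)
    summary$n_enriched_windows <- nrow(enriched)
    summary$n_biased_regions <-
      sum(!is.na(res$biased_regions$biased_hap))
  }
  if ("chromothripsis" %in% stages) {
    need("sv", "chromothripsis")
    res$chromothripsis <- chromothripsis_calls(
      res$phased_svs, sim$cn,
      min_svs = config$ct_min_svs, min_osc2 = config$ct_min_osc2,
      min_osc3 = config$ct_min_osc3,
      min_sv_density = config$ct_min_sv_density,
      min_cn_density = config$ct_min_cn_density)
    summary$n_chromothripsis <- sum(res$chromothripsis$passed)
  }
  if ("methylation" %in% stages && nrow(sim$methylation)) {
    need("phasing", "methylation")
    freqs <- haplotype_methylation_frequency(sim$methylation, res$tags)
    res$dmrs <- call_dmrs(freqs, config$dmr_min_cpgs,
                          config$dmr_min_diff, config$dmr_q_alpha)
    res$dmr_blocks <- dmr_bias_blocks(
      res$dmrs, NULL, res$blocks, config$dmr_bias_min,
      config$dmr_bias_ratio, config$dmr_bias_per_mb)
    summary$n_dmrs <- nrow(res$dmrs)
    summary$n_dmr_bias_blocks <- nrow(res$dmr_blocks)
  }
  if ("expression" %in% stages && nrow(sim$rna)) {
    rna_tags <- tag_rna_reads(sim$rna, sim$genome$snps,
                              config$min_tag_snps, config$min_tag_ratio)
    cnts <- allelic_counts(sim$rna, rna_tags)
    res$ase <- allelic_expression_test(cnts, config$ase_alpha,
                                       config$ase_min_total)
    summary$n_ase_snps_tested <- sum(res$ase$snps$status == "tested")
    summary$n_ase_tumor_specific <- sum(res$ase$snps$tumor_specific)
  }
  res$summary <- summary

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    outp <- function(f) file.path(config$out_dir, f)
    if (!is.null(res$blocks)) write_bed(res$blocks, outp("blocks.bed"))
    if (!is.null(res$phased_snvs))
      write_somatic_vcf(res$phased_snvs, outp("somatic_phased.vcf"))
    if (!is.null(res$phased_svs))
      write_tsv(res$phased_svs, outp("svs_phased.tsv"))
    if (!is.null(res$biased_regions))
      write_tsv(res$biased_regions, outp("biased_regions.tsv"))
    if (!is.null(res$chromothripsis))
      write_tsv(res$chromothripsis, outp("chromothripsis.tsv"))
    if (!is.null(res$dmrs)) write_tsv(res$dmrs, outp("dmrs.tsv"))
    if (!is.null(res$dmr_blocks))
      write_tsv(res$dmr_blocks, outp("dmr_bias_blocks.tsv"))
    if (!is.null(res$ase)) {
      write_tsv(res$ase$snps, outp("ase_snps.tsv"))
      write_tsv(res$ase$genes, outp("ase_genes.tsv"))
    }
    jsonlite::write_json(summary, outp("summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
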