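#' Write a table as TSV
#' @param x data.frame. @param path output file.
#' @export
write_tsv <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t")
  invisible(path)
}

#' Read a TSV table
#' @param path file. @return data.table.
#' @export
read_tsv <- function(path) fread(path, sep = "\t")

#' Write intervals as BED (0-based half-open)
#'
#' Internal coordinates are 1-based inclusive; BED output converts to
#' 0-based half-open.
#'
#' @param x data.frame with `chrom`, `start`, `end` and optionally a
#'   `name` column.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  d <- as.data.table(x)
  bed <- d[, .(chrom, start = start - 1L, end)]
  if ("name" %in% names(d)) bed[, name := d$name]
  else if ("block_id" %in% names(d)) bed[, name := d$block_id]
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write reference sequences as FASTA
#' @param reference named character vector of sequences.
#' @param path output file. @param width line width.
#' @export
write_fasta <- function(reference, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(reference)) {
    writeLines(paste0(">", nm), con)
    s <- reference[[nm]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Write reads as minimal SAM with haplotype tags
#'
#' Emits one alignment line per read with a full-match CIGAR, `SEQ`
#' omitted (`*`), and `HP`/`PS` tags from the haplotag table, so
#' downstream tools that honour HP/PS can consume simulated reads
#' without an aligner.
#'
#' @param reads read table (`read_id`, `chrom`, `start`, `end`).
#' @param chrom_lengths named chromosome lengths (header `@SQ` lines).
#' @param path output file.
#' @param tags optional haplotag table from [tag_reads()].
#' @export
write_sam <- function(reads, chrom_lengths, path, tags = NULL) {
  rd <- as.data.table(reads)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  hp <- rep(NA_integer_, nrow(rd))
  ps <- rep(NA_character_, nrow(rd))
  if (!is.null(tags)) {
    tg <- as.data.table(tags)[label %in% c("HP1", "HP2")]
    tg <- tg[order(read_id, -n_obs)][!duplicated(read_id)]
    i <- match(rd$read_id, tg$read_id)
    hp[!is.na(i)] <- as.integer(sub("HP", "", tg$label[i[!is.na(i)]]))
    ps[!is.na(i)] <- tg$block_id[i[!is.na(i)]]
  }
  opt <- ifelse(is.na(hp), "",
                paste0("\tHP:i:", hp, "\tPS:Z:", ps))
  rows <- paste0(rd$read_id, "\t0\t", rd$chrom, "\t", rd$start, "\t60\t",
                 rd$end - rd$start + 1L, "M\t*\t0\t0\t*\t*", opt)
  setorder(rd, chrom, start)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write somatic variants as an annotated VCF
#'
#' INFO carries `VAF`, the assigned haplotype (`HAP=HP1/HP2/unknown`)
#' and the phase block (`PS=`) when known.
#'
#' @param variants phased variant table (from [phase_snvs()]).
#' @param path output file.
#' @export
write_somatic_vcf <- function(variants, path) {
  v <- as.data.table(variants)
  setorder(v, chrom, pos)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
           "##INFO=<ID=HAP,Number=1,Type=String,Description=\"Assigned haplotype\">",
           "##INFO=<ID=PS,Number=1,Type=String,Description=\"Phase block\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- paste0("VAF=", signif(v$vaf, 4), ";HAP=",
                 if ("hap" %in% names(v)) v$hap else "unknown",
                 ifelse("block_id" %in% names(v) & !is.na(v$block_id),
                        paste0(";PS=", v$block_id), ""))
  rows <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", info,
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a somatic VCF written by [write_somatic_vcf()] (or any VCF with
#' an INFO `VAF` field)
#' @param path VCF file.
#' @return data.table: `id`, `chrom`, `pos`, `ref`, `alt`, `vaf`, `hap`.
#' @export
read_somatic_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L)
    return(data.table(id = character(), chrom = character(),
                      pos = integer(), ref = character(),
                      alt = character(), vaf = numeric(),
                      hap = character()))
  f <- tstrsplit(body, "\t", fixed = TRUE)
  info <- f[[8]]
  grab <- function(key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    out <- rep(NA_character_, length(info))
    out[grepl(paste0(key, "="), info)] <- sub(paste0(key, "="), "", m)
    out
  }
  data.table(id = f[[3]], chrom = f[[1]], pos = as.integer(f[[2]]),
             ref = f[[4]], alt = f[[5]],
             vaf = as.numeric(grab("VAF")), hap = grab("HAP"))
}
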