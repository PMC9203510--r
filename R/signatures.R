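#' The 96 trinucleotide substitution categories
#'
#' Pyrimidine-centric single-base-substitution categories in the
#' conventional catalogue order: substitution class (C>A, C>G, C>T, T>A,
#' T>C, T>G), then 5' base, then 3' base, written as e.g. `"A[C>T]G"`.
#'
#' @return character vector of length 96.
#' @export
sbs_categories <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) for (p5 in bases) for (p3 in bases)
    out <- c(out, paste0(p5, "[", s, "]", p3))
  out
}

#' Built-in synthetic mutational signatures
#'
#' A small signature catalogue for tests and synthetic-data generation.
#' These are synthetic stand-ins constructed in code, not the COSMIC
#' reference profiles: `"APOBEC-like"` concentrates probability on C>T
#' and C>G changes in a TpC context (the hallmark of APOBEC deamination
#' and of kataegis), `"aging-like"` on C>T at CpG sites, and `"flat"` is
#' uniform. A user-supplied COSMIC-format matrix (96 rows, one column per
#' signature) can be used anywhere this catalogue is accepted.
#'
#' @return a 96 x 3 numeric matrix; rows are [sbs_categories()], columns
#'   sum to 1.
#' @export
builtin_signatures <- function() {
  cats <- sbs_categories()
  apobec <- setNames(rep(0.1 / 92, 96), cats)
  apobec[c("T[C>T]A", "T[C>T]T")] <- 0.30
  apobec[c("T[C>G]A", "T[C>G]T")] <- 0.15
  aging <- setNames(rep(0.2 / 92, 96), cats)
  aging[paste0(c("A", "C", "G", "T"), "[C>T]G")] <- 0.2
  flat <- rep(1 / 96, 96)
  m <- cbind(`APOBEC-like` = apobec / sum(apobec),
             `aging-like` = aging / sum(aging),
             flat = flat)
  rownames(m) <- cats
  m
}
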