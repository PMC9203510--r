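#' N50 of a set of lengths
#'
#' The N50 is the length \eqn{L} such that elements of length \eqn{\ge L}
#' jointly cover at least half of the total length. It is the standard
#' summary for both read-length and phased-block-length distributions.
#'
#' @param lengths numeric vector of non-negative lengths.
#' @return a single number; 0 for an empty input.
#' @examples
#' n50(c(1, 1, 1, 1, 1, 1, 1, 1, 2, 10) * 1000)  # 10000
#' @export
n50 <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  if (length(lengths) == 0L || sum(lengths) == 0) return(0)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

# Derive a reproducible stage seed from the run seed. Offsets are fixed
# per stage so stages are independently reproducible; kept < 2^31.
sub_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

# complement / reverse complement for plain character vectors
comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b)
    paste(rev(unname(comp_base[b])), collapse = ""), character(1))
}
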