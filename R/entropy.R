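#' Shannon entropy of a nucleotide sequence
#'
#' Computes \eqn{H(S) = -\sum_i p(s_i) \log_2 p(s_i)} over the empirical
#' mononucleotide frequencies of the sequence.  For the 4-letter DNA
#' alphabet the result lies in \[0, 2\] bits.  Seeds are required to exceed
#' an entropy threshold (default 1.5 bits) so that low-complexity matches,
#' e.g. from poly-A tails, are discarded.
#'
#' @param s character vector of non-empty sequences.
#' @return numeric vector of entropies in bits.
#' @examples
#' shannon_entropy("AACG")          # 1.5
#' shannon_entropy("ACGTACGTACGT")  # 2.0
#' @export
shannon_entropy <- function(s) {
  vapply(as.character(s), function(x) {
    if (is.na(x) || !nzchar(x)) stop("shannon_entropy: empty sequence")
    p <- table(strsplit(x, "", fixed = TRUE)[[1]])
    p <- as.numeric(p) / sum(p)
    -sum(p * log2(p))
  }, numeric(1), USE.NAMES = FALSE)
}
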