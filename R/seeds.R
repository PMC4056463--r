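#' Collect filtered seed alignments for all suffixes of a read
#'
#' Every suffix of the read and of its reverse complement is matched against
#' the index; the longest exact prefix of each suffix that occurs in the
#' genome becomes a candidate seed (with an optional single-substitution
#' extension for unique-locus seeds when `max_seed_errors >= 1`).  At most
#' `2(m - l)` suffixes are examined.  Candidates are kept when the covered
#' read substring has Shannon entropy at or above `entropy_threshold` and
#' the seed occurs at most `max_occurrences` times.  The seed score is
#' matches minus (mismatches + insertions + deletions).
#'
#' @param read a single read sequence (A,C,G,T,N; uppercased internally).
#' @param index a [build_index()] result.
#' @param params a [seed_params()] object.
#' @return a data.frame with one row per seed group: `read_start`,
#'   `read_end` (0-based inclusive read interval), `score`, `strand`,
#'   `n_occ`, `entropy`, and a list-column `occurrences` of data.frames with
#'   `chrom`, `ref_start`, `ref_end` (0-based half-open forward coordinates)
#'   and `strand`.  Reads shorter than the minimum suffix length yield an
#'   empty set with a warning.
#' @export
collect_seeds <- function(read, index, params = seed_params()) {
  read <- toupper(as.character(read))
  empty <- data.frame(read_start = integer(), read_end = integer(),
                      score = integer(), strand = character(),
                      n_occ = integer(), entropy = numeric(),
                      stringsAsFactors = FALSE)
  empty$occurrences <- list()
  if (nchar(read) <= params$min_suffix_length) {
    warning("read shorter than min_suffix_length; no seeds collected")
    return(empty)
  }
  raw <- collect_seeds_raw(read, index, params)
  if (length(raw$read_start) == 0L) return(empty)
  strand <- c("+", "-")[raw$strand + 1L]
  occurrences <- lapply(seq_along(raw$occ), function(i) {
    loc <- text_to_genomic(index, raw$occ[[i]])
    data.frame(chrom = loc$chrom, ref_start = loc$pos,
               ref_end = loc$pos + raw$ref_len[i],
               strand = strand[i], stringsAsFactors = FALSE)
  })
  out <- data.frame(read_start = raw$read_start, read_end = raw$read_end,
                    score = raw$score, strand = strand,
                    n_occ = raw$n_occ, entropy = raw$entropy,
                    stringsAsFactors = FALSE)
  out$occurrences <- occurrences
  out[order(out$read_start, out$read_end, out$strand), , drop = FALSE]
}

# thin wrapper kept separate so the per-read pipeline can use the raw
# C++ result without data.frame overhead
collect_seeds_raw <- function(read, index, params) {
  collect_seeds_cpp(index$text, index$sa, read,
                    params$min_suffix_length, params$max_occurrences,
                    params$entropy_threshold, params$max_seed_errors)
}
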