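#' Seed-finding parameters
#'
#' @param min_suffix_length minimum seed (suffix match) length in nt;
#'   must be >= 10.  Default 20.
#' @param max_occurrences maximum number of genomic occurrences a seed may
#'   have before it is discarded as repetitive.  Default 50.
#' @param max_seed_errors seed error budget; when >= 1, unique-locus seeds
#'   are extended through a single substitution.  Default 1.
#' @param entropy_threshold minimum Shannon entropy (bits) of the read
#'   substring covered by a seed.  Default 1.5.
#' @param min_accuracy minimum percent identity of the final alignment for a
#'   read to be reported.  Default 80.
#' @return a list of class `seed_params`.
#' @export
seed_params <- function(min_suffix_length = 20L, max_occurrences = 50L,
                        max_seed_errors = 1L, entropy_threshold = 1.5,
                        min_accuracy = 80) {
  stopifnot(min_suffix_length >= 10L, max_occurrences >= 1L,
            entropy_threshold >= 0, max_seed_errors >= 0L)
  structure(list(min_suffix_length = as.integer(min_suffix_length),
                 max_occurrences = as.integer(max_occurrences),
                 max_seed_errors = as.integer(max_seed_errors),
                 entropy_threshold = entropy_threshold,
                 min_accuracy = min_accuracy),
            class = "seed_params")
}

#' Build a suffix-array index over a reference genome
#'
#' Chromosomes are concatenated (separated by sentinels that cannot match
#' read characters) and indexed with a suffix array, supporting maximal
#' exact-prefix queries for every read suffix on both strands.  Reverse
#' strand hits are reported in forward coordinates with strand `-`.
#'
#' @param genome a [reference_genome()] object.
#' @return an object of class `suffix_index`.
#' @export
build_index <- function(genome) {
  if (!inherits(genome, "reference_genome")) genome <- reference_genome(genome)
  text <- paste0(paste(genome$sequences, collapse = "#"), "#")
  chrom_starts <- c(0L, cumsum(genome$lengths + 1L))
  chrom_starts <- chrom_starts[seq_along(genome$lengths)]
  sa <- sa_build_cpp(text)
  structure(list(text = text, sa = sa,
                 chrom_names = names(genome$sequences),
                 chrom_starts = as.integer(chrom_starts),
                 chrom_lengths = as.integer(genome$lengths),
                 genome = genome,
                 version = "splitmap-index-1"),
            class = "suffix_index")
}

#' @export
print.suffix_index <- function(x, ...) {
  cat("suffix_index (", x$version, "): ", length(x$chrom_names),
      " sequence(s), ", format(nchar(x$text), big.mark = ","),
      " indexed positions\n", sep = "")
  invisible(x)
}

#' Save / load a suffix index
#'
#' The index is persisted as a single serialized archive carrying a version
#' tag; [read_index()] refuses files written by an incompatible version.
#'
#' @param index a `suffix_index` object.
#' @param path file path.
#' @return `path` (write) or the index (read).
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "suffix_index"))
  saveRDS(index, path)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  index <- readRDS(path)
  if (!inherits(index, "suffix_index") ||
      !identical(index$version, "splitmap-index-1")) {
    stop("not a splitmap index (or incompatible version): ", path)
  }
  index
}

# map a position in the concatenated text to (chrom, 0-based position)
text_to_genomic <- function(index, pos) {
  ci <- findInterval(pos, index$chrom_starts)
  list(chrom = index$chrom_names[ci],
       pos = pos - index$chrom_starts[ci],
       chrom_idx = ci)
}

# forward-strand genomic slice [start, end) as a string (0-based, half-open)
genomic_slice <- function(index, chrom_idx, start, end) {
  off <- index$chrom_starts[chrom_idx]
  substr(index$text, off + start + 1L, off + end)
}

#' Locate all exact occurrences of a pattern in the indexed genome
#'
#' Searches both strands; minus-strand hits are reported in forward
#' coordinates.
#'
#' @param index a `suffix_index`.
#' @param pattern a single A/C/G/T string.
#' @return data.frame with columns `chrom`, `start` (0-based), `end`
#'   (half-open) and `strand`.
#' @export
query_index <- function(index, pattern) {
  pattern <- toupper(as.character(pattern))
  hits <- function(pat, strand) {
    res <- sa_find_cpp(index$text, index$sa, pat)
    if (length(res$positions) == 0L) return(NULL)
    loc <- text_to_genomic(index, res$positions)
    data.frame(chrom = loc$chrom, start = loc$pos,
               end = loc$pos + nchar(pat), strand = strand,
               stringsAsFactors = FALSE)
  }
  out <- rbind(hits(pattern, "+"),
               if (pattern != revcomp(pattern)) hits(revcomp(pattern), "-") else NULL)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}
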