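#' Construct a reference genome object
#'
#' A reference genome is a named set of chromosome sequences over the
#' alphabet A, C, G, T, N.  Sequences are uppercased on input.
#'
#' @param sequences named character vector (or named list of single strings)
#'   of chromosome sequences.
#' @return an object of class `reference_genome` with elements `sequences`
#'   (named character) and `lengths` (named integer).
#' @examples
#' reference_genome(c(chr1 = "ACGTACGT"))
#' @export
reference_genome <- function(sequences) {
  sequences <- vapply(sequences, as.character, character(1))
  if (length(sequences) == 0L) stop("empty genome: no sequences given")
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) stop("all sequences must be named")
  if (anyDuplicated(nm)) stop("duplicated chromosome names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences))) {
    stop("empty sequence for: ", paste(nm[!nzchar(sequences)], collapse = ", "))
  }
  bad <- vapply(sequences, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ", paste(nm[bad], collapse = ", "))
  }
  structure(list(sequences = sequences,
                 lengths = setNames(nchar(sequences), nm)),
            class = "reference_genome")
}

#' Read a reference genome from a (multi-record, wrapped) FASTA file
#'
#' @param path path to a FASTA file.
#' @return a [reference_genome()] object.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  # FASTA description lines: keep the first word as the chromosome name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  reference_genome(seqs)
}

#' Write a reference genome to FASTA
#'
#' @param genome a [reference_genome()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "reference_genome"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$sequences), path)
  invisible(path)
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("reference_genome:", length(x$sequences), "sequence(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "nt total\n")
  for (nm in head(names(x$sequences), 10)) {
    cat("  ", nm, ": ", format(x$lengths[[nm]], big.mark = ","), " nt\n", sep = "")
  }
  invisible(x)
}

#' Reverse complement of plain character sequences
#'
#' @param x character vector of DNA sequences (A,C,G,T,N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# scalar reverse complement without Biostrings overhead (hot loops)
revcomp1 <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# base at a genomic position as read on a given strand (0-based position)
char_at <- function(genome, chrom, pos, strand) {
  b <- substr(genome$sequences[[chrom]], pos + 1L, pos + 1L)
  if (strand == "-") b <- chartr("ACGTN", "TGCAN", b)
  b
}
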