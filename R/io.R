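#' Read single-end reads from FASTA or FASTQ
#'
#' @param path input file; format detected from the first character.
#' @return data.frame with `id`, `sequence` and `quality` (all `I` for
#'   FASTA input).
#' @export
read_reads <- function(path) {
  first <- substr(readLines(path, n = 1L), 1L, 1L)
  if (identical(first, "@")) {
    ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(ss)$qualities)
  } else {
    ss <- Biostrings::readDNAStringSet(path)
    qual <- strrep("I", Biostrings::width(ss))
  }
  data.frame(id = sub("\\s.*$", "", names(ss)),
             sequence = as.character(ss), quality = qual,
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ (Sanger qualities)
#'
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id), reads$sequence,
                           "+", reads$quality))
  writeLines(lines, path)
  invisible(path)
}

#' Write junction calls as a BED-like table
#'
#' Tab-separated with one line per junction: donor chromosome and 1-based
#' position, acceptor chromosome and 1-based position, class, split-read
#' support and the two strand flags.
#'
#' @param junctions aggregated junction data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_junctions_bed <- function(junctions, path) {
  df <- data.frame(chrom1 = junctions$chrom1, pos1 = junctions$pos1 + 1L,
                   chrom2 = junctions$chrom2, pos2 = junctions$pos2 + 1L,
                   class = junctions$class, support = junctions$support,
                   strand1 = junctions$strand1, strand2 = junctions$strand2,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_junctions_bed
#' @export
read_junctions_bed <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$pos1 <- df$pos1 - 1L
  df$pos2 <- df$pos2 - 1L
  df
}

#' Write inter-chromosomal junctions as BEDPE
#'
#' @param junctions aggregated junction data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_junctions_bedpe <- function(junctions, path) {
  j <- junctions[junctions$chrom1 != junctions$chrom2, , drop = FALSE]
  df <- data.frame(chrom1 = j$chrom1, start1 = j$pos1, end1 = j$pos1 + 1L,
                   chrom2 = j$chrom2, start2 = j$pos2, end2 = j$pos2 + 1L,
                   name = paste0("junction_", seq_len(nrow(j))),
                   score = j$support, strand1 = j$strand1,
                   strand2 = j$strand2, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write / read a truth-junction table as TSV
#'
#' @param truth the `$truth` data.frame from [simulate_isoforms()].
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
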