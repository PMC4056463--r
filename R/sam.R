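#' Write split alignments as SAM
#'
#' Each read yields one primary record (its highest-scoring fragment) and
#' one supplementary record (flag 0x800) per additional fragment;
#' minus-strand fragments carry the reverse-complement flag and store the
#' reverse-complemented sequence with a genome-forward CIGAR.  Unaligned
#' read ends are soft-clipped, so the split structure is recoverable from
#' positions and CIGARs alone.
#'
#' @param alignments list of `split_alignment` objects (e.g.
#'   `$alignments` from [map_reads()]).
#' @param reads data.frame with `id`, `sequence` and optionally `quality`
#'   for the sequences to emit.
#' @param index the `suffix_index` the alignments refer to (for the
#'   header).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (i in seq_along(index$chrom_names)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", index$chrom_names[i],
                       index$chrom_lengths[i]), con)
  }
  writeLines(sprintf("@PG\tID:splitmap\tPN:splitmap\tVN:%s",
                     as.character(utils::packageVersion("splitmap"))), con)
  seqs <- setNames(toupper(reads$sequence), reads$id)
  quals <- if ("quality" %in% names(reads)) setNames(reads$quality, reads$id)
           else setNames(strrep("I", nchar(reads$sequence)), reads$id)
  aligned <- character(0)
  for (aln in alignments) {
    aligned <- c(aligned, aln$read_id)
    seq <- seqs[[aln$read_id]]
    qual <- quals[[aln$read_id]]
    m <- nchar(seq)
    fr <- aln$fragments
    primary <- which.max(fr$score)
    for (f in seq_len(nrow(fr))) {
      flag <- 0L
      if (fr$strand[f] == "-") flag <- flag + 16L
      if (f != primary) flag <- flag + 2048L
      cigar <- frag_cigar(fr[f, ], m)
      if (fr$strand[f] == "-") {
        sq <- revcomp1(seq)
        ql <- paste(rev(strsplit(qual, "", fixed = TRUE)[[1]]), collapse = "")
      } else {
        sq <- seq; ql <- qual
      }
      nm <- nchar(gsub("[M]", "", fr$ops[f]))
      writeLines(paste(aln$read_id, flag, fr$chrom[f], fr$ref_start[f] + 1L,
                       if (f == primary) 60L else 3L, cigar, "*", 0L, 0L,
                       sq, ql, sprintf("NM:i:%d", nm),
                       sprintf("AS:i:%d", fr$score[f]), sep = "\t"), con)
    }
  }
  for (id in setdiff(reads$id, aligned)) {
    writeLines(paste(id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                     seqs[[id]], quals[[id]], sep = "\t"), con)
  }
  invisible(path)
}

# CIGAR of one fragment, with soft clips for the unaligned read ends;
# minus-strand fragments are emitted in genome-forward orientation
frag_cigar <- function(f, read_len) {
  ops <- strsplit(f$ops, "", fixed = TRUE)[[1]]
  ops[ops == "X"] <- "M"
  left <- f$read_start
  right <- read_len - 1L - f$read_end
  if (f$strand == "-") {
    ops <- rev(ops)
    tmp <- left; left <- right; right <- tmp
  }
  r <- rle(ops)
  body <- paste0(r$lengths, r$values, collapse = "")
  paste0(if (left > 0L) paste0(left, "S") else "", body,
         if (right > 0L) paste0(right, "S") else "")
}
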