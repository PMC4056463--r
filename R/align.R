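#' Transition-alignment parameters
#'
#' @param match match score (> 0).  Default 1.
#' @param mismatch mismatch score (< 0).  Default -1.
#' @param indel indel penalty delta (> 0, subtracted).  Default 1.
#' @param transition transition penalty tau (>= 0) paid for every jump
#'   between loci.  Default 3.
#' @param boundary_extension nt added to each side of a seed's reference
#'   interval when its alignment window is cut from the genome.  Must be
#'   comfortably larger than the minimum seed length: a sequencing error
#'   closer than one seed length to a junction truncates the flanking seed,
#'   and the window must still reach across the true boundary.  Default 30.
#' @param min_fragment_length fragments shorter than this are trimmed from
#'   the alignment ends (suppresses spurious 1-2 nt fragments at window
#'   edges).  Default 15.
#' @param min_transition_gap minimum shift of the alignment diagonal
#'   (genomic position minus read position, strand-adjusted) for two
#'   chain-adjacent seeds to count as distinct loci; seeds shifted by less
#'   (error-split continuations of one exon) share a single window.  This
#'   doubles as the minimum callable intron/junction span.  Default 50.
#' @return a list of class `align_params`.
#' @export
align_params <- function(match = 1L, mismatch = -1L, indel = 1L,
                         transition = 3L, boundary_extension = 30L,
                         min_fragment_length = 15L, min_transition_gap = 50L) {
  stopifnot(indel > 0, transition >= 0, boundary_extension >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 indel = as.integer(indel), transition = as.integer(transition),
                 boundary_extension = as.integer(boundary_extension),
                 min_fragment_length = as.integer(min_fragment_length),
                 min_transition_gap = as.integer(min_transition_gap)),
            class = "align_params")
}

#' Semi-global alignment of a read against a reference window
#'
#' Minimal edit distance of the whole read against any substring of the
#' window (gaps at the window ends are free).  Ties are broken towards the
#' leftmost end position.
#'
#' @param read,window non-empty sequences.
#' @return list with `distance`, `end` (0-based exclusive end in the
#'   window), `start` (0-based start), and `ops` (per-column edit string
#'   over M, X, I, D; I = base present only in the read).
#' @export
semi_global_align <- function(read, window) {
  read <- toupper(as.character(read)); window <- toupper(as.character(window))
  stopifnot(nzchar(read), nzchar(window))
  semi_global_cpp(read, window)
}

#' Cut (extended) alignment windows for a resolved chain
#'
#' One window per chained locus, in chain order: the seed's reference
#' interval widened by `boundary_extension` on both sides and clipped to
#' the chromosome.  Minus-strand windows are reverse complemented so that
#' the read aligns to them in its own orientation.  Seeds that are
#' collinear continuations of the same locus (same chromosome and strand,
#' alignment diagonals within `min_transition_gap`) are merged into one
#' window, so sequencing errors inside an exon do not masquerade as
#' transitions.
#'
#' @param chain a resolved `seed_chain` (see [resolve_occurrences()]).
#' @param genome a [reference_genome()] object.
#' @param params an [align_params()] object.
#' @param merge_collinear set `FALSE` to force one window per seed.
#' @return data.frame with columns `seq`, `chrom`, `start`, `end`
#'   (0-based half-open, forward coordinates) and `strand`, in chain order.
#' @export
extract_windows <- function(chain, genome, params = align_params(),
                            merge_collinear = TRUE) {
  stopifnot(inherits(chain, "seed_chain"))
  s <- chain$seeds
  if (!all(c("chrom", "ref_start", "ref_end", "strand") %in% names(s))) {
    stop("chain is not resolved; call resolve_occurrences() first")
  }
  w <- data.frame(chrom = s$chrom, start = s$ref_start, end = s$ref_end,
                  strand = s$strand, stringsAsFactors = FALSE)
  # alignment diagonal: constant along a gapless continuation of one locus
  diag <- ifelse(s$strand == "+", s$ref_start - s$read_start,
                 s$ref_end + s$read_start)
  if (merge_collinear && nrow(w) > 1L) {
    keep <- rep(TRUE, nrow(w))
    for (i in 2:nrow(w)) {
      j <- max(which(keep[1:(i - 1L)]))
      if (w$chrom[i] == w$chrom[j] && w$strand[i] == w$strand[j] &&
          abs(diag[i] - diag[j]) < params$min_transition_gap) {
        w$start[j] <- min(w$start[j], w$start[i])
        w$end[j] <- max(w$end[j], w$end[i])
        keep[i] <- FALSE
      }
    }
    w <- w[keep, , drop = FALSE]
  }
  ext <- params$boundary_extension
  w$start <- pmax(0L, w$start - ext)
  w$end <- pmin(unname(genome$lengths[w$chrom]), w$end + ext)
  w$seq <- vapply(seq_len(nrow(w)), function(i) {
    sl <- substr(genome$sequences[[w$chrom[i]]], w$start[i] + 1L, w$end[i])
    if (w$strand[i] == "-") revcomp(sl) else sl
  }, character(1))
  rownames(w) <- NULL
  w[, c("seq", "chrom", "start", "end", "strand")]
}

#' Local transition alignment of a read across its chained loci
#'
#' Runs the three-dimensional local alignment over (read position, locus,
#' locus position): every cell takes the best of 0, a diagonal
#' match/mismatch, an indel, or a penalized transition continuing from the
#' running maximum (`lms`) of any preceding locus.  With a single window
#' the recursion reduces exactly to Smith-Waterman.  The traceback of the
#' maximal cell yields an ordered multi-fragment split alignment.
#'
#' @param read the read sequence.
#' @param windows a window data.frame from [extract_windows()] (or a plain
#'   character vector of window sequences).
#' @param params an [align_params()] object.
#' @param read_id identifier stored in the result.
#' @return an object of class `split_alignment` with elements `read_id`,
#'   `fragments` (data.frame: `read_start`, `read_end` 0-based inclusive,
#'   `chrom`, `ref_start`, `ref_end` 0-based half-open, `strand`, `ops`,
#'   `score`), `score`, `transitions`; or `NULL` when no cell exceeds 0
#'   (read unmapped).
#' @export
transition_align <- function(read, windows, params = align_params(),
                             read_id = "read") {
  read <- toupper(as.character(read))
  if (is.character(windows)) {
    windows <- data.frame(seq = toupper(windows),
                          chrom = paste0("window", seq_along(windows)),
                          start = 0L, end = nchar(windows), strand = "+",
                          stringsAsFactors = FALSE)
  }
  stopifnot(nrow(windows) >= 1L)
  res <- transition_align_cpp(read, windows$seq, params$match,
                              params$mismatch, params$indel,
                              params$transition)
  build_split_alignment(res, windows, params, read_id)
}

# shared by transition_align() and the per-read pipeline
build_split_alignment <- function(res, windows, params, read_id) {
  if (res$total <= 0 || length(res$fragments) == 0L) return(NULL)
  fr <- do.call(rbind, lapply(res$fragments, function(f) {
    k <- f$window
    wlen <- nchar(windows$seq[k])
    if (windows$strand[k] == "+") {
      rs <- windows$start[k] + f$win_start
      re <- windows$start[k] + f$win_end + 1L
    } else {
      rs <- windows$start[k] + (wlen - 1L - f$win_end)
      re <- windows$start[k] + (wlen - f$win_start)
    }
    data.frame(read_start = f$read_start, read_end = f$read_end,
               chrom = windows$chrom[k], ref_start = rs, ref_end = re,
               strand = windows$strand[k], ops = f$ops, score = f$score,
               stringsAsFactors = FALSE)
  }))
  # trim short terminal fragments (spurious slivers at window edges)
  while (nrow(fr) > 1L &&
         frag_len(fr$read_start[1L], fr$read_end[1L]) < params$min_fragment_length) {
    fr <- fr[-1L, , drop = FALSE]
  }
  while (nrow(fr) > 1L && {
    n <- nrow(fr)
    frag_len(fr$read_start[n], fr$read_end[n]) < params$min_fragment_length
  }) {
    fr <- fr[-nrow(fr), , drop = FALSE]
  }
  if (nrow(fr) == 1L &&
      frag_len(fr$read_start[1L], fr$read_end[1L]) < params$min_fragment_length) {
    return(NULL)
  }
  rownames(fr) <- NULL
  structure(list(read_id = read_id, fragments = fr,
                 score = sum(fr$score) - params$transition * (nrow(fr) - 1L),
                 transitions = nrow(fr) - 1L),
            class = "split_alignment")
}

frag_len <- function(rs, re) re - rs + 1L

#' @export
print.split_alignment <- function(x, ...) {
  cat("split_alignment '", x$read_id, "': ", nrow(x$fragments),
      " fragment(s), score ", x$score, ", ", x$transitions,
      " transition(s)\n", sep = "")
  for (i in seq_len(nrow(x$fragments))) {
    f <- x$fragments[i, ]
    cat(sprintf("  read[%d,%d] -> %s:%d-%d (%s)\n", f$read_start, f$read_end,
                f$chrom, f$ref_start, f$ref_end, f$strand))
  }
  invisible(x)
}

# percent identity of the aligned part of the read
alignment_accuracy <- function(aln) {
  ops <- paste(aln$fragments$ops, collapse = "")
  n_m <- nchar(gsub("[^M]", "", ops))
  n_all <- nchar(ops)
  if (n_all == 0L) 0 else 100 * n_m / n_all
}
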