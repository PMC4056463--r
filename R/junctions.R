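#' Junction parameters
#'
#' @param long_range_distance same-strand junctions spanning more than this
#'   many nt (or joining two chromosomes) are classed long-range.
#'   Default 200000.
#' @param min_support junctions supported by fewer split reads are dropped
#'   by [aggregate_support()].  Default 1 (a value of 3 reproduces the
#'   stricter trans-splicing survey filter).
#' @param merge_tolerance breakpoint tolerance (nt) within which junction
#'   observations are merged; the cluster's modal breakpoint is reported.
#'   Sequencing errors at the very junction shift single observations by a
#'   few nt, so calls are consolidated within 5 nt by default; set 0 for
#'   strictly exact merging.
#' @return a list of class `junction_params`.
#' @export
junction_params <- function(long_range_distance = 200000L, min_support = 1L,
                            merge_tolerance = 5L) {
  stopifnot(long_range_distance > 0, min_support >= 1, merge_tolerance >= 0)
  structure(list(long_range_distance = as.integer(long_range_distance),
                 min_support = as.integer(min_support),
                 merge_tolerance = as.integer(merge_tolerance)),
            class = "junction_params")
}

empty_junctions <- function() {
  data.frame(chrom1 = character(), pos1 = integer(), strand1 = character(),
             chrom2 = character(), pos2 = integer(), strand2 = character(),
             class = character(), support = integer(),
             stringsAsFactors = FALSE)
}

#' Extract junctions from a split alignment
#'
#' Each adjacent fragment pair implies one junction: the donor is the last
#' aligned base (in transcription direction) of the earlier-in-read
#' fragment, the acceptor the first aligned base of the later one.
#' Positions are 0-based.  When the genome is supplied, sequence-identical
#' boundary placements are canonicalized by shifting the breakpoint as far
#' towards the read start as the flanking sequence allows, so that
#' equivalent observations from different reads coincide.
#'
#' @param aln a `split_alignment` (single-fragment alignments yield an
#'   empty junction list).
#' @param genome optional [reference_genome()] for breakpoint
#'   canonicalization.
#' @param params a [junction_params()] object.
#' @return data.frame of junctions (donor = `chrom1,pos1,strand1`,
#'   acceptor = `chrom2,pos2,strand2`) with `class` and `support` (= 1 per
#'   observation).
#' @export
extract_junctions <- function(aln, genome = NULL, params = junction_params()) {
  if (is.null(aln) || nrow(aln$fragments) < 2L) return(empty_junctions())
  fr <- aln$fragments
  out <- lapply(seq_len(nrow(fr) - 1L), function(i) {
    a <- fr[i, ]; b <- fr[i + 1L, ]
    donor_pos <- if (a$strand == "+") a$ref_end - 1L else a$ref_start
    accpt_pos <- if (b$strand == "+") b$ref_start else b$ref_end - 1L
    data.frame(chrom1 = a$chrom, pos1 = donor_pos, strand1 = a$strand,
               chrom2 = b$chrom, pos2 = accpt_pos, strand2 = b$strand,
               stringsAsFactors = FALSE)
  })
  out <- finalize_junctions(do.call(rbind, out), genome, params)
  out$support <- 1L
  out
}

# shared by the caller and the simulator truth: bring a raw donor/acceptor
# table into its canonical, orientation-invariant form.  The breakpoints are
# first put into canonical order (so sense and antisense observations of a
# junction coincide), then sequence-identical boundary placements are
# collapsed by the canonical shift, and the class is assigned.
finalize_junctions <- function(j, genome = NULL, params = junction_params()) {
  if (is.null(j) || nrow(j) == 0L) return(empty_junctions())
  j <- normalize_junctions(j)
  if (!is.null(genome)) {
    shifted <- do.call(rbind, lapply(seq_len(nrow(j)), function(r) {
      canonicalize_junction(genome, j[r, , drop = FALSE])
    }))
    shifted <- normalize_junctions(shifted)  # a shift can reorder close ends
    shifted$swapped <- j$swapped
    j <- shifted
  }
  j$class <- classify_junction(j, params)
  rownames(j) <- NULL
  j
}

# shift a junction towards the read start while the donor's last base is
# identical to the base just upstream of the acceptor: such placements are
# sequence-equivalent and must map to one canonical breakpoint
canonicalize_junction <- function(genome, j, max_shift = 100L) {
  dir1 <- if (j$strand1 == "+") 1L else -1L
  dir2 <- if (j$strand2 == "+") 1L else -1L
  len1 <- unname(genome$lengths[j$chrom1])
  len2 <- unname(genome$lengths[j$chrom2])
  for (s in seq_len(max_shift)) {
    p1 <- j$pos1
    p2p <- j$pos2 - dir2
    if (p1 - dir1 < 0L || p1 - dir1 >= len1) break
    if (p2p < 0L || p2p >= len2) break
    if (char_at(genome, j$chrom1, p1, j$strand1) !=
        char_at(genome, j$chrom2, p2p, j$strand2)) break
    j$pos1 <- p1 - dir1
    j$pos2 <- p2p
  }
  j
}

#' Classify junctions by their breakpoint geometry
#'
#' A junction is *strand-reversing* when its two sides lie on opposite
#' strands; otherwise *long-range* when the sides lie on different
#' chromosomes or further apart than `long_range_distance`; otherwise
#' *circular* when the acceptor lies upstream of the donor in transcription
#' direction (the back-splice signature); otherwise *regular*.
#'
#' @param j a junction data.frame (columns `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`), donor first.
#' @param params a [junction_params()] object.
#' @return character vector of classes.
#' @export
classify_junction <- function(j, params = junction_params()) {
  vapply(seq_len(nrow(j)), function(i) {
    if (j$strand1[i] != j$strand2[i]) return("strand-reversing")
    if (j$chrom1[i] != j$chrom2[i] ||
        abs(j$pos2[i] - j$pos1[i]) > params$long_range_distance) {
      return("long-range")
    }
    upstream <- if (j$strand1[i] == "+") j$pos2[i] < j$pos1[i]
                else j$pos2[i] > j$pos1[i]
    if (upstream) "circular" else "regular"
  }, character(1))
}

# canonical breakpoint ordering for non-strand-specific libraries: the
# lexicographically smaller breakpoint first; both strands are flipped on a
# swap so sense and antisense observations of one junction coincide
normalize_junctions <- function(j) {
  if (nrow(j) == 0L) return(j)
  swap <- (j$chrom2 < j$chrom1) | (j$chrom2 == j$chrom1 & j$pos2 < j$pos1)
  if (any(swap)) {
    tmp <- j[swap, c("chrom1", "pos1", "strand1")]
    j[swap, c("chrom1", "pos1")] <- j[swap, c("chrom2", "pos2")]
    j[swap, c("chrom2", "pos2")] <- tmp[, c("chrom1", "pos1")]
    s1 <- chartr("+-", "-+", j$strand2[swap])
    s2 <- chartr("+-", "-+", tmp$strand1)
    j$strand1[swap] <- s1
    j$strand2[swap] <- s2
  }
  j$swapped <- swap
  j
}

junction_key <- function(j) {
  paste(j$chrom1, j$pos1, j$chrom2, j$pos2, j$strand1 != j$strand2,
        j$class, sep = ":")
}

#' Merge junction observations and apply the support filter
#'
#' Observations with identical breakpoints (within `merge_tolerance`) are
#' merged and their split-read support summed; junctions supported by fewer
#' than `min_support` reads are removed.
#'
#' @param junctions data.frame of junction observations (normalized, as
#'   produced by [extract_junctions()]).
#' @param params a [junction_params()] object.
#' @return data.frame of merged junctions with summed `support`.
#' @export
aggregate_support <- function(junctions, params = junction_params()) {
  if (is.null(junctions) || nrow(junctions) == 0L) return(empty_junctions())
  j <- junctions
  if (params$merge_tolerance > 0L) {
    # single-linkage clustering on both breakpoints within tolerance
    o <- order(j$chrom1, j$chrom2, j$class, j$pos1, j$pos2)
    j <- j[o, , drop = FALSE]
    grp <- integer(nrow(j)); grp[1L] <- 1L
    for (i in seq_len(nrow(j))[-1L]) {
      prev <- i - 1L
      same <- j$chrom1[i] == j$chrom1[prev] && j$chrom2[i] == j$chrom2[prev] &&
        j$class[i] == j$class[prev] &&
        abs(j$pos1[i] - j$pos1[prev]) <= params$merge_tolerance &&
        abs(j$pos2[i] - j$pos2[prev]) <= params$merge_tolerance
      grp[i] <- if (same) grp[prev] else grp[prev] + 1L
    }
    key <- grp
  } else {
    key <- junction_key(j)
  }
  idx <- split(seq_len(nrow(j)), key)
  out <- do.call(rbind, lapply(idx, function(ii) {
    # representative: the modal exact breakpoint of the cluster
    ek <- junction_key(j[ii, , drop = FALSE])
    tab <- sort(table(ek), decreasing = TRUE)
    best <- names(tab)[tab == tab[1L]]
    pick <- ii[ek == min(best)][1L]
    r <- j[pick, c("chrom1", "pos1", "strand1", "chrom2", "pos2",
                   "strand2", "class"), drop = FALSE]
    r$support <- sum(j$support[ii])
    r
  }))
  out <- out[out$support >= params$min_support, , drop = FALSE]
  out <- out[order(out$chrom1, out$pos1, out$chrom2, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
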