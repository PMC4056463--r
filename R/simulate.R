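#' Simulation configuration
#'
#' Bundles every knob of the spliced-read simulator.  The defaults emulate
#' the benchmark protocol at desk scale: multi-exon isoforms drawn from a
#' synthetic genome, 20 percent irregular exons (strand-flipped or
#' substituted by a distant exon) in the mixed datasets, 100 nt
#' substitution-dominated (Illumina-style) or 400 nt indel-dominated
#' (454-style) single-end reads at 10-20x coverage.
#'
#' Error-model defaults (chosen per model when the rate arguments are left
#' `NULL`): `illumina` uses substitutions 0.004, insertions/deletions 5e-4
#' each, no homopolymer scaling; `r454` uses substitutions 0.002,
#' insertions/deletions 0.005 each, with the per-base indel probability
#' scaled by `1 + 0.3 * (homopolymer_length - 1)` to emulate the
#' pyrosequencing regime.
#'
#' @param genome_size total genome size in nt (split over `n_chrom`).
#' @param n_chrom number of chromosomes.
#' @param n_isoforms number of simulated isoforms.
#' @param exons_per_isoform integer range `c(min, max)`.
#' @param exon_length integer range in nt.
#' @param intron_length integer range in nt.
#' @param irregular_fraction probability that an exon is irregular
#'   (flipped or distant).  Default 0.2.
#' @param irregular_type `"both"` (flip or substitute, 50/50),
#'   `"flip"` (strand flips only) or `"distant"` (distant substitutions
#'   only).
#' @param read_length read length in nt, or `"full"` for full-length
#'   transcript reads.
#' @param coverage fold coverage of each isoform.
#' @param error_model `"illumina"`, `"r454"`, or `"none"`.
#' @param sub_rate,ins_rate,del_rate per-base error rates in \[0, 0.1\];
#'   `NULL` picks the model default.
#' @param hp_scale homopolymer scaling of the indel probability;
#'   `NULL` picks the model default.
#' @param circular simulate circularized transcripts (reads may span the
#'   end-to-start junction).
#' @param decoy_fraction fraction of genome bases overwritten with
#'   low-complexity (poly-A) decoy tracts.
#' @param anchor minimum nt a read must overlap on both sides of a junction
#'   to count as a witness of it in the truth table.  Default 10.
#' @param seed RNG seed (same config implies identical output).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genome_size = 2e6, n_chrom = 2L, n_isoforms = 100L,
                       exons_per_isoform = c(3L, 6L),
                       exon_length = c(80L, 300L),
                       intron_length = c(100L, 5000L),
                       irregular_fraction = 0.2,
                       irregular_type = c("both", "flip", "distant"),
                       read_length = 100L, coverage = 10,
                       error_model = c("illumina", "r454", "none"),
                       sub_rate = NULL, ins_rate = NULL, del_rate = NULL,
                       hp_scale = NULL,
                       circular = FALSE, decoy_fraction = 0,
                       anchor = 10L, seed = 1L) {
  error_model <- match.arg(error_model)
  irregular_type <- match.arg(irregular_type)
  defaults <- switch(error_model,
    illumina = list(sub = 0.004, ins = 5e-4, del = 5e-4, hp = 0),
    r454     = list(sub = 0.002, ins = 0.005, del = 0.005, hp = 0.3),
    none     = list(sub = 0, ins = 0, del = 0, hp = 0))
  sub_rate <- if (is.null(sub_rate)) defaults$sub else sub_rate
  ins_rate <- if (is.null(ins_rate)) defaults$ins else ins_rate
  del_rate <- if (is.null(del_rate)) defaults$del else del_rate
  hp_scale <- if (is.null(hp_scale)) defaults$hp else hp_scale
  stopifnot(irregular_fraction >= 0, irregular_fraction <= 1,
            sub_rate >= 0, sub_rate <= 0.1, ins_rate >= 0, ins_rate <= 0.1,
            del_rate >= 0, del_rate <= 0.1,
            identical(read_length, "full") || read_length >= 30)
  structure(list(genome_size = genome_size, n_chrom = as.integer(n_chrom),
                 n_isoforms = as.integer(n_isoforms),
                 exons_per_isoform = as.integer(exons_per_isoform),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 irregular_fraction = irregular_fraction,
                 irregular_type = irregular_type,
                 read_length = read_length, coverage = coverage,
                 error_model = error_model, sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 hp_scale = hp_scale, circular = circular,
                 decoy_fraction = decoy_fraction,
                 anchor = as.integer(anchor), seed = as.integer(seed)),
            class = "sim_config")
}

# draw uniformly from an inclusive integer range (safe for lo == hi,
# unlike sample(lo:hi, ...))
sample_range <- function(lo, hi, n = 1L) {
  if (lo >= hi) rep(as.integer(lo), n)
  else as.integer(sample(lo:hi, n, replace = TRUE))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulate a random reference genome
#'
#' Sequences are i.i.d. uniform over A/C/G/T; when `decoy_fraction > 0`,
#' poly-A tracts of 50-200 nt are overwritten into the sequence so the
#' entropy filter can be exercised.
#'
#' @param config a [sim_config()] object.
#' @return a [reference_genome()] object (deterministic per seed).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$genome_size >= 1e4)
  with_seed(config$seed, {
    per <- ceiling(config$genome_size / config$n_chrom)
    seqs <- vapply(seq_len(config$n_chrom), function(i) {
      s <- sample(c("A", "C", "G", "T"), per, replace = TRUE)
      if (config$decoy_fraction > 0) {
        budget <- config$decoy_fraction * per
        used <- 0
        while (used < budget) {
          len <- sample(50:200, 1L)
          at <- sample(per - len, 1L)
          s[at:(at + len - 1L)] <- "A"
          used <- used + len
        }
      }
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(config$n_chrom))
    reference_genome(seqs)
  })
}

# transcription-direction breakpoint helpers for an exon (0-based, half-open)
exon_donor <- function(exon) {
  list(chrom = exon$chrom, strand = exon$strand,
       pos = if (exon$strand == "+") exon$end - 1L else exon$start)
}
exon_acceptor <- function(exon) {
  list(chrom = exon$chrom, strand = exon$strand,
       pos = if (exon$strand == "+") exon$start else exon$end - 1L)
}
exon_seq <- function(genome, exon) {
  s <- substr(genome$sequences[[exon$chrom]], exon$start + 1L, exon$end)
  if (exon$strand == "-") revcomp(s) else s
}

#' Simulate isoforms with regular and irregular junctions
#'
#' Isoforms are laid out as non-overlapping exon chains along the genome
#' and their sequences obtained by concatenating the exon sequences.  With
#' probability `irregular_fraction` an exon is flipped to the opposite
#' strand or substituted by a distant exon (more than 200 kb away or on
#' another chromosome), producing strand-reversing and long-range truth
#' junctions.  With `circular = TRUE` the transcript is circularized: reads
#' may span the end-to-start junction, which is recorded as a circular
#' truth junction.
#'
#' @param genome a [reference_genome()].
#' @param config a [sim_config()].
#' @param jparams a [junction_params()] used to class the truth junctions.
#' @return list with `isoforms` (list of per-isoform records: `id`,
#'   `exons` data.frame, `sequence`, `circular`, `junction_pos` 0-based
#'   positions in the transcript of each junction's last donor base) and
#'   `truth` (data.frame of truth junctions with `isoform`, breakpoints,
#'   `class`, and transcript position `tpos`).
#' @export
simulate_isoforms <- function(genome, config, jparams = junction_params()) {
  stopifnot(inherits(genome, "reference_genome"), inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    n_chrom <- length(genome$sequences)
    cursors <- setNames(rep(1000L, n_chrom), names(genome$sequences))
    isoforms <- vector("list", config$n_isoforms)
    truth <- vector("list", config$n_isoforms)
    for (iso in seq_len(config$n_isoforms)) {
      chrom <- names(genome$sequences)[1L + (iso - 1L) %% n_chrom]
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample_range(config$exons_per_isoform[1L],
                           config$exons_per_isoform[2L])
      lens <- sample_range(config$exon_length[1L], config$exon_length[2L], n_ex)
      gaps <- sample_range(config$intron_length[1L], config$intron_length[2L],
                           n_ex)
      start <- cursors[[chrom]]
      pos <- start
      exons <- vector("list", n_ex)
      for (e in seq_len(n_ex)) {
        exons[[e]] <- list(chrom = chrom, start = pos, end = pos + lens[e],
                           strand = strand, irregular = FALSE)
        pos <- pos + lens[e] + gaps[e]
      }
      if (pos + 1000L > genome$lengths[[chrom]]) {
        stop("genome too small for the requested isoform budget")
      }
      cursors[[chrom]] <- pos + sample(500:2000, 1L)
      if (strand == "-") exons <- rev(exons)  # transcription order
      # irregular exons: flip in place or substitute a distant exon
      for (e in seq_len(n_ex)) {
        if (runif(1) < config$irregular_fraction) {
          flip <- switch(config$irregular_type,
                         both = runif(1) < 0.5, flip = TRUE, distant = FALSE)
          if (flip) {
            exons[[e]]$strand <- if (exons[[e]]$strand == "+") "-" else "+"
          } else {
            exons[[e]] <- distant_exon(genome, exons[[e]], start,
                                       config, jparams)
          }
          exons[[e]]$irregular <- TRUE
        }
      }
      seqs <- vapply(exons, function(ex) exon_seq(genome, ex), character(1))
      sequence <- paste(seqs, collapse = "")
      cum <- cumsum(nchar(seqs))
      jpos <- if (n_ex > 1L) cum[-n_ex] - 1L else integer()
      pairs <- if (n_ex > 1L) {
        lapply(seq_len(n_ex - 1L), function(e) {
          c(exon_donor(exons[[e]]), exon_acceptor(exons[[e + 1L]]))
        })
      } else list()
      if (config$circular) {
        pairs <- c(pairs, list(c(exon_donor(exons[[n_ex]]),
                                 exon_acceptor(exons[[1L]]))))
        jpos <- c(jpos, nchar(sequence) - 1L)
      }
      jl <- if (length(pairs)) {
        jj <- do.call(rbind, lapply(pairs, function(p) {
          data.frame(chrom1 = p$chrom, pos1 = p$pos, strand1 = p$strand,
                     chrom2 = p[[4L]], pos2 = p[[6L]], strand2 = p[[5L]],
                     stringsAsFactors = FALSE)
        }))
        names(jj) <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
        jj <- finalize_junctions(jj, genome, jparams)
        jj$isoform <- sprintf("iso%04d", iso)
        jj$tpos <- jpos
        jj
      } else NULL
      isoforms[[iso]] <- list(id = sprintf("iso%04d", iso), exons = exons,
                              sequence = sequence, circular = config$circular,
                              junction_pos = jpos)
      truth[[iso]] <- jl
    }
    truth <- do.call(rbind, truth)
    if (is.null(truth)) truth <- cbind(empty_junctions(),
                                       data.frame(isoform = character(),
                                                  tpos = integer()))
    rownames(truth) <- NULL
    list(isoforms = isoforms, truth = truth)
  })
}

# exon of the same length, placed > long_range_distance away (relative to
# the isoform locus) or on another chromosome; strand kept
distant_exon <- function(genome, exon, anchor_pos, config, jparams) {
  len <- exon$end - exon$start
  for (i in 1:200) {
    chrom <- sample(names(genome$sequences), 1L)
    max_start <- genome$lengths[[chrom]] - len - 1L
    pos <- sample(max_start, 1L)
    ok <- chrom != exon$chrom ||
      abs(pos - anchor_pos) > jparams$long_range_distance + 10000L
    if (ok) {
      return(list(chrom = chrom, start = pos, end = pos + len,
                  strand = exon$strand, irregular = TRUE))
    }
  }
  stop("could not place a distant exon; genome too small?")
}

#' Apply a sequencing error model to a template sequence
#'
#' Substitutions are drawn per base at `sub_rate`; insertions and
#' deletions at `ins_rate`/`del_rate`, each scaled by
#' `1 + hp_scale * (homopolymer_length - 1)` (capped at 0.25) to emulate
#' indel-dominated pyrosequencing errors inside homopolymers.
#'
#' @param seq template sequence.
#' @param sub_rate,ins_rate,del_rate per-base rates.
#' @param hp_scale homopolymer scaling factor.
#' @return list with `seq` (the mutated sequence) and counts `n_sub`,
#'   `n_ins`, `n_del`, `n_bases`.
#' @export
mutate_sequence <- function(seq, sub_rate = 0, ins_rate = 0, del_rate = 0,
                            hp_scale = 0) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n == 0L) return(list(seq = "", n_sub = 0L, n_ins = 0L, n_del = 0L,
                           n_bases = 0L))
  f <- 1
  if (hp_scale > 0) {
    r <- rle(chars)
    f <- rep(1 + hp_scale * (r$lengths - 1), r$lengths)
  }
  sub <- runif(n) < sub_rate
  ins <- runif(n) < pmin(ins_rate * f, 0.25)
  del <- runif(n) < pmin(del_rate * f, 0.25)
  bases <- c("A", "C", "G", "T")
  if (any(sub)) {
    chars[sub] <- vapply(chars[sub], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  out <- chars
  out[del] <- ""
  if (any(ins)) {
    out[ins] <- paste0(out[ins], sample(bases, sum(ins), replace = TRUE))
  }
  list(seq = paste(out, collapse = ""), n_sub = sum(sub), n_ins = sum(ins),
       n_del = sum(del), n_bases = n)
}

#' Simulate single-end reads from isoforms with a ground-truth table
#'
#' Reads are drawn uniformly along each isoform to the target coverage
#' (for circular isoforms, uniformly around the circle so reads span the
#' back-splice point), reverse complemented with probability 0.5
#' (non-strand-specific library), and passed through the configured error
#' model.  The per-read truth lists the junctions the template overlaps
#' with at least `anchor` nt on both sides.
#'
#' @param iso result of [simulate_isoforms()].
#' @param config a [sim_config()].
#' @return list with `reads` (data.frame: `id`, `sequence`, `quality`,
#'   `isoform`, `start`, `flipped`), `read_truth` (long data.frame:
#'   `read_id` x truth-junction row index `truth_row`), and `truth`
#'   (the isoform truth table passed through).
#' @export
simulate_reads <- function(iso, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    full_len <- identical(config$read_length, "full")
    qchar <- switch(config$error_model, illumina = "I", r454 = "F", none = "I")
    reads <- list(); rt <- list(); ridx <- 0L
    for (it in iso$isoforms) {
      L <- nchar(it$sequence)
      rl <- if (full_len) L else config$read_length
      if (rl > L) {
        stop("read_length exceeds isoform length for ", it$id)
      }
      n_reads <- max(1L, round(config$coverage * L / rl))
      if (config$coverage == 0) n_reads <- 0L
      tmpl <- if (it$circular) paste0(it$sequence, it$sequence) else it$sequence
      max_start <- if (it$circular) L - 1L else L - rl
      jp <- it$junction_pos
      trows <- which(iso$truth$isoform == it$id)
      for (r in seq_len(n_reads)) {
        ridx <- ridx + 1L
        u <- if (max_start > 0L) sample(0:max_start, 1L) else 0L
        template <- substr(tmpl, u + 1L, u + rl)
        witnessed <- integer()
        if (length(jp)) {
          jcopies <- if (it$circular) c(jp, jp + L) else jp
          for (q in seq_along(jp)) {
            pos <- if (it$circular) c(jp[q], jp[q] + L) else jp[q]
            hit <- any(pos - u + 1L >= config$anchor &
                       (u + rl - 1L) - pos >= config$anchor)
            if (hit) witnessed <- c(witnessed, trows[q])
          }
        }
        flipped <- runif(1) < 0.5
        if (flipped) template <- revcomp1(template)
        mut <- mutate_sequence(template, config$sub_rate, config$ins_rate,
                               config$del_rate, config$hp_scale)
        sq <- mut$seq
        if (!full_len && nchar(sq) > rl) sq <- substr(sq, 1L, rl)
        id <- sprintf("%s_r%05d", it$id, r)
        reads[[ridx]] <- list(id = id, sequence = sq,
                              quality = strrep(qchar, nchar(sq)),
                              isoform = it$id, start = u, flipped = flipped)
        if (length(witnessed)) {
          rt[[length(rt) + 1L]] <- data.frame(read_id = id,
                                              truth_row = witnessed,
                                              stringsAsFactors = FALSE)
        }
      }
    }
    reads <- do.call(rbind, lapply(reads, function(x) {
      data.frame(x, stringsAsFactors = FALSE)
    }))
    if (is.null(reads)) {
      reads <- data.frame(id = character(), sequence = character(),
                          quality = character(), isoform = character(),
                          start = integer(), flipped = logical(),
                          stringsAsFactors = FALSE)
    }
    read_truth <- if (length(rt)) do.call(rbind, rt) else
      data.frame(read_id = character(), truth_row = integer(),
                 stringsAsFactors = FALSE)
    list(reads = reads, read_truth = read_truth, truth = iso$truth)
  })
}
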