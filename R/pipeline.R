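#' Full run configuration
#'
#' Bundles the parameter sets of all pipeline stages.  The defaults
#' reproduce the method's standard behavior: seed entropy threshold 1.5
#' bits, chain coverage 0.80, long-range distance 200 kb.
#'
#' @param seed a [seed_params()] object.
#' @param chain a [chain_params()] object.
#' @param align an [align_params()] object.
#' @param junction a [junction_params()] object.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = seed_params(), chain = chain_params(),
                       align = align_params(), junction = junction_params()) {
  structure(list(seed = seed, chain = chain, align = align,
                 junction = junction), class = "run_config")
}

#' Map a single read
#'
#' Runs seeding, chaining, occurrence resolution, window extraction and the
#' transition alignment for one read.  Exposed mainly for inspection; use
#' [map_reads()] for batches.
#'
#' @param read read sequence.
#' @param index a [build_index()] result.
#' @param config a [run_config()].
#' @param read_id identifier for the read.
#' @return list with `status` (`"unmapped"`, `"unsplit"` or `"split"`),
#'   `alignment` (a `split_alignment` or `NULL`), `junctions` (data.frame
#'   of junction observations) and `unique` (logical: best chain
#'   unambiguous).
#' @export
map_read <- function(read, index, config = run_config(), read_id = "read") {
  read <- toupper(as.character(read))
  m <- nchar(read)
  unmapped <- list(status = "unmapped", alignment = NULL,
                   junctions = empty_junctions(), unique = FALSE)
  if (m <= config$seed$min_suffix_length) return(unmapped)
  raw <- collect_seeds_raw(read, index, config$seed)
  k <- length(raw$read_start)
  if (k == 0L) return(unmapped)

  dp <- greedy_chain_cpp(raw$read_start, raw$read_end, raw$score)
  top_score <- max(dp$sigma)
  tied <- which(dp$sigma == top_score)
  best <- tied[order(dp$nfrag[tied])][1L]
  members <- chain_members(dp$back, best)
  cov <- coverage_fraction(raw$read_start[members], raw$read_end[members], m)
  if (cov <= config$chain$min_coverage) return(unmapped)

  occs <- lapply(members, function(i) {
    loc <- text_to_genomic(index, raw$occ[[i]])
    data.frame(chrom = loc$chrom, ref_start = loc$pos,
               ref_end = loc$pos + raw$ref_len[i],
               strand = c("+", "-")[raw$strand[i] + 1L],
               stringsAsFactors = FALSE)
  })
  pick <- resolve_core(occs)
  one <- do.call(rbind, lapply(seq_along(occs), function(i) {
    occs[[i]][pick[i], , drop = FALSE]
  }))
  seeds <- data.frame(read_start = raw$read_start[members],
                      read_end = raw$read_end[members],
                      score = raw$score[members],
                      chrom = one$chrom, ref_start = one$ref_start,
                      ref_end = one$ref_end, strand = one$strand,
                      stringsAsFactors = FALSE)
  chain <- structure(list(seeds = seeds, score = top_score,
                          read_coverage = cov, n = nrow(seeds)),
                     class = "seed_chain")
  windows <- extract_windows(chain, index$genome, config$align)
  res <- transition_align_cpp(read, windows$seq, config$align$match,
                              config$align$mismatch, config$align$indel,
                              config$align$transition)
  aln <- build_split_alignment(res, windows, config$align, read_id)
  if (is.null(aln)) return(unmapped)
  if (alignment_accuracy(aln) < config$seed$min_accuracy) return(unmapped)

  is_unique <- length(tied) == 1L && min(raw$n_occ[members]) == 1L
  jn <- extract_junctions(aln, index$genome, config$junction)
  list(status = if (nrow(aln$fragments) > 1L) "split" else "unsplit",
       alignment = aln, junctions = jn, unique = is_unique)
}

#' Map a batch of reads and call junctions
#'
#' Runs [map_read()] over all reads, aggregates the junction observations
#' with [aggregate_support()], and returns the alignments together with the
#' junction calls.  Output order is deterministic for fixed inputs.
#'
#' @param index a [build_index()] result.
#' @param reads a data.frame with columns `id` and `sequence` (e.g.
#'   `$reads` from [simulate_reads()]), or a named character vector.
#' @param config a [run_config()].
#' @param unique_only use only uniquely mapping split reads for the
#'   junction calls.  Default `FALSE`.
#' @return list with `alignments` (list of `split_alignment`),
#'   `junction_obs` (per-read junction observations with `read_id` and
#'   `unique`), `junctions` (aggregated calls), and `summary` (per-status
#'   read counts).
#' @export
map_reads <- function(index, reads, config = run_config(),
                      unique_only = FALSE) {
  if (is.character(reads)) {
    reads <- data.frame(id = if (is.null(names(reads)))
      sprintf("read%05d", seq_along(reads)) else names(reads),
      sequence = unname(reads), stringsAsFactors = FALSE)
  }
  n <- nrow(reads)
  alignments <- vector("list", n)
  obs <- vector("list", n)
  status <- character(n)
  for (i in seq_len(n)) {
    r <- map_read(reads$sequence[i], index, config, reads$id[i])
    status[i] <- r$status
    alignments[[i]] <- r$alignment
    if (nrow(r$junctions) > 0L) {
      jn <- r$junctions
      jn$read_id <- reads$id[i]
      jn$unique <- r$unique
      obs[[i]] <- jn
    }
  }
  junction_obs <- do.call(rbind, obs)
  if (is.null(junction_obs)) {
    junction_obs <- cbind(empty_junctions(),
                          data.frame(read_id = character(),
                                     unique = logical()))
  }
  keep <- if (unique_only) junction_obs[junction_obs$unique, , drop = FALSE]
          else junction_obs
  junctions <- aggregate_support(keep, config$junction)
  summary <- as.data.frame(table(factor(status,
                                        levels = c("split", "unsplit",
                                                   "unmapped"))),
                           stringsAsFactors = FALSE)
  names(summary) <- c("status", "reads")
  list(alignments = Filter(Negate(is.null), alignments),
       junction_obs = junction_obs, junctions = junctions,
       summary = summary)
}
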