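#' Chain-selection parameters
#'
#' @param min_coverage minimum fraction of read positions the top chain must
#'   cover for the read to proceed to the transition alignment.  Default 0.8
#'   (the chain must cover more than 80 percent of the read).
#' @return a list of class `chain_params`.
#' @export
chain_params <- function(min_coverage = 0.80) {
  stopifnot(min_coverage > 0, min_coverage <= 1)
  structure(list(min_coverage = min_coverage), class = "chain_params")
}

#' Score of an ordered seed chain
#'
#' The chain score is the sum of the seed scores minus, for every adjacent
#' pair, the absolute difference between the previous seed's read end and
#' the next seed's read start: gaps and overlaps in read coordinates are
#' penalized alike.
#'
#' @param chain a chain object from [greedy_chain()], or a data.frame of
#'   seeds (columns `read_start`, `read_end`, `score`) ordered by
#'   `read_start`.
#' @return integer chain score.
#' @export
chain_score <- function(chain) {
  seeds <- if (inherits(chain, "seed_chain")) chain$seeds else chain
  n <- nrow(seeds)
  if (is.null(n) || n == 0L) stop("chain_score: empty chain")
  if (is.unsorted(seeds$read_start)) stop("seeds must be ordered by read_start")
  s <- sum(seeds$score)
  if (n > 1L) {
    s <- s - sum(abs(seeds$read_end[-n] - seeds$read_start[-1L]))
  }
  as.integer(s)
}

# fraction of [0, m) covered by the union of seed intervals
coverage_fraction <- function(read_start, read_end, m) {
  o <- order(read_start, read_end)
  rs <- read_start[o]; re <- read_end[o]
  tot <- 0L; cur_s <- rs[1L]; cur_e <- re[1L]
  if (length(rs) > 1L) for (i in 2L:length(rs)) {
    if (rs[i] <= cur_e + 1L) cur_e <- max(cur_e, re[i])
    else { tot <- tot + (cur_e - cur_s + 1L); cur_s <- rs[i]; cur_e <- re[i] }
  }
  tot <- tot + (cur_e - cur_s + 1L)
  tot / m
}

new_chain <- function(seeds, m) {
  structure(list(seeds = seeds,
                 score = chain_score(seeds),
                 read_coverage = coverage_fraction(seeds$read_start,
                                                   seeds$read_end, m),
                 n = nrow(seeds)),
            class = "seed_chain")
}

#' @export
print.seed_chain <- function(x, ...) {
  cat("seed_chain: ", x$n, " seed(s), score ", x$score,
      ", read coverage ", sprintf("%.1f%%", 100 * x$read_coverage), "\n", sep = "")
  invisible(x)
}

#' Greedy seed chaining
#'
#' Seeds are sorted by read start; each seed starts as a chain of its own,
#' and for each seed the best preceding chain (one whose last seed ends
#' strictly before this seed ends) is concatenated when doing so improves
#' the chain score.  The dynamic program performs at most
#' `|C|(|C|-1)/2` pairwise comparisons.
#'
#' @param seeds a data.frame of seeds as returned by [collect_seeds()]
#'   (columns `read_start`, `read_end`, `score`; other columns carried
#'   through).
#' @param m read length in nt (used for the coverage of each chain); when
#'   missing, `max(read_end) + 1` is used.
#' @return list of `seed_chain` objects sorted by score (descending; ties:
#'   fewer fragments first, then leftmost genomic occurrence).  An empty
#'   seed set yields an empty list.
#' @export
greedy_chain <- function(seeds, m = NULL) {
  if (is.null(seeds) || nrow(seeds) == 0L) return(list())
  if (is.null(m)) m <- max(seeds$read_end) + 1L
  dp <- greedy_chain_cpp(seeds$read_start, seeds$read_end, seeds$score)
  chains <- lapply(seq_len(nrow(seeds)), function(i) {
    idx <- chain_members(dp$back, i)
    new_chain(seeds[idx, , drop = FALSE], m)
  })
  leftmost <- if ("occurrences" %in% names(seeds)) {
    vapply(chains, function(ch) {
      min(vapply(ch$seeds$occurrences, function(o) {
        if (is.null(o) || nrow(o) == 0L) Inf else min(o$ref_start)
      }, numeric(1)))
    }, numeric(1))
  } else {
    vapply(chains, function(ch) min(ch$seeds$read_start), numeric(1))
  }
  scores <- vapply(chains, `[[`, numeric(1), "score")
  nfrag <- vapply(chains, `[[`, numeric(1), "n")
  chains[order(-scores, nfrag, leftmost)]
}

# trace back the chain ending at (0-based C++) seed index i-1
chain_members <- function(back, i) {
  idx <- integer()
  j <- i - 1L  # 0-based
  while (j >= 0L) { idx <- c(j + 1L, idx); j <- back[j + 1L] }
  idx
}

#' Select the chain used for the transition alignment
#'
#' Only the highest-ranking chain is used, and only when it covers more
#' than `min_coverage` of the read; otherwise the read is reported
#' unmapped/unsplit.
#'
#' @param chains list of chains sorted by score (from [greedy_chain()]).
#' @param m read length in nt.
#' @param params a [chain_params()] object.
#' @return the top `seed_chain`, or `NULL`.
#' @export
select_chain <- function(chains, m, params = chain_params()) {
  if (length(chains) == 0L) return(NULL)
  top <- chains[[1L]]
  cov <- coverage_fraction(top$seeds$read_start, top$seeds$read_end, m)
  if (cov > params$min_coverage) top else NULL
}

#' Resolve each chained seed to a single genomic occurrence
#'
#' Multi-locus seeds are fixed to exactly one occurrence so that adjacent
#' seeds minimize their genomic distance and, where possible, lie on the
#' same chromosome and strand.  When the number of occurrence combinations
#' is small (<= 256) the minimization is exhaustive; otherwise seeds are
#' fixed greedily outward from the least-ambiguous seed.
#'
#' @param chain a `seed_chain` whose seeds carry an `occurrences`
#'   list-column.
#' @return the chain with each seed's `occurrences` reduced to one row (and
#'   convenience columns `chrom`, `ref_start`, `ref_end` filled in).
#' @export
resolve_occurrences <- function(chain) {
  stopifnot(inherits(chain, "seed_chain"))
  occs <- chain$seeds$occurrences
  pick <- resolve_core(occs)
  chain$seeds$occurrences <- lapply(seq_along(occs), function(i) {
    occs[[i]][pick[i], , drop = FALSE]
  })
  one <- do.call(rbind, chain$seeds$occurrences)
  chain$seeds$chrom <- one$chrom
  chain$seeds$ref_start <- one$ref_start
  chain$seeds$ref_end <- one$ref_end
  chain$seeds$strand <- one$strand
  chain
}

# occurrence-resolution core shared by the exposed op and the fast pipeline.
# occs: list (chain order) of data.frames with chrom, ref_start, strand.
# Returns an index into each data.frame.
resolve_core <- function(occs) {
  k <- length(occs)
  sizes <- vapply(occs, nrow, integer(1))
  if (k == 1L) return(resolve_single(occs[[1L]]))
  BIG <- 1e9
  pair_cost <- function(a, ai, b, bi) {
    if (a$chrom[ai] != b$chrom[bi]) BIG
    else abs(a$ref_start[ai] - b$ref_start[bi])
  }
  strand_changes <- function(idx) {
    st <- vapply(seq_len(k), function(i) occs[[i]]$strand[idx[i]], character(1))
    sum(st[-1L] != st[-k])
  }
  if (prod(sizes) <= 256) {
    grid <- as.matrix(expand.grid(lapply(sizes, seq_len)))
    best <- NULL; best_key <- NULL
    for (r in seq_len(nrow(grid))) {
      idx <- grid[r, ]
      d <- sum(vapply(2:k, function(i) {
        pair_cost(occs[[i - 1L]], idx[i - 1L], occs[[i]], idx[i])
      }, numeric(1)))
      key <- c(d, strand_changes(idx),
               vapply(seq_len(k), function(i) occs[[i]]$ref_start[idx[i]], numeric(1)))
      if (is.null(best_key) || key_less(key, best_key)) {
        best <- idx; best_key <- key
      }
    }
    return(as.integer(best))
  }
  # greedy: anchor the seed with fewest occurrences, fix outward
  anchor <- which.min(sizes)
  pick <- integer(k)
  try_anchor <- function(ai) {
    p <- integer(k); p[anchor] <- ai
    total <- 0
    fix_dir <- function(rng, p) {
      for (i in rng) {
        ref <- if (i > anchor) i - 1L else i + 1L
        cand_cost <- vapply(seq_len(sizes[i]), function(ci) {
          pair_cost(occs[[ref]], p[ref], occs[[i]], ci)
        }, numeric(1))
        same_strand <- occs[[i]]$strand == occs[[ref]]$strand[p[ref]]
        o <- order(cand_cost, !same_strand, occs[[i]]$ref_start)
        p[i] <- o[1L]
        total <<- total + cand_cost[o[1L]]
      }
      p
    }
    if (anchor < k) p <- fix_dir((anchor + 1L):k, p)
    if (anchor > 1L) p <- fix_dir((anchor - 1L):1L, p)
    list(pick = p, cost = total)
  }
  sols <- lapply(seq_len(sizes[anchor]), try_anchor)
  costs <- vapply(sols, `[[`, numeric(1), "cost")
  sols[[which.min(costs)]]$pick
}

resolve_single <- function(occ) {
  # lone seed: keep the leftmost occurrence for determinism
  which.min(occ$ref_start + ifelse(occ$strand == "+", 0, 0.5))
}

key_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}
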