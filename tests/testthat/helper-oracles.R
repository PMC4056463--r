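# Fixtures and independent oracles used across the test files.
# Oracles are deliberately naive (enumeration / quadratic DP in plain R)
# and never call the implementation paths they check.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# quadratic edit-distance DP: min distance of read vs any window substring
edit_oracle <- function(read, window) {
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  m <- length(r); n <- length(w)
  D <- matrix(0L, m + 1, n + 1)
  D[, 1] <- 0:m
  for (i in 1:m) for (j in 1:n) {
    D[i + 1, j + 1] <- min(D[i, j] + (r[i] != w[j]),
                           D[i, j + 1] + 1L, D[i + 1, j] + 1L)
  }
  min(D[m + 1, ])
}

# plain Smith-Waterman score of read vs window (no transitions)
sw_oracle <- function(read, window, match = 1, mismatch = -1, indel = 1) {
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  m <- length(r); n <- length(w)
  if (m == 0 || n == 0) return(0)
  H <- matrix(0, m + 1, n + 1)
  best <- 0
  for (i in 1:m) for (j in 1:n) {
    s <- if (r[i] == w[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] - indel,
                           H[i + 1, j] - indel)
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# brute-force transition-alignment oracle: best total over every ordered
# window subsequence and every placement of the read split points, scoring
# each part by plain Smith-Waterman minus tau per transition
split_oracle <- function(read, windows, match = 1, mismatch = -1, indel = 1,
                         tau = 3) {
  m <- nchar(read)
  K <- length(windows)
  best <- 0
  subsets <- function(v) {
    if (length(v) == 0) return(list(integer(0)))
    rest <- subsets(v[-1])
    c(rest, lapply(rest, function(s) c(v[1], s)))
  }
  for (ws in subsets(seq_len(K))) {
    p <- length(ws)
    if (p == 0 || p > 3) next
    cuts <- if (p == 1) matrix(integer(0), 1, 0)
            else if (p == 2) matrix(1:(m - 1), ncol = 1)
            else {
              cmb <- expand.grid(b1 = 1:(m - 1), b2 = 1:(m - 1))
              as.matrix(cmb[cmb$b1 < cmb$b2, , drop = FALSE])
            }
    for (ci in seq_len(nrow(cuts))) {
      b <- c(0, cuts[ci, ], m)
      tot <- -tau * (p - 1)
      for (q in seq_len(p)) {
        part <- substr(read, b[q] + 1, b[q + 1])
        tot <- tot + sw_oracle(part, windows[ws[q]], match, mismatch, indel)
      }
      best <- max(best, tot)
    }
  }
  best
}

# exhaustive chain oracle: max chain score over every seed subset that is
# admissible under the chaining design (read start and read end strictly
# increasing along the chain)
chain_oracle <- function(seeds) {
  k <- nrow(seeds)
  best <- -Inf
  for (mask in 1:(2^k - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    idx <- idx[order(seeds$read_start[idx], seeds$read_end[idx])]
    if (length(idx) > 1) {
      re <- seeds$read_end[idx]
      rs <- seeds$read_start[idx]
      if (any(diff(re) <= 0)) next
      sc <- sum(seeds$score[idx]) -
        sum(abs(re[-length(idx)] - rs[-1]))
    } else {
      sc <- seeds$score[idx]
    }
    best <- max(best, sc)
  }
  best
}

# genome with known exon layout for constructed split reads
make_toy_genome <- function(n = 6000, seed = 99) {
  set.seed(seed)
  reference_genome(c(chrA = random_seq(n), chrB = random_seq(n)))
}
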