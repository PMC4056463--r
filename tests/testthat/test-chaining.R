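seed_df <- function(rs, re, score) {
  data.frame(read_start = rs, read_end = re, score = score)
}

test_that("chain_score follows the gap/overlap-penalized sum", {
  expect_equal(chain_score(seed_df(0, 39, 40)), 40L)
  expect_equal(chain_score(seed_df(c(0, 30), c(29, 59), c(30, 30))), 59L)
  expect_equal(chain_score(seed_df(c(0, 41), c(50, 95), c(45, 45))), 81L)
  expect_error(chain_score(seed_df(integer(), integer(), integer())), "empty")
})

test_that("greedy chaining links tiling seeds and ranks chains by score", {
  one <- greedy_chain(seed_df(0, 39, 40))
  expect_length(one, 1L)
  expect_equal(one[[1]]$score, 40L)

  tiling <- seed_df(c(0, 33, 66), c(32, 65, 99), c(33, 33, 34))
  chains <- greedy_chain(tiling, m = 100)
  expect_equal(chains[[1]]$score, 98L)  # 100 - two adjacency penalties
  expect_equal(chains[[1]]$n, 3L)
  # every seed appears in at least one chain
  starts <- unique(unlist(lapply(chains, function(c) c$seeds$read_start)))
  expect_setequal(starts, tiling$read_start)
})

test_that("greedy top chain matches exhaustive enumeration on random seeds", {
  set.seed(77)
  for (trial in 1:120) {
    k <- sample(2:8, 1)
    rs <- sort(sample(0:80, k))
    re <- rs + sample(5:40, k, replace = TRUE)
    # distinct read ends keep the admissibility predicate unambiguous
    while (anyDuplicated(re)) re <- rs + sample(5:40, k, replace = TRUE)
    seeds <- seed_df(rs, re, pmax(1L, (re - rs + 1L) - sample(0:3, k, replace = TRUE)))
    chains <- greedy_chain(seeds, m = max(re) + 1)
    expect_equal(chains[[1]]$score, chain_oracle(seeds),
                 info = sprintf("trial %d", trial))
  }
})

test_that("the comparison count respects the quadratic bound", {
  set.seed(78)
  for (k in c(2, 5, 20, 60)) {
    rs <- sort(sample(0:400, k))
    re <- rs + sample(5:40, k, replace = TRUE)
    dp <- splitmap:::greedy_chain_cpp(rs, re, re - rs + 1L)
    expect_lte(dp$comparisons, k * (k - 1) / 2)
  }
})

test_that("chain scores survive recomputation (no stale scores)", {
  set.seed(79)
  rs <- sort(sample(0:150, 10)); re <- rs + sample(10:30, 10, replace = TRUE)
  chains <- greedy_chain(seed_df(rs, re, re - rs + 1L))
  for (ch in chains) expect_equal(ch$score, chain_score(ch$seeds))
})

test_that("select_chain enforces the coverage threshold", {
  cover95 <- greedy_chain(seed_df(0, 94, 95), m = 100)
  expect_s3_class(select_chain(cover95, 100), "seed_chain")
  cover60 <- greedy_chain(seed_df(0, 59, 60), m = 100)
  expect_null(select_chain(cover60, 100))
  expect_s3_class(select_chain(cover60, 100, chain_params(min_coverage = 0.5)),
                  "seed_chain")
  expect_null(select_chain(list(), 100))
})

occ_df <- function(chrom, start, strand, len = 30L) {
  data.frame(chrom = chrom, ref_start = start, ref_end = start + len,
             strand = strand, stringsAsFactors = FALSE)
}

make_chain <- function(occs) {
  k <- length(occs)
  seeds <- data.frame(read_start = (seq_len(k) - 1L) * 30L,
                      read_end = seq_len(k) * 30L - 1L,
                      score = rep(30L, k))
  seeds$occurrences <- occs
  structure(list(seeds = seeds, score = 30L * k, read_coverage = 1, n = k),
            class = "seed_chain")
}

test_that("occurrence resolution minimizes distance with strand preference", {
  ch <- make_chain(list(occ_df("chr1", 800L, "+"),
                        occ_df(c("chr1", "chr2"), c(1000L, 500L), c("+", "+"))))
  r <- resolve_occurrences(ch)
  expect_equal(r$seeds$ref_start[2], 1000L)
  expect_equal(r$seeds$chrom[2], "chr1")

  ch2 <- make_chain(list(occ_df("chr1", 1000L, "+"),
                         occ_df(c("chr1", "chr1"), c(900L, 1100L), c("-", "+"))))
  r2 <- resolve_occurrences(ch2)
  expect_equal(r2$seeds$strand[2], "+")  # equidistant: same strand wins
})

test_that("resolution matches the exhaustive oracle on multi-hit chains", {
  set.seed(80)
  BIG <- 1e9
  for (trial in 1:50) {
    occs <- lapply(1:3, function(i) {
      n <- sample(1:4, 1)
      occ_df(sample(c("chr1", "chr2"), n, replace = TRUE),
             as.integer(sample(0:5000, n)),
             sample(c("+", "-"), n, replace = TRUE))
    })
    r <- resolve_occurrences(make_chain(occs))
    # independent enumeration over all combinations
    grid <- expand.grid(lapply(occs, function(o) seq_len(nrow(o))))
    cost <- apply(grid, 1, function(idx) {
      tot <- 0; changes <- 0
      for (i in 2:3) {
        a <- occs[[i - 1]][idx[i - 1], ]; b <- occs[[i]][idx[i], ]
        tot <- tot + if (a$chrom != b$chrom) BIG else abs(a$ref_start - b$ref_start)
        changes <- changes + (a$strand != b$strand)
      }
      tot + changes / 10
    })
    got <- 0; changes <- 0
    for (i in 2:3) {
      a <- r$seeds[i - 1, ]; b <- r$seeds[i, ]
      got <- got + if (a$chrom != b$chrom) BIG else abs(a$ref_start - b$ref_start)
      changes <- changes + (a$strand != b$strand)
    }
    expect_equal(got + changes / 10, min(cost), info = sprintf("trial %d", trial))
  }
})
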