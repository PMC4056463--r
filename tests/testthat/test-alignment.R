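test_that("semi-global alignment finds contained and mutated reads", {
  r <- semi_global_align("ACGT", "TTACGTTT")
  expect_equal(r$distance, 0L)
  expect_equal(r$end, 6L)
  expect_equal(semi_global_align("ACGT", "TTAGGTTT")$distance, 1L)
})

test_that("semi-global distance equals the quadratic DP oracle", {
  set.seed(90)
  for (trial in 1:200) {
    read <- random_seq(sample(5:25, 1))
    window <- random_seq(sample(10:50, 1))
    expect_equal(semi_global_align(read, window)$distance,
                 edit_oracle(read, window), info = sprintf("trial %d", trial))
  }
})

test_that("windows are extended, clipped, and strand-flipped", {
  g <- make_toy_genome()
  mk <- function(start, end, strand) {
    seeds <- data.frame(read_start = 0L, read_end = end - start - 1L,
                        score = end - start, chrom = "chrA",
                        ref_start = start, ref_end = end, strand = strand,
                        stringsAsFactors = FALSE)
    structure(list(seeds = seeds, score = end - start, read_coverage = 1,
                   n = 1L), class = "seed_chain")
  }
  p <- align_params(boundary_extension = 10L)
  w <- extract_windows(mk(100L, 150L, "+"), g, p)
  expect_equal(c(w$start, w$end), c(90L, 160L))
  w0 <- extract_windows(mk(0L, 50L, "+"), g, p)
  expect_equal(c(w0$start, w0$end), c(0L, 60L))
  wm <- extract_windows(mk(100L, 150L, "-"), g, p)
  expect_equal(wm$seq, rc(substr(g$sequences[["chrA"]], 91, 160)))
})

test_that("a single window reduces exactly to Smith-Waterman", {
  set.seed(91)
  p <- align_params(min_fragment_length = 1L)
  for (trial in 1:40) {
    read <- random_seq(sample(10:30, 1))
    window <- random_seq(sample(20:60, 1))
    aln <- transition_align(read, window, p)
    expected <- sw_oracle(read, window)
    got <- if (is.null(aln)) 0 else aln$score
    expect_equal(got, expected, info = sprintf("trial %d", trial))
    if (!is.null(aln)) expect_equal(aln$transitions, 0L)
  }
  # exact containment: full score, no transitions
  g <- make_toy_genome()
  read <- substr(g$sequences[["chrA"]], 301, 400)
  aln <- transition_align(read, read, align_params())
  expect_equal(aln$score, 100L)
  expect_equal(nrow(aln$fragments), 1L)
})

test_that("a chimeric read splits into two fragments at the stated cost", {
  set.seed(92)
  wa <- random_seq(50); wb <- random_seq(50)
  read <- paste0(wa, wb)
  p <- align_params()
  aln <- transition_align(read, c(wa, wb), p)
  expect_equal(nrow(aln$fragments), 2L)
  expect_equal(aln$fragments$read_start, c(0L, 50L))
  expect_equal(aln$fragments$read_end, c(49L, 99L))
  expect_equal(aln$score, 100L - p$transition)
})

test_that("back-splice geometry inverts genomic order relative to the read", {
  g <- make_toy_genome()
  exon1 <- substr(g$sequences[["chrA"]], 1001, 1080)
  exon2 <- substr(g$sequences[["chrA"]], 1501, 1580)
  read <- paste0(substr(exon2, 41, 80), substr(exon1, 1, 40))
  seeds <- data.frame(read_start = c(0L, 40L), read_end = c(39L, 79L),
                      score = c(40L, 40L), chrom = "chrA",
                      ref_start = c(1540L, 1000L), ref_end = c(1580L, 1040L),
                      strand = "+", stringsAsFactors = FALSE)
  chain <- structure(list(seeds = seeds, score = 80L, read_coverage = 1,
                          n = 2L), class = "seed_chain")
  w <- extract_windows(chain, g, align_params())
  aln <- transition_align(read, w, align_params())
  expect_equal(nrow(aln$fragments), 2L)
  expect_gt(aln$fragments$ref_start[1], aln$fragments$ref_start[2])
  jn <- extract_junctions(aln, g)
  expect_equal(jn$class, "circular")
})

test_that("total score equals the brute-force split-point oracle", {
  set.seed(93)
  p <- align_params(min_fragment_length = 1L)
  inject <- function(s, n_err) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (at in sample(length(ch), n_err)) {
      ch[at] <- sample(setdiff(c("A", "C", "G", "T"), ch[at]), 1)
    }
    paste(ch, collapse = "")
  }
  for (trial in 1:170) {  # two windows
    w <- c(random_seq(sample(20:40, 1)), random_seq(sample(20:40, 1)))
    half <- sample(8:15, 2)
    read <- paste0(substr(w[1], 3, 2 + half[1]), substr(w[2], 5, 4 + half[2]))
    read <- inject(read, sample(0:2, 1))
    aln <- transition_align(read, w, p)
    got <- if (is.null(aln)) 0 else aln$score
    expect_equal(got, split_oracle(read, w), info = sprintf("2-window trial %d", trial))
  }
  for (trial in 1:40) {  # three windows, small reads
    w <- c(random_seq(15), random_seq(15), random_seq(15))
    read <- paste0(substr(w[1], 1, 8), substr(w[2], 4, 11), substr(w[3], 6, 13))
    read <- inject(read, sample(0:2, 1))
    aln <- transition_align(read, w, p)
    got <- if (is.null(aln)) 0 else aln$score
    expect_equal(got, split_oracle(read, w), info = sprintf("3-window trial %d", trial))
  }
})

test_that("raising the transition penalty never adds transitions", {
  set.seed(94)
  for (trial in 1:25) {
    w <- c(random_seq(40), random_seq(40))
    read <- paste0(substr(w[1], 1, 20), substr(w[2], 11, 30))
    last <- Inf
    for (tau in c(0L, 2L, 5L, 10L)) {
      aln <- transition_align(read, w,
                              align_params(transition = tau,
                                           min_fragment_length = 1L))
      tr <- if (is.null(aln)) 0L else aln$transitions
      expect_lte(tr, last)
      last <- tr
    }
  }
})

test_that("the split score dominates every single-window alignment", {
  set.seed(95)
  for (trial in 1:25) {
    w <- c(random_seq(40), random_seq(40), random_seq(40))
    read <- paste0(substr(w[2], 1, 18), substr(w[3], 20, 39))
    aln <- transition_align(read, w, align_params(min_fragment_length = 1L))
    best_single <- max(vapply(w, function(x) sw_oracle(read, x), numeric(1)))
    expect_gte(aln$score, best_single)
  }
})

test_that("alignment score is symmetric under reverse complement", {
  set.seed(96)
  for (trial in 1:25) {
    w <- c(random_seq(40), random_seq(40))
    read <- paste0(substr(w[1], 3, 22), substr(w[2], 7, 28))
    p <- align_params(min_fragment_length = 1L)
    fwd <- transition_align(read, w, p)
    rev <- transition_align(rc(read), rev(vapply(w, rc, character(1))), p)
    expect_equal(fwd$score, rev$score)
    expect_equal(fwd$transitions, rev$transitions)
  }
})
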