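frag_df <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

mk_aln <- function(fragments) {
  structure(list(read_id = "r", fragments = fragments,
                 score = sum(fragments$score), transitions = nrow(fragments) - 1L),
            class = "split_alignment")
}

test_that("one junction per adjacent fragment pair", {
  f2 <- frag_df(read_start = c(0L, 50L), read_end = c(49L, 99L),
                chrom = "chr1", ref_start = c(100L, 500L),
                ref_end = c(150L, 550L), strand = "+",
                ops = strrep("M", 50), score = 50L)
  expect_equal(nrow(extract_junctions(mk_aln(f2))), 1L)
  f4 <- frag_df(read_start = c(0L, 25L, 50L, 75L),
                read_end = c(24L, 49L, 74L, 99L), chrom = "chr1",
                ref_start = c(100L, 500L, 900L, 1300L),
                ref_end = c(125L, 525L, 925L, 1325L), strand = "+",
                ops = strrep("M", 25), score = 25L)
  expect_equal(nrow(extract_junctions(mk_aln(f4))), 3L)
  expect_equal(nrow(extract_junctions(mk_aln(f2[1, ]))), 0L)
})

test_that("classification follows the donor/acceptor geometry", {
  j <- function(p1, s1, p2, s2, c1 = "chr1", c2 = "chr1") {
    data.frame(chrom1 = c1, pos1 = p1, strand1 = s1,
               chrom2 = c2, pos2 = p2, strand2 = s2, stringsAsFactors = FALSE)
  }
  expect_equal(classify_junction(j(10000L, "+", 11000L, "+")), "regular")
  expect_equal(classify_junction(j(10000L, "+", 11000L, "-")),
               "strand-reversing")
  expect_equal(classify_junction(j(10000L, "+", 260000L, "+")), "long-range")
  expect_equal(classify_junction(j(10000L, "+", 1000L, "+", "chr1", "chr2")),
               "long-range")
  expect_equal(classify_junction(j(10000L, "+", 5000L, "+")), "circular")
  # minus-strand mirror: acceptor at larger coordinate is the back-splice
  expect_equal(classify_junction(j(10000L, "-", 15000L, "-")), "circular")
  expect_equal(classify_junction(j(10000L, "-", 5000L, "-")), "regular")
})

test_that("classification is total and deterministic", {
  set.seed(70)
  j <- data.frame(chrom1 = sample(c("chr1", "chr2"), 200, TRUE),
                  pos1 = sample.int(4e5, 200),
                  strand1 = sample(c("+", "-"), 200, TRUE),
                  chrom2 = sample(c("chr1", "chr2"), 200, TRUE),
                  pos2 = sample.int(4e5, 200),
                  strand2 = sample(c("+", "-"), 200, TRUE),
                  stringsAsFactors = FALSE)
  cl <- classify_junction(j)
  expect_true(all(cl %in% c("regular", "strand-reversing", "long-range",
                            "circular")))
  expect_identical(cl, classify_junction(j))
})

test_that("sense and antisense observations normalize identically", {
  g <- make_toy_genome()
  sense <- data.frame(chrom1 = "chrA", pos1 = 1200L, strand1 = "+",
                      chrom2 = "chrA", pos2 = 2400L, strand2 = "+",
                      stringsAsFactors = FALSE)
  anti <- data.frame(chrom1 = "chrA", pos1 = 2400L, strand1 = "-",
                     chrom2 = "chrA", pos2 = 1200L, strand2 = "-",
                     stringsAsFactors = FALSE)
  a <- splitmap:::finalize_junctions(sense, g)
  b <- splitmap:::finalize_junctions(anti, g)
  cols <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2", "class")
  expect_identical(a[cols], b[cols])
  expect_equal(a$class, "regular")
})

obs <- function(n, pos1 = 1000L, pos2 = 2000L) {
  data.frame(chrom1 = "chr1", pos1 = pos1, strand1 = "+",
             chrom2 = "chr1", pos2 = pos2, strand2 = "+",
             class = "regular", support = rep(1L, n), swapped = FALSE,
             stringsAsFactors = FALSE)
}

test_that("support is summed, filtered, and conserved", {
  three <- obs(3)
  out <- aggregate_support(three, junction_params(min_support = 3))
  expect_equal(nrow(out), 1L)
  expect_equal(out$support, 3L)
  expect_equal(nrow(aggregate_support(obs(2), junction_params(min_support = 3))),
               0L)
  # conservation: total support equals the observation count
  set.seed(71)
  many <- do.call(rbind, lapply(1:20, function(i) {
    obs(sample(1:4, 1), pos1 = sample(c(1000L, 1500L), 1),
        pos2 = sample(c(2000L, 2500L), 1))
  }))
  merged <- aggregate_support(many, junction_params(merge_tolerance = 0))
  expect_equal(sum(merged$support), nrow(many))
})

test_that("the merge tolerance contract distinguishes 0 from 1", {
  five <- rbind(obs(3), obs(2, pos1 = 1001L))
  exact <- aggregate_support(five, junction_params(merge_tolerance = 0))
  expect_equal(nrow(exact), 2L)
  fuzzy <- aggregate_support(five, junction_params(merge_tolerance = 1))
  expect_equal(nrow(fuzzy), 1L)
  expect_equal(fuzzy$support, 5L)
  expect_equal(fuzzy$pos1, 1000L)  # modal breakpoint wins
})
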