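test_that("simulation is deterministic per seed", {
  cfg <- sim_config(genome_size = 5e4, n_isoforms = 5, seed = 42,
                    exon_length = c(60, 120), intron_length = c(100, 400))
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1$sequences, g2$sequences)
  i1 <- simulate_isoforms(g1, cfg); i2 <- simulate_isoforms(g2, cfg)
  expect_identical(i1$truth, i2$truth)
  r1 <- simulate_reads(i1, cfg); r2 <- simulate_reads(i2, cfg)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$read_truth, r2$read_truth)
})

test_that("genome composition is uniform with optional decoys", {
  cfg <- sim_config(genome_size = 1e5, n_chrom = 1L, seed = 8)
  g <- simulate_genome(cfg)
  gc <- sum(strsplit(g$sequences[[1]], "")[[1]] %in% c("G", "C")) /
    nchar(g$sequences[[1]])
  expect_lt(abs(gc - 0.5), 0.02)
  cfgd <- sim_config(genome_size = 1e5, n_chrom = 1L, decoy_fraction = 0.05,
                     seed = 8)
  gd <- simulate_genome(cfgd)
  expect_true(grepl(strrep("A", 50), gd$sequences[[1]]))
})

test_that("irregular fraction controls the truth junction classes", {
  base <- function(...) sim_config(genome_size = 1e6, n_isoforms = 40,
                                   exon_length = c(60, 150),
                                   intron_length = c(100, 500), seed = 9, ...)
  reg <- simulate_isoforms(simulate_genome(base(irregular_fraction = 0)),
                           base(irregular_fraction = 0))
  expect_true(all(reg$truth$class == "regular"))

  flip <- base(irregular_fraction = 1, irregular_type = "flip")
  tf <- simulate_isoforms(simulate_genome(flip), flip)$truth
  expect_false(any(tf$class == "long-range"))

  mix <- base(irregular_fraction = 0.3, irregular_type = "flip")
  tm <- simulate_isoforms(simulate_genome(mix), mix)$truth
  expect_true(any(tm$class == "strand-reversing"))

  dist <- base(irregular_fraction = 0.5, irregular_type = "distant")
  td <- simulate_isoforms(simulate_genome(dist), dist)$truth
  expect_true(any(td$class == "long-range"))
  expect_false(any(td$class == "strand-reversing"))
})

test_that("irregular exon counts follow the binomial law", {
  cfg <- sim_config(genome_size = 4e6, n_chrom = 4L, n_isoforms = 250,
                    exons_per_isoform = c(4L, 4L), exon_length = c(60, 100),
                    intron_length = c(100, 300), irregular_fraction = 0.2,
                    seed = 10)
  iso <- simulate_isoforms(simulate_genome(cfg), cfg)
  n_exons <- 250 * 4
  n_irr <- sum(vapply(iso$isoforms, function(it) {
    sum(vapply(it$exons, `[[`, logical(1), "irregular"))
  }, numeric(1)))
  sigma <- sqrt(n_exons * 0.2 * 0.8)
  expect_lt(abs(n_irr - n_exons * 0.2), 3 * sigma)
})

test_that("error-free reads are exact isoform substrings", {
  cfg <- sim_config(genome_size = 1e5, n_isoforms = 5, error_model = "none",
                    exon_length = c(60, 150), intron_length = c(100, 400),
                    read_length = 80L, seed = 11)
  iso <- simulate_isoforms(simulate_genome(cfg), cfg)
  sim <- simulate_reads(iso, cfg)
  seqs <- setNames(vapply(iso$isoforms, `[[`, character(1), "sequence"),
                   vapply(iso$isoforms, `[[`, character(1), "id"))
  for (i in seq_len(nrow(sim$reads))) {
    r <- sim$reads[i, ]
    template <- substr(seqs[[r$isoform]], r$start + 1, r$start + 80)
    if (r$flipped) template <- rc(template)
    expect_identical(r$sequence, template)
  }
})

test_that("substitution rate calibrates within binomial bounds", {
  set.seed(12)
  tot_sub <- 0L; tot_bases <- 0L
  for (i in 1:10) {
    m <- mutate_sequence(random_seq(1e5), sub_rate = 0.01)
    tot_sub <- tot_sub + m$n_sub
    tot_bases <- tot_bases + m$n_bases
  }
  expect_equal(tot_bases, 1e6)
  sigma <- sqrt(1e6 * 0.01 * 0.99)
  expect_lt(abs(tot_sub - 1e6 * 0.01), 3 * sigma)
})

test_that("homopolymer scaling raises the indel rate inside runs", {
  set.seed(13)
  hp <- paste(rep(strrep("A", 8), 2000), collapse = "")   # long runs
  mixed <- random_seq(16000)
  m_hp <- mutate_sequence(hp, ins_rate = 0.005, del_rate = 0.005, hp_scale = 0.3)
  m_mx <- mutate_sequence(mixed, ins_rate = 0.005, del_rate = 0.005, hp_scale = 0.3)
  expect_gt(m_hp$n_ins + m_hp$n_del, 1.5 * (m_mx$n_ins + m_mx$n_del))
})

test_that("coverage arithmetic and anchors drive the read truth", {
  cfg <- sim_config(genome_size = 5e4, n_isoforms = 1,
                    exons_per_isoform = c(4L, 4L), exon_length = c(250L, 250L),
                    intron_length = c(100L, 200L), read_length = 100L,
                    coverage = 10, error_model = "none", seed = 14)
  iso <- simulate_isoforms(simulate_genome(cfg), cfg)
  sim <- simulate_reads(iso, cfg)
  expect_equal(nrow(sim$reads), 100L)  # 10x * 1000 nt / 100 nt
  # each witnessed junction is overlapped with >= anchor on both sides
  jp <- iso$isoforms[[1]]$junction_pos
  for (i in seq_len(nrow(sim$read_truth))) {
    rid <- sim$read_truth$read_id[i]
    r <- sim$reads[sim$reads$id == rid, ]
    row <- sim$read_truth$truth_row[i]
    tp <- sim$truth$tpos[row]
    expect_gte(tp - r$start + 1L, cfg$anchor)
    expect_gte(r$start + 100L - 1L - tp, cfg$anchor)
  }
})

test_that("fastq output round-trips", {
  cfg <- sim_config(genome_size = 5e4, n_isoforms = 2, read_length = 60L,
                    exon_length = c(80, 120), intron_length = c(100, 200),
                    seed = 15)
  iso <- simulate_isoforms(simulate_genome(cfg), cfg)
  sim <- simulate_reads(iso, cfg)
  path <- tempfile(fileext = ".fq")
  write_fastq(sim$reads, path)
  back <- read_reads(path)
  expect_identical(back$id, sim$reads$id)
  expect_identical(back$sequence, sim$reads$sequence)
  expect_identical(back$quality, sim$reads$quality)
})
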