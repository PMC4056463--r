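#' Run a self-contained simulation benchmark
#'
#' Reproduces the simulation protocol at desk scale: a seeded synthetic
#' genome, multi-exon isoforms (20 percent irregular exons in the mixed
#' scenarios), error-model reads, the full index/map/call pipeline, and
#' junction evaluation against the truth table at exact tolerance.
#'
#' Scenarios: `regular-454` / `mixed-454` (400 nt indel-dominated reads,
#' regular-only vs 20 percent irregular exons), `regular-illumina` /
#' `mixed-illumina` (100 nt substitution-dominated reads),
#' `circular-short` (100 nt reads across the back-splice point of
#' circularized transcripts; junction calls restricted to uniquely mapping
#' split reads), and `circular-long` (full-length 0.5-5 kb 454-style reads
#' from circular plus collinear transcripts).
#'
#' @param scenario one of the scenario names above.
#' @param seed RNG seed for the whole benchmark.
#' @param scale scaling of the problem size (fraction of isoforms and
#'   genome); 1 is the standard desk-scale setup.
#' @return list with the scenario name, the [match_junctions()] report,
#'   the run configuration, and headline numbers in `values` (percentages):
#'   overall `recall` and `fpr`, plus `recall_circular` and
#'   `precision_circular` where applicable.
#' @export
run_benchmark <- function(scenario = c("regular-454", "mixed-454",
                                       "regular-illumina", "mixed-illumina",
                                       "circular-short", "circular-long"),
                          seed = 1L, scale = 1) {
  scenario <- match.arg(scenario)
  seed <- as.integer(seed)
  n_iso <- function(n) max(4L, as.integer(round(n * scale)))
  gsize <- function(n) max(2e5, n * scale)
  base <- switch(scenario,
    "regular-454" = sim_config(genome_size = gsize(2e6), n_chrom = 2L,
      n_isoforms = n_iso(100), exons_per_isoform = c(3L, 6L),
      exon_length = c(150L, 400L), intron_length = c(100L, 5000L),
      irregular_fraction = 0, read_length = 400L, coverage = 10,
      error_model = "r454", seed = seed),
    "mixed-454" = sim_config(genome_size = gsize(2e6), n_chrom = 2L,
      n_isoforms = n_iso(100), exons_per_isoform = c(3L, 6L),
      exon_length = c(150L, 400L), intron_length = c(100L, 5000L),
      irregular_fraction = 0.2, read_length = 400L, coverage = 10,
      error_model = "r454", seed = seed),
    "regular-illumina" = sim_config(genome_size = gsize(2e6), n_chrom = 2L,
      n_isoforms = n_iso(100), exons_per_isoform = c(3L, 6L),
      exon_length = c(80L, 300L), intron_length = c(100L, 5000L),
      irregular_fraction = 0, read_length = 100L, coverage = 10,
      error_model = "illumina", seed = seed),
    "mixed-illumina" = sim_config(genome_size = gsize(2e6), n_chrom = 2L,
      n_isoforms = n_iso(100), exons_per_isoform = c(3L, 6L),
      exon_length = c(80L, 300L), intron_length = c(100L, 5000L),
      irregular_fraction = 0.2, read_length = 100L, coverage = 10,
      error_model = "illumina", seed = seed),
    "circular-short" = sim_config(genome_size = gsize(1.5e6), n_chrom = 2L,
      n_isoforms = n_iso(100), exons_per_isoform = c(1L, 3L),
      exon_length = c(100L, 400L), intron_length = c(100L, 3000L),
      irregular_fraction = 0, read_length = 100L, coverage = 10,
      error_model = "illumina", circular = TRUE, seed = seed),
    "circular-long" = sim_config(genome_size = gsize(1.5e6), n_chrom = 2L,
      n_isoforms = n_iso(50), exons_per_isoform = c(2L, 5L),
      exon_length = c(200L, 1000L), intron_length = c(100L, 5000L),
      irregular_fraction = 0, read_length = "full", coverage = 4,
      error_model = "r454", circular = TRUE, seed = seed))
  cfg <- run_config()
  unique_only <- scenario == "circular-short"

  one_run <- function(simcfg) {
    genome <- simulate_genome(simcfg)
    iso <- simulate_isoforms(genome, simcfg)
    sim <- simulate_reads(iso, simcfg)
    index <- build_index(genome)
    res <- map_reads(index, sim$reads, cfg, unique_only = unique_only)
    list(pred = res$junctions, truth = sim$truth, n_reads = nrow(sim$reads))
  }

  runs <- list(one_run(base))
  if (scenario == "circular-long") {
    # the collinear half of the long-read benchmark
    linear <- base
    linear$circular <- FALSE
    linear$seed <- seed + 1000L
    runs <- c(runs, list(one_run(linear)))
  }
  pred <- do.call(rbind, lapply(seq_along(runs), function(i) {
    p <- runs[[i]]$pred
    if (nrow(p)) p$chrom1 <- paste0("run", i, ":", p$chrom1)
    if (nrow(p)) p$chrom2 <- paste0("run", i, ":", p$chrom2)
    p
  }))
  truth <- do.call(rbind, lapply(seq_along(runs), function(i) {
    tt <- runs[[i]]$truth
    if (nrow(tt)) tt$chrom1 <- paste0("run", i, ":", tt$chrom1)
    if (nrow(tt)) tt$chrom2 <- paste0("run", i, ":", tt$chrom2)
    tt
  }))
  report <- match_junctions(pred, truth, tolerance = 0)

  values <- list(recall = 100 * report$recall, fpr = 100 * report$fpr)
  bd <- report$breakdown
  if (!is.null(bd) && "circular" %in% bd$class) {
    circ <- bd[bd$class == "circular", ]
    values$recall_circular <- 100 * circ$n_correct / circ$n_truth
    values$precision_circular <-
      if (circ$n_predicted > 0) 100 * (1 - circ$n_wrong / circ$n_predicted)
      else NA_real_
    values$n_circular_truth <- circ$n_truth
    values$n_circular_predicted <- circ$n_predicted
  }
  list(scenario = scenario, report = report, config = base,
       n_reads = sum(vapply(runs, `[[`, numeric(1), "n_reads")),
       values = values)
}
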