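test_that("RT score is bounded, antisymmetric and NA on empty bins", {
  expect_equal(rtScore(10, 10), 0)
  expect_equal(rtScore(5, 0), 1)
  expect_equal(rtScore(0, 7), -1)
  expect_true(is.na(rtScore(0, 0)))
  set.seed(71)
  e <- rpois(50, 5); l <- rpois(50, 5)
  s <- rtScore(e, l)
  expect_true(all(s >= -1 & s <= 1, na.rm = TRUE))
  expect_equal(rtScore(l, e), -s)
  expect_error(rtScore(-1, 2), "nonnegative")
})

test_that("expression transform rounds log10 and resolves overlaps", {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 2001, 5001), c(1000, 3000, 6000)),
    counts = c(0, 9, 999))
  tr <- transformExpression(gr)
  expect_equal(tr$transformed, c(0, 1, 3))

  # overlap: higher count wins the shared stretch
  ov <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 500), c(1000, 1500)),
    counts = c(9, 999), gene = c("lo", "hi"))
  res <- transformExpression(ov)
  expect_true(all(IRanges::width(GenomicRanges::reduce(res)) ==
                    sum(IRanges::width(GenomicRanges::disjoin(res)))))
  hi <- res[res$gene == "hi"]
  lo <- res[res$gene == "lo"]
  expect_equal(GenomicRanges::start(hi), 500)
  expect_equal(GenomicRanges::end(hi), 1500)
  expect_equal(GenomicRanges::end(lo), 499)   # truncated by the winner

  # tie on counts: earlier interval start wins
  tie <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 500), c(1000, 1500)),
    counts = c(7, 7), gene = c("first", "second"))
  res_tie <- transformExpression(tie)
  expect_equal(GenomicRanges::end(res_tie[res_tie$gene == "first"]), 1000)
  expect_equal(GenomicRanges::start(res_tie[res_tie$gene == "second"]), 1001)
  expect_error(transformExpression(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10), counts = -1)),
    "nonnegative")
})

test_that("cumulative origin correlation peaks where origins replicate first", {
  coh <- ladder_cohort(n_cells = 16, seed = 72)
  mol <- coh$molecules
  ord <- new("OrderingResult",
    table = data.table::data.table(
      cell = names(coh$stage), consensus_position = coh$stage,
      kept = TRUE, n_successful_runs = 10L, cluster_size = 10L),
    placements = matrix(0, 16, 10), n_runs = 10L, oriented = TRUE)

  # an origin track matching the earliest cells' coverage: with the
  # gradient timing profile, early cells replicate near the chromosome
  # start, so weight bins by closeness to the start
  b <- binCounts(mol, 1e5)
  grid <- unique(b[, .(chrom, bin_start)])
  layout_len <- 2e7
  origin <- grid[, .(chrom, bin_start,
                     value = pmax(0, 1 - bin_start / (0.3 * layout_len)))]
  cc <- cumulativeOriginCorrelation(mol, ord, origin)
  expect_equal(nrow(cc), 16)
  # strongest agreement early in S, declining as late DNA accumulates
  first_q <- mean(cc$pearson[1:4], na.rm = TRUE)
  last_q <- mean(cc$pearson[13:16], na.rm = TRUE)
  expect_gt(first_q, last_q)

  # origin equal to the final cumulative coverage: last prefix has r = 1
  final_cum <- b[cell %in% names(coh$stage),
                 .(value = sum(value)), by = .(chrom, bin_start)]
  cc2 <- cumulativeOriginCorrelation(mol, ord, final_cum)
  expect_equal(cc2$pearson[nrow(cc2)], 1)

  # orthogonal random track: negligible correlation
  set.seed(73)
  rnd <- grid[, .(chrom, bin_start, value = rnorm(.N))]
  cc3 <- cumulativeOriginCorrelation(mol, ord, rnd)
  expect_lt(abs(cc3$pearson[nrow(cc3)]), 0.15)
})

test_that("region-weighted speed densities localize planted slow regions", {
  set.seed(74)
  layout <- genomeLayout("chr1", 4e7)
  # forks inside the left half run at 0.7 kb/min, outside at 1.3
  slow_region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2e7))
  mk_cell <- function() {
    f_in <- simulateWholeCell(genomeLayout("chr1", 2e7), n_forks = 40,
                              speed_mu = 0.7, speed_sigma = 0.05,
                              scheme = pulseScheme(60), sampling_rate = 0.3,
                              seed = 75)
    f_out <- simulateWholeCell(genomeLayout("chr1", 2e7), n_forks = 40,
                               speed_mu = 1.3, speed_sigma = 0.05,
                               scheme = pulseScheme(60), sampling_rate = 0.3,
                               seed = 76)
    d_out <- molecules(f_out$molecules)
    d_out[, pos := pos + 2e7]
    d <- rbind(molecules(f_in$molecules), d_out)
    d[, cell := "mix"]
    MoleculeTable(d, layout)
  }
  mol <- mk_cell()
  fit <- suppressWarnings(fitMixture(pairDistances(mol, "mix"), seed = 5))
  res <- weightedSpeedByRegion(mol, list(mix = fit), slow_region,
                               delta_t = 75, seed = 6)
  mode_of <- function(s) {
    dd <- res$density[res$density$side == s]
    dd$speed[which.max(dd$density)]
  }
  expect_lt(mode_of("inside"), mode_of("outside"))
  expect_lt(res$test$p.value, 0.01)

  # whole-genome region: inside density equals the unweighted speed
  # density (posterior-weighted), outside side is empty
  whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 4e7))
  res_w <- suppressWarnings(weightedSpeedByRegion(mol, list(mix = fit),
                                                  whole, delta_t = 75))
  expect_true(all(res_w$weights$overlap_frac == 1))
  expect_false("outside" %in% res_w$density$side)
})

test_that("z-scored bulk tracks compare through rank correlation", {
  set.seed(77)
  a <- data.table::data.table(chrom = "chr1", bin_start = (0:99) * 5e4,
                              value = rpois(100, 20))
  self <- zscoreBulkTracks(a, a)
  expect_equal(self$spearman, 1)
  neg <- data.table::copy(a)[, value := -value]
  expect_equal(zscoreBulkTracks(a, neg)$spearman, -1)
  expect_equal(mean(self$tracks$z_a), 0, tolerance = 1e-12)
  expect_equal(sd(self$tracks$z_a), 1, tolerance = 1e-12)
  flat <- data.table::copy(a)[, value := 5]
  expect_error(zscoreBulkTracks(a, flat), "zero-variance")
})
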