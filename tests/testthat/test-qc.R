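test_that("density filter applies mode-specific thresholds", {
  # 1-Mb + 0.5-Mb genome = 15 bins of 100 kb
  layout <- tiny_layout()
  mk <- function(cell, n, labeling = "single", spread = TRUE) {
    pos <- if (spread) floor(seq(0, 999999, length.out = n))
           else seq(100, by = 200, length.out = n)
    data.table::data.table(cell = cell, chrom = "chr1", pos = pos,
                           strand = "+", sample = "s",
                           labeling = labeling,
                           delta_t = if (labeling == "double") 75 else NA_real_)
  }
  mol <- MoleculeTable(rbind(
    mk("low_single", 3),            # mean 0.2  < 0.37 -> fail
    mk("ok_single", 15),            # mean 1.0 in [0.37, 2.72] -> pass
    mk("ok_double", 75, "double"),  # mean 5.0 in [0.08, 12.18] -> pass
    mk("hi_double", 200, "double")  # mean 13.3 > 12.18 -> fail
  ), layout)
  qc <- computeQC(mol)
  expect_false(qc[cell == "low_single", pass_density])
  expect_true(qc[cell == "ok_single", pass_density])
  expect_true(qc[cell == "ok_double", pass_density])
  expect_false(qc[cell == "hi_double", pass_density])
})

test_that("dispersion gate keeps clumped (track-like) cells at mean 1", {
  # at mean 1 (log mean = 0) the rule reduces to: keep iff CV > e^0.1
  layout <- genomeLayout("chr1", 1e6)   # 10 bins of 100 kb
  uniform <- data.table::data.table(    # 1 read per bin: CV = 0, flat
    cell = "uniform", chrom = "chr1", pos = seq(0, 9) * 1e5 + 10,
    strand = "+")
  lumpy <- data.table::data.table(      # 10 reads in one bin
    cell = "lumpy", chrom = "chr1", pos = seq(10, 1000, length.out = 10),
    strand = "+")
  mol <- MoleculeTable(rbind(uniform, lumpy), layout)
  expect_warning(computeQC(mol), "CV undefined")
  qc <- suppressWarnings(computeQC(mol))
  expect_equal(qc[cell == "uniform", mean_per_bin], 1)
  expect_equal(qc[cell == "lumpy", mean_per_bin], 1)
  # Poisson-flat coverage carries no replication-track signal
  expect_false(qc[cell == "uniform", pass_dispersion])  # CV 0 < e^0.1
  # a single nonzero bin leaves the CV undefined: cannot be assessed
  expect_true(is.na(qc[cell == "lumpy", cv]))
  expect_false(qc[cell == "lumpy", pass_dispersion])
})

test_that("dispersion boundary follows log(CV) > -0.5 log(mean) + 0.1", {
  # direct evaluation of the inequality on synthetic bin vectors
  layout <- genomeLayout("chr1", 2e6)   # 20 bins
  counts_to_tbl <- function(cell, counts) {
    pos <- unlist(lapply(seq_along(counts), function(i)
      if (counts[i] > 0) (i - 1) * 1e5 + seq_len(counts[i]) * 37))
    data.table::data.table(cell = cell, chrom = "chr1", pos = pos,
                           strand = "+")
  }
  counts_a <- rep(c(2, 2, 2, 2, 3), 4)      # near-flat coverage
  counts_b <- rep(c(0, 0, 0, 0, 10), 4)     # clumped, track-like
  mol <- MoleculeTable(rbind(counts_to_tbl("a", counts_a),
                             counts_to_tbl("b", counts_b)), layout)
  qc <- computeQC(mol)
  for (cc in c("a", "b")) {
    cv <- qc[cell == cc, cv]; mu <- qc[cell == cc, mean_per_bin]
    expect_equal(qc[cell == cc, pass_dispersion],
                 log(cv) > -0.5 * log(mu) + 0.1)
  }
  expect_false(qc[cell == "a", pass_dispersion])
  expect_true(qc[cell == "b", pass_dispersion])
})

test_that("foreground selection keeps clustered reads, drops isolated ones", {
  set.seed(31)
  layout <- genomeLayout("chr1", 3e7)
  clustered <- clustered_positions(k = 12, per = 8, gap = 100)
  isolated <- seq(1.5e7, 2.9e7, length.out = 12) + sample(1:50, 12)
  mol <- MoleculeTable(data.table::data.table(
    cell = "A", chrom = "chr1", pos = c(clustered, isolated),
    strand = "+"), layout)
  fg <- selectForegroundReads(mol)
  expect_true(all(fg$posterior >= 0 & fg$posterior <= 1))
  res <- merge(molecules(mol), fg, by = c("cell", "chrom", "pos", "strand"))
  expect_true(all(res[pos %in% clustered & neighbor_dist <= 200, keep]))
  expect_false(any(res[pos %in% isolated, keep]))

  # oracle: posterior under the true generating parameters agrees on
  # which side of 0.5 each read falls (well-separated scales)
  post_true <- function(d, m1 = 100, m2 = 1.2e6, p1 = 0.85) {
    f1 <- p1 * dexp(d, 1 / m1); f2 <- (1 - p1) * dexp(d, 1 / m2)
    f1 / (f1 + f2)
  }
  expect_equal(res$keep, post_true(res$neighbor_dist) > 0.5)
})

test_that("foreground selection is order invariant and sane when degenerate", {
  set.seed(32)
  layout <- genomeLayout(c("chr1", "chr2"), c(3e7, 3e7))
  d <- data.table::data.table(
    cell = "A",
    chrom = sample(c("chr1", "chr2"), 60, TRUE),
    pos = sample.int(3e7, 60), strand = "+")
  mol1 <- MoleculeTable(d, layout)
  mol2 <- MoleculeTable(d[sample(.N)], layout)
  fg1 <- suppressWarnings(selectForegroundReads(mol1))
  fg2 <- suppressWarnings(selectForegroundReads(mol2))
  data.table::setkey(fg1, cell, chrom, pos)
  data.table::setkey(fg2, cell, chrom, pos)
  expect_equal(fg1$keep, fg2$keep)
  expect_equal(fg1$posterior, fg2$posterior)

  # identical gaps: single effective component, deterministic, no crash
  mol_eq <- MoleculeTable(data.table::data.table(
    cell = "A", chrom = "chr1", pos = seq(0, 5000, by = 500),
    strand = "+"), genomeLayout("chr1", 1e6))
  fg_eq1 <- selectForegroundReads(mol_eq)
  fg_eq2 <- selectForegroundReads(mol_eq)
  expect_identical(fg_eq1, fg_eq2)
})

test_that("QC pass decisions do not depend on row order", {
  coh <- ladder_cohort(n_cells = 12, seed = 40)
  d <- molecules(coh$molecules)
  m1 <- MoleculeTable(d, genomeLayout(c("chr1", "chr2"), c(2e7, 2e7)))
  set.seed(1)
  m2 <- MoleculeTable(d[sample(.N)], genomeLayout(c("chr1", "chr2"), c(2e7, 2e7)))
  q1 <- suppressWarnings(computeQC(m1))
  q2 <- suppressWarnings(computeQC(m2))
  expect_equal(q1, q2)
})
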