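test_that("smoothed profiles have Gaussian shape and unit mass per read", {
  layout <- genomeLayout("chr1", 1e6)
  mol <- MoleculeTable(data.table::data.table(
    cell = "A", chrom = "chr1", pos = 500000, strand = "+"), layout)
  prof <- smoothProfiles(mol, grid_step = 2500)
  p <- prof$chr1["A", ]
  grid <- (seq_along(p) - 1) * 2500
  peak <- which.max(p)
  expect_equal(grid[peak], 500000)
  # Gaussian shape: the ratio to the peak at the grid point nearest one
  # kernel sd away matches the Gaussian evaluated at that grid distance
  at_sd <- which.min(abs(grid - (500000 + 8333.333)))
  expect_equal(p[at_sd] / p[peak],
               exp(-0.5 * ((grid[at_sd] - 500000) / 8333.333)^2),
               tolerance = 0.01)
  # unit mass for an interior read
  expect_equal(sum(p), 1, tolerance = 1e-6)

  # two reads 100 kb apart (> 5 sd): two separated modes, negligible
  # cross-talk at the midpoint
  mol2 <- MoleculeTable(data.table::data.table(
    cell = "A", chrom = "chr1", pos = c(400000, 500000), strand = "+"),
    layout)
  p2 <- smoothProfiles(mol2, grid_step = 2500)$chr1["A", ]
  mid <- which.min(abs(grid - 450000))
  expect_lt(p2[mid], 1e-6 * max(p2))
  expect_equal(sum(p2), 2, tolerance = 1e-6)
})

test_that("overlap score converts to the capped reciprocal distance", {
  expect_equal(scoreToDistance(1), 0)
  expect_equal(scoreToDistance(0.5), 1)
  expect_equal(scoreToDistance(0), 1000)
  # cap engages exactly at score <= 1/1001
  expect_equal(scoreToDistance(1 / 1001), 1000)
  expect_equal(scoreToDistance(1e-6), 1000)
  expect_lt(scoreToDistance(1 / 1000.99), 1000)
})

test_that("cell distance matrix is symmetric, capped and permutation equivariant", {
  coh <- ladder_cohort(n_cells = 12, seed = 21)
  prof <- smoothProfiles(coh$molecules)
  D <- cellDistanceMatrix(prof)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, nrow(D)))
  expect_true(all(D >= 0 & D <= 1000))

  # identical profiles -> distance 0; disjoint -> 1000
  layout <- genomeLayout("chr1", 1e6)
  mol <- MoleculeTable(data.table::data.table(
    cell = rep(c("X", "Y", "Z"), each = 2), chrom = "chr1",
    pos = c(1e5, 2e5, 1e5, 2e5, 8e5, 9e5), strand = "+"), layout)
  D2 <- cellDistanceMatrix(smoothProfiles(mol))
  expect_equal(D2["X", "Y"], 0, tolerance = 1e-9)
  expect_equal(D2["X", "Z"], 1000)

  # relabeling permutes rows/columns consistently
  set.seed(9)
  shuffle <- sample(nrow(prof[[1]]))
  prof_p <- lapply(prof, function(P) P[shuffle, , drop = FALSE])
  Dp <- cellDistanceMatrix(prof_p)
  expect_equal(Dp, D[shuffle, shuffle])
})

test_that("embedding recovers a ladder ordering up to flip", {
  coh <- ladder_cohort(n_cells = 24, seed = 22)
  D <- cellDistanceMatrix(smoothProfiles(coh$molecules))
  ord <- embedOrder(D, n_runs = 25, seed = 5)
  tab <- orderingTable(ord)
  truth <- coh$stage[tab$cell]
  rho <- cor(tab$consensus_position, truth, method = "spearman")
  expect_gt(abs(rho), 0.9)

  # agrees with an independent seriation oracle on the same matrix
  ser <- seriation_ranks(D)
  rho_ser <- cor(rank(tab$consensus_position), ser, method = "spearman")
  expect_gt(abs(rho_ser), 0.85)

  # orientation anchor: early-decile fraction puts early S at 0
  layout <- genomeLayout(c("chr1", "chr2"), c(2e7, 2e7))
  ef <- earlyFraction(coh$molecules, gradientTiming(layout))
  ord2 <- embedOrder(D, n_runs = 25, seed = 5, early_fraction = ef)
  tab2 <- orderingTable(ord2)
  expect_lt(cor(tab2$consensus_position, ef[tab2$cell]), 0)
  expect_gt(cor(tab2$consensus_position, truth, method = "spearman"), 0.9)
})

test_that("duplicate cells receive identical consensus positions", {
  coh <- ladder_cohort(n_cells = 24, seed = 23)
  prof <- smoothProfiles(coh$molecules)
  # duplicate the 6th cell under a new name
  prof2 <- lapply(prof, function(P) {
    P2 <- rbind(P, P[12, , drop = FALSE])
    rownames(P2)[nrow(P2)] <- "twin"
    P2
  })
  D <- cellDistanceMatrix(prof2)
  expect_equal(D["twin", rownames(prof[[1]])[12]], 0, tolerance = 1e-9)
  ord <- embedOrder(D, n_runs = 25, seed = 11)
  tab <- orderingTable(ord)
  orig <- rownames(prof[[1]])[12]
  # identical profiles can differ by at most a rank step or two of
  # stochastic embedding jitter
  expect_lt(abs(tab[cell == "twin", consensus_position] -
                tab[cell == orig, consensus_position]), 0.1)
})

test_that("removing one cell barely perturbs the remaining ranks", {
  coh <- ladder_cohort(n_cells = 24, seed = 24)
  D <- cellDistanceMatrix(smoothProfiles(coh$molecules))
  ord_full <- orderingTable(embedOrder(D, n_runs = 25, seed = 3))
  drop <- rownames(D)[12]
  keep <- setdiff(rownames(D), drop)
  ord_sub <- orderingTable(embedOrder(D[keep, keep], n_runs = 25, seed = 3))
  full_sub <- ord_full[cell %in% keep][order(cell)]
  sub <- ord_sub[order(cell)]
  r_full <- rank(full_sub$consensus_position)
  r_sub <- rank(sub$consensus_position)
  shift <- min(max(abs(r_full - r_sub)),
               max(abs(r_full - (length(r_sub) + 1 - r_sub))))
  expect_lte(shift, 2)
})
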