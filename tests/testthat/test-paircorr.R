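test_that("pair distances equal brute force and respect the cutoff", {
  set.seed(61)
  layout <- genomeLayout(c("chr1", "chr2"), c(1e6, 1e6))
  d <- data.table::data.table(
    cell = "A", chrom = sample(c("chr1", "chr2"), 40, TRUE),
    pos = sample.int(9e5, 40), strand = "+")
  mol <- MoleculeTable(d, layout)
  got <- sort(pairDistances(mol, "A"))
  want <- sort(unlist(lapply(split(d$pos, d$chrom),
                             brute_force_pairs, maxdist = 4e5)))
  expect_identical(got, as.numeric(want))

  # binning examples
  m1 <- MoleculeTable(data.table::data.table(
    cell = "A", chrom = "chr1", pos = c(0, 10000), strand = "+"), layout)
  pc <- pairCorrelation(m1, "A")
  expect_equal(pc[count > 0, bin_start], 10000)
  m2 <- MoleculeTable(data.table::data.table(
    cell = "A", chrom = "chr1", pos = c(0, 500000), strand = "+"),
    genomeLayout("chr1", 1e6))
  expect_equal(sum(pairCorrelation(m2, "A")$count), 0)
})

test_that("pooling cells is not additive: cross-cell pairs appear", {
  layout <- genomeLayout("chr1", 1e6)
  a <- c(1000, 2000, 3000); b <- c(1500, 2500, 60000)
  two <- MoleculeTable(data.table::data.table(
    cell = rep(c("A", "B"), each = 3), chrom = "chr1", pos = c(a, b),
    strand = "+"), layout)
  pooled <- MoleculeTable(data.table::data.table(
    cell = "P", chrom = "chr1", pos = c(a, b), strand = "+"), layout)
  per_cell <- sort(c(pairDistances(two, "A"), pairDistances(two, "B")))
  pool <- sort(pairDistances(pooled, "P"))
  expect_equal(per_cell,
               sort(c(brute_force_pairs(a, 4e5), brute_force_pairs(b, 4e5))))
  expect_gt(length(pool), length(per_cell))   # extra cross-cell pairs
})

test_that("mixture EM recovers the interpulse distance within 2 kb", {
  set.seed(62)
  x <- mixture_draws(5000)
  fit <- fitMixture(x, seed = 1)
  expect_lt(abs(fit@normal_mean - 75000), 2000)
  expect_equal(sum(fit@weights), 1, tolerance = 1e-9)
  # constraints honored
  expect_gte(fit@weights[["exp"]], 0.01)
  expect_gt(fit@exp_mean, 1000)
  # likelihood non-decreasing
  ll <- fit@loglik
  expect_true(all(diff(ll) > -1e-7 * abs(ll[-length(ll)])))
  # invariance to distance order
  fit2 <- fitMixture(sample(x), seed = 1)
  expect_equal(fit2@normal_mean, fit@normal_mean, tolerance = 1e-6)
})

test_that("constraint projection lifts the exponential floor", {
  set.seed(63)
  # data with almost no short-scale component: pi_exp wants to vanish
  x <- c(runif(2000, 0, 4e5), rnorm(1000, 75000, 12000))
  x <- x[x > 0 & x <= 4e5]
  fit <- fitMixture(x, init = list(weights = c(0.49, 0.005, 0.49, 0.015) /
                                     sum(c(0.49, 0.005, 0.49, 0.015))))
  expect_gte(fit@weights[["exp"]], 0.01 - 1e-9)
  expect_gt(fit@exp_mean, 1000)
})

test_that("posteriors normalize and feed the speed conversion", {
  set.seed(64)
  x <- mixture_draws(3000)
  fit <- fitMixture(x, seed = 2)
  post <- mixturePosteriors(fit, c(1000, 50000, 75000, 200000))
  expect_equal(unname(rowSums(post)), rep(1, 4))
  # the interpulse peak location is dominated by the normal component
  expect_gt(post[3, "normal"], 0.5)

  expect_equal(estimateSpeed(fit, 75)$raw_speed, fit@normal_mean / 75000)
  expect_equal(
    estimateSpeed(new("MixtureFit",
      weights = c(uniform = 0.25, exp = 0.25, halfnormal = 0.25,
                  normal = 0.25),
      exp_mean = 5000, halfnormal_sd = 1e4, normal_mean = 105000,
      normal_sd = 1e4, upper = 4e5, loglik = 0, n_iter = 1L,
      converged = TRUE, n_obs = 100L), 105)$raw_speed, 1)
  expect_error(estimateSpeed(fit, 0), "delta_t")
})

test_that("bootstrap interval brackets the generating interpulse distance", {
  set.seed(65)
  x <- mixture_draws(4000)
  ci <- bootstrapCI(x, B = 40, seed = 3)
  expect_lt(ci$ci_low, 75000)
  expect_gt(ci$ci_high, 73000)
  expect_lte(ci$ci_low, ci$ci_high)
  expect_false(ci$widened)
  # deterministic under a fixed seed
  ci2 <- bootstrapCI(x, B = 40, seed = 3)
  expect_identical(ci$boot_means, ci2$boot_means)
})

test_that("single-pulse cells show no interpulse component, double-pulse do", {
  layout <- genomeLayout(c("chr1", "chr2"), c(3e7, 3e7))
  single <- simulateWholeCell(layout, n_forks = 120, scheme = "single",
                              sampling_rate = 0.25, background_rate = 0.002,
                              seed = 66)
  dbl <- simulateWholeCell(layout, n_forks = 120, scheme = pulseScheme(60),
                           sampling_rate = 0.25, background_rate = 0.002,
                           seed = 66)
  fs <- suppressWarnings(fitMixture(pairDistances(single$molecules, "cell1"),
                                    seed = 4))
  fd <- suppressWarnings(fitMixture(pairDistances(dbl$molecules, "cell1"),
                                    seed = 4))
  # the double-pulse cell has a tight interpulse peak at the true
  # distance; the single-pulse cell has no such maximum -- any mass the
  # normal component picks up is broad, diffuse background
  expect_lt(fd@normal_sd, 15000)
  expect_gt(fs@normal_sd, 2 * fd@normal_sd)
  expect_equal(fd@normal_mean, 75000, tolerance = 0.1)
  # and the single-pulse fit does not place a tight component anywhere
  # near a pulse-separation distance
  expect_false(abs(fs@normal_mean - 75000) < 10000 && fs@normal_sd < 15000)
})

test_that("bias surface corrects the length-weighting of fast forks", {
  surf <- buildBiasSurface(mu_grid = c(0.6, 1.0, 1.4, 1.8),
                           sigma_grid = c(0, 0.2, 0.4),
                           n_rep = 250, seed = 67)
  g <- surf@grid
  # fitted mean is monotone in mu at fixed sigma
  for (s in unique(g$sigma)) {
    sub <- g[sigma == s][order(mu)]
    expect_true(all(diff(sub$fitted_mean) > 0))
  }
  # sigma = 0: fitted ~ true (no weighting bias)
  sub0 <- g[sigma == 0]
  expect_equal(sub0$fitted_mean, sub0$mu, tolerance = 0.1)
  # broad sigma: pooled fit overshoots the true mean
  sub4 <- g[sigma == 0.4]
  expect_true(all(sub4$fitted_mean > sub4$mu))

  # correction inverts the bias and flags out-of-hull queries
  est <- data.table::data.table(raw_speed = sub4$fitted_mean,
                                normal_sd_speed = sub4$fitted_sd)
  corr <- applyCorrection(est, surf)
  expect_equal(corr$corrected_speed, sub4$mu, tolerance = 0.15)
  expect_true(all(corr$corrected_speed < corr$raw_speed))
  far <- suppressWarnings(applyCorrection(
    data.table::data.table(raw_speed = 10, normal_sd_speed = 0.1), surf))
  expect_true(far$extrapolated)
})
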