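# Shared fixtures, built in code.

tiny_layout <- function() genomeLayout(c("chr1", "chr2"), c(1e6, 5e5))

# a valid 3-cell molecule table on tiny_layout()
tiny_molecules <- function() {
  data.table::data.table(
    cell = rep(c("A", "B", "C"), times = c(4, 3, 2)),
    chrom = c("chr1", "chr1", "chr2", "chr1",
              "chr1", "chr2", "chr2",
              "chr1", "chr1"),
    pos = c(100, 200, 300, 900000,
            5000, 100, 499000,
            10, 60020),
    strand = "+",
    sample = "s1", labeling = "single", delta_t = NA_real_)
}

# clustered reads: k clusters of `per` reads (100-bp gaps) separated by
# ~1-Mb jumps, mimicking foreground tracks on a sparse background
clustered_positions <- function(k = 10, per = 8, gap = 100, jump = 1e6,
                                start = 1000) {
  starts <- start + (seq_len(k) - 1) * jump
  unlist(lapply(starts, function(s) s + (seq_len(per) - 1) * gap))
}

# ladder cohort used by ordering tests (cheap: 2 x 20 Mb genome)
ladder_cohort <- function(n_cells = 24, seed = 10, n_forks = 60,
                          sampling_rate = 0.2) {
  layout <- genomeLayout(c("chr1", "chr2"), c(2e7, 2e7))
  simulateCohort(layout, stages = seq(0.05, 0.95, length.out = n_cells),
                 timing = gradientTiming(layout), n_forks = n_forks,
                 scheme = "single", sampling_rate = sampling_rate,
                 background_rate = 0.001, seed = seed)
}

# distances drawn from the 4-component reference composition
mixture_draws <- function(n, normal_mean = 75000, normal_sd = 12000,
                          upper = 4e5) {
  x <- c(runif(0.3 * n, 0, upper),
         rexp(0.2 * n, 1 / 5000),
         abs(rnorm(0.2 * n, 0, 8000)),
         rnorm(0.3 * n, normal_mean, normal_sd))
  x[x > 0 & x <= upper]
}
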