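## Seeded simulators: (i) pulse-labeled replication tracks for comparing
## single- versus double-pulse speed estimators, (ii) per-fork pair
## correlation draws used to build the sampling-bias surface, and
## (iii) a whole-cell generator combining forks, background and genome
## placement for end-to-end runs.

#' Double-pulse labeling scheme
#'
#' A 15-min EdU pulse, a chase gap, and a second 15-min pulse.  The
#' center-to-center spacing is \code{delta_t = pulse_len + gap}; the
#' experiments use gaps of 30/60/90 min, i.e. delta_t of 45/75/105 min.
#'
#' @param gap chase time between pulses (min).
#' @param pulse_len pulse duration (min), default 15.
#' @return a list with \code{pulse_len}, \code{gap}, \code{delta_t}.
#' @examples
#' pulseScheme(60)$delta_t  # 75
#' @export
pulseScheme <- function(gap, pulse_len = 15) {
  if (gap <= 0 || pulse_len <= 0) stop("pulse_len and gap must be positive")
  structure(list(pulse_len = pulse_len, gap = gap,
                 delta_t = pulse_len + gap), class = "pulse_scheme")
}

## truncated-at-zero normal draws (rejection; exact for sigma = 0)
rtruncnorm0 <- function(n, mu, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(rep(mu, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mu, sigma)
    out <- c(out, x[x > 0])
  }
  out[seq_len(n)]
}

#' Simulate pulse-labeled replication tracks
#'
#' Generates independent replication tracks labeled with a single or a
#' double EdU pulse.  The number of reads per pulse is Poisson with the
#' given intensity and read positions are uniform within each labeled
#' window.  Window lengths equal \code{pulse_len * speed}, so the
#' ground-truth speed (default 1 kb/min) is encoded in physical units;
#' for a double pulse the second window starts \code{delta_t * speed}
#' after the first, giving a center-to-center separation of
#' \code{delta_t * speed} kb.
#'
#' @param n_tracks number of tracks (1,000 in the reference design).
#' @param read_intensity Poisson mean reads per pulse (> 0).
#' @param scheme \code{"single"} or a [pulseScheme()]; the bare string
#'   \code{"double"} uses a 15-min gap (windows at 0--1 and 2--3 pulse
#'   units).
#' @param speed ground-truth replication speed (kb/min), default 1.
#' @param seed integer seed.
#' @return list with \code{reads} (data.table: track, pulse, pos in bp),
#'   \code{truth} (per-track speed and window coordinates),
#'   \code{scheme}, \code{unit} (bp per pulse window).
#' @export
simulatePulseTracks <- function(n_tracks = 1000, read_intensity,
                                scheme = "single", speed = 1, seed = 1) {
  if (read_intensity <= 0) stop("read_intensity must be > 0")
  if (n_tracks < 1) stop("n_tracks must be >= 1")
  if (identical(scheme, "double")) scheme <- pulseScheme(gap = 15)
  double <- inherits(scheme, "pulse_scheme")
  pulse_len <- if (double) scheme$pulse_len else 15
  unit <- pulse_len * speed * 1000          # bp labeled per pulse
  set.seed(seed)
  n1 <- rpois(n_tracks, read_intensity)
  truth <- data.table::data.table(
    track = seq_len(n_tracks), speed = speed,
    p1_start = 0, p1_end = unit,
    p2_start = if (double) scheme$delta_t * speed * 1000 else NA_real_,
    p2_end = if (double) scheme$delta_t * speed * 1000 + unit else NA_real_)
  reads <- data.table::data.table(
    track = rep(seq_len(n_tracks), n1), pulse = 1L,
    pos = runif(sum(n1), 0, unit))
  if (double) {
    n2 <- rpois(n_tracks, read_intensity)
    reads <- rbind(reads, data.table::data.table(
      track = rep(seq_len(n_tracks), n2), pulse = 2L,
      pos = runif(sum(n2), truth$p2_start[1], truth$p2_end[1])))
  }
  data.table::setkey(reads, track, pulse, pos)
  list(reads = reads[], truth = truth, scheme = if (double) scheme else "single",
       unit = unit)
}

#' Track-level speed estimators on simulated pulses
#'
#' \code{doublePulseEstimate} averages all first-to-second-pulse pairwise
#' read distances and divides by \code{delta_t}; it is unbiased at any
#' sampling depth.  \code{singlePulseEstimate} uses the sampling-corrected
#' track width \code{w + w/(n-1)} divided by the pulse length and is the
#' width-based estimator whose accuracy degrades at low read counts.
#'
#' @param sim output of [simulatePulseTracks()].
#' @return speed estimate in kb/min.
#' @export
doublePulseEstimate <- function(sim) {
  if (!inherits(sim$scheme, "pulse_scheme"))
    stop("double-pulse estimate requires a double-pulse simulation")
  r <- sim$reads
  cross <- merge(r[pulse == 1L, .(track, p1 = pos)],
                 r[pulse == 2L, .(track, p2 = pos)],
                 by = "track", allow.cartesian = TRUE)
  if (nrow(cross) == 0) return(NA_real_)
  mean(abs(cross$p2 - cross$p1)) / 1000 / sim$scheme$delta_t
}

#' @rdname doublePulseEstimate
#' @param min_reads tracks with fewer reads in the first pulse are skipped.
#' @export
singlePulseEstimate <- function(sim, min_reads = 2) {
  r <- sim$reads[pulse == 1L]
  per <- r[, .(n = .N, w = max(pos) - min(pos)), by = track][n >= min_reads]
  if (nrow(per) == 0) return(NA_real_)
  pulse_len <- if (inherits(sim$scheme, "pulse_scheme")) sim$scheme$pulse_len else 15
  mean((per$w + per$w / (per$n - 1)) / 1000 / pulse_len)
}

#' Simulate per-fork pair-correlation draws
#'
#' Each replicate is one double-pulse-labeled fork.  A per-fork speed
#' factor \code{s} is drawn from a normal distribution with mean
#' \code{mu} and sd \code{sigma}, truncated at zero.  In
#' \code{"equal"} intensity mode, candidate reads are uniform on the
#' fixed support \code{window} (kb) with a Poisson(\code{reads_mean})
#' count and are retained iff they fall in the labeled windows
#' \code{(-45 s, -30 s)} or \code{(30 s, 45 s)} -- constant read density
#' per kb, so faster forks retain proportionally more reads (the
#' length-weighting that biases pooled fits).  In \code{"unequal"} mode
#' the support itself is scaled by \code{s} before placement, so every
#' fork retains the same expected read count.
#'
#' At \code{s = 1} the two retained windows are centered at -37.5 and
#' +37.5 kb: a 75-kb interpulse separation, i.e. 1 kb/min at
#' \code{delta_t} = 75 min.
#'
#' @param mu,sigma mean and sd of the truncated-normal speed factor.
#' @param n_rep number of forks (2,000 in the reference design).
#' @param reads_mean Poisson mean of candidate reads per fork (80).
#' @param window support of candidate read placement in kb,
#'   default c(-200, 200).
#' @param mode \code{"equal"} or \code{"unequal"} sampling intensity.
#' @param seed integer seed.
#' @return list with \code{reads} (data.table: rep, pos in kb),
#'   \code{truth} (rep, s), and the call parameters.
#' @export
simulatePairCorrCell <- function(mu, sigma, n_rep = 2000, reads_mean = 80,
                                 window = c(-200, 200),
                                 mode = c("equal", "unequal"), seed = 1) {
  mode <- match.arg(mode)
  if (sigma < 0) stop("sigma must be >= 0")
  if (n_rep < 1) stop("n_rep must be >= 1")
  set.seed(seed)
  s <- rtruncnorm0(n_rep, mu, sigma)
  m <- rpois(n_rep, reads_mean)
  rep_id <- rep(seq_len(n_rep), m)
  s_read <- s[rep_id]
  lo <- window[1]; hi <- window[2]
  r <- if (mode == "equal") runif(length(rep_id), lo, hi)
       else runif(length(rep_id), lo * s_read, hi * s_read)
  keep <- (r > -45 * s_read & r < -30 * s_read) |
          (r > 30 * s_read & r < 45 * s_read)
  list(reads = data.table::data.table(rep = rep_id[keep], pos = r[keep]),
       truth = data.table::data.table(rep = seq_len(n_rep), s = s),
       mu = mu, sigma = sigma, mode = mode)
}

#' Pooled within-fork pairwise distances of a pair-correlation simulation
#'
#' @param sim output of [simulatePairCorrCell()].
#' @return numeric vector of pairwise distances in bp (pooled over
#'   forks; no cross-fork pairs).
#' @export
pairCorrSimDistances <- function(sim) {
  r <- sim$reads
  out <- r[, if (.N >= 2) .(d = as.vector(stats::dist(pos))), by = rep]
  if (nrow(out) == 0) return(numeric(0))
  out$d * 1000
}

#' Simulate a whole labeled cell on a genome
#'
#' Places bidirectional replication origins on the genome (two divergent
#' forks per origin), draws per-fork speeds from a truncated normal,
#' lays down the pulse-labeled windows each fork traverses, and samples
#' reads uniformly within the windows at a density controlled by
#' \code{sampling_rate} (expected fraction of ~250-bp restriction
#' fragments recovered).  Uniform background reads are added at
#' \code{background_rate}.  When a replication-timing function and a
#' cell \code{stage} are supplied, origins are placed preferentially
#' where the timing value matches the stage, giving cohorts an S-phase
#' structure that ordering can recover.
#'
#' @param layout a Seqinfo ([genomeLayout()]).
#' @param n_forks number of forks (>= 1); origins = ceiling(n_forks/2).
#' @param speed_mu,speed_sigma truncated-normal fork speed (kb/min).
#' @param scheme \code{"single"} or a [pulseScheme()].
#' @param sampling_rate expected recovered fraction of labeled 250-bp
#'   sites, in (0, 1].
#' @param background_rate expected background reads per 250-bp site
#'   genome-wide, in [0, 1].
#' @param stage optional S-phase stage in [0, 1] used with
#'   \code{timing}.
#' @param timing optional function(chrom, pos) returning a replication
#'   timing value in [0, 1] (0 = earliest).
#' @param timing_bw kernel width on the timing axis for origin
#'   weighting.
#' @param fire_age_max maximum age of an origin at the first pulse
#'   (min); each origin fired uniformly 0..fire_age_max minutes before
#'   labeling, so its two forks are separated by the unlabeled DNA
#'   replicated pre-pulse.  Default 60.
#' @param site_spacing restriction-site spacing (bp), default 250.
#' @param cell_id,sample_id identifiers for the output table.
#' @param seed integer seed.
#' @return list with \code{molecules} (a \linkS4class{MoleculeTable}),
#'   \code{truth$forks} (per-fork origin, direction, speed, window
#'   coordinates) and \code{truth$reads} (per-read fork/pulse source;
#'   fork 0 = background).
#' @export
simulateWholeCell <- function(layout, n_forks, speed_mu = 1,
                              speed_sigma = 0.1, scheme = "single",
                              sampling_rate = 0.3, background_rate = 0,
                              stage = NULL, timing = NULL,
                              timing_bw = 0.08, fire_age_max = 60,
                              site_spacing = 250,
                              cell_id = "cell1", sample_id = "sim",
                              seed = 1) {
  if (n_forks < 1) stop("n_forks must be >= 1")
  if (sampling_rate <= 0 || sampling_rate > 1)
    stop("sampling_rate must be in (0, 1]")
  if (background_rate < 0 || background_rate > 1)
    stop("background_rate must be in [0, 1]")
  double <- inherits(scheme, "pulse_scheme")
  if (identical(scheme, "double")) { scheme <- pulseScheme(60); double <- TRUE }
  pulse_len <- if (double) scheme$pulse_len else 15
  span_min <- if (double) scheme$delta_t + pulse_len else pulse_len
  len <- GenomeInfoDb::seqlengths(layout)
  genome <- sum(as.numeric(len))
  if (n_forks * span_min * speed_mu * 1000 > 0.8 * genome)
    stop("n_forks exceeds genome capacity at this track length")
  set.seed(seed)
  n_origins <- ceiling(n_forks / 2)
  ## candidate origin positions, optionally weighted by timing match
  n_cand <- if (is.null(timing)) n_origins else max(20L * n_origins, 2000L)
  cand_chrom <- sample(names(len), n_cand, replace = TRUE,
                       prob = as.numeric(len) / genome)
  cand_pos <- floor(runif(n_cand) * len[cand_chrom])
  if (!is.null(timing)) {
    if (is.null(stage)) stop("stage is required when timing is supplied")
    tau <- timing(cand_chrom, cand_pos)
    w <- exp(-(tau - stage)^2 / (2 * timing_bw^2))
    if (sum(w) == 0) w <- rep(1, n_cand)
    idx <- sample.int(n_cand, n_origins, replace = FALSE, prob = w)
  } else idx <- seq_len(n_origins)
  ori <- data.table::data.table(chrom = cand_chrom[idx], origin = cand_pos[idx])
  forks <- ori[rep(seq_len(n_origins), each = 2)]
  forks[, dir := rep(c(-1, 1), n_origins)]
  forks <- forks[seq_len(n_forks)]
  forks[, fork := .I]
  forks[, speed := rtruncnorm0(.N, speed_mu, speed_sigma)]
  ## both forks of an origin share its firing age
  age <- runif(n_origins, 0, fire_age_max)
  forks[, age := age[ceiling(.I / 2)]]
  ## pulse windows along the direction of travel (bp), offset by the
  ## pre-pulse travel age * speed
  forks[, front := origin + dir * speed * age * 1000]
  forks[, `:=`(w1_a = front, w1_b = front + dir * speed * pulse_len * 1000)]
  if (double) {
    forks[, `:=`(w2_a = front + dir * speed * scheme$delta_t * 1000,
                 w2_b = front + dir * speed * (scheme$delta_t + pulse_len) * 1000)]
  } else forks[, `:=`(w2_a = NA_real_, w2_b = NA_real_)]

  draw_window <- function(a, b, chrom, fork, pulse) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    n <- rpois(length(lo), (hi - lo) / site_spacing * sampling_rate)
    i <- rep(seq_along(lo), n)
    pos <- floor(runif(sum(n), lo[i], hi[i]))
    data.table::data.table(chrom = chrom[i], pos = pos,
                           fork = fork[i], pulse = pulse)
  }
  reads <- draw_window(forks$w1_a, forks$w1_b, forks$chrom, forks$fork, 1L)
  if (double)
    reads <- rbind(reads, draw_window(forks$w2_a, forks$w2_b, forks$chrom,
                                      forks$fork, 2L))
  if (background_rate > 0) {
    nb <- rpois(1, genome / site_spacing * background_rate)
    bchrom <- sample(names(len), nb, replace = TRUE,
                     prob = as.numeric(len) / genome)
    reads <- rbind(reads, data.table::data.table(
      chrom = bchrom, pos = floor(runif(nb) * len[bchrom]),
      fork = 0L, pulse = 0L))
  }
  reads <- reads[pos >= 0 & pos < len[chrom]]
  ## unique genomic positions; first source wins on collision
  reads <- unique(reads, by = c("chrom", "pos"))
  mol <- MoleculeTable(
    data.table::data.table(cell = cell_id, chrom = reads$chrom,
                           pos = reads$pos, strand = "+",
                           sample = sample_id,
                           labeling = if (double) "double" else "single",
                           delta_t = if (double) scheme$delta_t else NA_real_),
    layout)
  list(molecules = mol,
       truth = list(forks = forks[], reads = reads[]),
       scheme = if (double) scheme else "single", seed = seed)
}

#' Simulate a cohort of staged cells
#'
#' Runs [simulateWholeCell()] once per requested stage (distinct
#' sub-seeds derived from \code{seed}) and combines the results.
#'
#' @param stages numeric vector of S-phase stages in [0, 1]; one cell
#'   per entry.
#' @inheritParams simulateWholeCell
#' @param ... further arguments to [simulateWholeCell()].
#' @return list with \code{molecules} (combined MoleculeTable),
#'   \code{stage} (named by cell), \code{truth} (per-cell list).
#' @export
simulateCohort <- function(layout, stages, timing, seed = 1, ...) {
  cells_l <- lapply(seq_along(stages), function(i)
    simulateWholeCell(layout, stage = stages[i], timing = timing,
                      cell_id = sprintf("cell%03d", i),
                      seed = seed + i, ...))
  tabs <- lapply(cells_l, function(x) x$molecules@data)
  mol <- new("MoleculeTable", data = data.table::setkeyv(
    data.table::rbindlist(tabs), c("cell", "chrom", "pos")),
    layout = layout)
  validObject(mol)
  list(molecules = mol,
       stage = setNames(stages, sprintf("cell%03d", seq_along(stages))),
       truth = lapply(cells_l, `[[`, "truth"))
}

#' Monotone replication-timing profile for simulations
#'
#' Returns a timing function where position along each chromosome maps
#' linearly to replication timing (left end earliest).  A convenient
#' ground truth for ladder cohorts.
#'
#' @param layout a Seqinfo.
#' @return function(chrom, pos) -> timing in [0, 1].
#' @export
gradientTiming <- function(layout) {
  len <- GenomeInfoDb::seqlengths(layout)
  function(chrom, pos) pos / len[chrom]
}
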