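## Per-cell quality filters and foreground read selection.
##
## Cells are filtered on the average count per 100-kb bin (mode-specific
## lower/upper thresholds) and on dispersion relative to Poisson:
## genuine S-phase cells carry clumped replication-track signal and are
## over-dispersed, log(CV) > -0.5 * log(mean) + 0.1 (natural logs);
## cells whose coverage is Poisson-flat (ambient background, no tracks)
## fail the gate.
## Foreground reads are then selected per cell with a two-component
## exponential mixture on the distances between successive reads: the
## short-distance component captures reads laid down inside replication
## tracks, the long-distance one background.

.qc_thresholds <- list(single = c(lower = 0.37, upper = 2.72),
                       double = c(lower = 0.08, upper = 12.18))

#' Per-cell quality metrics and filter decisions
#'
#' Computes, per cell, the mean and coefficient of variation of the
#' 100-kb binned counts over the whole genome (zero bins included) and
#' applies the density and dispersion filters.  Density thresholds are
#' labeling-mode specific (single pulse: 0.37--2.72; double pulse:
#' 0.08--12.18 reads per 100-kb bin, both inclusive).  The dispersion
#' filter keeps a cell only when its binned coverage deviates from
#' Poisson behavior, \code{log(cv) > -0.5 * log(mean) + threshold}
#' (natural logarithms): replication tracks clump reads, so a
#' Poisson-flat pattern indicates background rather than S-phase
#' signal.
#'
#' @param x a MoleculeTable.
#' @param bin_size QC bin width (bp), default 100 kb.
#' @param thresholds named list with \code{single}/\code{double}
#'   two-element vectors (lower, upper) overriding the defaults.
#' @param dispersion_threshold intercept of the dispersion rule,
#'   default 0.1.
#' @return data.table (cell, labeling, mean_per_bin, cv, pass_density,
#'   pass_dispersion, pass).
#' @export
computeQC <- function(x, bin_size = 100000, thresholds = .qc_thresholds,
                      dispersion_threshold = 0.1) {
  stopifnot(is(x, "MoleculeTable"))
  b <- binCounts(x, bin_size)
  lab <- x@data[, .(labeling = labeling[1]), by = cell]
  m <- b[, .(mean_per_bin = mean(value),
             cv = {
               mu <- mean(value)
               if (sum(value > 0) < 2 || mu == 0) NA_real_ else sd(value) / mu
             },
             n_nonzero = sum(value > 0)), by = cell]
  m <- merge(m, lab, by = "cell")
  thr <- function(mode) thresholds[[mode]]
  m[, pass_density := mean_per_bin >= thr(labeling)[["lower"]] &
                      mean_per_bin <= thr(labeling)[["upper"]], by = labeling]
  if (any(is.na(m$cv)))
    warning(sum(is.na(m$cv)),
            " cell(s) with < 2 nonzero bins: CV undefined, dispersion filter failed")
  m[, pass_dispersion := !is.na(cv) & cv > 0 &
      log(cv) > -0.5 * log(mean_per_bin) + dispersion_threshold]
  m[, pass := pass_density & pass_dispersion]
  m[, n_nonzero := NULL]
  data.table::setkey(m, cell)
  m[]
}

#' Drop cells failing QC
#'
#' @param x a MoleculeTable.
#' @param qc output of [computeQC()]; computed when missing.
#' @return a MoleculeTable restricted to passing cells.
#' @export
applyQC <- function(x, qc = computeQC(x)) {
  keep <- qc$cell[qc$pass]
  new("MoleculeTable", data = x@data[cell %in% keep], layout = x@layout)
}

## two-component exponential mixture EM on nonnegative distances;
## component 1 is the smaller-mean (foreground) component
fitExpMixture <- function(d, max_iter = 200, tol = 1e-8) {
  d <- d[is.finite(d)]
  d <- pmax(d, 1e-9)
  med <- median(d)
  m1 <- mean(d[d <= med]); m2 <- mean(d[d > med])
  if (!is.finite(m2) || m2 <= m1) m2 <- m1 * 2
  pi1 <- 0.5
  ll_old <- -Inf; converged <- FALSE; ll <- NA_real_
  for (it in seq_len(max_iter)) {
    f1 <- pi1 * dexp(d, 1 / m1)
    f2 <- (1 - pi1) * dexp(d, 1 / m2)
    tot <- f1 + f2
    tot[tot == 0] <- .Machine$double.xmin
    r1 <- f1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE; break
    }
    ll_old <- ll
    pi1 <- mean(r1)
    pi1 <- min(max(pi1, 1e-6), 1 - 1e-6)
    m1 <- sum(r1 * d) / sum(r1)
    m2 <- sum((1 - r1) * d) / sum(1 - r1)
    if (!is.finite(m1) || m1 <= 0) m1 <- mean(d) / 2
    if (!is.finite(m2) || m2 <= 0) m2 <- mean(d) * 2
    if (m1 > m2) { tmp <- m1; m1 <- m2; m2 <- tmp; pi1 <- 1 - pi1 }
  }
  list(mean = c(m1, m2), pi = c(pi1, 1 - pi1), loglik = ll,
       converged = converged)
}

#' Posterior foreground probability of a distance under a fitted mixture
#' @noRd
expMixturePosterior <- function(d, fit) {
  f1 <- fit$pi[1] * dexp(pmax(d, 1e-9), 1 / fit$mean[1])
  f2 <- fit$pi[2] * dexp(pmax(d, 1e-9), 1 / fit$mean[2])
  tot <- f1 + f2
  tot[tot == 0] <- .Machine$double.xmin
  f1 / tot
}

#' Select foreground reads per cell
#'
#' Fits, per cell, a two-component exponential mixture on the distances
#' between successive reads (all chromosomes concatenated) and assigns
#' each read the posterior probability of the short-distance
#' (foreground) component evaluated at its distance to the first
#' neighbor -- the smaller of its two flanking gaps (chromosome ends use
#' the single available gap).  Reads with posterior > 0.5 are kept.
#'
#' @param x a MoleculeTable.
#' @param posterior_cutoff keep threshold, default 0.5.
#' @return data.table (cell, chrom, pos, strand, neighbor_dist,
#'   posterior, keep, em_flag); \code{em_flag} marks cells where the EM
#'   did not converge (all reads kept).
#' @export
selectForegroundReads <- function(x, posterior_cutoff = 0.5) {
  stopifnot(is(x, "MoleculeTable"))
  d <- data.table::copy(x@data)
  data.table::setorder(d, cell, chrom, pos)
  d[, gap_prev := pos - data.table::shift(pos), by = .(cell, chrom)]
  d[, gap_next := data.table::shift(pos, type = "lead") - pos, by = .(cell, chrom)]
  d[, neighbor_dist := pmin(gap_prev, gap_next, na.rm = TRUE)]
  out <- d[, {
    gaps <- gap_prev[!is.na(gap_prev)]
    if (length(gaps) < 2 || all(!is.finite(neighbor_dist))) {
      .(chrom = chrom, pos = pos, strand = strand,
        neighbor_dist = neighbor_dist, posterior = rep(1, .N),
        keep = rep(TRUE, .N), em_flag = rep(TRUE, .N))
    } else {
      fit <- fitExpMixture(gaps)
      post <- expMixturePosterior(neighbor_dist, fit)
      post[!is.finite(neighbor_dist)] <- 0
      flag <- !fit$converged
      .(chrom = chrom, pos = pos, strand = strand,
        neighbor_dist = neighbor_dist,
        posterior = if (flag) rep(1, .N) else post,
        keep = if (flag) rep(TRUE, .N) else post > posterior_cutoff,
        em_flag = rep(flag, .N))
    }
  }, by = cell]
  if (any(out$em_flag))
    warning("exponential mixture EM flagged for ",
            length(unique(out$cell[out$em_flag])),
            " cell(s); all their reads kept")
  out[]
}

#' Restrict a MoleculeTable to foreground reads
#'
#' @param x a MoleculeTable.
#' @param fg output of [selectForegroundReads()]; computed when missing.
#' @return a MoleculeTable containing kept reads only.
#' @export
filterForeground <- function(x, fg = selectForegroundReads(x)) {
  keep <- fg[keep == TRUE, .(cell, chrom, pos, strand)]
  d <- merge(x@data, keep, by = c("cell", "chrom", "pos", "strand"))
  data.table::setkey(d, cell, chrom, pos)
  new("MoleculeTable", data = d, layout = x@layout)
}
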