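## Hidden semi-Markov segmentation of per-cell inter-read distances into
## replication fork tracks, fork counting and width-based single-pulse
## speed.  Reads laid down by one replisome sit close together; the
## foreground state captures these short gaps, the background state the
## long gaps between forks and to spurious reads.

## discretised gamma sojourn log-pmf on durations 1..Dmax
.sojourn_logpmf <- function(shape, scale, Dmax) {
  d <- seq_len(Dmax)
  lp <- stats::dgamma(d, shape = shape, scale = scale, log = TRUE)
  lp - .logsumexp(lp)
}

.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

.gaps_by_chrom <- function(x, cell_id) {
  d <- x@data[cell == cell_id]
  data.table::setorder(d, chrom, pos)
  split_pos <- split(d$pos, d$chrom)
  gaps <- lapply(split_pos, function(p) if (length(p) >= 2) diff(p) else numeric(0))
  gaps[vapply(gaps, length, 1L) > 0]
}

#' Fit a two-state hidden semi-Markov model on inter-read distances
#'
#' EM fit of a two-state explicit-duration HSMM with exponential
#' emission distributions and a gamma sojourn distribution per state.
#' Each chromosome of the cell is one observation sequence.  The state
#' with the smaller emission mean is labeled foreground (replication
#' track).  Durations are measured in gap counts.  If the two emission
#' means collapse, the model falls back to a quantile-threshold
#' segmentation with a warning.
#'
#' @param gaps a list of numeric vectors (inter-read distances per
#'   chromosome, bp), or a \linkS4class{MoleculeTable} together with
#'   \code{cell}.
#' @param cell cell barcode when \code{gaps} is a MoleculeTable.
#' @param max_iter,tol EM control (default 200 iterations, relative
#'   log-likelihood tolerance 1e-6).
#' @param max_duration sojourn truncation in gap counts.
#' @param min_gaps minimum total gaps required (default 20).
#' @return an \linkS4class{HSMMModel}.
#' @export
fitHSMM <- function(gaps, cell = NULL, max_iter = 200, tol = 1e-6,
                    max_duration = 300L, min_gaps = 20) {
  if (is(gaps, "MoleculeTable")) {
    stopifnot(!is.null(cell))
    gaps <- .gaps_by_chrom(gaps, cell)
  }
  gaps <- gaps[vapply(gaps, length, 1L) > 0]
  allg <- unlist(gaps, use.names = FALSE)
  if (length(allg) < min_gaps)
    stop("need at least ", min_gaps, " inter-read distances")
  Dmax <- as.integer(min(max_duration, max(vapply(gaps, length, 1L))))

  m <- pmax(quantile(allg, c(0.1, 0.9), names = FALSE), 1)
  if (m[2] <= m[1]) m[2] <- m[1] * 2
  shape <- c(2, 2); scale <- c(2.5, 2.5)
  pi0 <- c(0.5, 0.5)
  ll_trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    logdur <- cbind(.sojourn_logpmf(shape[1], scale[1], Dmax),
                    .sojourn_logpmf(shape[2], scale[2], Dmax))
    stats_tot <- list(ll = 0, ew = c(0, 0), eg = c(0, 0),
                      dn = c(0, 0), ds = c(0, 0), ds2 = c(0, 0),
                      pin = c(0, 0))
    for (g in gaps) {
      logf <- cbind(dexp(g, 1 / m[1], log = TRUE),
                    dexp(g, 1 / m[2], log = TRUE))
      es <- .hsmm_estep(g, logf, logdur, log(pi0))
      stats_tot$ll <- stats_tot$ll + es$loglik
      stats_tot$ew <- stats_tot$ew + es$emis_wsum
      stats_tot$eg <- stats_tot$eg + es$emis_gsum
      stats_tot$dn <- stats_tot$dn + es$dur_n
      stats_tot$ds <- stats_tot$ds + es$dur_sum
      stats_tot$ds2 <- stats_tot$ds2 + es$dur_sum2
      stats_tot$pin <- stats_tot$pin + es$pi_new
    }
    ll_trace <- c(ll_trace, stats_tot$ll)
    if (iter > 1) {
      prev <- ll_trace[iter - 1]
      if (abs(stats_tot$ll - prev) <= tol * abs(prev)) { converged <- TRUE; break }
    }
    ## M-step
    m_new <- ifelse(stats_tot$eg > 0, stats_tot$ew / stats_tot$eg, m)
    m <- pmax(m_new, 1e-3)
    dmean <- ifelse(stats_tot$dn > 0, stats_tot$ds / stats_tot$dn, shape * scale)
    dvar <- pmax(ifelse(stats_tot$dn > 0,
                        stats_tot$ds2 / stats_tot$dn - dmean^2, 1), 1e-3)
    shape <- pmin(pmax(dmean^2 / dvar, 0.05), 500)
    scale <- pmax(dmean / shape, 1e-3)
    pi0 <- stats_tot$pin / sum(stats_tot$pin)
    pi0 <- pmin(pmax(pi0, 1e-4), 1 - 1e-4)
    pi0 <- pi0 / sum(pi0)
    if (m[1] > m[2]) {       # keep state 1 = foreground (small gaps)
      m <- rev(m); shape <- rev(shape); scale <- rev(scale); pi0 <- rev(pi0)
    }
  }
  if (m[2] / m[1] < 1.2) {
    warning("HSMM states collapsed; falling back to quantile-threshold segmentation")
    return(new("HSMMModel", emission_mean = m, sojourn_shape = shape,
               sojourn_scale = scale, init = pi0, loglik = ll_trace,
               converged = FALSE, fallback = TRUE, max_duration = Dmax))
  }
  new("HSMMModel", emission_mean = m, sojourn_shape = shape,
      sojourn_scale = scale, init = pi0, loglik = ll_trace,
      converged = converged, fallback = FALSE, max_duration = Dmax)
}

## decode one gap sequence -> integer states (1 fg, 2 bg) + fg posterior
.decode_gaps <- function(model, g) {
  if (model@fallback) {
    thr <- quantile(g, 0.25, names = FALSE)
    st <- ifelse(g <= thr, 1L, 2L)
    return(list(states = st, posterior = as.numeric(st == 1L)))
  }
  Dmax <- min(model@max_duration, length(g))
  logdur <- cbind(.sojourn_logpmf(model@sojourn_shape[1], model@sojourn_scale[1], Dmax),
                  .sojourn_logpmf(model@sojourn_shape[2], model@sojourn_scale[2], Dmax))
  logf <- cbind(dexp(g, 1 / model@emission_mean[1], log = TRUE),
                dexp(g, 1 / model@emission_mean[2], log = TRUE))
  st <- .hsmm_viterbi(logf, logdur, log(model@init))
  es <- .hsmm_estep(g, logf, logdur, log(model@init), want_gamma = TRUE)
  list(states = st, posterior = es$gamma[, 1])
}

#' Decode replication fork tracks with the Viterbi algorithm
#'
#' Runs Viterbi decoding of the fitted HSMM on each chromosome of a
#' cell.  Maximal runs of foreground-state gaps become tracks: the reads
#' flanking such a run belong to one track traveled by a single
#' polymerase.  The track width \code{w} is the genomic distance between
#' its first and last read; \code{corrected_width} applies the sampling
#' correction \code{w + w/(n - 1)} (NA for n < 2, which cannot occur for
#' decoded tracks as a track always spans at least one gap).
#'
#' @param model an \linkS4class{HSMMModel} from [fitHSMM()].
#' @param x a MoleculeTable.
#' @param cell cell barcode to decode.
#' @return a \code{GRanges} of tracks, sorted and disjoint per
#'   chromosome, with metadata columns \code{cell}, \code{n} (reads),
#'   \code{w}, \code{corrected_width} (bp) and \code{posterior} (mean
#'   foreground occupancy of the track's gaps).
#' @export
viterbiTracks <- function(model, x, cell) {
  stopifnot(is(model, "HSMMModel"), is(x, "MoleculeTable"))
  cid <- cell
  d <- x@data[x@data$cell == cid]
  data.table::setorder(d, chrom, pos)
  out <- list()
  for (ch in unique(d$chrom)) {
    p <- d$pos[d$chrom == ch]
    if (length(p) < 2) next
    g <- diff(p)
    dec <- .decode_gaps(model, g)
    st <- dec$states
    r <- rle(st == 1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    fg <- which(r$values)
    if (!length(fg)) next
    for (k in fg) {
      i0 <- starts[k]; i1 <- ends[k]         # gap indices
      first <- i0; last <- i1 + 1            # read indices
      n <- last - first + 1L
      w <- p[last] - p[first]
      out[[length(out) + 1]] <- data.table::data.table(
        chrom = ch, start = p[first], end = p[last], n = n, w = w,
        posterior = mean(dec$posterior[i0:i1]))
    }
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges(seqinfo = x@layout)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      cell = character(0), n = integer(0), w = numeric(0),
      corrected_width = numeric(0), posterior = numeric(0))
    return(gr)
  }
  tr <- data.table::rbindlist(out)
  gr <- GenomicRanges::GRanges(tr$chrom,
          IRanges::IRanges(start = tr$start + 1, end = pmax(tr$end, tr$start + 1)),
          seqinfo = x@layout)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cell = cid, n = tr$n, w = tr$w,
    corrected_width = correctWidth(tr$w, tr$n),
    posterior = tr$posterior)
  sort(gr)
}

#' Segment one cell end to end
#'
#' Convenience wrapper: extracts per-chromosome gaps, fits the HSMM and
#' decodes tracks.
#'
#' @inheritParams viterbiTracks
#' @param ... passed to [fitHSMM()].
#' @return a GRanges of tracks (see [viterbiTracks()]).
#' @export
segmentCell <- function(x, cell, ...) {
  model <- fitHSMM(x, cell = cell, ...)
  viterbiTracks(model, x, cell)
}

#' Sampling correction of a track width
#'
#' A track's observed width underestimates the traveled path because
#' reads sample the labeled stretch; analogous to estimating the range
#' of a uniform sample, the corrected width is \code{w + w/(n - 1)}.
#'
#' @param w observed width(s), bp (>= 0).
#' @param n read count(s) per track; n < 2 yields NA.
#' @return corrected width(s), bp.
#' @examples
#' correctWidth(10000, 2)  # 20000
#' correctWidth(8000, 5)   # 10000
#' @export
correctWidth <- function(w, n) {
  stopifnot(all(w >= 0, na.rm = TRUE))
  ifelse(n >= 2, w + w / (n - 1), NA_real_)
}

#' Width-based replication speed from single-pulse tracks
#'
#' Per track, speed = corrected width / pulse length; the per-cell
#' summary is the median over tracks with defined corrected width.
#'
#' @param tracks GRanges from [viterbiTracks()].
#' @param pulse_len pulse duration in minutes (default 15).
#' @return list with \code{per_track} (data.table: cell, chrom, n,
#'   corrected_width, speed in kb/min) and \code{per_cell} (data.table:
#'   cell, speed = median, n_tracks).
#' @export
singlePulseSpeed <- function(tracks, pulse_len = 15) {
  m <- S4Vectors::mcols(tracks)
  per <- data.table::data.table(
    cell = m$cell, chrom = as.character(GenomeInfoDb::seqnames(tracks)),
    n = m$n, corrected_width = m$corrected_width,
    speed = m$corrected_width / 1000 / pulse_len)
  per_cell <- per[!is.na(speed),
                  .(speed = median(speed), n_tracks = .N), by = cell]
  list(per_track = per[], per_cell = per_cell[])
}

#' Fork counts per cell and chromosome
#'
#' @param tracks GRanges from [viterbiTracks()] (one or more cells).
#' @param min_reads minimum reads for a countable fork (default 2);
#'   counts with >= 3 reads are reported alongside.
#' @return list with \code{summary} (cell, forks_total, forks_ge3),
#'   \code{per_chrom} (cell, chrom, forks) and \code{reads_per_fork}
#'   (cell, n).
#' @export
countForks <- function(tracks, min_reads = 2) {
  m <- S4Vectors::mcols(tracks)
  d <- data.table::data.table(
    cell = m$cell, chrom = as.character(GenomeInfoDb::seqnames(tracks)),
    n = m$n)
  d <- d[n >= min_reads]
  list(summary = d[, .(forks_total = .N, forks_ge3 = sum(n >= 3)), by = cell],
       per_chrom = d[, .(forks = .N), by = .(cell, chrom)],
       reads_per_fork = d[, .(cell, n)])
}

#' Detected forks versus read downsampling
#'
#' Subsamples each cell's unique reads to the requested fractions,
#' refits the HSMM and re-decodes tracks per fraction, and counts
#' detected forks -- the sensitivity analysis of fork detection.
#'
#' @param x a MoleculeTable.
#' @param fractions fractions of reads to retain, each in (0, 1].
#' @param min_reads countable-fork threshold (see [countForks()]).
#' @param seed integer seed for the subsampling.
#' @param ... passed to [fitHSMM()].
#' @return data.table (fraction, cell, forks, forks_ge3).
#' @export
downsampleAnalysis <- function(x, fractions, min_reads = 2, seed = 1, ...) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  set.seed(seed)
  out <- list()
  for (f in fractions) {
    d <- x@data[, .SD[sample(.N, max(2, floor(.N * f)))], by = cell]
    data.table::setkey(d, cell, chrom, pos)
    sub <- new("MoleculeTable", data = d, layout = x@layout)
    for (cid in cells(sub)) {
      tr <- tryCatch(segmentCell(sub, cid, ...), error = function(e) NULL)
      nf <- if (is.null(tr) || length(tr) == 0) c(0L, 0L)
            else {
              cnt <- countForks(tr, min_reads)$summary
              c(cnt$forks_total[1], cnt$forks_ge3[1])
            }
      out[[length(out) + 1]] <- data.table::data.table(
        fraction = f, cell = cid, forks = nf[1], forks_ge3 = nf[2])
    }
  }
  data.table::rbindlist(out)
}

#' Export tracks as BED6+
#'
#' Columns: chrom, start, end, cell, n, strand ('.'), corrected_width,
#' posterior.  Coordinates are BED-native (0-based half-open).
#'
#' @param tracks GRanges from [viterbiTracks()].
#' @param path output file.
#' @export
writeTracksBED <- function(tracks, path) {
  m <- S4Vectors::mcols(tracks)
  d <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(tracks)),
    start = GenomicRanges::start(tracks) - 1L,
    end = GenomicRanges::end(tracks),
    name = m$cell, score = m$n, strand = ".",
    corrected_width = m$corrected_width, posterior = m$posterior)
  data.table::fwrite(d, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
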