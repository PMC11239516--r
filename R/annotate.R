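## Annotation-conditioned analyses: replication-timing scores,
## initiation-zone correlation over S phase, expression transforms with
## gene-overlap priority, overlap-weighted speed densities, and z-scored
## bulk track comparison.

#' Replication timing score from early/late read counts
#'
#' \code{RT = (early - late) / (early + late)}, in [-1, 1]; bins with
#' no reads in either fraction are undefined (NA) and excluded
#' downstream.
#'
#' @param early,late nonnegative read counts (vectorized).
#' @return numeric score(s).
#' @examples
#' rtScore(10, 10)  # 0
#' rtScore(5, 0)    # 1
#' @export
rtScore <- function(early, late) {
  if (any(early < 0 | late < 0)) stop("counts must be nonnegative")
  tot <- early + late
  ifelse(tot == 0, NA_real_, (early - late) / tot)
}

#' Correlation of cumulative replication signal with an origin track
#'
#' Orders cells by S-phase progression, accumulates their binned reads
#' prefix by prefix, and computes per prefix the binwise Pearson
#' correlation with an origin (initiation-zone) signal on the same
#' bins.  Early prefixes of a cohort replicating out of genuine origins
#' correlate most strongly.
#'
#' @param x a MoleculeTable.
#' @param order an \linkS4class{OrderingResult}.
#' @param origin data.table (chrom, bin_start, value): origin signal on
#'   the same \code{bin_size} grid.
#' @param bin_size bin width (bp), default 100 kb.
#' @return data.table (prefix_frac, n_cells, pearson); correlation is
#'   NA where a prefix has zero variance.
#' @export
cumulativeOriginCorrelation <- function(x, order, origin,
                                        bin_size = 100000) {
  stopifnot(is(x, "MoleculeTable"), is(order, "OrderingResult"))
  tab <- orderingTable(order, kept_only = TRUE)
  tab <- tab[base::order(tab$consensus_position)]
  b <- binCounts(x, bin_size, cells = tab$cell)
  org <- data.table::as.data.table(origin)
  wide <- data.table::dcast(b, chrom + bin_start ~ cell, value.var = "value")
  m <- merge(wide, org[, .(chrom, bin_start, origin_value = value)],
             by = c("chrom", "bin_start"))
  if (nrow(m) == 0) stop("origin track shares no bins with the data")
  ov <- m$origin_value
  cum <- rep(0, nrow(m))
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cum <- cum + m[[tab$cell[i]]]
    r <- if (sd(cum) == 0 || sd(ov) == 0) NA_real_ else cor(cum, ov)
    out[[i]] <- data.table::data.table(
      prefix_frac = i / nrow(tab), n_cells = i, pearson = r)
  }
  data.table::rbindlist(out)
}

#' Transform gene expression counts and resolve overlaps
#'
#' Applies \code{round(log10(counts + 1))} per gene and resolves
#' overlapping gene intervals by giving the gene with the higher raw
#' count priority over the shared portion (ties: earlier interval start
#' wins).  The output intervals are disjoint.
#'
#' @param genes a GRanges with a \code{counts} metadata column
#'   (nonnegative integers) and optionally \code{gene} names.
#' @return a GRanges of disjoint intervals with columns \code{gene},
#'   \code{counts} and \code{transformed}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 500), c(1000, 1500)), counts = c(9, 999))
#' transformExpression(gr)
#' @export
transformExpression <- function(genes) {
  if (is.null(genes$counts) || any(genes$counts < 0))
    stop("genes need a nonnegative 'counts' column")
  if (is.null(genes$gene))
    genes$gene <- paste0("gene", seq_along(genes))
  pieces <- GenomicRanges::disjoin(genes)
  hits <- GenomicRanges::findOverlaps(pieces, genes)
  h <- data.table::data.table(
    piece = S4Vectors::queryHits(hits), gene = S4Vectors::subjectHits(hits),
    counts = genes$counts[S4Vectors::subjectHits(hits)],
    gstart = GenomicRanges::start(genes)[S4Vectors::subjectHits(hits)])
  data.table::setorder(h, piece, -counts, gstart)
  win <- h[, .SD[1], by = piece]
  out <- sort(pieces[win$piece])
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(out)),
    start = GenomicRanges::start(out), end = GenomicRanges::end(out),
    gene = genes$gene[win$gene], counts = win$counts)
  ## merge adjacent pieces won by the same gene back together
  dt[, grp := cumsum(!(gene == data.table::shift(gene, fill = "") &
                       chrom == data.table::shift(chrom, fill = "") &
                       start == data.table::shift(end, fill = -1) + 1))]
  dt <- dt[, .(chrom = chrom[1], start = start[1], end = end[.N],
               gene = gene[1], counts = counts[1]), by = grp]
  GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start, dt$end),
                         gene = dt$gene, counts = dt$counts,
                         transformed = round(log10(dt$counts + 1)))
}

#' Overlap-weighted replication speed densities inside/outside regions
#'
#' Each pairwise distance of a double-pulse cell defines a genomic span
#' between its two reads.  The span's fractional overlap with the
#' region set, multiplied by the mixture posterior of the speed
#' (normal) component at that distance, weights the implied speed
#' \code{distance / delta_t} in the inside density; the complement
#' fraction weights the outside density.  Densities are max-normalized.
#' Significance is assessed by resampling \code{n_resample} speeds from
#' each weighted distribution and a two-sided t-test.
#'
#' @param x a MoleculeTable (double-pulse).
#' @param fits named list of \linkS4class{MixtureFit} per cell (e.g.
#'   built during [estimateCellSpeeds()]); cells without a fit are
#'   skipped.
#' @param regions a GRanges region set (e.g. transcribed genes).
#' @param delta_t pulse spacing (min); from the table when NULL.
#' @param max_dist distance cutoff (bp).
#' @param n_resample resamples per density for the test (default
#'   10,000).
#' @param seed integer seed for the resampling test.
#' @return list with \code{density} (data.table: side, speed, density
#'   max-normalized), \code{weights} (per-distance table) and
#'   \code{test} (t-test p-value on resampled speeds; adjust across
#'   region classes with p.adjust(..., "bonferroni")).
#' @export
weightedSpeedByRegion <- function(x, fits, regions, delta_t = NULL,
                                  max_dist = 400000, n_resample = 10000,
                                  seed = 1) {
  stopifnot(is(x, "MoleculeTable"))
  rows <- list()
  for (cid in intersect(cells(x), names(fits))) {
    d <- x@data[cell == cid]
    dt_cell <- if (is.null(delta_t)) d$delta_t[1] else delta_t
    if (is.na(dt_cell)) stop("delta_t unknown for cell ", cid)
    data.table::setorder(d, chrom, pos)
    for (ch in unique(d$chrom)) {
      p <- d$pos[d$chrom == ch]
      if (length(p) < 2) next
      pr <- .pair_index_sorted(p, max_dist)
      if (!nrow(pr)) next
      rows[[length(rows) + 1]] <- data.table::data.table(
        cell = cid, chrom = ch, start = p[pr$i], end = p[pr$j],
        dist = p[pr$j] - p[pr$i], delta_t = dt_cell)
    }
  }
  if (!length(rows)) stop("no pairwise spans found")
  spans <- data.table::rbindlist(rows)
  spans <- spans[dist > 0]
  gr <- GenomicRanges::GRanges(spans$chrom,
          IRanges::IRanges(spans$start + 1, spans$end))
  ovl <- GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(regions),
                                     ignore.strand = TRUE)
  inter <- GenomicRanges::pintersect(
    gr[S4Vectors::queryHits(ovl)],
    GenomicRanges::reduce(regions)[S4Vectors::subjectHits(ovl)])
  ow <- data.table::data.table(idx = S4Vectors::queryHits(ovl),
                               w = IRanges::width(inter))
  ow <- ow[, .(w = sum(w)), by = idx]
  spans[, overlap_frac := 0]
  spans[ow$idx, overlap_frac := pmin(ow$w / dist, 1)]
  ## posterior of the speed component per distance, per cell
  spans[, post := {
    f <- fits[[cell[1]]]
    mixturePosteriors(f, dist)[, "normal"]
  }, by = cell]
  spans[, speed := dist / 1000 / delta_t]
  spans[, `:=`(w_in = overlap_frac * post, w_out = (1 - overlap_frac) * post)]
  dens_one <- function(sp, w) {
    if (sum(w) <= 0) return(NULL)
    dd <- density(sp, weights = w / sum(w), bw = stats::bw.nrd0(sp))
    data.table::data.table(speed = dd$x, density = dd$y / max(dd$y))
  }
  din <- dens_one(spans$speed, spans$w_in)
  dout <- dens_one(spans$speed, spans$w_out)
  if (is.null(din) || is.null(dout))
    warning("empty region class: one side has zero total weight")
  dens <- data.table::rbindlist(list(
    if (!is.null(din)) cbind(side = "inside", din),
    if (!is.null(dout)) cbind(side = "outside", dout)))
  test <- NULL
  if (!is.null(din) && !is.null(dout)) {
    set.seed(seed)
    s_in <- sample(spans$speed, n_resample, replace = TRUE,
                   prob = spans$w_in)
    s_out <- sample(spans$speed, n_resample, replace = TRUE,
                    prob = spans$w_out)
    test <- t.test(s_in, s_out)
  }
  list(density = dens, weights = spans[], test = test)
}

## index pairs (i < j) with pos[j] - pos[i] <= maxdist on sorted pos
.pair_index_sorted <- function(p, maxdist) {
  n <- length(p)
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n - 1)) {
    j <- i + 1
    while (j <= n && p[j] - p[i] <= maxdist) j <- j + 1
    if (j > i + 1) {
      jj <- c(jj, seq(i + 1, j - 1))
      ii <- c(ii, rep(i, j - 1 - i))
    }
  }
  data.table::data.table(i = ii, j = jj)
}

#' Z-scored bulk track comparison
#'
#' Z-scores two binned signals per sample and returns the tracks with
#' their Spearman rank correlation (the bulk replication-profile
#' comparison at 50-kb resolution).
#'
#' @param a,b data.tables (chrom, bin_start, value) on identical bins.
#' @return list with \code{tracks} (chrom, bin_start, z_a, z_b) and
#'   \code{spearman}.
#' @export
zscoreBulkTracks <- function(a, b) {
  a <- data.table::as.data.table(a); b <- data.table::as.data.table(b)
  m <- merge(a[, .(chrom, bin_start, va = value)],
             b[, .(chrom, bin_start, vb = value)],
             by = c("chrom", "bin_start"))
  if (nrow(m) == 0) stop("no shared bins")
  if (sd(m$va) == 0 || sd(m$vb) == 0) stop("zero-variance sample")
  m[, `:=`(z_a = (va - mean(va)) / sd(va), z_b = (vb - mean(vb)) / sd(vb))]
  list(tracks = m[, .(chrom, bin_start, z_a, z_b)],
       spearman = cor(m$z_a, m$z_b, method = "spearman"))
}
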