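## Readers/writers and binning.  Coordinates are 0-based, half-open
## internally; BED interchange is native; 1-based inputs are converted
## on load via `one_based = TRUE`.

#' Construct a genome layout
#'
#' A genome layout is a \code{\link[GenomeInfoDb]{Seqinfo}}: unique
#' chromosome names with positive lengths.
#'
#' @param chrom character vector of chromosome names.
#' @param length integer vector of chromosome lengths (bp).
#' @return a Seqinfo.
#' @examples
#' genomeLayout(c("chr1", "chr2"), c(2e7, 1e7))
#' @export
genomeLayout <- function(chrom, length) {
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  GenomeInfoDb::Seqinfo(seqnames = as.character(chrom),
                        seqlengths = as.integer(length))
}

#' Read a two-column chrom.sizes file
#'
#' @param path path to a whitespace-delimited file with chromosome name
#'   and length columns (UCSC chrom.sizes convention).
#' @return a Seqinfo.
#' @export
readChromSizes <- function(path) {
  d <- data.table::fread(path, header = FALSE, col.names = c("chrom", "length"))
  genomeLayout(d$chrom, d$length)
}

#' Construct a MoleculeTable from a data.frame
#'
#' Validates and normalizes a long-format molecule table.  Rows on
#' chromosomes absent from the layout are dropped with a warning;
#' duplicate (cell, chrom, pos, strand) rows are collapsed to one.
#'
#' @param data data.frame/data.table with columns \code{cell},
#'   \code{chrom}, \code{pos}, \code{strand}; optional \code{sample},
#'   \code{labeling} (default \code{"single"}), \code{delta_t} (min,
#'   \code{NA} for single-pulse).
#' @param layout a Seqinfo (see [genomeLayout()]).
#' @param one_based are input positions 1-based?  Converted to the
#'   internal 0-based convention on load.
#' @return a \linkS4class{MoleculeTable}.
#' @export
MoleculeTable <- function(data, layout, one_based = FALSE) {
  d <- data.table::as.data.table(data)
  req <- c("cell", "chrom", "pos", "strand")
  if (!all(req %in% names(d)))
    stop("missing required column(s): ", paste(setdiff(req, names(d)), collapse = ", "))
  if (!"sample" %in% names(d)) d[, sample := "sample1"]
  if (!"labeling" %in% names(d)) d[, labeling := "single"]
  if (!"delta_t" %in% names(d)) d[, delta_t := NA_real_]
  d <- d[, .(cell = as.character(cell), chrom = as.character(chrom),
             pos = as.numeric(pos), strand = as.character(strand),
             sample = as.character(sample), labeling = as.character(labeling),
             delta_t = as.numeric(delta_t))]
  if (one_based) d[, pos := pos - 1]
  if (any(d$pos < 0)) stop("negative positions after coordinate conversion")
  known <- GenomeInfoDb::seqnames(layout)
  n_bad <- sum(!d$chrom %in% known)
  if (n_bad > 0) {
    warning(n_bad, " row(s) on chromosomes absent from the layout were dropped")
    d <- d[chrom %in% known]
  }
  n_dup <- sum(duplicated(d, by = c("cell", "chrom", "pos", "strand")))
  if (n_dup > 0)
    d <- unique(d, by = c("cell", "chrom", "pos", "strand"))
  data.table::setkey(d, cell, chrom, pos)
  new("MoleculeTable", data = d, layout = layout)
}

#' Read a molecule table from delimited text
#'
#' @param path TSV/CSV file with columns \code{cell}, \code{chrom},
#'   \code{pos}, \code{strand} (and optionally \code{sample},
#'   \code{labeling}, \code{delta_t}).
#' @inheritParams MoleculeTable
#' @return a \linkS4class{MoleculeTable}.
#' @export
readMoleculeTable <- function(path, layout, one_based = FALSE) {
  d <- data.table::fread(path)
  MoleculeTable(d, layout, one_based = one_based)
}

#' Write a molecule table as TSV
#'
#' Round-trips through [readMoleculeTable()] losslessly.
#'
#' @param x a MoleculeTable.
#' @param path output file.
#' @export
writeMoleculeTable <- function(x, path) {
  stopifnot(is(x, "MoleculeTable"))
  data.table::fwrite(x@data, path, sep = "\t")
  invisible(path)
}

#' Read labeled intervals (BED3+label) as a RegionSet
#'
#' @param path BED file; columns chrom, start, end and optionally name
#'   (label) and score.  BED is 0-based half-open, matching the internal
#'   convention.
#' @param layout optional Seqinfo to attach.
#' @return a \code{GRanges} with metadata columns \code{label} and,
#'   when present, \code{score}.
#' @export
readRegions <- function(path, layout = NULL) {
  d <- data.table::fread(path, header = FALSE)
  if (ncol(d) < 3) stop("BED input needs at least 3 columns")
  names(d)[1:3] <- c("chrom", "start", "end")
  if (any(d$start >= d$end)) stop("intervals must satisfy start < end")
  gr <- GenomicRanges::GRanges(d$chrom,
          IRanges::IRanges(start = d$start + 1, end = d$end))
  if (ncol(d) >= 4) S4Vectors::mcols(gr)$label <- as.character(d[[4]])
  if (ncol(d) >= 5) S4Vectors::mcols(gr)$score <- as.numeric(d[[5]])
  if (!is.null(layout)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
    GenomeInfoDb::seqinfo(gr) <- layout
  }
  gr
}

#' Bin read counts per cell
#'
#' Fixed-width binning with bin index \code{floor(pos / bin_size)}; each
#' read falls in exactly one bin, so per-cell totals are conserved.
#' Empty bins are present with value 0 for every cell, tiling
#' \code{[0, chrom length)}.
#'
#' @param x a MoleculeTable.
#' @param bin_size bin width in bp (> 0); 100 kb is used for QC, 50 kb
#'   for heatmaps and bulk comparisons, 10 kb for replication timing.
#' @param cells optional subset of cell barcodes.
#' @return a data.table (cell, chrom, bin_start, value) with attribute
#'   \code{bin_size}.
#' @export
binCounts <- function(x, bin_size, cells = NULL) {
  stopifnot(is(x, "MoleculeTable"))
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0)
    stop("bin_size must be a single positive number")
  d <- x@data
  if (!is.null(cells)) d <- d[cell %in% cells]
  ids <- if (is.null(cells)) unique(d$cell) else cells
  len <- GenomeInfoDb::seqlengths(x@layout)
  grid <- data.table::rbindlist(lapply(GenomeInfoDb::seqnames(x@layout),
    function(ch) data.table::data.table(
      chrom = ch,
      bin_start = (seq_len(ceiling(len[[ch]] / bin_size)) - 1) * bin_size)))
  full <- data.table::CJ(cell = ids, idx = seq_len(nrow(grid)))
  full <- cbind(full[, .(cell)], grid[full$idx])
  cnt <- d[, .(value = as.numeric(.N)),
           by = .(cell, chrom, bin_start = floor(pos / bin_size) * bin_size)]
  out <- merge(full, cnt, by = c("cell", "chrom", "bin_start"), all.x = TRUE)
  out[is.na(value), value := 0]
  data.table::setkey(out, cell, chrom, bin_start)
  data.table::setattr(out, "bin_size", bin_size)
  out[]
}

#' Max-normalized heatmap matrix of replication signal
#'
#' Bins each ordered cell's reads (default 50 kb) and divides by the
#' maximum bin value observed for that cell on the window's chromosome,
#' giving values in [0, 1] suitable for track heatmaps over S phase.
#' All-zero rows stay zero.
#'
#' @param x a MoleculeTable.
#' @param order an \linkS4class{OrderingResult}; rows are emitted in
#'   increasing S-phase progression (kept cells only).
#' @param window a length-1 \code{GRanges} on a single chromosome.
#' @param bin_size bin width in bp (default 50 kb).
#' @return numeric matrix, one row per ordered cell, one column per bin
#'   of the window; rownames are cell barcodes, values in [0, 1].
#' @export
maxNormalizeHeatmap <- function(x, order, window, bin_size = 50000) {
  stopifnot(is(x, "MoleculeTable"), is(order, "OrderingResult"))
  if (length(window) != 1 || IRanges::width(window) < 1)
    stop("window must be a single non-empty range")
  ch <- as.character(GenomeInfoDb::seqnames(window))
  tab <- orderingTable(order, kept_only = TRUE)
  tab <- tab[base::order(tab$consensus_position)]
  b <- binCounts(x, bin_size, cells = tab$cell)
  b <- b[chrom == ch]
  ## per-cell max over the whole chromosome (the normalization reference)
  b[, cellmax := max(value), by = cell]
  b[, norm := ifelse(cellmax > 0, value / cellmax, 0)]
  w0 <- GenomicRanges::start(window) - 1
  w1 <- GenomicRanges::end(window)
  b <- b[bin_start >= floor(w0 / bin_size) * bin_size & bin_start < w1]
  if (nrow(b) == 0) stop("window overlaps no bins")
  wide <- data.table::dcast(b, cell ~ bin_start, value.var = "norm")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$cell
  m[match(tab$cell, rownames(m)), , drop = FALSE]
}

#' Export a binned signal as bedGraph
#'
#' @param binned output of [binCounts()] (a single cell's rows, or any
#'   (chrom, bin_start, value) table).
#' @param path output file.
#' @param bin_size bin width; defaults to the table's
#'   \code{bin_size} attribute.
#' @export
writeBedGraph <- function(binned, path, bin_size = attr(binned, "bin_size")) {
  if (is.null(bin_size)) stop("bin_size unknown")
  d <- data.table::as.data.table(binned)
  out <- d[, .(chrom, start = as.integer(bin_start),
               end = as.integer(bin_start + bin_size), value)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
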