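#' Extract the molecule table
#'
#' Returns a copy of the underlying \code{data.table} of a
#' \linkS4class{MoleculeTable} (columns \code{cell}, \code{chrom},
#' \code{pos}, \code{strand}, \code{sample}, \code{labeling},
#' \code{delta_t}).
#'
#' @param x a MoleculeTable.
#' @return a data.table.
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))

#' @rdname molecules
#' @export
setMethod("molecules", "MoleculeTable", function(x) data.table::copy(x@data))

#' Cell barcodes present in an object
#'
#' @param x a MoleculeTable or OrderingResult.
#' @return character vector of cell identifiers.
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @rdname cells
#' @export
setMethod("cells", "MoleculeTable", function(x) unique(x@data$cell))

#' @rdname cells
#' @export
setMethod("cells", "OrderingResult", function(x) x@table$cell)

#' Number of molecules per object or per cell
#'
#' @param x a MoleculeTable.
#' @param per_cell return a named vector of counts per cell?
#' @return integer count(s).
#' @export
setGeneric("nReads", function(x, per_cell = FALSE) standardGeneric("nReads"))

#' @rdname nReads
#' @export
setMethod("nReads", "MoleculeTable", function(x, per_cell = FALSE) {
  if (!per_cell) return(nrow(x@data))
  cnt <- x@data[, .N, by = cell]
  setNames(cnt$N, cnt$cell)
})

#' @importFrom GenomeInfoDb seqinfo
#' @export
setMethod("seqinfo", "MoleculeTable", function(x) x@layout)

#' Ordering table accessor
#'
#' Per-cell consensus S-phase positions with kept/discarded status.
#'
#' @param x an OrderingResult.
#' @param kept_only drop cells that could not be placed definitively?
#' @return a data.table (cell, consensus_position, kept,
#'   n_successful_runs, cluster_size).
#' @export
setGeneric("orderingTable", function(x, kept_only = FALSE)
  standardGeneric("orderingTable"))

#' @rdname orderingTable
#' @export
setMethod("orderingTable", "OrderingResult", function(x, kept_only = FALSE) {
  tab <- data.table::copy(x@table)
  if (kept_only) tab <- tab[tab$kept]
  tab
})

#' Mixture-fit parameter accessors
#'
#' \code{interpulseDistance} returns the fitted normal-component mean
#' (bp), the average fork travel between the two EdU pulses;
#' \code{mixtureWeights} the component weights.
#'
#' @param x a MixtureFit.
#' @export
setGeneric("interpulseDistance", function(x)
  standardGeneric("interpulseDistance"))

#' @rdname interpulseDistance
#' @export
setMethod("interpulseDistance", "MixtureFit", function(x) x@normal_mean)

#' @rdname interpulseDistance
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))

#' @rdname interpulseDistance
#' @export
setMethod("mixtureWeights", "MixtureFit", function(x) x@weights)
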