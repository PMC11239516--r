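## Central S4 containers.  The genome layout is a plain
## GenomeInfoDb::Seqinfo; intervals are GRanges; per-cell tabular data
## live in data.tables inside the containers below.

setOldClass("data.table")

#' MoleculeTable: deduplicated per-cell genomic read positions
#'
#' The universal input of the package: one row per unique molecule with
#' cell barcode, chromosome, genomic position of the NlaIII site (0-based
#' bp), strand, sample identifier, labeling mode (\code{"single"} or
#' \code{"double"}) and, for double-pulse samples, the center-to-center
#' pulse spacing \code{delta_t} in minutes.  Rows are unique on
#' (cell, chrom, pos, strand); every chromosome must be present in the
#' genome layout.  Strand is carried but ignored by all downstream
#' computations.
#'
#' @slot data a \code{data.table} with columns \code{cell}, \code{chrom},
#'   \code{pos}, \code{strand}, \code{sample}, \code{labeling},
#'   \code{delta_t}.
#' @slot layout a \code{\link[GenomeInfoDb]{Seqinfo}} giving chromosome
#'   names and lengths.
#'
#' @seealso [readMoleculeTable()], [binCounts()], [simulateWholeCell()]
#' @export
setClass("MoleculeTable",
  slots = c(data = "data.table", layout = "Seqinfo"))

.molcols <- c("cell", "chrom", "pos", "strand", "sample", "labeling", "delta_t")

setValidity("MoleculeTable", function(object) {
  d <- object@data
  msg <- character()
  if (!all(.molcols %in% names(d)))
    msg <- c(msg, paste("missing columns:",
                        paste(setdiff(.molcols, names(d)), collapse = ", ")))
  else {
    if (nrow(d) && any(d$pos < 0)) msg <- c(msg, "pos must be >= 0")
    if (nrow(d) && !all(d$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    if (nrow(d) && !all(d$labeling %in% c("single", "double")))
      msg <- c(msg, "labeling must be 'single' or 'double'")
    bad <- setdiff(unique(d$chrom), GenomeInfoDb::seqnames(object@layout))
    if (length(bad))
      msg <- c(msg, paste("chromosomes absent from layout:",
                          paste(bad, collapse = ", ")))
    if (anyDuplicated(d, by = c("cell", "chrom", "pos", "strand")))
      msg <- c(msg, "rows must be unique on (cell, chrom, pos, strand)")
    len <- GenomeInfoDb::seqlengths(object@layout)[d$chrom]
    if (nrow(d) && any(d$pos >= len))
      msg <- c(msg, "pos must be < chromosome length")
  }
  if (length(msg)) msg else TRUE
})

#' HSMMModel: two-state hidden semi-Markov segmentation model
#'
#' Fitted per cell on the distances between neighboring reads, with
#' exponential emission distributions and a gamma sojourn (dwell-time)
#' distribution per state.  The state with the smaller emission mean is
#' the foreground (replication track) state.
#'
#' @slot emission_mean numeric(2), exponential emission means (bp) for
#'   foreground and background.
#' @slot sojourn_shape,sojourn_scale numeric(2), gamma sojourn parameters
#'   per state; durations are measured in gap counts.
#' @slot init numeric(2), initial state probabilities.
#' @slot loglik numeric, log-likelihood trace across EM iterations.
#' @slot converged logical.
#' @slot fallback logical; TRUE when the EM collapsed and a
#'   quantile-threshold segmentation was used instead.
#' @slot max_duration integer, duration cap used in the dynamic programs.
#' @export
setClass("HSMMModel",
  slots = c(emission_mean = "numeric", sojourn_shape = "numeric",
            sojourn_scale = "numeric", init = "numeric",
            loglik = "numeric", converged = "logical",
            fallback = "logical", max_duration = "integer"))

setValidity("HSMMModel", function(object) {
  msg <- character()
  if (!object@fallback) {
    if (length(object@emission_mean) != 2 || any(object@emission_mean <= 0))
      msg <- c(msg, "emission_mean must be two positive values")
    if (any(object@sojourn_shape <= 0) || any(object@sojourn_scale <= 0))
      msg <- c(msg, "sojourn parameters must be positive")
    if (length(object@emission_mean) == 2 &&
        object@emission_mean[1] >= object@emission_mean[2])
      msg <- c(msg, "foreground (state 1) emission mean must be smaller")
  }
  if (length(msg)) msg else TRUE
})

#' MixtureFit: four-component pair-correlation mixture model
#'
#' Per-cell fit of the within-chromosome pairwise read distance
#' distribution with uniform, exponential, half-normal and normal
#' components.  The normal component captures the interpulse distances;
#' its mean is the average fork travel between the two EdU pulses and
#' yields the replication speed when divided by the pulse spacing.
#'
#' @slot weights named numeric(4) on the simplex
#'   (uniform, exp, halfnormal, normal).
#' @slot exp_mean exponential component mean, constrained > 1000 bp.
#' @slot halfnormal_sd half-normal scale (bp).
#' @slot normal_mean,normal_sd interpulse distance component (bp).
#' @slot upper support maximum of the uniform component (bp).
#' @slot loglik log-likelihood trace; @slot n_iter iterations used.
#' @slot converged logical; @slot n_obs number of distances fitted.
#' @export
setClass("MixtureFit",
  slots = c(weights = "numeric", exp_mean = "numeric",
            halfnormal_sd = "numeric", normal_mean = "numeric",
            normal_sd = "numeric", upper = "numeric",
            loglik = "numeric", n_iter = "integer",
            converged = "logical", n_obs = "integer"))

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (abs(sum(object@weights) - 1) > 1e-6)
    msg <- c(msg, "weights must sum to 1")
  if (object@weights[["exp"]] < 0.01 - 1e-9)
    msg <- c(msg, "exponential weight must be >= 0.01")
  if (object@exp_mean <= 1000)
    msg <- c(msg, "exponential mean must be > 1000 bp")
  if (object@n_iter > 100L) msg <- c(msg, "n_iter must be <= 100")
  if (length(msg)) msg else TRUE
})

#' OrderingResult: per-cell consensus S-phase position
#'
#' Result of repeated 1-D embedding of the cell-cell overlap distance
#' matrix.  Each retained run contributes a z-scored axis position per
#' cell; cells whose placements cluster tightly across runs receive a
#' consensus position, rescaled by rank to S-phase progression in [0, 1].
#'
#' @slot table data.table with columns \code{cell},
#'   \code{consensus_position}, \code{kept}, \code{n_successful_runs},
#'   \code{cluster_size}.
#' @slot placements matrix (cells x retained runs) of z-scored,
#'   sign-aligned axis positions.
#' @slot n_runs total number of embedding runs attempted.
#' @slot oriented logical, TRUE when the early-S end was anchored to a
#'   reference timing track.
#' @export
setClass("OrderingResult",
  slots = c(table = "data.table", placements = "matrix",
            n_runs = "integer", oriented = "logical"))

#' BiasSurface: simulation-derived correction for sampling bias
#'
#' Grid of (true speed mean, true speed sd) versus the mean/sd fitted by
#' the mixture model on simulated pair correlations, with local-regression
#' inverse predictors that map a measured (mean, sd) back to the ground
#' truth.  Faster forks lay longer labeled tracks and contribute more
#' read pairs, biasing the pooled fit upward; this surface undoes that.
#'
#' @slot grid data.table with columns \code{mu}, \code{sigma},
#'   \code{fitted_mean}, \code{fitted_sd} (speeds, kb/min).
#' @slot mu_model,sigma_model \code{loess} fits predicting true mu/sigma
#'   from fitted mean and sd.
#' @slot delta_t pulse spacing (min) the surface was built for.
#' @export
setClass("BiasSurface",
  slots = c(grid = "data.table", mu_model = "ANY", sigma_model = "ANY",
            delta_t = "numeric"))

## show() methods ------------------------------------------------------

setMethod("show", "MoleculeTable", function(object) {
  d <- object@data
  cat("MoleculeTable:", nrow(d), "molecules,",
      length(unique(d$cell)), "cells,",
      length(GenomeInfoDb::seqnames(object@layout)), "chromosomes\n")
  if (nrow(d)) {
    lab <- unique(d$labeling)
    cat("  labeling:", paste(lab, collapse = "/"))
    if ("double" %in% lab)
      cat("; delta_t:", paste(unique(stats::na.omit(d$delta_t)), collapse = ","),
          "min")
    cat("\n")
  }
})

setMethod("show", "HSMMModel", function(object) {
  if (object@fallback) {
    cat("HSMMModel (fallback quantile segmentation)\n")
  } else {
    cat("HSMMModel: 2-state, exponential emissions / gamma sojourn\n")
    cat(sprintf("  emission means (bp): fg %.1f, bg %.1f\n",
                object@emission_mean[1], object@emission_mean[2]))
    cat(sprintf("  sojourn (gaps): fg shape %.2f scale %.2f, bg shape %.2f scale %.2f\n",
                object@sojourn_shape[1], object@sojourn_scale[1],
                object@sojourn_shape[2], object@sojourn_scale[2]))
    cat(sprintf("  loglik %.2f after %d iterations (%s)\n",
                tail(object@loglik, 1), length(object@loglik),
                if (object@converged) "converged" else "max iterations"))
  }
})

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit: uniform/exponential/half-normal/normal on",
      object@n_obs, "distances\n")
  w <- object@weights
  cat(sprintf("  weights: unif %.3f exp %.3f halfnorm %.3f norm %.3f\n",
              w[["uniform"]], w[["exp"]], w[["halfnormal"]], w[["normal"]]))
  cat(sprintf("  interpulse distance: %.0f bp (sd %.0f); exp mean %.0f; halfnormal sd %.0f\n",
              object@normal_mean, object@normal_sd, object@exp_mean,
              object@halfnormal_sd))
  cat(sprintf("  %d iterations (%s)\n", object@n_iter,
              if (object@converged) "converged" else "max iterations"))
})

setMethod("show", "OrderingResult", function(object) {
  tab <- object@table
  cat("OrderingResult:", nrow(tab), "cells,",
      ncol(object@placements), "retained runs of", object@n_runs, "\n")
  cat(sprintf("  kept: %d (%.0f%%); orientation %s\n", sum(tab$kept),
              100 * mean(tab$kept),
              if (object@oriented) "anchored to timing reference" else "arbitrary"))
})

setMethod("show", "BiasSurface", function(object) {
  cat("BiasSurface:", nrow(object@grid), "grid points; mu in [",
      min(object@grid$mu), ",", max(object@grid$mu), "] kb/min, sigma in [",
      min(object@grid$sigma), ",", max(object@grid$sigma), "]\n")
})
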