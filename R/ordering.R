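## S-phase ordering: kernel-smoothed per-cell replication profiles,
## pairwise overlap-coefficient distances, and repeated 1-D embedding
## with consensus filtering.

#' Kernel-smoothed replication profiles
#'
#' Each foreground read contributes a unit-mass Gaussian (sd
#' 8,333.333 bp) evaluated on a fixed grid per chromosome (step
#' 2,500 bp), so a profile's sum approximates the cell's read count on
#' that chromosome (up to edge truncation).
#'
#' @param x a MoleculeTable (foreground reads).
#' @param grid_step grid spacing in bp (default 2,500, about sd/3.3).
#' @param kernel_sd Gaussian kernel standard deviation in bp
#'   (default 8,333.333).
#' @param cells optional subset of cell barcodes (default: all, in
#'   first-appearance order).
#' @return a list with one element per chromosome: a matrix (cells x
#'   grid points) of nonnegative smoothed signal; attributes
#'   \code{grid_step} and \code{kernel_sd}.
#' @export
smoothProfiles <- function(x, grid_step = 2500, kernel_sd = 8333.333,
                           cells = NULL) {
  stopifnot(is(x, "MoleculeTable"))
  d <- x@data
  if (is.null(cells)) cells <- unique(d$cell)
  empty <- setdiff(cells, unique(d$cell))
  if (length(empty))
    warning(length(empty), " cell(s) with no reads: zero profiles")
  len <- GenomeInfoDb::seqlengths(x@layout)
  half <- ceiling(5 * kernel_sd / grid_step)
  kern <- dnorm(seq(-half, half) * grid_step, sd = kernel_sd) * grid_step
  out <- list()
  for (ch in GenomeInfoDb::seqnames(x@layout)) {
    G <- ceiling(len[[ch]] / grid_step)
    mat <- matrix(0, nrow = length(cells), ncol = G,
                  dimnames = list(cells, NULL))
    dch <- d[chrom == ch & cell %in% cells]
    if (nrow(dch)) {
      for (cid in unique(dch$cell)) {
        p <- dch$pos[dch$cell == cid]
        cnt <- tabulate(pmin(floor(p / grid_step) + 1, G), nbins = G)
        sm <- stats::convolve(cnt, rev(kern), type = "open")
        mat[cid, ] <- sm[(half + 1):(half + G)]
      }
    }
    mat[mat < 0] <- 0    # convolution round-off
    out[[ch]] <- mat
  }
  structure(out, grid_step = grid_step, kernel_sd = kernel_sd)
}

#' Convert an overlap score to a distance
#'
#' \code{Distance = min(1/score - 1, 1000)}; a score of 0 (disjoint
#' profiles, or an all-zero profile) maps to the cap 1000.  Any score
#' at or below 1/1001 saturates at the cap.
#'
#' @param score overlap coefficient(s) in [0, 1].
#' @return distance value(s) in [0, 1000].
#' @examples
#' scoreToDistance(1)    # 0
#' scoreToDistance(0.5)  # 1
#' scoreToDistance(1e-6) # 1000
#' @export
scoreToDistance <- function(score) {
  out <- ifelse(score > 0, pmin(1 / score - 1, 1000), 1000)
  pmax(out, 0)
}

#' Pairwise cell distance matrix from smoothed profiles
#'
#' Per chromosome, the overlap coefficient between two profiles a, b is
#' \code{sum(min(a_i, b_i)) / min(sum(a), sum(b))}
#' (Szymkiewicz-Simpson on nonnegative signal); it is converted to a
#' distance with [scoreToDistance()] and averaged over chromosomes.
#' A chromosome on which either profile is all-zero contributes the
#' capped distance 1000.
#'
#' @param profiles output of [smoothProfiles()].
#' @return symmetric matrix of distances with zero diagonal, dimnames =
#'   cell barcodes.
#' @export
cellDistanceMatrix <- function(profiles) {
  ids <- rownames(profiles[[1]])
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (P in profiles) {
    rs <- rowSums(P)
    Dc <- matrix(1000, n, n)
    diag(Dc) <- 0
    for (i in seq_len(n - 1)) {
      if (rs[i] == 0) next
      for (j in seq((i + 1), n)) {
        if (rs[j] == 0) next
        score <- sum(pmin(P[i, ], P[j, ])) / min(rs[i], rs[j])
        Dc[i, j] <- Dc[j, i] <- scoreToDistance(score)
      }
    }
    D <- D + Dc
  }
  D / length(profiles)
}

#' Order cells along S phase by repeated 1-D embedding
#'
#' Embeds the cell distance matrix in one dimension with UMAP
#' \code{n_runs} times (distinct seeds), z-scores each run's axis,
#' discards runs whose mean absolute Spearman correlation with the
#' other runs falls below \code{spearman_cutoff}, and sign-aligns the
#' retained runs to the first retained run.  Per cell, the sorted
#' placements are split into clusters wherever two successive placings
#' are >= \code{cluster_gap} apart (z units); the cell is kept when its
#' largest cluster holds at least \code{cluster_frac} of the retained
#' runs, and its consensus is that cluster's mean.  Consensus values
#' are rank-rescaled to S-phase progression in [0, 1].
#'
#' The axis direction is arbitrary unless \code{early_fraction} (per
#' cell, e.g. the fraction of its reads in the earliest-replicating
#' decile of a reference timing track) is supplied, in which case the
#' axis is oriented so that progression 0 is early S.
#'
#' @param D distance matrix from [cellDistanceMatrix()] (>= 10 cells).
#' @param n_runs number of embedding runs (default 100).
#' @param seed master seed; run k uses seed + k.
#' @param n_neighbors,min_dist UMAP hyperparameters (15, 0.1).
#' @param spearman_cutoff run-retention threshold (0.85).
#' @param cluster_gap successive-placement gap that splits clusters
#'   (0.1 z units).
#' @param cluster_frac minimum fraction of retained runs in the largest
#'   cluster for a cell to be kept (0.8).
#' @param early_fraction optional named per-cell vector anchoring the
#'   early-S end.
#' @return an \linkS4class{OrderingResult}.
#' @export
embedOrder <- function(D, n_runs = 100, seed = 1, n_neighbors = 15,
                       min_dist = 0.1, spearman_cutoff = 0.85,
                       cluster_gap = 0.1, cluster_frac = 0.8,
                       early_fraction = NULL) {
  n <- nrow(D)
  if (n < 10) stop("need at least 10 cells to order")
  ids <- rownames(D)
  dd <- stats::as.dist(D)
  emb <- matrix(NA_real_, n, n_runs, dimnames = list(ids, NULL))
  for (k in seq_len(n_runs)) {
    e <- uwot::umap(dd, n_components = 1,
                    n_neighbors = min(n_neighbors, n - 1),
                    min_dist = min_dist, seed = seed + k)[, 1]
    emb[, k] <- (e - mean(e)) / sd(e)
  }
  ## retain the largest mutually consistent set of runs: drop the run
  ## with the lowest mean |Spearman| against the current set until all
  ## remaining runs clear the cutoff
  rho <- abs(cor(emb, method = "spearman"))
  retained <- seq_len(n_runs)
  while (length(retained) > 1) {
    sub <- rho[retained, retained, drop = FALSE]
    mean_abs <- (rowSums(sub) - 1) / (length(retained) - 1)
    if (min(mean_abs) >= spearman_cutoff) break
    retained <- retained[-which.min(mean_abs)]
  }
  if (length(retained) < n_runs / 2)
    stop(sprintf(paste0("only %d/%d embedding runs mutually consistent ",
                        "(mean |Spearman| >= %.2f); ordering failed"),
                 length(retained), n_runs, spearman_cutoff))
  anchor <- retained[1]
  pl <- emb[, retained, drop = FALSE]
  for (k in seq_along(retained))
    if (cor(pl[, k], emb[, anchor], method = "spearman") < 0)
      pl[, k] <- -pl[, k]
  R <- ncol(pl)
  cons <- numeric(n); kept <- logical(n); csize <- integer(n)
  for (i in seq_len(n)) {
    v <- sort(pl[i, ])
    splits <- which(diff(v) >= cluster_gap)
    cl <- cumsum(c(1, as.integer(seq_len(R - 1) %in% splits)))
    sizes <- tabulate(cl)
    big <- which.max(sizes)
    csize[i] <- sizes[big]
    kept[i] <- sizes[big] >= cluster_frac * R
    cons[i] <- mean(v[cl == big])
  }
  pos <- (rank(cons) - 1) / (n - 1)
  oriented <- FALSE
  if (!is.null(early_fraction)) {
    ef <- early_fraction[ids]
    if (cor(pos, ef, method = "spearman", use = "complete.obs") > 0)
      pos <- 1 - pos
    oriented <- TRUE
  }
  tab <- data.table::data.table(cell = ids, consensus_position = pos,
                                kept = kept, n_successful_runs = R,
                                cluster_size = csize)
  new("OrderingResult", table = tab, placements = pl,
      n_runs = as.integer(n_runs), oriented = oriented)
}

#' Fraction of each cell's reads in the earliest-replicating bins
#'
#' Helper for orienting the S-phase axis: given a reference timing
#' function (0 = earliest), returns per cell the fraction of reads
#' falling where timing <= \code{decile}.
#'
#' @param x a MoleculeTable.
#' @param timing function(chrom, pos) -> timing in [0, 1].
#' @param decile timing cutoff (default 0.1).
#' @return named numeric vector per cell.
#' @export
earlyFraction <- function(x, timing, decile = 0.1) {
  d <- x@data
  early <- timing(d$chrom, d$pos) <= decile
  v <- data.table::data.table(cell = d$cell, early = early)[,
         .(frac = mean(early)), by = cell]
  setNames(v$frac, v$cell)
}
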