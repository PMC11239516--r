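## Pair correlation of within-cell read distances, four-component
## mixture fit, bootstrap confidence intervals, speed computation, and
## the simulation-based correction for Poisson sampling bias.

#' Within-cell pairwise read distances
#'
#' All unordered pairwise distances between a cell's reads, computed
#' within chromosome only and truncated at \code{max_dist}.
#'
#' @param x a MoleculeTable.
#' @param cell cell barcode.
#' @param max_dist distance cutoff in bp (default 400 kb).
#' @return numeric vector of distances (bp).
#' @export
pairDistances <- function(x, cell, max_dist = 400000) {
  stopifnot(is(x, "MoleculeTable"))
  cid <- cell
  d <- x@data[x@data$cell == cid]
  if (nrow(d) < 2) {
    warning("cell has fewer than 2 reads; no distances")
    return(numeric(0))
  }
  data.table::setorder(d, chrom, pos)
  unlist(lapply(split(d$pos, d$chrom), function(p) {
    if (length(p) < 2) return(numeric(0))
    .pair_distances_sorted(as.numeric(p), max_dist)
  }), use.names = FALSE)
}

#' Pair correlation function of a cell
#'
#' Histogram of the within-chromosome pairwise read distances in 5-kb
#' bins up to 400 kb.  The secondary peak of a double-pulse cell sits at
#' the interpulse distance and encodes the fork travel between pulses.
#'
#' @inheritParams pairDistances
#' @param bin_size histogram bin width (bp), default 5 kb.
#' @param normalize \code{"none"}, \code{"sum"} (counts sum to 1) or
#'   \code{"range01"} (max-scaled).
#' @return data.table (bin_start, bin_end, count) with attribute
#'   \code{cell}.
#' @export
pairCorrelation <- function(x, cell, bin_size = 5000, max_dist = 400000,
                            normalize = c("none", "sum", "range01")) {
  normalize <- match.arg(normalize)
  dist <- if (is(x, "MoleculeTable")) pairDistances(x, cell, max_dist)
          else x[x > 0 & x <= max_dist]
  edges <- seq(0, max_dist, by = bin_size)
  nbins <- length(edges) - 1
  ## bins are [start, end); the boundary distance max_dist joins the
  ## last bin rather than being discarded
  idx <- pmin(floor(dist[dist > 0 & dist <= max_dist] / bin_size) + 1, nbins)
  cnt <- as.numeric(tabulate(idx, nbins = nbins))
  if (normalize == "sum" && sum(cnt) > 0) cnt <- cnt / sum(cnt)
  if (normalize == "range01" && max(cnt) > 0) cnt <- cnt / max(cnt)
  out <- data.table::data.table(bin_start = edges[-length(edges)],
                                bin_end = edges[-1], count = cnt)
  if (is(x, "MoleculeTable")) data.table::setattr(out, "cell", cell)
  out[]
}

## data-driven initial guess of the interpulse peak: mode of the 5-kb
## binned density beyond 20 kb
.normal_mean_init <- function(d, bin_size = 5000, lower = 20000) {
  d2 <- d[d > lower]
  if (length(d2) < 10) return(max(median(d), lower + bin_size))
  br <- seq(lower, max(d2) + bin_size, by = bin_size)
  h <- tabulate(findInterval(d2, br, left.open = TRUE), nbins = length(br) - 1)
  br[which.max(h)] + bin_size / 2
}

#' Fit the four-component pair-correlation mixture model
#'
#' EM with soft labels on raw (unbinned) distances in (0, 400 kb]:
#' uniform background (interfork pairs), exponential and half-normal
#' (intrapulse pairs), and a normal component whose mean is the
#' interpulse distance.  The exponential mean is constrained to
#' > 1,000 bp and its prior probability to >= 0.01; iteration stops at
#' relative log-likelihood tolerance 1e-8 or 100 iterations.  A
#' collapsing normal component triggers up to 3 restarts from perturbed
#' initializations.
#'
#' @param distances numeric vector of distances (bp); values outside
#'   (0, upper] are dropped.
#' @param upper support maximum (bp), default 400 kb.
#' @param seed seed for restart perturbations.
#' @param init optional named list overriding initial values
#'   (\code{exp_mean}, \code{halfnormal_sd}, \code{normal_mean},
#'   \code{normal_sd}, \code{weights}).
#' @param max_restarts restarts on collapse (default 3).
#' @return a \linkS4class{MixtureFit}.
#' @export
fitMixture <- function(distances, upper = 400000, seed = 1, init = list(),
                       max_restarts = 3) {
  d <- distances[distances > 0 & distances <= upper]
  if (length(d) < 200)
    warning("fewer than 200 retained distances; fit is low-power")
  if (length(d) < 8) stop("too few distances to fit a 4-component mixture")
  mu0 <- if (!is.null(init$normal_mean)) init$normal_mean else .normal_mean_init(d)
  em0 <- if (!is.null(init$exp_mean)) init$exp_mean else 5000
  hs0 <- if (!is.null(init$halfnormal_sd)) init$halfnormal_sd else 10000
  ns0 <- if (!is.null(init$normal_sd)) init$normal_sd else 10000
  w0 <- if (!is.null(init$weights)) init$weights else rep(0.25, 4)
  set.seed(seed)
  fit <- NULL
  for (attempt in 0:max_restarts) {
    mu_try <- if (attempt == 0) mu0 else mu0 * runif(1, 0.7, 1.3)
    res <- .mixture_em(d, upper, w0, em0, hs0, mu_try, ns0)
    ## label switch: the normal component abandoned the data-driven
    ## interpulse seed and collapsed onto the intrapulse scale
    switched <- res$normal_mean < 0.4 * mu0 && mu0 > 20000
    if (!res$collapsed && !switched) { fit <- res; break }
    fit <- res; fit$collapsed <- TRUE
  }
  if (fit$collapsed)
    warning("normal component collapsed after ", max_restarts, " restarts")
  new("MixtureFit",
      weights = setNames(fit$weights,
                         c("uniform", "exp", "halfnormal", "normal")),
      exp_mean = fit$exp_mean, halfnormal_sd = fit$halfnormal_sd,
      normal_mean = fit$normal_mean, normal_sd = fit$normal_sd,
      upper = upper, loglik = fit$loglik, n_iter = as.integer(fit$n_iter),
      converged = fit$converged, n_obs = length(d))
}

#' Component responsibilities under a fitted mixture
#'
#' @param fit a MixtureFit.
#' @param distances distances (bp).
#' @return matrix (length(distances) x 4) of posterior probabilities,
#'   columns uniform/exp/halfnormal/normal; rows sum to 1.
#' @export
mixturePosteriors <- function(fit, distances) {
  w <- fit@weights
  f <- cbind(
    uniform = w[["uniform"]] / fit@upper,
    exp = w[["exp"]] * dexp(distances, 1 / fit@exp_mean),
    halfnormal = w[["halfnormal"]] * sqrt(2 / pi) / fit@halfnormal_sd *
      exp(-distances^2 / (2 * fit@halfnormal_sd^2)),
    normal = w[["normal"]] * dnorm(distances, fit@normal_mean, fit@normal_sd))
  f / pmax(rowSums(f), .Machine$double.xmin)
}

#' Bootstrap confidence interval for the interpulse distance
#'
#' Resamples the distances with replacement \code{B} times, refits the
#' mixture and returns the percentile 2.5/97.5 interval of the fitted
#' normal-component mean.
#'
#' @inheritParams fitMixture
#' @param B bootstrap resamples (default 100).
#' @param ... passed to [fitMixture()].
#' @return list with \code{ci_low}, \code{ci_high} (bp),
#'   \code{boot_means}, \code{n_failed} and \code{widened} (TRUE when
#'   more than 20\% of refits failed).
#' @export
bootstrapCI <- function(distances, B = 100, seed = 1, ...) {
  d <- distances[distances > 0]
  set.seed(seed)
  seeds <- sample.int(1e6, B)
  means <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    db <- d[sample.int(length(d), length(d), replace = TRUE)]
    fb <- tryCatch(suppressWarnings(fitMixture(db, seed = seeds[b], ...)),
                   error = function(e) NULL)
    if (!is.null(fb)) means[b] <- fb@normal_mean
  }
  ok <- means[!is.na(means)]
  n_failed <- sum(is.na(means))
  if (!length(ok)) stop("all bootstrap refits failed")
  ci <- quantile(ok, c(0.025, 0.975), names = FALSE)
  list(ci_low = ci[1], ci_high = ci[2], boot_means = ok,
       n_failed = n_failed, widened = n_failed > 0.2 * B)
}

#' Replication speed from a mixture fit
#'
#' Speed = interpulse distance / pulse spacing, in kb/min.
#'
#' @param fit a MixtureFit.
#' @param delta_t center-to-center pulse spacing in minutes (45, 75 or
#'   105 in the experiments; any positive value accepted).
#' @param ci optional output of [bootstrapCI()] on the same distances.
#' @return data.table (delta_t, interpulse_bp, raw_speed, ci_low,
#'   ci_high in kb/min).
#' @export
estimateSpeed <- function(fit, delta_t, ci = NULL) {
  if (!is.numeric(delta_t) || delta_t <= 0) stop("delta_t must be > 0")
  data.table::data.table(
    delta_t = delta_t,
    interpulse_bp = fit@normal_mean,
    raw_speed = fit@normal_mean / 1000 / delta_t,
    ci_low = if (!is.null(ci)) ci$ci_low / 1000 / delta_t else NA_real_,
    ci_high = if (!is.null(ci)) ci$ci_high / 1000 / delta_t else NA_real_)
}

#' Per-cell replication speeds for a double-pulse sample
#'
#' Runs the pair-correlation + mixture pipeline per cell: distances,
#' mixture fit, optional bootstrap CI, speed; optionally joins S-phase
#' positions from an ordering and applies a bias surface.
#'
#' @param x a MoleculeTable (double-pulse cells).
#' @param delta_t pulse spacing (min); taken from the table when NULL.
#' @param bootstrap bootstrap resamples per cell (0 = none).
#' @param order optional \linkS4class{OrderingResult}.
#' @param surface optional \linkS4class{BiasSurface}.
#' @param seed integer seed.
#' @param min_distances cells with fewer retained distances are skipped
#'   with a warning (default 200).
#' @return data.table (cell, delta_t, interpulse_bp, raw_speed, ci_low,
#'   ci_high, normal_sd_speed, and when requested s_phase_position,
#'   corrected_speed, corrected_sd).
#' @export
estimateCellSpeeds <- function(x, delta_t = NULL, bootstrap = 0,
                               order = NULL, surface = NULL, seed = 1,
                               min_distances = 200) {
  stopifnot(is(x, "MoleculeTable"))
  out <- list()
  for (cid in cells(x)) {
    dt_cell <- delta_t
    if (is.null(dt_cell)) {
      dt_cell <- x@data[cell == cid, delta_t[1]]
      if (is.na(dt_cell))
        stop("delta_t missing for cell ", cid, " (single-pulse cell?)")
    }
    d <- pairDistances(x, cid)
    if (length(d) < min_distances) {
      warning("cell ", cid, ": only ", length(d),
              " distances; skipped as low-power")
      next
    }
    fit <- fitMixture(d, seed = seed)
    ci <- if (bootstrap > 0) bootstrapCI(d, B = bootstrap, seed = seed) else NULL
    row <- estimateSpeed(fit, dt_cell, ci)
    row[, `:=`(cell = cid, normal_sd_speed = fit@normal_sd / 1000 / dt_cell)]
    out[[length(out) + 1]] <- row
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, "cell")
  if (!is.null(order)) {
    ot <- orderingTable(order)
    res <- merge(res, ot[, .(cell, s_phase_position = consensus_position)],
                 by = "cell", all.x = TRUE)
  }
  if (!is.null(surface)) res <- applyCorrection(res, surface)
  res[]
}

#' Build the sampling-bias correction surface
#'
#' For every (mu, sigma) of a grid of ground-truth speed distributions,
#' simulates a cell's worth of double-pulse forks with
#' [simulatePairCorrCell()] (equal-intensity mode: constant read density
#' per kb, so faster forks contribute proportionally more read pairs),
#' fits the mixture to the pooled pair distances, and records the
#' fitted speed mean and sd.  Local quadratic regressions (span 0.75)
#' then predict the true mu and sigma from fitted values.
#'
#' @param mu_grid,sigma_grid ground-truth speed means and sds (kb/min);
#'   defaults mu 0.4--2.0 by 0.2, sigma 0--0.6 by 0.1.
#' @param n_rep forks per grid point (2,000 in the reference design).
#' @param delta_t pulse spacing the simulation encodes (75 min: the
#'   windows sit at 30--45 pulse-length units, centered 75 units apart
#'   per unit speed factor).
#' @param seed integer seed.
#' @param span loess span (0.75).
#' @return a \linkS4class{BiasSurface}.
#' @export
buildBiasSurface <- function(mu_grid = seq(0.4, 2.0, by = 0.2),
                             sigma_grid = seq(0, 0.6, by = 0.1),
                             n_rep = 2000, delta_t = 75, seed = 1,
                             span = 0.75) {
  grid <- data.table::CJ(mu = mu_grid, sigma = sigma_grid)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sim <- simulatePairCorrCell(grid$mu[i], grid$sigma[i], n_rep = n_rep,
                                mode = "equal", seed = seed + i)
    d <- pairCorrSimDistances(sim)
    fit <- suppressWarnings(fitMixture(d, seed = seed + i))
    if (fit@normal_mean < 20000) {
      warning("grid point (mu=", grid$mu[i], ", sigma=", grid$sigma[i],
              ") dropped: interpulse component not identified")
      next
    }
    res[[i]] <- data.table::data.table(
      mu = grid$mu[i], sigma = grid$sigma[i],
      fitted_mean = fit@normal_mean / 1000 / delta_t,
      fitted_sd = fit@normal_sd / 1000 / delta_t)
  }
  g <- data.table::rbindlist(res)
  ## local quadratic needs a dense grid; fall back to local linear on
  ## the reduced grids used for quick surfaces
  deg <- if (nrow(g) >= 20) 2 else 1
  mu_model <- loess(mu ~ fitted_mean + fitted_sd, data = g, span = span,
                    degree = deg,
                    control = stats::loess.control(surface = "direct"))
  sigma_model <- loess(sigma ~ fitted_mean + fitted_sd, data = g,
                       span = span, degree = deg,
                       control = stats::loess.control(surface = "direct"))
  new("BiasSurface", grid = g, mu_model = mu_model,
      sigma_model = sigma_model, delta_t = delta_t)
}

#' Apply the bias correction to measured speeds
#'
#' Predicts ground-truth speed mean/sd from measured values with the
#' surface's inverse regressions.  Queries outside the fitted grid hull
#' are clamped to the nearest boundary and flagged.
#'
#' @param est data.table with columns \code{raw_speed} and
#'   \code{normal_sd_speed} (e.g. from [estimateCellSpeeds()]), or a
#'   numeric vector of raw speeds (then \code{sd} must be given).
#' @param surface a \linkS4class{BiasSurface}.
#' @param sd measured speed sds when \code{est} is a vector.
#' @return the input with \code{corrected_speed}, \code{corrected_sd}
#'   and \code{extrapolated} columns (or a data.table for vector
#'   input).
#' @export
applyCorrection <- function(est, surface, sd = NULL) {
  vec_in <- is.numeric(est)
  if (vec_in) {
    if (is.null(sd)) stop("sd required for vector input")
    est <- data.table::data.table(raw_speed = est, normal_sd_speed = sd)
  } else est <- data.table::as.data.table(est)
  g <- surface@grid
  rng_m <- range(g$fitted_mean); rng_s <- range(g$fitted_sd)
  qm <- pmin(pmax(est$raw_speed, rng_m[1]), rng_m[2])
  qs <- pmin(pmax(est$normal_sd_speed, rng_s[1]), rng_s[2])
  flag <- qm != est$raw_speed | qs != est$normal_sd_speed
  nd <- data.frame(fitted_mean = qm, fitted_sd = qs)
  est[, corrected_speed := as.numeric(predict(surface@mu_model, newdata = nd))]
  est[, corrected_sd := as.numeric(predict(surface@sigma_model, newdata = nd))]
  est[, extrapolated := flag]
  if (any(flag))
    warning(sum(flag), " value(s) outside the surface grid; ",
            "clamped to the boundary")
  est[]
}
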