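# Independent oracles used by tests.

# Brute-force decoding of the 2-state explicit-duration semi-Markov
# model by exhaustive enumeration of all 2^T labelings.  Shares only
# the model definition (not the dynamic program) with the package:
# P(path, obs) = pi[s1] * prod_seg dur(d, s) * prod_t f(x_t | s_t),
# with the gamma sojourn pmf normalised on 1..T.
#
# Path enumeration and per-path run-length decompositions depend only
# on T, so they are cached: per path, `segcount` holds the number of
# segments of each (duration, state) pair, making the per-instance work
# two matrix products over all 2^T paths.
.brute_cache <- new.env(parent = emptyenv())

.brute_paths <- function(T) {
  key <- as.character(T)
  if (!is.null(.brute_cache[[key]])) return(.brute_cache[[key]])
  masks <- 0:(2^T - 1)
  paths <- t(vapply(masks,
                    function(m) as.integer(intToBits(m))[1:T] + 1L,
                    integer(T)))
  segcount <- matrix(0L, nrow = length(masks), ncol = 2 * T)
  first_state <- integer(length(masks))
  for (i in seq_along(masks)) {
    r <- rle(paths[i, ])
    first_state[i] <- r$values[1]
    idx <- (r$values - 1L) * T + r$lengths   # column (state, duration)
    for (k in idx) segcount[i, k] <- segcount[i, k] + 1L
  }
  res <- list(is_fg = paths == 1L, paths = paths, segcount = segcount,
              first_state = first_state)
  .brute_cache[[key]] <- res
  res
}

brute_force_decode <- function(g, emission_mean, shape, scale, pi0) {
  T <- length(g)
  logdur <- sapply(1:2, function(j) {
    lp <- dgamma(1:T, shape = shape[j], scale = scale[j], log = TRUE)
    lp - (max(lp) + log(sum(exp(lp - max(lp)))))
  })
  logf <- cbind(dexp(g, 1 / emission_mean[1], log = TRUE),
                dexp(g, 1 / emission_mean[2], log = TRUE))
  cache <- .brute_paths(T)
  emis <- cache$is_fg %*% logf[, 1] + (!cache$is_fg) %*% logf[, 2]
  dur <- cache$segcount %*% as.vector(logdur)
  total <- as.vector(emis + dur) + log(pi0)[cache$first_state]
  best <- which.max(total)
  list(loglik = total[best], path = cache$paths[best, ])
}

# all-pairs within-chromosome distances by double loop (no sorting
# tricks), for cross-checking pairDistances
brute_force_pairs <- function(pos, maxdist) {
  out <- numeric(0)
  n <- length(pos)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- abs(pos[j] - pos[i])
      if (d <= maxdist) out <- c(out, d)
    }
  }
  sort(out)
}

# overlap coefficient computed independently (plain arithmetic)
oracle_overlap <- function(a, b) sum(pmin(a, b)) / min(sum(a), sum(b))

# classical 1-D seriation: first non-trivial eigenvector of the doubly
# centered squared-distance matrix (principal coordinate), as an
# ordering oracle for a ladder distance matrix
seriation_ranks <- function(D) {
  rank(cmdscale(as.dist(D), k = 1)[, 1])
}
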