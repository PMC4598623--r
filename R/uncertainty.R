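#' Integrated autocorrelation time
#'
#' Sums the normalized autocorrelation function of a series up to the first
#' negative estimate (adaptive window cutoff): tau = sum_{k>=1} rho_k.  For
#' exchange simulations, compute tau on the continuous replica trajectories
#' rather than on window-reconstructed series -- replicas carry the full
#' temporal correlation and so give an upper bound for the per-image times.
#'
#' @param series numeric vector, >= 100 points.
#' @param lag_max maximum lag examined (default n - 1, capped at 10 * sqrt(n)
#'   below the cutoff heuristic only by the first negative crossing).
#' @return tau in units of the sampling lag (>= 0).  A constant series
#'   returns 0 with attribute `zero_variance = TRUE`.
#' @export
autocorrelation_time <- function(series, lag_max = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 100L) stop("autocorrelation_time needs at least 100 points")
  if (stats::var(series) < 1e-300) {
    return(structure(0, zero_variance = TRUE))
  }
  if (is.null(lag_max)) lag_max <- n - 1L
  ac <- stats::acf(series, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[-1L]
  neg <- which(ac < 0)
  if (length(neg)) ac <- ac[seq_len(neg[1L] - 1L)]
  max(sum(ac), 0)
}

#' Statistical inefficiency
#'
#' g = 1 + 2 tau / tau_lag: the factor by which correlated sampling inflates
#' the variance of a mean, with tau the autocorrelation time of the quantity
#' and tau_lag the lag between the data points used in the analysis.  The
#' effective number of independent samples is N / g.
#'
#' @param tau autocorrelation time (>= 0), in time units.
#' @param lag lag between analyzed points, same units (> 0).
#' @return g >= 1.
#' @export
statistical_inefficiency <- function(tau, lag = 1) {
  stopifnot(tau >= 0, lag > 0)
  1 + 2 * tau / lag
}

#' Block bootstrap over replica time series
#'
#' Estimates the sampling error of any reduction of a (weighted) sample set
#' by resampling contiguous blocks, which preserves within-block temporal
#' correlation.  Blocks never span replica boundaries.  Classical mode
#' resamples blocks with replacement (multinomial block weights); Bayesian
#' mode draws block weights from a flat Dirichlet, the Bayesian bootstrap
#' applied at block granularity.  Both are passed to the estimator as
#' per-sample weights.
#'
#' @param x per-sample values (vector or matrix with one row per sample).
#' @param replica replica label per sample.
#' @param block_length samples per block (must divide each replica's length).
#' @param n_boot number of bootstrap replicates.
#' @param estimator function(x, w) -> numeric scalar or vector; default the
#'   weighted mean.
#' @param bayesian logical: Dirichlet block weights instead of resampling.
#' @param weights optional base per-sample weights multiplied into the
#'   bootstrap weights (e.g. reweighting weights).
#' @param seed mandatory RNG seed.
#' @return list with `estimate` (estimator at uniform block weights), `mean`
#'   and `sd` over bootstrap replicates (vectors if the estimator returns
#'   one), and `n_blocks`.
#' @export
block_bootstrap <- function(x, replica = NULL, block_length, n_boot = 200L,
                            estimator = NULL, bayesian = TRUE,
                            weights = NULL, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  xm <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  n <- nrow(xm)
  if (is.null(replica)) replica <- rep(1L, n)
  stopifnot(length(replica) == n, block_length >= 1)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(estimator))
    estimator <- function(v, w) colSums(v * w) / sum(w)
  block_length <- as.integer(block_length)
  block_id <- integer(n)
  nb <- 0L
  for (r in unique(replica)) {
    idx <- which(replica == r)
    if (length(idx) %% block_length != 0L)
      stop("block_length (", block_length, ") must divide the sample count ",
           "of replica ", r, " (", length(idx), ")")
    k <- length(idx) %/% block_length
    block_id[idx] <- nb + rep(seq_len(k), each = block_length)
    nb <- nb + k
  }
  if (nb < 2L) stop("block bootstrap needs at least 2 blocks")
  est0 <- estimator(xm, weights)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bw <- if (bayesian) {
        g <- stats::rgamma(nb, shape = 1)   # flat Dirichlet up to scale
        g / sum(g) * nb
      } else {
        tabulate(sample.int(nb, nb, replace = TRUE), nbins = nb)
      }
      estimator(xm, weights * bw[block_id])
    }, numeric(length(est0)))
  })
  boots <- matrix(boots, nrow = length(est0))
  list(estimate = est0,
       mean = rowMeans(boots),
       sd = apply(boots, 1, stats::sd),
       n_blocks = nb)
}

#' Per-image averages along a pathway
#'
#' Mean of an arbitrary per-sample quantity within each image (window),
#' weighted by reweighting weights or unweighted (the unweighted estimator
#' tracks the average behaviour of the sampled pathway and is often the more
#' efficient choice under stiff restraints).  Reported standard errors are
#' inflated by the statistical inefficiency: se = sqrt(var * g / N_i).
#'
#' @param values per-sample quantity (numeric vector).
#' @param image image/window label per sample.
#' @param weights optional per-sample weights (NULL = unweighted).
#' @param g statistical inefficiency of the quantity (scalar or per image),
#'   from [statistical_inefficiency()] on continuous replica series.
#' @return data frame with `image`, `n`, `mean`, `sd`, `se`; images with
#'   fewer than 2 samples are masked (NA) with a warning.
#' @export
path_average <- function(values, image, weights = NULL, g = 1) {
  values <- as.numeric(values)
  stopifnot(length(image) == length(values))
  imgs <- sort(unique(image))
  g <- rep_len(g, length(imgs))
  if (is.null(weights)) weights <- rep(1, length(values))
  out <- do.call(rbind, lapply(seq_along(imgs), function(k) {
    i <- imgs[k]
    sel <- image == i
    n <- sum(sel)
    if (n < 2L)
      return(data.frame(image = i, n = n, mean = NA_real_, sd = NA_real_,
                        se = NA_real_))
    w <- weights[sel] / sum(weights[sel])
    m <- sum(w * values[sel])
    v <- sum(w * (values[sel] - m)^2) * n / (n - 1)
    data.frame(image = i, n = n, mean = m, sd = sqrt(v),
               se = sqrt(v * g[k] / n))
  }))
  if (any(out$n < 2L))
    warning("image(s) ", paste(out$image[out$n < 2L], collapse = ", "),
            " have fewer than 2 samples; masked")
  out
}
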