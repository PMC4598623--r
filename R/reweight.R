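#' Resolve bias energies into an n x N matrix
#'
#' Accepts a precomputed matrix of window bias energies U_i(zeta^t), a
#' [window_ladder()] (harmonic windows evaluated at the sample coordinates),
#' or a list of bias objects.
#' @param biases matrix, ladder, or list of biases.
#' @param samples the samples the energies refer to.
#' @return n x N numeric matrix.
#' @keywords internal
bias_energy_matrix <- function(biases, samples) {
  X <- if (inherits(samples, "sample_set")) samples$coords else as.matrix(samples)
  if (is.matrix(biases)) {
    if (nrow(biases) != nrow(X)) stop("bias energy matrix row count mismatch")
    return(biases)
  }
  if (inherits(biases, "window_ladder")) return(ladder_bias_energies(biases, X))
  if (is.list(biases))
    return(vapply(biases, function(b) b$energy(X), numeric(nrow(X))))
  stop("biases must be a matrix, window_ladder, or list of bias objects")
}

window_counts <- function(samples, n_windows) {
  if (!inherits(samples, "sample_set"))
    stop("window sample counts T_j require a sample_set with window labels")
  Tj <- tabulate(samples$window, nbins = n_windows)
  if (any(Tj == 0L))
    stop("window(s) ", paste(which(Tj == 0L), collapse = ", "),
         " have no samples")
  Tj
}

# warn about window pairs whose sampled regions do not overlap
check_overlap <- function(E, floor = 1e-8) {
  N <- ncol(E)
  for (i in seq_len(N - 1L)) {
    if (!any(E[, i] > floor & E[, i + 1L] > floor)) {
      warning("no sampled overlap between windows ", i, " and ", i + 1L,
              "; free-energy differences across this pair are ill-conditioned")
    }
  }
}

#' Self-consistent perturbed free energies (WHAM)
#'
#' Solves the weighted-histogram self-consistency system for the perturbed
#' free energies F_i of each umbrella window,
#' exp(-beta F_i) = sum_t w^t exp(-beta U_i(zeta^t)) with
#' w^t = 1 / sum_j T_j exp(beta F_j - beta U_j(zeta^t)),
#' by fixed-point iteration on the F's (method "self-consistent") or by
#' explicitly alternating the weight and free-energy equations (method
#' "iterative-weights"; algebraically the same fixed point, kept as a
#' cross-check of the estimator family).  Exponentials are handled through a
#' common scale shift so 100+-window problems do not underflow.  F is
#' anchored at F_1 = 0.
#'
#' @param samples a [sample_set()] (its `window` labels give the per-window
#'   sample counts T_j).
#' @param biases window biases: matrix of U_i(zeta^t), [window_ladder()], or
#'   list of bias objects.
#' @param beta inverse temperature.
#' @param tol convergence threshold on max |Delta F_i| between sweeps
#'   (energy units).
#' @param max_iter sweep cap.
#' @param method see above.
#' @param obs_weights optional nonnegative per-sample multiplicities (e.g.
#'   Bayesian-bootstrap block weights); default 1 for every sample.  Window
#'   counts become effective counts sum_t obs_weights within the window.
#' @param F_init optional starting F vector (warm start, e.g. the full-data
#'   solution when re-solving under bootstrap weights).
#' @return object of class `perturbed_free_energies`: list with `F`
#'   (anchored), `beta`, `T` (window counts), `iterations`, `converged`.
#' @export
wham_solve <- function(samples, biases, beta = 1, tol = 1e-8,
                       max_iter = 20000L,
                       method = c("self-consistent", "iterative-weights"),
                       obs_weights = NULL, F_init = NULL) {
  method <- match.arg(method)
  U <- bias_energy_matrix(biases, samples)
  N <- ncol(U)
  Tj <- window_counts(samples, N)
  if (!is.null(obs_weights)) {
    stopifnot(length(obs_weights) == nrow(U), all(obs_weights >= 0))
    Tj_eff <- as.numeric(rowsum(obs_weights, samples$window))
    if (any(Tj_eff <= 0)) stop("a window lost all weight under obs_weights")
  } else Tj_eff <- Tj
  E <- exp(-pmin(beta * U, 700))
  check_overlap(E)
  g <- if (is.null(F_init)) numeric(N) else beta * (F_init - F_init[1L])
  ow <- if (is.null(obs_weights)) rep(1, nrow(E)) else obs_weights
  # The self-consistent system is the stationarity condition of a convex
  # likelihood; minimize it first (BFGS, analytic gradient) so the slow
  # collective modes of long/cyclic ladders are fully relaxed, then verify
  # by fixed-point sweeps below until the sweep residual meets tol.
  nll <- function(gf) {
    gg <- c(0, gf)
    denom <- as.numeric(E %*% (Tj_eff * exp(gg - max(gg)))) # common shift ok
    sum(ow * log(denom)) - sum(Tj_eff * (gg - max(gg)))
  }
  nll_grad <- function(gf) {
    gg <- c(0, gf)
    a <- Tj_eff * exp(gg - max(gg))
    denom <- as.numeric(E %*% a)
    (a * as.numeric(crossprod(E, ow / denom)) - Tj_eff)[-1L]
  }
  opt <- stats::optim(g[-1L], nll, nll_grad, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-15))
  g <- c(0, opt$par)
  w <- NULL
  for (it in seq_len(max_iter)) {
    if (method == "self-consistent") {
      denom <- as.numeric(E %*% (Tj_eff * exp(g - max(g))))
      li <- if (is.null(obs_weights)) as.numeric(crossprod(E, 1 / denom))
            else as.numeric(crossprod(E, obs_weights / denom))
    } else {
      w <- 1 / as.numeric(E %*% (Tj_eff * exp(g - max(g))))
      li <- if (is.null(obs_weights)) as.numeric(crossprod(E, w))
            else as.numeric(crossprod(E, obs_weights * w))
    }
    g_new <- -log(li)
    g_new <- g_new - g_new[1L]
    delta <- max(abs(g_new - g)) / beta
    g <- g_new
    if (delta < tol) {
      return(structure(list(F = g / beta, beta = beta, T = Tj,
                            iterations = it, converged = TRUE),
                       class = "perturbed_free_energies"))
    }
  }
  stop("WHAM did not converge in ", max_iter, " sweeps (residual ",
       format(max(abs(delta))), " > tol ", tol, ")")
}

#' @export
print.perturbed_free_energies <- function(x, ...) {
  cat("<perturbed_free_energies>", length(x$F), "windows, beta =", x$beta,
      if (x$converged) sprintf("(converged in %d sweeps)\n", x$iterations)
      else "(NOT converged)\n")
  print(stats::setNames(round(x$F, 4), paste0("F", seq_along(x$F))))
  invisible(x)
}

#' Per-sample unbiased weights from perturbed free energies
#'
#' w^t = 1 / sum_i T_i exp(beta F_i) exp(-beta U_i(zeta^t)), the unnormalized
#' weight of each configuration in the unbiased ensemble; normalized to sum
#' to 1 on request (the default).  Shifting all F_i by a constant leaves the
#' normalized weights unchanged.
#'
#' @param samples a [sample_set()].
#' @param biases as in [wham_solve()].
#' @param F a `perturbed_free_energies` object (or numeric F vector).
#' @param beta inverse temperature (taken from `F` when it carries one).
#' @param normalize logical.
#' @return object of class `weighted_ensemble`: list with `w`, `log_w`
#'   (unnormalized, up to a common constant), and provenance (`window`,
#'   `replica`, `time`).
#' @export
sample_weights <- function(samples, biases, F, beta = NULL,
                           normalize = TRUE) {
  if (inherits(F, "perturbed_free_energies")) {
    if (is.null(beta)) beta <- F$beta
    Tj <- F$T
    Fv <- F$F
  } else {
    Fv <- as.numeric(F)
    if (is.null(beta)) beta <- 1
    Tj <- window_counts(samples, length(Fv))
  }
  U <- bias_energy_matrix(biases, samples)
  stopifnot(ncol(U) == length(Fv))
  # log-sum-exp over windows, per sample
  A <- sweep(-beta * U, 2, log(Tj) + beta * Fv, `+`)
  M <- apply(A, 1, max)
  log_denom <- M + log(rowSums(exp(A - M)))
  log_w <- -log_denom
  w <- exp(log_w - max(log_w))
  if (normalize) w <- w / sum(w)
  prov <- if (inherits(samples, "sample_set"))
    samples[c("window", "replica", "time")] else NULL
  structure(list(w = w, log_w = log_w, normalized = normalize,
                 window = prov$window, replica = prov$replica,
                 time = prov$time),
            class = "weighted_ensemble")
}

#' @export
print.weighted_ensemble <- function(x, ...) {
  cat("<weighted_ensemble>", length(x$w), "samples,",
      if (x$normalized) "normalized," else "unnormalized,",
      sprintf("effective sample size %.1f\n", 1 / sum((x$w / sum(x$w))^2)))
  invisible(x)
}

#' Bayesian reweighting by Gibbs sampling
#'
#' Draws the per-sample weights {w^t} and the transformed free energies
#' f_i = T_i exp(beta F_i) from their posterior by alternating Gamma
#' conditionals: f_i | w ~ Gamma(shape = T_i, rate = sum_t w^t
#' exp(-beta U_i(zeta^t))) and w^t | f ~ Gamma(shape = 1, rate = sum_i f_i
#' exp(-beta U_i(zeta^t))), normalizing {w^t} after each sweep.  The
#' stationary point of the conditional means reproduces the maximum-
#' likelihood (WHAM) equations, and every post-burn-in draw is an equally
#' likely reweighting usable for PMF reconstruction; the spread of the draws
#' is the posterior uncertainty.
#'
#' @param samples a [sample_set()].
#' @param biases as in [wham_solve()].
#' @param beta inverse temperature.
#' @param n_draws posterior draws retained after burn-in.
#' @param burn_in discarded initial sweeps.
#' @param seed mandatory RNG seed.
#' @param init `"wham"` (default) starts the chain from the
#'   maximum-likelihood weights, so the burn-in only needs to relax the
#'   local fluctuations; `"uniform"` starts from flat weights, which for
#'   long window ladders requires a burn-in comparable to the WHAM
#'   iteration count to reach the mode.
#' @return list with `F_draws` (n_draws x N, anchored at F_1 = 0), `F_mean`,
#'   `F_sd`, `w_mean`, `w_sd`, `w_last` (one exact posterior draw), `beta`.
#' @export
gibbs_reweight <- function(samples, biases, beta = 1, n_draws = 200L,
                           burn_in = 100L, seed,
                           init = c("wham", "uniform")) {
  if (missing(seed)) stop("an explicit seed is required")
  init <- match.arg(init)
  U <- bias_energy_matrix(biases, samples)
  N <- ncol(U)
  Tj <- window_counts(samples, N)
  E <- exp(-pmin(beta * U, 700))
  check_overlap(E)
  n <- nrow(E)
  F_draws <- matrix(NA_real_, n_draws, N)
  w_sum <- numeric(n); w_sqsum <- numeric(n); w_last <- NULL
  w_start <- if (init == "wham") {
    F0 <- wham_solve(samples, U, beta = beta, tol = 1e-6)
    sample_weights(samples, U, F0)$w
  } else rep(1 / n, n)
  with_seed(seed, {
    w <- w_start
    total <- burn_in + n_draws
    for (sweep in seq_len(total)) {
      rate_f <- as.numeric(crossprod(E, w))
      if (any(!is.finite(rate_f) | rate_f <= 0))
        stop("non-finite Gamma rate for f at sweep ", sweep)
      f <- stats::rgamma(N, shape = Tj, rate = rate_f)
      rate_w <- as.numeric(E %*% f)
      if (any(!is.finite(rate_w) | rate_w <= 0))
        stop("non-finite Gamma rate for w at sweep ", sweep)
      w <- stats::rexp(n, rate = 1) / rate_w   # Gamma(1, rate) draws
      w <- w / sum(w)
      if (sweep > burn_in) {
        i <- sweep - burn_in
        bF <- log(f / Tj)
        F_draws[i, ] <- (bF - bF[1L]) / beta
        w_sum <- w_sum + w
        w_sqsum <- w_sqsum + w^2
        if (i == n_draws) w_last <- w
      }
    }
  })
  w_mean <- w_sum / n_draws
  w_var <- pmax(w_sqsum / n_draws - w_mean^2, 0)
  list(F_draws = F_draws,
       F_mean = colMeans(F_draws),
       F_sd = apply(F_draws, 2, stats::sd),
       w_mean = w_mean, w_sd = sqrt(w_var), w_last = w_last,
       beta = beta, seed = seed)
}

#' Project a weighted ensemble onto a PMF grid
#'
#' G(xi) = -beta^-1 log sum_t w^t K(xi - xi^t), up to an additive constant,
#' for an arbitrary projection variable xi evaluated on every sample.
#' Kernels: top-hat histogram (1D or 2D) or Gaussian (1D) with Silverman's
#' default bandwidth.  Bins supported by fewer raw samples than
#' `occupancy_floor` are masked (reported, never extrapolated): the
#' projection is only trustworthy where sampling of xi has converged.
#'
#' @param weights a `weighted_ensemble` or numeric weight vector.
#' @param xi per-sample projection values: vector (1D) or 2-column matrix.
#' @param kernel `"histogram"` or `"gaussian"`.
#' @param breaks bin breaks: vector (1D) or list of two vectors (2D).
#' @param beta inverse temperature.
#' @param bandwidth Gaussian kernel bandwidth (default Silverman).
#' @param occupancy_floor minimum raw-sample support per bin.
#' @return object of class `pmf_grid`: list with `mid` (bin centers; a
#'   two-element list for 2D), `G` (anchored to 0 at the occupied minimum;
#'   masked bins NA), `se` (delta-method error from the weight spread),
#'   `count`, `mask`, `dim`.
#' @export
project_pmf <- function(weights, xi, kernel = c("histogram", "gaussian"),
                        breaks, beta = 1, bandwidth = NULL,
                        occupancy_floor = 5L) {
  kernel <- match.arg(kernel)
  w <- if (inherits(weights, "weighted_ensemble")) weights$w else as.numeric(weights)
  w <- w / sum(w)
  two_d <- (is.matrix(xi) && ncol(xi) == 2L)
  if (!two_d) xi <- as.numeric(xi)
  if (kernel == "gaussian") {
    if (two_d) stop("gaussian kernel is implemented for 1D projections")
    if (is.null(bandwidth)) {
      m <- sum(w * xi); sdw <- sqrt(sum(w * (xi - m)^2))
      n_eff <- 1 / sum(w^2)
      bandwidth <- 1.06 * sdw * n_eff^(-1 / 5)
    }
    grid <- if (is.list(breaks)) stop("1D projection needs a breaks vector")
            else breaks
    mid <- (grid[-1] + grid[-length(grid)]) / 2
    S <- vapply(mid, function(x0)
      sum(w * stats::dnorm(xi - x0, sd = bandwidth)), numeric(1))
    cnt <- vapply(mid, function(x0)
      sum(abs(xi - x0) <= 2 * bandwidth), numeric(1))
    S2 <- vapply(mid, function(x0)
      sum((w * stats::dnorm(xi - x0, sd = bandwidth))^2), numeric(1))
    mask <- cnt < occupancy_floor | S <= 0
    G <- ifelse(mask, NA_real_, -log(S) / beta)
    se <- ifelse(mask, NA_real_, sqrt(S2) / S / beta)
    G <- G - min(G, na.rm = TRUE)
    if (any(mask)) warning(sum(mask), " bin(s) masked below occupancy floor")
    return(structure(list(mid = mid, G = G, se = se, count = cnt,
                          mask = mask, dim = 1L, kernel = kernel,
                          bandwidth = bandwidth),
                     class = "pmf_grid"))
  }
  if (two_d) {
    stopifnot(is.list(breaks), length(breaks) == 2L)
    ix <- cut(xi[, 1], breaks[[1]], labels = FALSE, include.lowest = TRUE)
    iy <- cut(xi[, 2], breaks[[2]], labels = FALSE, include.lowest = TRUE)
    nx <- length(breaks[[1]]) - 1L; ny <- length(breaks[[2]]) - 1L
    ok <- !is.na(ix) & !is.na(iy)
    bin <- (iy[ok] - 1L) * nx + ix[ok]
    S <- numeric(nx * ny); S2 <- numeric(nx * ny); cnt <- numeric(nx * ny)
    agg <- rowsum(cbind(w[ok], w[ok]^2, 1), bin)
    idx <- as.integer(rownames(agg))
    S[idx] <- agg[, 1]; S2[idx] <- agg[, 2]; cnt[idx] <- agg[, 3]
    mask <- cnt < occupancy_floor | S <= 0
    G <- ifelse(mask, NA_real_, -log(S) / beta)
    se <- ifelse(mask, NA_real_, sqrt(S2) / S / beta)
    if (all(mask)) stop("no occupied bins in the projection grid")
    G <- G - min(G, na.rm = TRUE)
    mids <- list((breaks[[1]][-1] + breaks[[1]][-(nx + 1L)]) / 2,
                 (breaks[[2]][-1] + breaks[[2]][-(ny + 1L)]) / 2)
    return(structure(list(mid = mids, G = matrix(G, nx, ny),
                          se = matrix(se, nx, ny),
                          count = matrix(cnt, nx, ny),
                          mask = matrix(mask, nx, ny), dim = 2L,
                          kernel = kernel),
                     class = "pmf_grid"))
  }
  ib <- cut(xi, breaks, labels = FALSE, include.lowest = TRUE)
  nb <- length(breaks) - 1L
  ok <- !is.na(ib)
  if (!any(ok)) stop("no samples fall inside the projection grid")
  S <- numeric(nb); S2 <- numeric(nb); cnt <- numeric(nb)
  agg <- rowsum(cbind(w[ok], w[ok]^2, 1), ib[ok])
  idx <- as.integer(rownames(agg))
  S[idx] <- agg[, 1]; S2[idx] <- agg[, 2]; cnt[idx] <- agg[, 3]
  mask <- cnt < occupancy_floor | S <= 0
  if (all(mask)) stop("no occupied bins in the projection grid")
  G <- ifelse(mask, NA_real_, -log(S) / beta)
  se <- ifelse(mask, NA_real_, sqrt(S2) / S / beta)
  G <- G - min(G, na.rm = TRUE)
  if (any(mask)) warning(sum(mask), " bin(s) masked below occupancy floor")
  mid <- (breaks[-1] + breaks[-(nb + 1L)]) / 2
  structure(list(mid = mid, G = G, se = se, count = cnt, mask = mask,
                 dim = 1L, kernel = kernel),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat("<pmf_grid>", if (x$dim == 1L) length(x$G) else paste(dim(x$G), collapse = " x "),
      "bins,", sum(x$mask), "masked,", x$kernel, "kernel\n")
  invisible(x)
}

#' Stiff-spring correction of path free energies
#'
#' In the stiff-spring regime the PMF along the path arc length s is
#' recovered from the perturbed free energies by the second-order expansion
#' G(s) = F(s) + F'(s)^2 / (2 k) - F''(s) / (2 beta k) + O(1/k^2).
#' Derivatives are estimated by second-order central finite differences
#' (wrapped for cyclic paths, one-sided at open endpoints).  The per-image
#' correction magnitude is reported so the validity of the approximation can
#' be checked a posteriori (it should be small against the statistical
#' error).
#'
#' @param F perturbed free energies along the path: numeric vector or a
#'   `perturbed_free_energies` object, >= 5 images.
#' @param s arc lengths of the images (uniformly spaced).
#' @param k biasing force constant (energy / length^2 in s units).
#' @param beta inverse temperature.
#' @param cyclic logical; wrap the derivatives for a closed path.
#' @return list with `G` (anchored to min 0), `correction` (per image),
#'   `F` (anchored input), `s`.
#' @export
stiff_spring_correct <- function(F, s, k, beta = 1, cyclic = FALSE) {
  if (inherits(F, "perturbed_free_energies")) { beta <- F$beta; F <- F$F }
  F <- as.numeric(F)
  n <- length(F)
  if (n < 5L) stop("stiff-spring correction needs at least 5 images")
  stopifnot(length(s) == n, k > 0)
  h <- diff(s)
  if (max(abs(h - mean(h))) > 1e-6 * abs(mean(h)))
    stop("image arc lengths must be uniformly spaced")
  h <- mean(h)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  Fp <- (F[ip] - F[im]) / (2 * h)
  Fpp <- (F[ip] - 2 * F + F[im]) / h^2
  if (!cyclic) {
    Fp[1] <- (-3 * F[1] + 4 * F[2] - F[3]) / (2 * h)
    Fp[n] <- (3 * F[n] - 4 * F[n - 1] + F[n - 2]) / (2 * h)
    Fpp[1] <- (2 * F[1] - 5 * F[2] + 4 * F[3] - F[4]) / h^2
    Fpp[n] <- (2 * F[n] - 5 * F[n - 1] + 4 * F[n - 2] - F[n - 3]) / h^2
  }
  correction <- Fp^2 / (2 * k) - Fpp / (2 * beta * k)
  G <- F + correction
  list(G = G - min(G), correction = correction, F = F - min(F), s = s)
}

#' Locate free-energy extrema along a profile
#'
#' @param G free-energy values along the path.
#' @param cyclic wrap the neighborhood comparison.
#' @return list with `minima` and `maxima` (indices).
#' @export
find_extrema <- function(G, cyclic = FALSE) {
  n <- length(G)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  lo <- G < G[ip] & G < G[im]
  hi <- G > G[ip] & G > G[im]
  if (!cyclic) {
    lo[1] <- G[1] < G[2]; lo[n] <- G[n] < G[n - 1]
    hi[1] <- G[1] > G[2]; hi[n] <- G[n] > G[n - 1]
  }
  list(minima = which(lo), maxima = which(hi))
}

#' State and barrier free energies along a path
#'
#' Tabulates pairwise free-energy differences between named states and
#' barrier heights from states to transition states, with errors combined in
#' quadrature from per-image standard deviations (identical indices report
#' zero by construction).
#'
#' @param G free-energy profile (e.g. from [stiff_spring_correct()]).
#' @param states named integer vector of state image indices.
#' @param barriers named integer vector of transition-state image indices
#'   (may be empty).
#' @param se optional per-image standard deviations (same length as `G`).
#' @return list with `dG` (data frame from, to, dG, se) and `barrier`
#'   (data frame state, ts, height, se).
#' @export
state_free_energies <- function(G, states, barriers = integer(0), se = NULL) {
  n <- length(G)
  idx <- c(states, barriers)
  if (any(idx < 1L | idx > n)) stop("state/barrier index out of range")
  if (is.null(se)) se <- numeric(n)
  stopifnot(length(se) == n)
  comb <- function(i, j) if (i == j) 0 else sqrt(se[i]^2 + se[j]^2)
  pairs <- expand.grid(from = names(states), to = names(states),
                       stringsAsFactors = FALSE)
  dG <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- states[[pairs$from[r]]]; j <- states[[pairs$to[r]]]
    data.frame(from = pairs$from[r], to = pairs$to[r],
               dG = G[j] - G[i], se = comb(i, j))
  }))
  barrier <- if (length(barriers)) {
    do.call(rbind, lapply(names(barriers), function(b) {
      do.call(rbind, lapply(names(states), function(s) {
        i <- states[[s]]; j <- barriers[[b]]
        data.frame(state = s, ts = b, height = G[j] - G[i],
                   se = comb(i, j))
      }))
    }))
  } else data.frame(state = character(), ts = character(),
                    height = numeric(), se = numeric())
  list(dG = dG, barrier = barrier)
}
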