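#' Umbrella window ladders
#'
#' An ordered set of harmonic umbrella windows along a (possibly cyclic)
#' pathway, one replica per window, used by the bias-exchange umbrella
#' sampling driver and by the reweighting estimators.
#'
#' @param centers N x d matrix of window centers in CV space.
#' @param k force constant(s): scalar, one per window, or an N x d matrix.
#' @param cyclic logical; window N neighbors window 1 and exchanges across
#'   the seam.
#' @param tube optional list(`radius`, `k`) adding a flat-bottom harmonic
#'   penalty on the distance beyond `radius` from the window center
#'   (a transition-tube restraint).
#' @return object of class `window_ladder`.
#' @export
window_ladder <- function(centers, k, cyclic = FALSE, tube = NULL) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 2L) stop("a window ladder needs at least 2 windows")
  seg <- sqrt(rowSums((centers[-1L, , drop = FALSE] -
                       centers[-nrow(centers), , drop = FALSE])^2))
  if (any(seg < 1e-12)) stop("consecutive window centers must be distinct")
  if (is.matrix(k)) {
    if (!all(dim(k) == dim(centers))) stop("k matrix must match centers")
  } else {
    # scalar, per-window (length N) or per-dimension (length d) k all allowed
    k <- matrix(rep_len(as.numeric(k), nrow(centers) * ncol(centers)),
                nrow(centers), ncol(centers),
                byrow = length(k) == ncol(centers) && ncol(centers) > 1)
  }
  stopifnot(all(k >= 0))
  structure(list(centers = centers, k = k, cyclic = isTRUE(cyclic),
                 tube = tube, n = nrow(centers)),
            class = "window_ladder")
}

#' @export
print.window_ladder <- function(x, ...) {
  cat("<window_ladder>", x$n, "windows, d =", ncol(x$centers),
      if (x$cyclic) "(cyclic)\n" else "(open)\n")
  invisible(x)
}

#' Bias energies of every window at every sample
#'
#' @param ladder a [window_ladder()].
#' @param coords n x d matrix of CV samples.
#' @return n x N matrix: U_i(zeta^t) for window i (column) and sample t
#'   (row); the input required by [wham_solve()] and friends.
#' @export
ladder_bias_energies <- function(ladder, coords) {
  coords <- as_row_matrix(as.matrix(coords), ncol(ladder$centers))
  U <- vapply(seq_len(ladder$n), function(i) {
    D <- sweep(coords, 2, ladder$centers[i, ])
    u <- 0.5 * rowSums(sweep(D^2, 2, ladder$k[i, ], `*`))
    if (!is.null(ladder$tube)) {
      r <- sqrt(rowSums(D^2))
      excess <- pmax(r - ladder$tube$radius, 0)
      u <- u + 0.5 * ladder$tube$k * excess^2
    }
    u
  }, numeric(nrow(coords)))
  matrix(U, nrow = nrow(coords))
}

#' Metropolis exchange attempt between two neighboring windows
#'
#' Hamiltonian replica-exchange criterion for swapping the biases of
#' neighboring umbrella windows: Delta = beta [(U_i(zeta_j) + U_j(zeta_i)) -
#' (U_i(zeta_i) + U_j(zeta_j))], accepted with probability min(1,
#' exp(-Delta)).  The uniform variate is drawn from the current RNG stream
#' (callers seed it).
#'
#' @param state_i,state_j current CV states of the replicas holding windows
#'   i and j.
#' @param bias_i,bias_j bias energy functions (e.g. from [harmonic_bias()];
#'   anything with an `energy(X)` evaluator).
#' @param beta inverse temperature.
#' @return list with `accepted` (logical) and `delta`.
#' @export
exchange_attempt <- function(state_i, state_j, bias_i, bias_j, beta = 1) {
  ui <- function(x) bias_i$energy(matrix(x, nrow = 1))
  uj <- function(x) bias_j$energy(matrix(x, nrow = 1))
  delta <- beta * ((ui(state_j) + uj(state_i)) - (ui(state_i) + uj(state_j)))
  accepted <- delta <= 0 || stats::runif(1) < exp(-delta)
  list(accepted = accepted, delta = delta)
}

# Exchange Delta for the ladder's harmonic windows, vectorized over pairs.
ladder_exchange_delta <- function(ladder, Xi, Xj, wi, wj, beta) {
  u <- function(w, X) {
    D <- X - ladder$centers[w, , drop = FALSE][rep(1, nrow(X)), , drop = FALSE]
    0.5 * rowSums(sweep(D^2, 2, ladder$k[w, ], `*`))
  }
  beta * ((u(wi, Xj) + u(wj, Xi)) - (u(wi, Xi) + u(wj, Xj)))
}

#' Bias-exchange umbrella sampling on a toy surface
#'
#' Runs one replica per window under its harmonic bias, periodically
#' attempting Metropolis swaps of the biases between neighboring windows
#' (alternating even/odd neighbor pairs each attempt epoch; cyclic ladders
#' exchange across the seam).  Exchanging biases rather than coordinates
#' keeps each replica's trajectory continuous, which is what the
#' autocorrelation analysis expects.
#'
#' @param ladder a [window_ladder()].
#' @param surface a [potential_surface()].
#' @param config a [brownian_config()]; `config$steps` is the total step
#'   count per replica.
#' @param exchange_interval steps between exchange attempt epochs; `Inf`
#'   disables exchange (independent umbrella sampling).
#' @param start optional N x d start matrix (default: the window centers).
#' @return list with `samples` (a [sample_set()]; `window` labels follow the
#'   biases as they migrate), `exchange_log` (data frame: time, i, j, delta,
#'   accepted), and `occupancy` (epochs x replicas matrix of window held).
#' @export
run_beus <- function(ladder, surface, config, exchange_interval = Inf,
                     start = NULL) {
  stopifnot(inherits(ladder, "window_ladder"),
            inherits(config, "brownian_config"))
  N <- ladder$n
  X <- if (is.null(start)) ladder$centers else as_row_matrix(start, surface$d)
  stopifnot(nrow(X) == N)
  Dvec <- rep_len(config$diffusion, surface$d)
  perm <- seq_len(N)   # perm[r] = window currently held by replica r
  seg_steps <- if (is.infinite(exchange_interval)) config$steps
               else as.integer(exchange_interval)
  stopifnot(seg_steps >= 1)
  n_epochs <- ceiling(config$steps / seg_steps)
  rec_chunks <- vector("list", n_epochs)
  win_chunks <- vector("list", n_epochs)
  log_rows <- list()
  occupancy <- matrix(NA_integer_, n_epochs, N)
  done <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(n_epochs)) {
      steps <- min(seg_steps, config$steps - done)
      res <- em_run(X, surface, steps, config$timestep, Dvec, config$beta,
                    config$noise_scale, config$guard,
                    centers = ladder$centers[perm, , drop = FALSE],
                    k = ladder$k[perm, , drop = FALSE],
                    stride = config$stride, label = "window",
                    metropolis = isTRUE(config$metropolis))
      X <- res$X
      rec_chunks[[epoch]] <- res$rec
      n_rec <- if (is.null(res$rec)) 0L else dim(res$rec)[1]
      win_chunks[[epoch]] <- matrix(rep(perm, each = n_rec), n_rec, N)
      done <- done + steps
      occupancy[epoch, ] <- perm
      if (!is.infinite(exchange_interval) && done < config$steps) {
        parity <- 1L + (epoch %% 2L)   # alternate even/odd neighbor pairs
        last <- if (ladder$cyclic) N else N - 1L
        first <- if (parity > last) integer(0) else seq(parity, last, by = 2L)
        for (wi in first) {
          wj <- if (wi == N) 1L else wi + 1L
          ri <- which(perm == wi); rj <- which(perm == wj)
          delta <- ladder_exchange_delta(ladder,
                                         X[ri, , drop = FALSE],
                                         X[rj, , drop = FALSE],
                                         wi, wj, config$beta)
          accepted <- delta <= 0 || stats::runif(1) < exp(-delta)
          if (accepted) { perm[ri] <- wj; perm[rj] <- wi }
          log_rows[[length(log_rows) + 1L]] <-
            data.frame(time = done * config$timestep, i = wi, j = wj,
                       delta = delta, accepted = accepted)
        }
      }
    }
  })
  # assemble: replica-major sample set with window labels per sample
  n_rec_tot <- sum(vapply(rec_chunks, function(r)
    if (is.null(r)) 0L else dim(r)[1], integer(1)))
  coords <- matrix(NA_real_, n_rec_tot * N, surface$d)
  windows <- integer(n_rec_tot * N)
  times <- numeric(n_rec_tot * N)
  for (r in seq_len(N)) {
    off <- (r - 1L) * n_rec_tot
    pos <- 0L
    for (epoch in seq_along(rec_chunks)) {
      rc <- rec_chunks[[epoch]]
      if (is.null(rc) || dim(rc)[1] == 0L) next
      nr <- dim(rc)[1]
      coords[off + pos + seq_len(nr), ] <- matrix(rc[, r, ], nr, surface$d)
      windows[off + pos + seq_len(nr)] <- win_chunks[[epoch]][, r]
      pos <- pos + nr
    }
    times[off + seq_len(n_rec_tot)] <-
      config$timestep * config$stride * seq_len(n_rec_tot)
  }
  samples <- sample_set(coords, times,
                        replica = rep(seq_len(N), each = n_rec_tot),
                        window = windows)
  ex_log <- if (length(log_rows)) do.call(rbind, log_rows)
            else data.frame(time = numeric(), i = integer(), j = integer(),
                            delta = numeric(), accepted = logical())
  list(samples = samples, exchange_log = ex_log, occupancy = occupancy)
}

#' Sample and block accounting for a BEUS analysis
#'
#' Bookkeeping of how many configurations and bootstrap blocks a run
#' yields after discarding equilibration: retained_samples = n_replicas *
#' (t_total - t_discard) / sample_interval and n_blocks = n_replicas *
#' (t_total - t_discard) / block_size.  For example, 150 replicas of 50 ns
#' with the first 10 ns discarded, sampled every 5 ps, give 1,200,000
#' configurations; a 10 ns block size gives 600 blocks.
#'
#' @param n_replicas number of replicas/windows.
#' @param t_total simulated time per replica.
#' @param t_discard equilibration time discarded from each replica
#'   (<= t_total).
#' @param sample_interval time between retained configurations.
#' @param block_size block duration for block bootstrapping.
#' @return list with `retained_samples` and `n_blocks`.
#' @export
beus_accounting <- function(n_replicas, t_total, t_discard, sample_interval,
                            block_size) {
  stopifnot(n_replicas >= 1, t_total > 0, t_discard >= 0,
            sample_interval > 0, block_size > 0)
  if (t_discard > t_total) stop("t_discard must not exceed t_total")
  retained <- t_total - t_discard
  divides <- function(interval, what) {
    ratio <- retained / interval
    if (abs(ratio - round(ratio)) > 1e-9 * max(1, ratio))
      stop(what, " (", interval, ") must divide the retained duration (",
           retained, "); truncate explicitly before accounting")
    round(ratio)
  }
  list(retained_samples = n_replicas * divides(sample_interval, "sample_interval"),
       n_blocks = n_replicas * divides(block_size, "block_size"))
}
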