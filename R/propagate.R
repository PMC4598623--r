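#' Configuration for the overdamped-Langevin propagator
#'
#' Euler--Maruyama integration of Brownian dynamics in collective-variable
#' space: d zeta = -beta D grad(U) dt + sqrt(2 D dt) dW.  Reduced units
#' (k_B T = 1 at beta = 1) throughout.
#'
#' @param timestep integration step (reduced time units), > 0.
#' @param diffusion diffusion coefficient, scalar or one per dimension, > 0.
#' @param beta inverse temperature, > 0.
#' @param steps number of integration steps.
#' @param stride record every `stride`-th step.
#' @param seed mandatory RNG seed; all noise flows from it.
#' @param noise_scale multiplier on the thermal noise amplitude; 0 gives the
#'   deterministic zero-temperature drift limit (mobility beta * D kept
#'   fixed).
#' @param metropolis logical; Metropolis-adjust each step (MALA), making the
#'   sampled stationary distribution exactly Boltzmann at any timestep.  Off
#'   by default (plain Euler--Maruyama); turn on when an analysis is
#'   sensitive to the O(timestep) discretization bias of the unadjusted
#'   propagator.
#' @param guard divergence guard: integration aborts if any coordinate
#'   exceeds this magnitude.
#' @return list of class `brownian_config`.
#' @export
brownian_config <- function(timestep, diffusion = 1, beta = 1, steps,
                            stride = 1L, seed, noise_scale = 1,
                            metropolis = FALSE, guard = 1e6) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  stopifnot(timestep > 0, all(diffusion > 0), beta > 0, steps >= 1,
            stride >= 1, noise_scale >= 0)
  structure(list(timestep = timestep, diffusion = diffusion, beta = beta,
                 steps = as.integer(steps), stride = as.integer(stride),
                 seed = as.integer(seed), noise_scale = noise_scale,
                 metropolis = isTRUE(metropolis), guard = guard),
            class = "brownian_config")
}

# Evaluate code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so package randomness never leaks.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Harmonic bias potential
#'
#' U(zeta) = 1/2 sum_j k_j (zeta_j - c_j)^2, the umbrella restraint used for
#' window ladders and string-image restraints.
#'
#' @param center bias center (length-d numeric).
#' @param k force constant, scalar or per-dimension, >= 0.
#' @return object of class `bias` with vectorized `energy` and `grad`.
#' @export
harmonic_bias <- function(center, k) {
  center <- as.numeric(center)
  k <- rep_len(as.numeric(k), length(center))
  stopifnot(all(k >= 0))
  structure(list(
    center = center, k = k,
    energy = function(X) {
      X <- as_row_matrix(X, length(center))
      0.5 * rowSums(sweep(sweep(X, 2, center), 2, sqrt(k), `*`)^2)
    },
    grad = function(X) {
      X <- as_row_matrix(X, length(center))
      sweep(sweep(X, 2, center), 2, k, `*`)
    }), class = "bias")
}

#' Sample sets from propagation
#'
#' Container for per-replica collective-variable time series with window
#' labels and bias provenance; times are strictly increasing within a
#' replica.
#'
#' @param coords n x d matrix of CV samples.
#' @param time sample times.
#' @param replica integer replica label per sample.
#' @param window integer window/image label per sample.
#' @return object of class `sample_set`.
#' @export
sample_set <- function(coords, time, replica = 1L, window = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  replica <- rep_len(as.integer(replica), n)
  window <- rep_len(as.integer(window), n)
  time <- rep_len(as.numeric(time), n)
  for (r in unique(replica)) {
    tr <- time[replica == r]
    if (length(tr) > 1L && any(diff(tr) <= 0))
      stop("times must be strictly increasing within replica ", r)
  }
  structure(list(coords = coords, time = time, replica = replica,
                 window = window, d = ncol(coords)),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set>", nrow(x$coords), "samples, d =", x$d, ",",
      length(unique(x$replica)), "replica(s),",
      length(unique(x$window)), "window(s)\n")
  invisible(x)
}

# One Euler-Maruyama step for a matrix of walkers. grad_fn(X) must return an
# n x d matrix of total-potential gradients.
em_step <- function(X, grad_fn, dt, Dvec, beta, noise_scale) {
  G <- grad_fn(X)
  drift <- -beta * sweep(G, 2, Dvec, `*`) * dt
  if (noise_scale > 0) {
    noise <- matrix(stats::rnorm(length(X)), nrow(X), ncol(X))
    noise <- sweep(noise, 2, sqrt(2 * Dvec * dt), `*`) * noise_scale
    X + drift + noise
  } else X + drift
}

# Inner integration loop over a fixed number of steps, drawing from the
# CURRENT RNG stream (callers own the seed).  Optional per-walker harmonic
# restraint centers (matrix, one row per walker) with force constant k
# (scalar or matrix matching centers).  With metropolis = TRUE each
# Euler-Maruyama proposal is accepted/rejected by the MALA criterion, so
# the chain samples exp(-beta U_total) exactly at any timestep.  Returns
# the final coordinates and, if stride is given, the recorded frames as an
# [n_rec, m, d] array.
em_run <- function(X, surface, steps, dt, Dvec, beta, noise_scale, guard,
                   biases = list(), centers = NULL, k = 0, stride = NULL,
                   label = "walker", metropolis = FALSE) {
  kmat <- NULL
  if (!is.null(centers))
    kmat <- if (is.matrix(k)) k
            else matrix(rep_len(k, ncol(X)), nrow(X), ncol(X), byrow = TRUE)
  grad_fn <- function(Z) {
    G <- surface$grad(Z)
    for (b in biases) G <- G + b$grad(Z)
    if (!is.null(centers)) G <- G + (Z - centers) * kmat
    G
  }
  energy_fn <- function(Z) {
    E <- surface$energy(Z)
    for (b in biases) E <- E + b$energy(Z)
    if (!is.null(centers)) E <- E + 0.5 * rowSums((Z - centers)^2 * kmat)
    E
  }
  if (metropolis && noise_scale != 1)
    stop("metropolis adjustment requires noise_scale = 1")
  n_rec <- if (is.null(stride)) 0L else steps %/% stride
  rec <- if (n_rec > 0L) array(NA_real_, c(n_rec, nrow(X), ncol(X))) else NULL
  irec <- 0L
  m <- nrow(X)
  Dm <- matrix(Dvec, m, ncol(X), byrow = TRUE)
  for (step in seq_len(steps)) {
    if (!metropolis) {
      X <- em_step(X, grad_fn, dt, Dvec, beta, noise_scale)
    } else {
      mean_x <- X - beta * Dm * grad_fn(X) * dt
      Y <- mean_x + matrix(stats::rnorm(length(X)), m, ncol(X)) *
        sqrt(2 * Dm * dt)
      mean_y <- Y - beta * Dm * grad_fn(Y) * dt
      log_a <- -beta * (energy_fn(Y) - energy_fn(X)) -
        rowSums((X - mean_y)^2 / (4 * Dm * dt)) +
        rowSums((Y - mean_x)^2 / (4 * Dm * dt))
      acc <- log(stats::runif(m)) < log_a
      X[acc, ] <- Y[acc, ]
    }
    if (any(!is.finite(X)) || any(abs(X) > guard)) {
      bad <- which(rowSums(!is.finite(X) | abs(X) > guard) > 0)[1]
      stop("trajectory diverged at step ", step, " (", label, " ", bad,
           " beyond guard ", guard, ")")
    }
    if (n_rec > 0L && step %% stride == 0L) {
      irec <- irec + 1L
      rec[irec, , ] <- X
    }
  }
  list(X = X, rec = rec)
}

#' Propagate Brownian dynamics on a surface with bias potentials
#'
#' Integrates one or more walkers under the total potential
#' surface + sum(biases) and records every `stride`-th step.  Deterministic
#' given the seed in `config`.
#'
#' @param start length-d start point, or m x d matrix of starts (one walker
#'   per row).
#' @param surface a [potential_surface()].
#' @param biases list of `bias` objects applied to every walker (may be
#'   empty).
#' @param config a [brownian_config()].
#' @return a [sample_set()] with one replica per walker.
#' @export
propagate <- function(start, surface, biases = list(), config) {
  stopifnot(inherits(config, "brownian_config"))
  if (inherits(biases, "bias")) biases <- list(biases)
  X <- as_row_matrix(start, surface$d)
  m <- nrow(X)
  Dvec <- rep_len(config$diffusion, surface$d)
  n_rec <- config$steps %/% config$stride
  res <- with_seed(config$seed,
    em_run(X, surface, config$steps, config$timestep, Dvec, config$beta,
           config$noise_scale, config$guard, biases = biases,
           stride = config$stride, label = "replica",
           metropolis = isTRUE(config$metropolis)))
  out <- res$rec
  times <- config$timestep * config$stride * seq_len(n_rec)
  coords <- do.call(rbind, lapply(seq_len(m), function(r)
    matrix(out[, r, ], n_rec, surface$d)))
  sample_set(coords = coords,
             time = rep(times, m),
             replica = rep(seq_len(m), each = n_rec),
             window = rep(seq_len(m), each = n_rec))
}

#' Crooks-consistent Gaussian work samples
#'
#' Draws forward and reverse nonequilibrium work values from the unique
#' equal-variance Gaussian pair satisfying the Crooks fluctuation relation
#' with free-energy difference `dG`: forward ~ N(dG + beta sigma^2 / 2,
#' sigma^2) and reverse ~ N(-dG + beta sigma^2 / 2, sigma^2) (reverse works
#' measured on the reverse process, so -W_r overlaps the forward
#' distribution around dG).
#'
#' @param dG free-energy difference (energy units).
#' @param sigma standard deviation of each work distribution, > 0.
#' @param n_forward,n_reverse sample counts.
#' @param beta inverse temperature.
#' @param seed RNG seed.
#' @return a [work_set()].
#' @export
make_crooks_work_samples <- function(dG, sigma, n_forward, n_reverse,
                                     beta = 1, seed) {
  stopifnot(sigma > 0, n_forward >= 1, n_reverse >= 1)
  if (missing(seed)) stop("an explicit seed is required")
  diss <- beta * sigma^2 / 2
  with_seed(seed, {
    wf <- stats::rnorm(n_forward, mean = dG + diss, sd = sigma)
    wr <- stats::rnorm(n_reverse, mean = -dG + diss, sd = sigma)
    work_set(forward = wf, reverse = wr, beta = beta)
  })
}
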