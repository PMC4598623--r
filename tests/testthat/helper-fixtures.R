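# Shared fixtures, all generated in code.

# Ideal alpha-helix C-alpha trace: radius 2.3 A, rise 1.5 A, 100 deg/residue.
ideal_helix <- function(n = 12, radius = 2.3, rise = 1.5, twist = 100) {
  i <- seq_len(n) - 1
  ang <- i * twist * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), rise * i)
}

rotate_coords <- function(coords, axis, angle, shift = c(0, 0, 0)) {
  R <- quat_to_matrix(axis_angle_quat(axis, angle))
  sweep(coords %*% t(R), 2, shift, `+`)
}

random_quat <- function() axis_angle_quat(stats::rnorm(3), stats::runif(1, 0.05, pi - 0.05))

# Exact Boltzmann samples from the curved-valley surface restricted to the
# upper half plane (polar factorization; inverse-CDF on dense grids).
valley_samples <- function(n, seed, surface = preset_surface("curved_valley_2d"),
                           beta = 1, full_circle = FALSE) {
  h <- surface$params$h; k_r <- surface$params$k_r; R <- surface$params$R
  set.seed(seed)
  top <- if (full_circle) 2 * pi else pi
  phig <- seq(0, top, length.out = 8001)
  dphi <- phig[2] - phig[1]
  phi <- sample(phig, n, replace = TRUE,
                prob = exp(-beta * surface$info$valley_profile(phig))) +
    stats::runif(n, -0.5, 0.5) * dphi
  rg <- seq(max(1e-3, R - 0.6), R + 0.6, length.out = 4001)
  dr <- rg[2] - rg[1]
  r <- sample(rg, n, replace = TRUE,
              prob = rg * exp(-beta * 0.5 * k_r * (rg - R)^2)) +
    stats::runif(n, -0.5, 0.5) * dr
  cbind(r * cos(phi), r * sin(phi))
}

# AR(1) series with given coefficient, exact stationary start.
ar1_series <- function(n, phi, sd = 1, seed = 1) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
  eps <- stats::rnorm(n - 1, 0, sd)
  for (i in 2:n) x[i] <- phi * x[i - 1] + eps[i - 1]
  x
}

# 1D harmonic surface (0.5 * kappa * x^2) used across reweighting tests.
harmonic_surface <- function(kappa = 1) {
  potential_surface("harmonic_1d", 1L,
                    energy = function(X) 0.5 * kappa * X[, 1]^2,
                    grad = function(X) kappa * X,
                    params = list(kappa = kappa),
                    info = list(domain = list(c(-8, 8))))
}

flat_surface_2d <- function() {
  potential_surface("flat_2d", 2L,
                    energy = function(X) rep(0, nrow(X)),
                    grad = function(X) X * 0,
                    info = list(domain = list(c(-10, 10), c(-10, 10))))
}
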