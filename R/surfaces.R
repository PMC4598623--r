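#' Analytic model potential surfaces
#'
#' A `potential_surface` bundles vectorized energy and gradient evaluators on
#' R^d with documented analytic structure (minima, saddle points, valley
#' curves), standing in for the effective potential G(zeta) that governs the
#' coarse-variable dynamics of a real system.  All surfaces use reduced units
#' (k_B T = 1 at beta = 1).
#'
#' @param name surface identifier.
#' @param d dimension.
#' @param energy function taking an n x d matrix, returning n energies.
#' @param grad function taking an n x d matrix, returning an n x d gradient.
#' @param params named list of parameters.
#' @param info named list of analytic features (minima, saddles, ...).
#' @return object of class `potential_surface`.
#' @export
potential_surface <- function(name, d, energy, grad, params = list(),
                              info = list()) {
  structure(list(name = name, d = d, energy = energy, grad = grad,
                 params = params, info = info),
            class = "potential_surface")
}

#' @export
print.potential_surface <- function(x, ...) {
  cat("<potential_surface>", x$name, " d =", x$d, "\n")
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params),
                           sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

as_row_matrix <- function(X, d) {
  if (is.null(dim(X))) X <- matrix(X, ncol = d, byrow = length(X) > d)
  if (ncol(X) != d) stop("coordinates must have ", d, " columns")
  X
}

# polar helpers for the circular-valley surfaces; guard the origin where the
# angular gradient is singular
polar_parts <- function(X) {
  r <- sqrt(X[, 1]^2 + X[, 2]^2)
  r <- pmax(r, 1e-10)
  list(r = r, phi = atan2(X[, 2], X[, 1]),
       cx = X[, 1] / r, cy = X[, 2] / r)
}

#' Built-in toy surfaces
#'
#' * `double_well_1d`: U(x) = b (x^2 - 1)^2; minima at x = +/-1 with U = 0,
#'   barrier of height exactly `b` at x = 0.
#' * `curved_valley_2d`: U = k_r/2 (r - R)^2 + (h/2)(1 - cos 2 phi) in polar
#'   coordinates; the valley curve is the circle r = R (the upper semicircle
#'   connects the two minima at (+/-R, 0) over a barrier of height h at
#'   (0, R)); the gradient normal to the circle vanishes on it by
#'   construction.
#' * `cyclic_channels_2d`: U = k_r/2 (r - R)^2 + V(phi) with
#'   V(phi) = h (1 - cos 2 phi) - (2 B / 3) sin^3(phi) - h + h
#'   = h - h cos 2 phi - (2 B / 3) sin^3 phi: two basins at phi = 0 and pi
#'   (V = 0) connected by two distinct channels, with barriers
#'   2 h - 2 B / 3 at phi = +pi/2 and 2 h + 2 B / 3 at phi = -pi/2; the
#'   planted inter-channel barrier gap is exactly 4 B / 3.  The four
#'   stationary points sit exactly at (R, 0), (0, R), (-R, 0), (0, -R).
#'
#' Defaults: `double_well_1d(b = 3)`; `curved_valley_2d(R = 1, k_r = 100,
#' h = 2)`; `cyclic_channels_2d(R = 1, k_r = 100, h = 2.75, B = 2.625)`
#' (barrier gap 3.5 reduced units, echoing a substrate-lowered transition
#' barrier).
#'
#' @param name one of `"double_well_1d"`, `"curved_valley_2d"`,
#'   `"cyclic_channels_2d"`.
#' @param params optional named list overriding the defaults above.
#' @return a [potential_surface()] whose `info` documents minima, saddles,
#'   valley curve and (where applicable) barrier heights.
#' @export
preset_surface <- function(name, params = list()) {
  switch(name,
    double_well_1d = {
      p <- utils::modifyList(list(b = 3), params)
      b <- p$b
      potential_surface(
        name, 1L,
        energy = function(X) { X <- as_row_matrix(X, 1); b * (X[, 1]^2 - 1)^2 },
        grad = function(X) { X <- as_row_matrix(X, 1)
          matrix(4 * b * X[, 1] * (X[, 1]^2 - 1), ncol = 1) },
        params = p,
        info = list(minima = rbind(-1, 1), saddles = rbind(0),
                    barrier = b, domain = list(c(-2.2, 2.2))))
    },
    curved_valley_2d = {
      p <- utils::modifyList(list(R = 1, k_r = 100, h = 2), params)
      R <- p$R; k_r <- p$k_r; h <- p$h
      potential_surface(
        name, 2L,
        energy = function(X) { X <- as_row_matrix(X, 2); pp <- polar_parts(X)
          0.5 * k_r * (pp$r - R)^2 + 0.5 * h * (1 - cos(2 * pp$phi)) },
        grad = function(X) { X <- as_row_matrix(X, 2); pp <- polar_parts(X)
          dr <- k_r * (pp$r - R); dphi <- h * sin(2 * pp$phi)
          cbind(dr * pp$cx - dphi * pp$cy / pp$r,
                dr * pp$cy + dphi * pp$cx / pp$r) },
        params = p,
        info = list(
          minima = rbind(c(R, 0), c(-R, 0)), saddles = rbind(c(0, R), c(0, -R)),
          barrier = h,
          valley = function(t) cbind(R * cos(pi * t), R * sin(pi * t)),
          valley_profile = function(phi) 0.5 * h * (1 - cos(2 * phi)),
          domain = list(c(-R - 1, R + 1), c(-R - 1, R + 1))))
    },
    cyclic_channels_2d = {
      p <- utils::modifyList(list(R = 1, k_r = 100, h = 2.75, B = 2.625),
                             params)
      R <- p$R; k_r <- p$k_r; h <- p$h; B <- p$B
      if (B >= 2 * h)
        stop("cyclic_channels_2d requires B < 2 h for exactly four stationary points")
      V <- function(phi) h - h * cos(2 * phi) - (2 * B / 3) * sin(phi)^3
      dV <- function(phi) 2 * h * sin(2 * phi) - 2 * B * sin(phi)^2 * cos(phi)
      potential_surface(
        name, 2L,
        energy = function(X) { X <- as_row_matrix(X, 2); pp <- polar_parts(X)
          0.5 * k_r * (pp$r - R)^2 + V(pp$phi) },
        grad = function(X) { X <- as_row_matrix(X, 2); pp <- polar_parts(X)
          dr <- k_r * (pp$r - R); dphi <- dV(pp$phi)
          cbind(dr * pp$cx - dphi * pp$cy / pp$r,
                dr * pp$cy + dphi * pp$cx / pp$r) },
        params = p,
        info = list(
          minima = rbind(c(R, 0), c(-R, 0)),
          saddles = rbind(c(0, R), c(0, -R)),
          stationary_points = rbind(c(R, 0), c(0, R), c(-R, 0), c(0, -R)),
          barrier_low = 2 * h - 2 * B / 3,
          barrier_high = 2 * h + 2 * B / 3,
          barrier_gap = 4 * B / 3,
          valley = function(t) cbind(R * cos(2 * pi * t), R * sin(2 * pi * t)),
          valley_profile = V,
          domain = list(c(-R - 1, R + 1), c(-R - 1, R + 1))))
    },
    stop("unknown preset surface '", name, "'")
  )
}

#' Reference free-energy profile by direct quadrature
#'
#' Computes the exact PMF of a toy surface along one coordinate (or along the
#' polar angle for the circular surfaces) by numerical quadrature of
#' exp(-beta U) over the orthogonal coordinate, anchored to 0 at its minimum.
#' A Richardson-style self-check repeats the quadrature at twice the
#' resolution; the maximum absolute discrepancy is returned and an error is
#' raised if it exceeds `tol`.
#'
#' @param surface a [potential_surface()] with d <= 2.
#' @param axis integer column index to keep, or `"angle"` for the polar angle
#'   of a circular surface (the profile is then a function of phi; arc length
#'   is `R * phi`).
#' @param grid vector of evaluation points for the kept coordinate.
#' @param beta inverse temperature (reduced units).
#' @param n_quad number of quadrature nodes for the integrated coordinate.
#' @param tol acceptable discrepancy between the two resolutions.
#' @return list with `grid`, `G` (anchored), and `self_check` (max
#'   discrepancy between resolutions).
#' @export
analytic_pmf <- function(surface, axis = 1, grid, beta = 1,
                         n_quad = 512, tol = 1e-3) {
  if (surface$d == 1L) {
    G <- surface$energy(matrix(grid, ncol = 1))
    return(list(grid = grid, G = G - min(G), self_check = 0))
  }
  if (surface$d != 2L) stop("analytic_pmf supports d <= 2")
  one_res <- function(nq) {
    if (identical(axis, "angle")) {
      R <- surface$params$R
      r_nodes <- seq(max(1e-6, R - 0.9), R + 0.9, length.out = nq)
      dr <- r_nodes[2] - r_nodes[1]
      vapply(grid, function(phi) {
        X <- cbind(r_nodes * cos(phi), r_nodes * sin(phi))
        # polar area element: integrate exp(-beta U) r dr at fixed phi
        -log(sum(exp(-beta * surface$energy(X)) * r_nodes) * dr) / beta
      }, numeric(1))
    } else {
      keep <- as.integer(axis)
      other <- if (keep == 1L) 2L else 1L
      dom <- surface$info$domain[[other]]
      y_nodes <- seq(dom[1], dom[2], length.out = nq)
      dy <- y_nodes[2] - y_nodes[1]
      vapply(grid, function(x) {
        X <- matrix(0, nq, 2); X[, keep] <- x; X[, other] <- y_nodes
        -log(sum(exp(-beta * surface$energy(X))) * dy) / beta
      }, numeric(1))
    }
  }
  G1 <- one_res(n_quad); G2 <- one_res(2L * n_quad)
  G1 <- G1 - min(G1); G2 <- G2 - min(G2)
  err <- max(abs(G1 - G2))
  if (err > tol)
    stop("analytic_pmf quadrature did not converge: resolutions differ by ",
         format(err), " (> tol = ", tol, ")")
  list(grid = grid, G = G2, self_check = err)
}
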