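test_that("preset surfaces expose their documented analytic structure", {
  dw <- preset_surface("double_well_1d", list(b = 2.5))
  expect_equal(dw$energy(matrix(0)) - dw$energy(matrix(1)), 2.5)
  expect_equal(dw$energy(matrix(-1)), 0)
  cv <- preset_surface("curved_valley_2d")
  tgrid <- seq(0.02, 0.98, length.out = 40)
  pts <- cv$info$valley(tgrid)
  g <- cv$grad(pts)
  # gradient normal to the arc (radial component) vanishes on the valley
  radial <- rowSums(g * pts) / sqrt(rowSums(pts^2))
  expect_lt(max(abs(radial)), 1e-8)
  expect_error(preset_surface("no_such_surface"), "unknown")
})

test_that("surface gradients match central differences", {
  set.seed(6)
  for (nm in c("double_well_1d", "curved_valley_2d", "cyclic_channels_2d")) {
    s <- preset_surface(nm)
    X <- matrix(runif(20 * s$d, -1.4, 1.4), 20, s$d)
    if (s$d == 2) X <- X[rowSums(X^2) > 0.04, , drop = FALSE]  # polar guard
    g <- s$grad(X)
    for (j in seq_len(s$d)) {
      h <- 1e-6
      Xp <- X; Xp[, j] <- Xp[, j] + h
      Xm <- X; Xm[, j] <- Xm[, j] - h
      num <- (s$energy(Xp) - s$energy(Xm)) / (2 * h)
      expect_equal(g[, j], num, tolerance = 1e-5 * max(1, max(abs(num))))
    }
  }
})

test_that("cyclic_channels_2d stationary points sit at the documented spots", {
  cc <- preset_surface("cyclic_channels_2d")
  expect_equal(cc$info$barrier_high - cc$info$barrier_low,
               cc$info$barrier_gap)
  for (i in seq_len(nrow(cc$info$stationary_points))) {
    p0 <- cc$info$stationary_points[i, ] + c(0.05, -0.04)
    sol <- stats::optim(p0, fn = function(z) sum(cc$grad(matrix(z, 1, 2))^2),
                        method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 500))
    expect_equal(sol$par, cc$info$stationary_points[i, ], tolerance = 1e-6)
  }
})

test_that("propagator is deterministic given the seed and honors zero noise", {
  flat <- flat_surface_2d()
  cfg0 <- brownian_config(timestep = 0.01, steps = 50, stride = 5, seed = 2,
                          noise_scale = 0)
  tr <- propagate(c(0.3, -0.2), flat, config = cfg0)
  expect_true(all(abs(sweep(tr$coords, 2, c(0.3, -0.2))) < 1e-14))
  cfg <- brownian_config(timestep = 0.01, steps = 200, stride = 2, seed = 42)
  t1 <- propagate(c(0, 0), flat, config = cfg)
  t2 <- propagate(c(0, 0), flat, config = cfg)
  expect_identical(t1$coords, t2$coords)
})

test_that("propagator samples the Boltzmann distribution of harmonic totals", {
  hs <- harmonic_surface(1)
  cfg <- brownian_config(timestep = 0.01, steps = 1e5, stride = 1, seed = 7)
  tr <- propagate(0, hs, config = cfg)
  expect_equal(var(tr$coords[, 1]), 1, tolerance = 0.05)
  # harmonic bias at the same center halves the variance (stiffness 2)
  tr2 <- propagate(0, hs, biases = list(harmonic_bias(0, 1)), config = cfg)
  expect_equal(var(tr2$coords[, 1]), 0.5, tolerance = 0.05)
  # KS distance to the analytic Gaussian, thinned to soften autocorrelation
  x <- tr$coords[seq(1, 1e5, by = 10), 1]
  ks <- suppressWarnings(stats::ks.test(x, "pnorm", 0, 1))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("Metropolis-adjusted propagation removes the timestep bias", {
  hs <- harmonic_surface(100)   # stiff: plain EM at dt = 1e-3 inflates var ~5%
  cfg <- brownian_config(timestep = 1e-3, steps = 2e5, stride = 2, seed = 3,
                         metropolis = TRUE)
  tr <- propagate(0, hs, config = cfg)
  expect_equal(var(tr$coords[, 1]), 1 / 100, tolerance = 0.03)
})

test_that("divergent trajectories error with the offending step", {
  steep <- potential_surface("steep", 1L,
                             energy = function(X) -50 * X[, 1]^2,
                             grad = function(X) -100 * X)
  cfg <- brownian_config(timestep = 0.1, steps = 100, stride = 1, seed = 1,
                         guard = 1e3)
  expect_error(propagate(1, steep, config = cfg), "diverged at step")
})

test_that("analytic_pmf honors separability and self-checks resolution", {
  sep <- potential_surface("sep", 2L,
    energy = function(X) 0.5 * X[, 1]^2 + 2 * (X[, 2]^2 - 1)^2,
    grad = function(X) cbind(X[, 1], 8 * X[, 2] * (X[, 2]^2 - 1)),
    info = list(domain = list(c(-5, 5), c(-2.5, 2.5))))
  grid <- seq(-2, 2, length.out = 41)
  pm <- analytic_pmf(sep, axis = 1, grid = grid)
  expect_lt(max(abs(pm$G - 0.5 * grid^2)), 1e-6)
  expect_lt(pm$self_check, 1e-4)
  dw <- preset_surface("double_well_1d")
  pm1 <- analytic_pmf(dw, grid = grid)
  expect_equal(pm1$G, dw$energy(matrix(grid)) - 0, tolerance = 1e-12)
  # curved valley along arc: profile equals the constructed valley depth
  cv <- preset_surface("curved_valley_2d")
  phi <- seq(0.05, pi - 0.05, length.out = 31)
  pm2 <- analytic_pmf(cv, axis = "angle", grid = phi)
  prof <- cv$info$valley_profile(phi)
  expect_lt(max(abs(pm2$G - (prof - min(prof)))), 1e-4)
})

test_that("Crooks-consistent work fixture has the constructed moments", {
  ws0 <- make_crooks_work_samples(1.5, 1e-4, 50, 50, seed = 2)
  expect_equal(mean(ws0$forward), 1.5, tolerance = 1e-4)
  expect_equal(mean(ws0$reverse), -1.5, tolerance = 1e-4)
  ws <- make_crooks_work_samples(2, 2, 2e4, 2e4, beta = 1, seed = 9)
  expect_lt(abs(mean(ws$forward) - 4), 3 * 2 / sqrt(2e4))
  expect_lt(abs(mean(ws$reverse) - 0), 3 * 2 / sqrt(2e4))
  # Crooks relation: log[P_f(W) / P_r(-W)] linear in W, slope beta,
  # intercept -beta * dG (regression on binned log-density ratio)
  big <- make_crooks_work_samples(2, 2, 1e5, 1e5, beta = 1, seed = 10)
  br <- seq(-2, 8, by = 0.25)
  hf <- hist(big$forward, breaks = c(-Inf, br, Inf), plot = FALSE)$counts
  hr <- hist(-big$reverse, breaks = c(-Inf, br, Inf), plot = FALSE)$counts
  mids <- (br[-1] + br[-length(br)]) / 2
  cf <- hf[-c(1, length(hf))]; cr <- hr[-c(1, length(hr))]
  keep <- cf >= 25 & cr >= 25
  y <- log(cf[keep] / cr[keep])
  fit <- stats::lm(y ~ mids[keep])
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.05)
  expect_equal(unname(stats::coef(fit)[1]), -2, tolerance = 0.15)
})
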