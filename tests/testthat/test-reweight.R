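# Shared harmonic-toy BEUS data: surface 0.5 * x^2, nine windows, k = 4.
harmonic_beus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      hs <- harmonic_surface(1)
      lad <- window_ladder(matrix(seq(-2, 2, length.out = 9), ncol = 1), k = 4)
      cfg <- brownian_config(timestep = 0.02, steps = 2e4, stride = 2,
                             seed = 3, metropolis = TRUE)
      bb <- run_beus(lad, hs, cfg, exchange_interval = Inf)
      cache <<- list(samples = bb$samples, ladder = lad,
                     centers = seq(-2, 2, length.out = 9))
    }
    cache
  }
})

test_that("WHAM recovers the Gaussian-convolution free energies", {
  hb <- harmonic_beus()
  F <- wham_solve(hb$samples, hb$ladder)
  expect_true(F$converged)
  expect_equal(F$F[1], 0)
  # F(c) = 0.5 * kappa k / (kappa + k) * c^2 + const, kappa = 1, k = 4
  Fan <- 0.5 * 4 / 5 * hb$centers^2
  Fan <- Fan - Fan[1]
  # 3 standard errors at 10^4 samples/window (se ~ 0.02 with g ~ 2)
  expect_lt(max(abs(F$F - Fan)), 0.06)
})

test_that("identical windows give equal free energies", {
  hs <- harmonic_surface(1)
  lad <- window_ladder(rbind(0, 1e-9 + 0 * 1, 2e-9), k = 2)
  lad$centers[] <- c(0, 1e-9, 2e-9)
  cfg <- brownian_config(timestep = 0.02, steps = 4000, stride = 2, seed = 6)
  bb <- run_beus(lad, hs, cfg, exchange_interval = Inf)
  F <- wham_solve(bb$samples, lad)
  expect_lt(max(abs(F$F)), 1e-6)
})

test_that("flat landscape gives equal window free energies by symmetry", {
  flat <- potential_surface("flat1", 1L,
                            energy = function(X) rep(0, nrow(X)),
                            grad = function(X) X * 0)
  lad <- window_ladder(matrix(seq(-1, 1, length.out = 5), ncol = 1), k = 4)
  cfg <- brownian_config(timestep = 0.02, steps = 2e4, stride = 2, seed = 10,
                         metropolis = TRUE)
  bb <- run_beus(lad, flat, cfg, exchange_interval = Inf)
  F <- wham_solve(bb$samples, lad)
  expect_lt(max(abs(F$F)), 0.05)
})

test_that("the two WHAM solution routes agree", {
  hb <- harmonic_beus()
  Fa <- wham_solve(hb$samples, hb$ladder, method = "self-consistent")
  Fb <- wham_solve(hb$samples, hb$ladder, method = "iterative-weights")
  expect_lt(max(abs(Fa$F - Fb$F)), 1e-7)
})

test_that("sample weights are normalized, gauge-invariant and Boltzmann-consistent", {
  hb <- harmonic_beus()
  F <- wham_solve(hb$samples, hb$ladder)
  w <- sample_weights(hb$samples, hb$ladder, F)
  expect_equal(sum(w$w), 1, tolerance = 1e-9)
  expect_true(all(w$w >= 0))
  # additive gauge: shifting all F leaves normalized weights unchanged
  w2 <- sample_weights(hb$samples, hb$ladder, F$F + 3.7, beta = 1)
  expect_equal(w$w, w2$w, tolerance = 1e-12)
  # weighted histogram reproduces exp(-beta G) for G = x^2/2
  x <- hb$samples$coords[, 1]
  br <- seq(-2.2, 2.2, by = 0.2)
  pm <- suppressWarnings(project_pmf(w, x, kernel = "histogram", breaks = br))
  ok <- !pm$mask & pm$count > 200
  expect_lt(max(abs(pm$G[ok] - (pm$mid[ok]^2 / 2 - min(pm$mid[ok]^2 / 2)))),
            0.12)
  # duplicated window invariance
  lad2 <- window_ladder(rbind(hb$ladder$centers, hb$ladder$centers[9, ] + 1e-9),
                        k = 4)
  ss <- hb$samples
  half <- ss$window == 9 & seq_along(ss$window) %% 2 == 0
  ss$window[half] <- 10L
  F2 <- wham_solve(ss, lad2)
  expect_lt(abs(F2$F[10] - F2$F[9]), 0.05)
})

test_that("single-window weights are equal at the window center", {
  # all samples at the bias center: every bias energy identical (zero)
  ss <- sample_set(matrix(rep(0, 50), ncol = 1), 1:50, 1L, 1L)
  U <- matrix(0, 50, 1)
  F1 <- wham_solve(ss, U)
  w1 <- sample_weights(ss, U, F1)
  expect_true(all(abs(w1$w - 1 / 50) < 1e-12))
})

test_that("Gibbs posterior agrees with WHAM and any draw reconstructs the PMF", {
  hb <- harmonic_beus()
  F <- wham_solve(hb$samples, hb$ladder)
  g <- gibbs_reweight(hb$samples, hb$ladder, n_draws = 150, burn_in = 100,
                      seed = 5)
  expect_true(all(abs(g$F_mean - F$F) <= 2 * pmax(g$F_sd, 1e-12) + 1e-9))
  # one posterior draw is itself a usable reweighting
  x <- hb$samples$coords[, 1]
  br <- seq(-2, 2, by = 0.25)
  pm <- suppressWarnings(project_pmf(g$w_last, x, breaks = br))
  ok <- !pm$mask & pm$count > 300
  ref <- pm$mid[ok]^2 / 2
  expect_lt(max(abs(pm$G[ok] - (ref - min(ref)))), 0.25)
  # different seeds give statistically identical posterior means
  g2 <- gibbs_reweight(hb$samples, hb$ladder, n_draws = 150, burn_in = 100,
                       seed = 6)
  z <- abs(g$F_mean[-1] - g2$F_mean[-1]) /
    sqrt(g$F_sd[-1]^2 / 150 + g2$F_sd[-1]^2 / 150)
  expect_lt(stats::median(z), 6)   # same posterior up to Monte-Carlo error
})

test_that("degenerate single-window Gibbs posterior is anchored and constant", {
  ss <- sample_set(matrix(rnorm(200), ncol = 1), 1:200, 1L, 1L)
  g <- gibbs_reweight(ss, matrix(0, 200, 1), n_draws = 50, burn_in = 10,
                      seed = 3)
  expect_true(all(g$F_draws == 0))
})

test_that("PMF projection handles kernels, masking and flat landscapes", {
  set.seed(30)
  xi <- runif(1e5, 0, 1)
  w <- rep(1 / 1e5, 1e5)
  pm <- project_pmf(w, xi, breaks = seq(0, 1, by = 0.1))
  expect_lt(max(pm$G, na.rm = TRUE) - min(pm$G, na.rm = TRUE), 0.08)
  # gaussian kernel on a quadratic well
  xg <- rnorm(20000)
  pg <- project_pmf(rep(1, 20000), xg, kernel = "gaussian",
                    breaks = seq(-2, 2, by = 0.2))
  ref <- pg$mid^2 / 2
  expect_lt(max(abs(pg$G - (ref - min(ref))), na.rm = TRUE), 0.15)
  # masked bins: samples only on [0, 1], grid wider
  xi2 <- runif(20000); w2 <- rep(1 / 20000, 20000)
  pmk <- suppressWarnings(project_pmf(w2, xi2, breaks = seq(-1, 2, by = 0.1)))
  expect_true(any(pmk$mask))
  expect_true(all(is.na(pmk$G[pmk$mask])))
  expect_error(project_pmf(w2, xi2 + 100, breaks = seq(0, 1, by = 0.1)),
               "no samples")
  # 2D histogram with occupancy mask
  xy <- cbind(runif(5000), runif(5000))
  p2 <- suppressWarnings(project_pmf(rep(1, 5000), xy,
                                     breaks = list(seq(0, 2, by = 0.25),
                                                   seq(0, 1, by = 0.25))))
  expect_identical(p2$dim, 2L)
  expect_true(all(p2$mask[5:8, ]))   # unsampled x > 1 half
})

test_that("stiff-spring correction deconvolves quadratic free energies", {
  s <- seq(-1, 1, length.out = 21)
  # constant F: zero correction
  g0 <- stiff_spring_correct(rep(2, 21), s, k = 50)
  expect_equal(g0$correction, rep(0, 21))
  expect_equal(g0$G, rep(0, 21))
  # quadratic F from a known G = 0.5 kappa s^2 sampled with stiff spring k:
  # kappa_eff = kappa k / (kappa + k); correction recovers kappa
  kappa <- 2
  for (k in c(200, 1000)) {
    k_eff <- kappa * k / (kappa + k)
    F <- 0.5 * k_eff * s^2
    g <- stiff_spring_correct(F, s, k = k)
    ref <- 0.5 * kappa * s^2
    expect_lt(max(abs(g$G - (ref - min(ref)))) / max(ref), 0.01)
  }
  # correction magnitude scales as 1/k
  ks <- c(20, 200, 2000)
  mags <- vapply(ks, function(k) {
    k_eff <- kappa * k / (kappa + k)
    max(abs(stiff_spring_correct(0.5 * k_eff * s^2, s, k = k)$correction))
  }, numeric(1))
  fit <- stats::lm(log(mags) ~ log(ks))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.05)
  expect_error(stiff_spring_correct(1:4, 1:4, k = 10), "at least 5")
})

test_that("cyclic stiff-spring derivatives wrap around the seam", {
  n <- 24
  s <- 2 * pi * (0:(n - 1)) / n
  F <- cos(s)   # smooth periodic profile
  g <- stiff_spring_correct(F, s, k = 1e6, cyclic = TRUE)
  # at huge k the correction vanishes and G is F re-anchored
  expect_lt(max(abs(g$G - (F - min(F)))), 1e-4)
  expect_lt(max(abs(g$correction)), 1e-5)
})

test_that("state and barrier tables do planted arithmetic with quadrature errors", {
  G <- c(0, 1, 2, 1, 0.5, 3, 2)   # minima at 1, 5(ish); maxima at 3, 6
  st <- state_free_energies(G, states = c(A = 1, B = 5),
                            barriers = c(TS = 6),
                            se = rep(0.3, 7))
  expect_equal(st$dG$dG[st$dG$from == "A" & st$dG$to == "B"], 0.5)
  expect_equal(st$dG$se[st$dG$from == "A" & st$dG$to == "A"], 0)
  expect_equal(st$dG$se[st$dG$from == "A" & st$dG$to == "B"],
               sqrt(0.09 + 0.09))
  expect_equal(st$barrier$height[st$barrier$state == "A"], 3)
  ex <- find_extrema(G)
  expect_true(5 %in% ex$minima && 1 %in% ex$minima)
  expect_true(6 %in% ex$maxima)
  expect_error(state_free_energies(G, states = c(A = 99)), "out of range")
  # planted profile with minima of depth 0 and 2 at known positions
  G2 <- c(0, 3, 2, 3.5, 1)
  st2 <- state_free_energies(G2, states = c(m1 = 1, m2 = 3))
  expect_equal(st2$dG$dG[st2$dG$from == "m1" & st2$dG$to == "m2"], 2)
})
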