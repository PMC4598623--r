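test_that("autocorrelation time matches closed forms", {
  set.seed(44)
  # white noise
  expect_lt(abs(autocorrelation_time(rnorm(1e5))), 0.05)
  # AR(1), tau = phi / (1 - phi) = 9 at phi = 0.9
  x <- ar1_series(1e5, 0.9, seed = 12)
  expect_equal(autocorrelation_time(x), 9, tolerance = 0.15)
  # constant series: zero with flag
  tz <- autocorrelation_time(rep(3, 200))
  expect_identical(as.numeric(tz), 0)
  expect_true(attr(tz, "zero_variance"))
  expect_error(autocorrelation_time(rnorm(50)), "at least 100")
})

test_that("duplicating every sample doubles tau plus one half", {
  # rho_k of the duplicated series: rho'_{2k} = rho_k and
  # rho'_{2k+1} ~ (rho_k + rho_{k+1})/2, so tau' = 2 tau + 1/2 exactly for
  # AR(1) in expectation; check against the ACF algebra on a long series
  x <- ar1_series(5e4, 0.8, seed = 7)
  dup <- rep(x, each = 2)
  t1 <- autocorrelation_time(x)
  t2 <- autocorrelation_time(dup)
  expect_equal(t2, 2 * t1 + 0.5, tolerance = 0.05)
})

test_that("statistical inefficiency follows g = 1 + 2 tau / lag", {
  expect_equal(statistical_inefficiency(0, 1), 1)
  expect_equal(statistical_inefficiency(5, 5), 3)
  expect_gte(statistical_inefficiency(runif(1, 0, 100), runif(1, 0.1, 10)), 1)
  # effective sample size N/g predicts the variance of the AR(1) mean
  phi <- 0.9; n <- 2e4
  means <- vapply(1:60, function(s) mean(ar1_series(n, phi, seed = s)),
                  numeric(1))
  tau <- phi / (1 - phi)
  g <- statistical_inefficiency(tau, 1)
  sd_pred <- sqrt(1 / (1 - phi^2)) * sqrt(g / n)
  expect_equal(sd(means), sd_pred, tolerance = 0.2)
})

test_that("block bootstrap reproduces the iid closed form and degenerate cases", {
  set.seed(9)
  x <- rnorm(4000, mean = 2, sd = 3)
  bb <- block_bootstrap(x, block_length = 1, n_boot = 2000,
                        bayesian = FALSE, seed = 4)
  expect_equal(bb$estimate, 2, tolerance = 0.1)
  expect_equal(bb$sd, 3 / sqrt(4000), tolerance = 0.05)
  # Bayesian and classical agree on iid data
  bb2 <- block_bootstrap(x, block_length = 1, n_boot = 2000,
                         bayesian = TRUE, seed = 4)
  expect_equal(bb2$sd, bb$sd, tolerance = 0.1)
  # identical blocks: zero spread
  const <- rep(1:4, times = 25)   # every block of length 4 identical
  bc <- block_bootstrap(const, block_length = 4, n_boot = 100, seed = 2)
  expect_equal(bc$sd, 0, tolerance = 1e-12)
  expect_error(block_bootstrap(rnorm(10), block_length = 3, n_boot = 10,
                               seed = 1), "divide")
  expect_error(block_bootstrap(rnorm(10), block_length = 10, n_boot = 10,
                               seed = 1), "at least 2 blocks")
})

test_that("block bootstrap handles autocorrelation like the analytic variance", {
  phi <- 0.9; n <- 2e4
  x <- ar1_series(n, phi, seed = 31)
  tau <- phi / (1 - phi)
  g <- 1 + 2 * tau
  sd_true <- sqrt(1 / (1 - phi^2)) * sqrt(g / n)
  big <- block_bootstrap(x, block_length = 500, n_boot = 600, seed = 5)
  expect_equal(big$sd, sd_true, tolerance = 0.25)
  tiny <- block_bootstrap(x, block_length = 1, n_boot = 600, seed = 6)
  expect_lt(tiny$sd, 0.5 * sd_true)   # 1-sample blocks underestimate
  # bootstrap sd non-decreasing in block size (up to noise)
  sds <- vapply(c(1, 10, 100, 500), function(b)
    block_bootstrap(x, block_length = b, n_boot = 400, seed = 7)$sd,
    numeric(1))
  expect_true(all(diff(sds) > -0.1 * sds[-1]))
})

test_that("bootstrap is seed-deterministic and blocks respect replicas", {
  x <- rnorm(400)
  rep_id <- rep(1:4, each = 100)
  b1 <- block_bootstrap(x, rep_id, block_length = 50, n_boot = 50, seed = 11)
  b2 <- block_bootstrap(x, rep_id, block_length = 50, n_boot = 50, seed = 11)
  expect_identical(b1, b2)
  expect_identical(b1$n_blocks, 8L)
  expect_error(block_bootstrap(x, rep(1:3, c(100, 150, 150)),
                               block_length = 70, n_boot = 10, seed = 1),
               "divide")
})

test_that("path averages weight, mask and inflate errors correctly", {
  set.seed(50)
  img <- rep(1:4, each = 500)
  vals <- rnorm(2000, mean = img)
  pa <- path_average(vals, img)
  expect_equal(pa$mean, 1:4, tolerance = 0.15)
  # constant quantity: sd exactly 0
  pc <- path_average(rep(7, 2000), img)
  expect_true(all(pc$mean == 7) && all(pc$sd == 0))
  # uniform weights equal unweighted
  pw <- path_average(vals, img, weights = rep(0.5, 2000))
  expect_equal(pw$mean, pa$mean, tolerance = 1e-12)
  # statistical inefficiency inflates the reported se by sqrt(g)
  pg <- path_average(vals, img, g = 4)
  expect_equal(pg$se, 2 * pa$se, tolerance = 1e-12)
  # starved image masked with warning
  expect_warning(ps <- path_average(c(vals, 0), c(img, 5L)), "fewer than 2")
  expect_true(is.na(ps$mean[5]))
})

test_that("planted AR(1) per-image noise is recovered within the g/N contract", {
  phi <- 0.8; sigma_marg <- 2
  g <- 1 + 2 * phi / (1 - phi)
  reported <- vapply(1:30, function(s) {
    x <- ar1_series(2000, phi, sd = sigma_marg * sqrt(1 - phi^2), seed = 100 + s)
    path_average(x, rep(1L, 2000), g = g)$se
  }, numeric(1))
  observed <- vapply(1:30, function(s)
    mean(ar1_series(2000, phi, sd = sigma_marg * sqrt(1 - phi^2),
                    seed = 100 + s)), numeric(1))
  expect_equal(mean(reported), sd(observed), tolerance = 0.2)
})
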