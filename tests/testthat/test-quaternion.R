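test_that("quaternion construction enforces unit norm and canonical hemisphere", {
  q <- quaternion(-1, 0, 0, 0)
  expect_equal(unclass(q), c(1, 0, 0, 0))   # hemisphere flip
  q2 <- quaternion(0, -0.6, 0, -0.8)
  expect_true(q2[2] > 0)                    # first nonzero positive at q0 = 0
  expect_error(quaternion(1, 1, 0, 0), "unit norm")
  expect_equal(sum(unclass(random_quat())^2), 1, tolerance = 1e-12)
})

test_that("best-fit quaternion reproduces identity and forced rotations", {
  ref <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, -1, -1) / sqrt(3))
  expect_equal(unclass(best_fit_quaternion(ref, ref)), c(1, 0, 0, 0),
               tolerance = 1e-9)
  frame <- rotate_coords(ref, c(0, 0, 1), pi / 2)
  expect_equal(unclass(best_fit_quaternion(frame, ref)),
               c(sqrt(2) / 2, 0, 0, sqrt(2) / 2), tolerance = 1e-9)
})

test_that("best-fit quaternion recovers random rotations to 1e-8", {
  set.seed(11)
  for (i in 1:50) {
    ref <- matrix(rnorm(24), 8, 3)
    q <- random_quat()
    R <- quat_to_matrix(q)
    frame <- rotate_coords(ref, rnorm(3), runif(1, 0, pi),
                           shift = rnorm(3))
    frame <- sweep(ref %*% t(R), 2, rnorm(3), `+`)   # known rotation + shift
    qr <- best_fit_quaternion(frame, ref)
    expect_lt(max(abs(quat_to_matrix(qr) - R)), 1e-8)
    # self-consistency: applying the fitted rotation superimposes the frames
    a <- sweep(ref, 2, colMeans(ref))
    b <- sweep(frame, 2, colMeans(frame))
    expect_lt(max(abs(a %*% t(quat_to_matrix(qr)) - b)), 1e-8)
  }
})

test_that("degenerate and mismatched inputs are rejected", {
  line <- cbind(1:5, 0, 0)
  ref <- matrix(rnorm(15), 5, 3)
  expect_error(best_fit_quaternion(line, ref), "degenerate")
  expect_error(best_fit_quaternion(ref[1:4, ], ref), "same number")
})

test_that("geodesic distance matches closed forms and is sign-invariant", {
  q90 <- axis_angle_quat(c(0, 0, 1), pi / 2)
  expect_equal(geodesic_distance(q90, q90), 0)
  expect_equal(geodesic_distance(c(1, 0, 0, 0), q90), pi / 4,
               tolerance = 1e-12)
  set.seed(4)
  for (i in 1:20) {
    P <- unclass(random_quat()); Q <- unclass(random_quat())
    d <- geodesic_distance(P, Q)
    expect_gte(d, 0); expect_lte(d, pi / 2 + 1e-12)
    expect_equal(geodesic_distance(-P, Q), d)
    expect_equal(geodesic_distance(P, -Q), d)
    expect_equal(geodesic_distance(Q, P), d)
  }
  expect_error(geodesic_distance(c(1, 1, 0, 0), q90), "unit quaternion")
})

test_that("small rotations: Omega^2 matches |P - Q|^2", {
  P <- c(1, 0, 0, 0)
  Q <- unclass(axis_angle_quat(c(1, 0, 0), 0.02))
  om <- geodesic_distance(P, Q)
  expect_equal(om, 0.01, tolerance = 1e-8)
  # |P - Q|^2 = 2 - 2 cos(Omega): agreement with Omega^2 is fourth order,
  # relative difference Omega^2 / 12 ~ 1e-5 at Omega = 0.01
  expect_equal(sum((P - Q)^2), om^2, tolerance = 1e-5)
})

test_that("geodesic distance is a pseudo-metric on the sign quotient", {
  set.seed(21)
  for (i in 1:1000) {
    a <- unclass(random_quat()); b <- unclass(random_quat())
    cc <- unclass(random_quat())
    expect_lte(geodesic_distance(a, cc),
               geodesic_distance(a, b) + geodesic_distance(b, cc) + 1e-9)
  }
})

test_that("orientation restraint energy and gradient are consistent", {
  q90 <- axis_angle_quat(c(0, 1, 0), pi / 2)
  r0 <- orientation_restraint(q90, q90, 5)
  expect_equal(r0$energy, 0)
  expect_equal(r0$gradient, rep(0, 4))
  r <- orientation_restraint(axis_angle_quat(c(0, 0, 1), pi / 2),
                             c(1, 0, 0, 0), k = 2)
  expect_equal(r$energy, pi^2 / 16, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    Q <- unclass(random_quat()); Qc <- unclass(random_quat())
    k <- runif(1, 0.5, 5)
    g <- orientation_restraint(Q, Qc, k)$gradient
    en <- function(x) orientation_restraint(x / sqrt(sum(x^2)), Qc, k)$energy
    num <- vapply(1:4, function(j) {
      h <- 1e-6; e <- rep(0, 4); e[j] <- h
      (en(Q + e) - en(Q - e)) / (2 * h)
    }, numeric(1))
    expect_equal(g, num, tolerance = 1e-5 * max(1, max(abs(num))))
  }
})

test_that("restraint agrees with the small-angle surrogate for Omega < 0.1", {
  set.seed(13)
  for (i in 1:50) {
    Qc <- unclass(random_quat())
    ax <- rnorm(3); th <- runif(1, 0.005, 0.19)   # Omega = th/2 < 0.1
    dq <- unclass(axis_angle_quat(ax, th))
    # rotate Qc by a small rotation: quaternion product dq * Qc
    Q <- c(dq[1] * Qc[1] - sum(dq[2:4] * Qc[2:4]),
           dq[1] * Qc[2:4] + Qc[1] * dq[2:4] +
             c(dq[3] * Qc[4] - dq[4] * Qc[3],
               dq[4] * Qc[2] - dq[2] * Qc[4],
               dq[2] * Qc[3] - dq[3] * Qc[2]))
    k <- runif(1, 0.5, 4)
    r <- orientation_restraint(Q, Qc, k)
    if (r$omega < 0.1 && r$omega > 1e-4) {
      Qh <- if (sum(Q * Qc) < 0) -Q else Q
      surrogate <- 0.5 * k * sum((Qh - Qc)^2)
      expect_equal(r$energy, surrogate, tolerance = 0.05)
    }
  }
})

test_that("quaternion PCA recovers planted variance structure", {
  set.seed(5)
  n <- 4000
  # one-direction ensemble
  dir1 <- c(1, 0, 0, 0, 0, 0)
  ens1 <- outer(rnorm(n), dir1)
  p1 <- quaternion_pca(ens1)
  expect_false(p1$zero_variance)
  expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-9)
  # zero variance
  p0 <- quaternion_pca(matrix(1, 10, 6))
  expect_true(p0$zero_variance)
  # two planted factors with variances 4:1
  d1 <- c(1, 0, 0, 0, 0, 0); d2 <- c(0, 1, 0, 0, 0, 0)
  ens <- outer(rnorm(n, sd = 2), d1) + outer(rnorm(n, sd = 1), d2)
  p <- quaternion_pca(ens)
  expect_equal(p$variance_fraction[1], 0.8, tolerance = 0.04)
  expect_equal(p$variance_fraction[2], 0.2, tolerance = 0.04)
  # orthonormal components, fractions sum to 1, projections reconstruct
  expect_equal(crossprod(p$components), diag(6), tolerance = 1e-9)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  rec <- p$projections %*% t(p$components)
  expect_equal(rec, sweep(ens, 2, p$center), tolerance = 1e-9)
})
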