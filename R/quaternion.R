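#' Unit quaternions for rigid-body orientation
#'
#' A `quat` is a numeric 4-vector (q0, q1, q2, q3) of unit norm representing a
#' rigid rotation: q0 = cos(theta/2) and (q1, q2, q3) the rotation axis scaled
#' by sin(theta/2).  Because Q and -Q encode the same rotation, every `quat`
#' is stored on the canonical hemisphere: q0 >= 0, and if q0 == 0 the first
#' nonzero component is positive.  All downstream operations (geodesic
#' distances, restraints, PCA on vector parts) are therefore well defined on
#' the quotient by sign.
#'
#' @param q0,q1,q2,q3 quaternion components, dimensionless.
#' @param tol tolerance on the unit-norm invariant.
#' @return an object of class `quat` (numeric length 4).
#' @examples
#' quaternion(1, 0, 0, 0)                    # identity rotation
#' quaternion(sqrt(0.5), 0, 0, sqrt(0.5))    # 90 degrees about z
#' @export
quaternion <- function(q0, q1, q2, q3, tol = 1e-9) {
  q <- c(q0, q1, q2, q3)
  if (length(q) != 4L || !is.numeric(q) || any(!is.finite(q)))
    stop("quaternion requires four finite numeric components")
  nrm <- sqrt(sum(q^2))
  if (abs(nrm - 1) > 1e-6)
    stop("quaternion components must have unit norm (got |Q| = ",
         format(nrm), ")")
  q <- q / nrm
  if (abs(sum(q^2) - 1) > tol) stop("quaternion normalization failed")
  q <- canonical_hemisphere(q)
  structure(as.numeric(q), class = "quat")
}

# Map q to the canonical hemisphere: q0 >= 0; at q0 == 0, first nonzero
# component positive.  Idempotent; safe on raw numeric 4-vectors.
canonical_hemisphere <- function(q) {
  lead <- q[which(abs(q) > 1e-12)[1]]
  if (is.na(lead)) stop("zero quaternion cannot be normalized")
  if (lead < 0) q <- -q
  q
}

#' @export
print.quat <- function(x, ...) {
  cat(sprintf("<quat> (%.6f, %.6f, %.6f, %.6f)  angle = %.4f rad\n",
              x[1], x[2], x[3], x[4], 2 * acos(min(1, abs(x[1])))))
  invisible(x)
}

is_quat <- function(x) inherits(x, "quat")

as_quat <- function(x) {
  if (is_quat(x)) return(x)
  quaternion(x[1], x[2], x[3], x[4])
}

#' Rotation matrix of a unit quaternion
#'
#' @param q a [quaternion()].
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
quat_to_matrix <- function(q) {
  q <- as_quat(q)
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), q0^2 - q1^2 + q2^2 - q3^2, 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), q0^2 - q1^2 - q2^2 + q3^2),
    nrow = 3, byrow = TRUE)
}

#' Quaternion from axis and angle
#'
#' @param axis rotation axis (3-vector, normalized internally).
#' @param angle rotation angle in radians.
#' @export
axis_angle_quat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  quaternion(cos(angle / 2), axis[1] * sin(angle / 2),
             axis[2] * sin(angle / 2), axis[3] * sin(angle / 2))
}

#' Best-fit (minimum-RMSD) orientation quaternion
#'
#' Computes the unit quaternion of the optimal rotation superimposing a
#' reference coordinate set onto a frame, i.e. the rotation R(Q) minimizing
#' sum_i |frame_i - R ref_i|^2 after both sets are centered on their
#' centroids.  Uses the 4x4 symmetric key-matrix eigenvalue method: Q is the
#' eigenvector of the largest eigenvalue.
#'
#' @param frame n x 3 matrix of coordinates (Angstrom).
#' @param reference n x 3 matrix, same atom order as `frame`.
#' @return a [quaternion()] on the canonical hemisphere.
#' @examples
#' ref <- rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(-1,-1,-1)/sqrt(3))
#' R90 <- quat_to_matrix(axis_angle_quat(c(0,0,1), pi/2))
#' best_fit_quaternion(ref %*% t(R90), ref)  # ~ (sqrt(2)/2, 0, 0, sqrt(2)/2)
#' @export
best_fit_quaternion <- function(frame, reference) {
  frame <- as_coord_matrix(frame, "frame")
  reference <- as_coord_matrix(reference, "reference")
  if (nrow(frame) != nrow(reference))
    stop("frame and reference must contain the same number of points (",
         nrow(frame), " vs ", nrow(reference), ")")
  if (nrow(frame) < 3L)
    stop("at least 3 points are required for an orientation fit")
  check_not_degenerate(frame, "frame")
  check_not_degenerate(reference, "reference")
  a <- sweep(reference, 2, colMeans(reference))
  b <- sweep(frame, 2, colMeans(frame))
  S <- crossprod(a, b)  # S[u, v] = sum_i ref_iu * frame_iv
  K <- key_matrix(S)
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1L]
  quaternion(q[1], q[2], q[3], q[4])
}

# Horn's 4x4 key matrix from the 3x3 coordinate correlation matrix.
key_matrix <- function(S) {
  matrix(c(
    S[1,1] + S[2,2] + S[3,3], S[2,3] - S[3,2], S[3,1] - S[1,3], S[1,2] - S[2,1],
    S[2,3] - S[3,2], S[1,1] - S[2,2] - S[3,3], S[1,2] + S[2,1], S[3,1] + S[1,3],
    S[3,1] - S[1,3], S[1,2] + S[2,1], -S[1,1] + S[2,2] - S[3,3], S[2,3] + S[3,2],
    S[1,2] - S[2,1], S[3,1] + S[1,3], S[2,3] + S[3,2], -S[1,1] - S[2,2] + S[3,3]),
    nrow = 4, byrow = TRUE)
}

as_coord_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L || !is.numeric(x) || anyNA(x))
    stop(what, " must be a numeric n x 3 coordinate matrix")
  x
}

# Collinear or coincident point sets have no unique best-fit rotation.
check_not_degenerate <- function(x, what) {
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = 0, nv = 0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1e-30) || sv[1] < 1e-12)
    stop("degenerate (collinear or coincident) point set in group '", what, "'")
  invisible(TRUE)
}

#' Geodesic distance between two orientation quaternions
#'
#' Omega(P, Q) = arccos(|P . Q|), the geodesic separation of the two
#' orientations on the unit sphere quotient by sign; lies in [0, pi/2] and is
#' invariant under negating either argument.  For small separations
#' Omega^2 ~ |P - Q|^2 (with both on the same hemisphere).
#'
#' @param P,Q unit quaternions (`quat` or numeric 4-vectors).
#' @return separation angle in radians.
#' @export
geodesic_distance <- function(P, Q) {
  P <- check_unit4(P, "P"); Q <- check_unit4(Q, "Q")
  d <- abs(sum(P * Q))
  acos(min(1, d))
}

check_unit4 <- function(q, what, tol = 1e-6) {
  q <- as.numeric(unclass(q))
  if (length(q) != 4L) stop(what, " must be a length-4 quaternion")
  if (abs(sum(q^2) - 1) > tol)
    stop(what, " is not a unit quaternion (|", what, "|^2 = ",
         format(sum(q^2)), ")")
  q
}

#' Harmonic orientation restraint
#'
#' Energy 0.5 * k * Omega(Q, Qc)^2 restraining an orientation quaternion Q to
#' the center Qc, with its gradient with respect to the four components of Q.
#' The gradient is taken on the normalized inner product, so it is tangent to
#' the unit sphere and vanishes as Omega -> 0.  The inner product is clamped
#' away from +/-1 (and 0) by 1e-12 to keep the arccos derivative finite;
#' below Omega = 1e-6 the Omega/sin(Omega) prefactor is replaced by its
#' series limit 1.
#'
#' @param Q orientation quaternion being restrained.
#' @param Qc restraint center (time-independent here; a moving center is just
#'   a sequence of calls).
#' @param k force constant, energy / rad^2; must be >= 0.
#' @return list with `energy`, `gradient` (length 4, d energy / d Q
#'   components), and `omega` (the separation used).
#' @export
orientation_restraint <- function(Q, Qc, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  Qv <- check_unit4(Q, "Q"); Pc <- check_unit4(Qc, "Qc")
  d <- sum(Pc * Qv)
  s <- if (d >= 0) 1 else -1
  ad <- min(abs(d), 1 - 1e-12)
  omega <- acos(ad)
  energy <- 0.5 * k * omega^2
  sin_om <- sqrt(max(1 - ad^2, 1e-24))
  ratio <- if (omega < 1e-6) 1 else omega / sin_om
  # d(0.5 k Omega^2)/dQ with Omega = arccos(|P.Q| / |Q|), evaluated at |Q|=1
  grad <- -k * ratio * s * (Pc - d * Qv)
  list(energy = energy, gradient = grad, omega = omega)
}

#' Principal-component analysis of quaternion vector parts
#'
#' Projects an ensemble of orientation-quaternion sets onto the principal
#' components of their vector parts (q1, q2, q3 of each quaternion,
#' hemisphere-aligned at construction), the QPC coordinates used to visualize
#' global conformational changes.
#'
#' @param ensemble numeric matrix, one row per sample, columns the
#'   concatenated vector parts (3 per quaternion).
#' @param weights optional nonnegative sample weights (normalized internally);
#'   default unweighted.
#' @return list with `components` (orthonormal columns), `variance_fraction`,
#'   `projections` (samples x components, of centered data), `center`, and
#'   `zero_variance` flag.  If the ensemble has no variance the fractions and
#'   projections are not meaningful numbers and `zero_variance` is `TRUE`.
#' @export
quaternion_pca <- function(ensemble, weights = NULL) {
  ensemble <- as.matrix(ensemble)
  if (nrow(ensemble) < 2L) stop("quaternion_pca requires at least 2 samples")
  if (is.null(weights)) weights <- rep(1, nrow(ensemble))
  if (length(weights) != nrow(ensemble) || any(weights < 0))
    stop("weights must be nonnegative, one per sample")
  w <- weights / sum(weights)
  center <- colSums(ensemble * w)
  xc <- sweep(ensemble, 2, center)
  cv <- crossprod(xc * sqrt(w), xc * sqrt(w))  # weighted covariance (biased)
  tot <- sum(diag(cv))
  if (tot < 1e-18) {
    return(list(components = NULL, variance_fraction = NULL,
                projections = NULL, center = center, zero_variance = TRUE))
  }
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  list(components = e$vectors,
       variance_fraction = vals / sum(vals),
       projections = xc %*% e$vectors,
       center = center,
       zero_variance = FALSE)
}
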