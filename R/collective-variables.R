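#' Best-fit RMSD between two coordinate sets
#'
#' Minimum root-mean-square deviation over rigid rotations after centering
#' both sets, computed from the largest eigenvalue of the quaternion key
#' matrix: RMSD^2 = (|a|^2 + |b|^2 - 2 lambda_max) / n.
#'
#' @param frame,reference n x 3 coordinate matrices (Angstrom).
#' @return RMSD in Angstrom.
#' @export
fit_rmsd <- function(frame, reference) {
  frame <- as_coord_matrix(frame, "frame")
  reference <- as_coord_matrix(reference, "reference")
  if (nrow(frame) != nrow(reference))
    stop("frame and reference must contain the same number of points")
  a <- sweep(reference, 2, colMeans(reference))
  b <- sweep(frame, 2, colMeans(frame))
  K <- key_matrix(crossprod(a, b))
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lmax) / nrow(frame)
  sqrt(max(msd, 0))
}

#' Difference-of-RMSD collective variable
#'
#' DeltaRMSD = RMSD(frame, refA) - RMSD(frame, refB), both best-fit, a signed
#' progress variable between two reference conformations (e.g. the
#' inward-facing and outward-facing states of a transporter).  Antisymmetric
#' under swapping the references.
#'
#' @param frame coordinates being scored (n x 3, Angstrom).
#' @param refA,refB reference coordinate sets, same point count as `frame`.
#' @return DeltaRMSD in Angstrom (negative near refA, positive near refB).
#' @export
delta_rmsd <- function(frame, refA, refB) {
  frame <- as_coord_matrix(frame, "frame")
  refA <- as_coord_matrix(refA, "refA")
  refB <- as_coord_matrix(refB, "refB")
  if (nrow(frame) != nrow(refA) || nrow(frame) != nrow(refB))
    stop("frame, refA and refB must all contain the same number of points")
  fit_rmsd(frame, refA) - fit_rmsd(frame, refB)
}

#' Substrate position along the membrane normal
#'
#' Z_P: the z component of the vector from the centroid of an anchor atom
#' group (lumenal C-alpha atoms) to the substrate position, plus a constant
#' offset C chosen so that Z_P approximately measures the substrate height
#' relative to the protein center of mass.
#'
#' @param substrate_position 3-vector, Angstrom.
#' @param anchor n x 3 matrix of anchor-group coordinates.
#' @param C constant offset in Angstrom (default 0); see
#'   [calibrate_z_offset()] for the a-posteriori estimator.
#' @return Z_P in Angstrom.
#' @export
substrate_z <- function(substrate_position, anchor, C = 0) {
  anchor <- as_coord_matrix(anchor, "anchor")
  if (nrow(anchor) < 1L) stop("anchor group must not be empty")
  substrate_position <- as.numeric(substrate_position)
  if (length(substrate_position) != 3L)
    stop("substrate_position must be a 3-vector")
  (substrate_position[3] - mean(anchor[, 3])) + C
}

#' Calibrate the Z_P offset against a target centroid
#'
#' Estimates the constant C a posteriori as the mean, over a sample of
#' frames, of the z distance between the full-reference centroid (e.g. the
#' protein center of mass) and the anchor centroid, so that anchor-based Z_P
#' matches target-based z on average.
#'
#' @param anchors list of anchor coordinate matrices, one per frame.
#' @param targets list of full-reference coordinate matrices, same length.
#' @return list with `C` (mean offset, Angstrom) and `sd` (its spread over
#'   frames).
#' @export
calibrate_z_offset <- function(anchors, targets) {
  if (length(anchors) != length(targets) || length(anchors) < 1L)
    stop("anchors and targets must be non-empty lists of equal length")
  dz <- vapply(seq_along(anchors), function(i) {
    a <- as_coord_matrix(anchors[[i]], "anchor")
    t <- as_coord_matrix(targets[[i]], "target")
    mean(a[, 3]) - mean(t[, 3])
  }, numeric(1))
  list(C = mean(dz), sd = stats::sd(dz))
}

# Dominant principal axis of a point cloud, oriented so its projection on the
# N-to-C end-to-end vector is positive.  Errors on isotropic clouds, where
# the axis is not defined.
helix_roll_axis <- function(coords, what = "helix") {
  coords <- as_coord_matrix(coords, what)
  if (nrow(coords) < 4L)
    stop(what, " needs at least 4 C-alpha points for an axis fit")
  xc <- sweep(coords, 2, colMeans(coords))
  e <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  if (e$values[1] < 1e-12 || e$values[2] / e$values[1] > 0.9)
    stop("degenerate principal axes for ", what,
         ": point cloud has no dominant direction")
  ax <- e$vectors[, 1L]
  ends <- coords[nrow(coords), ] - coords[1L, ]   # N -> C end-to-end
  if (sum(ax * ends) < 0) ax <- -ax
  ax
}

#' Interhelical roll-axis angle
#'
#' Angle between the roll axes of two helices, each the dominant principal
#' axis of its C-alpha cloud oriented along the N-to-C direction.  The
#' orientation step makes parallel and antiparallel arrangements
#' distinguishable (0 vs 180 degrees).
#'
#' @param helixA,helixB C-alpha coordinate matrices in N-to-C order
#'   (>= 4 points each).
#' @return angle in degrees, in [0, 180].
#' @export
interhelical_angle <- function(helixA, helixB) {
  a <- helix_roll_axis(helixA, "helixA")
  b <- helix_roll_axis(helixB, "helixB")
  d <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, d))) * 180 / pi
}

#' Read atom groups from a PDB file
#'
#' Minimal read-only selection of ATOM/HETATM coordinates via bio3d.  Groups
#' are specified as a list (or JSON file) of selections with fields `chain`,
#' `resid_start`, `resid_end` and `name` (atom name, e.g. "CA").
#'
#' @param pdb_file path to a PDB file.
#' @param groups named list of selections, or path to a JSON file containing
#'   one.
#' @return named list of n x 3 coordinate matrices (Angstrom).
#' @export
read_pdb_groups <- function(pdb_file, groups) {
  if (is.character(groups) && length(groups) == 1L)
    groups <- jsonlite::read_json(groups, simplifyVector = TRUE)
  pdb <- bio3d::read.pdb(pdb_file)
  out <- lapply(groups, function(g) {
    sel <- bio3d::atom.select(pdb,
                              chain = g$chain,
                              resno = seq(g$resid_start, g$resid_end),
                              elety = g$name, verbose = FALSE)
    if (length(sel$atom) == 0L)
      stop("selection matched no atoms in ", pdb_file)
    m <- matrix(pdb$xyz[sel$xyz], ncol = 3, byrow = TRUE)
    colnames(m) <- c("x", "y", "z")
    m
  })
  names(out) <- names(groups)
  out
}
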