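#' Transition pathways as strings of images
#'
#' A `string_path` is an ordered set of image centers in collective-variable
#' space, optionally cyclic, with an arc-length table.  It is the common
#' currency of the string-method drivers and the post-hoc string method.
#'
#' @param images N x d matrix of image centers (rows ordered along the path).
#' @param cyclic logical; `TRUE` for a closed transition cycle (image N
#'   neighbors image 1).
#' @param names optional component names.
#' @param scales optional positive metric scales, one per component (see
#'   [cv_metric()]).
#' @return object of class `string_path`.
#' @export
string_path <- function(images, cyclic = FALSE, names = NULL, scales = NULL) {
  images <- as.matrix(images)
  if (nrow(images) < 3L) stop("a string path needs at least 3 images")
  seg <- sqrt(rowSums((images[-1L, , drop = FALSE] -
                       images[-nrow(images), , drop = FALSE])^2))
  if (any(seg < 1e-12)) stop("consecutive image centers must be distinct")
  if (!is.null(names)) colnames(images) <- names
  arc <- c(0, cumsum(seg))
  structure(list(images = images, cyclic = isTRUE(cyclic), arc = arc,
                 scales = scales),
            class = "string_path")
}

#' @export
print.string_path <- function(x, ...) {
  cat("<string_path>", nrow(x$images), "images, d =", ncol(x$images),
      if (x$cyclic) "(cyclic)" else "(open)",
      sprintf("length %.4f\n", path_length(x)))
  invisible(x)
}

# Total arc length (chord approximation), including the closing segment for
# cyclic paths.
path_length <- function(path) {
  L <- path$arc[length(path$arc)]
  if (path$cyclic)
    L <- L + sqrt(sum((path$images[1L, ] - path$images[nrow(path$images), ])^2))
  L
}

#' Diagonal metric on collective-variable space
#'
#' Distances in CV space are weighted Euclidean: d(x, y)^2 =
#' sum_j (s_j (x_j - y_j))^2, where the strictly positive scales s_j
#' prioritize components (e.g. put quaternion components and Angstrom-valued
#' coordinates on a common footing).
#'
#' @param scales strictly positive scale per component.
#' @return numeric scale vector of class `cv_metric`.
#' @export
cv_metric <- function(scales) {
  scales <- as.numeric(scales)
  if (any(scales <= 0)) stop("metric scales must be strictly positive")
  structure(scales, class = "cv_metric")
}

# Apply metric scales to a coordinate matrix (identity when metric is NULL).
apply_metric <- function(X, metric) {
  if (is.null(metric)) return(X)
  sweep(X, 2, as.numeric(metric), `*`)
}

# Squared metric distances from every row of X to every row of C:
# n x m matrix.
cross_dist2 <- function(X, C, metric = NULL) {
  X <- apply_metric(as.matrix(X), metric)
  C <- apply_metric(as.matrix(C), metric)
  nx <- rowSums(X^2); nc <- rowSums(C^2)
  d2 <- outer(nx, nc, `+`) - 2 * X %*% t(C)
  pmax(d2, 0)
}

# Bernstein basis matrix for a degree-n Bezier at parameter values t.
bernstein_matrix <- function(t, n) {
  i <- 0:n
  logc <- lchoose(n, i)
  B <- matrix(0, length(t), n + 1L)
  for (j in seq_along(i)) {
    k <- i[j]
    # handle t = 0, 1 endpoints without log(0)
    lt <- if (k == 0) 0 else k * log(pmax(t, 1e-300))
    lu <- if (n - k == 0) 0 else (n - k) * log(pmax(1 - t, 1e-300))
    B[, j] <- exp(logc[j] + lt + lu)
  }
  B[t == 0, ] <- 0; B[t == 0, 1L] <- 1
  B[t == 1, ] <- 0; B[t == 1, n + 1L] <- 1
  B
}

#' Equidistant reparametrization along a Bezier curve
#'
#' Treats the supplied centers as the control points of a single global
#' Bezier curve (closed by duplicating the wrap-around control point for
#' cyclic paths), evaluates it densely, accumulates chord lengths, and
#' returns `N` points equidistant in arc length.  For open paths the first
#' and last output points coincide with the curve endpoints (the first and
#' last control points); for cyclic paths the N points divide the closed
#' curve into N equal arcs starting at the curve seam.
#'
#' Note that a Bezier curve does not interpolate its interior control
#' points: repeated application to a curved control polygon contracts the
#' path slightly (Bernstein smoothing of order curvature / N).  Only
#' collinear control polygons are exact fixed points.
#'
#' @param centers m x d matrix of control points.
#' @param N number of output images.
#' @param cyclic logical; close the curve.
#' @param n_dense number of dense evaluation points for the arc-length table.
#' @param interp `"bezier"` (default; the centers are Bezier control points)
#'   or `"spline"` (interpolating cubic spline through the centers --
#'   periodic for cyclic paths -- which does not contract curved paths the
#'   way a high-degree Bezier does; flagged in the `interp` attribute of the
#'   result).
#' @return a [string_path()] with `N` images.
#' @export
bezier_reparametrize <- function(centers, N, cyclic = FALSE,
                                 n_dense = NULL, interp = c("bezier", "spline")) {
  interp <- match.arg(interp)
  centers <- as.matrix(centers)
  if (nrow(centers) < 2L) stop("at least 2 control points are required")
  seg <- sqrt(rowSums((centers[-1L, , drop = FALSE] -
                       centers[-nrow(centers), , drop = FALSE])^2))
  if (any(seg < 1e-12))
    stop("coincident consecutive control points collapse the Bezier curve")
  ctrl <- if (cyclic) rbind(centers, centers[1L, ]) else centers
  n <- nrow(ctrl) - 1L
  if (is.null(n_dense)) n_dense <- max(2000L, 40L * nrow(ctrl), 40L * N)
  if (interp == "spline") {
    tc <- c(0, cumsum(sqrt(rowSums((ctrl[-1L, , drop = FALSE] -
                                    ctrl[-nrow(ctrl), , drop = FALSE])^2))))
    tq <- seq(0, tc[length(tc)], length.out = n_dense)
    P <- vapply(seq_len(ncol(ctrl)), function(j)
      stats::spline(tc, ctrl[, j], xout = tq,
                    method = if (cyclic) "periodic" else "natural")$y,
      numeric(n_dense))
    P <- matrix(P, n_dense)
  } else {
    t <- seq(0, 1, length.out = n_dense)
    P <- bernstein_matrix(t, n) %*% ctrl
  }
  dl <- sqrt(rowSums((P[-1L, , drop = FALSE] - P[-n_dense, , drop = FALSE])^2))
  cums <- c(0, cumsum(dl))
  L <- cums[n_dense]
  if (L < 1e-12) stop("degenerate Bezier curve of zero length")
  s_target <- if (cyclic) L * (seq_len(N) - 1L) / N
              else seq(0, L, length.out = N)
  out <- vapply(seq_len(ncol(P)), function(j)
    stats::approx(cums, P[, j], xout = s_target, ties = "ordered")$y,
    numeric(length(s_target)))
  out <- matrix(out, nrow = N)
  colnames(out) <- colnames(centers)
  sp <- string_path(out, cyclic = cyclic)
  attr(sp, "interp") <- interp
  sp
}

#' Per-iteration displacement metrics of a string history
#'
#' Computes, for each consecutive pair of paths in an iteration history, the
#' maximum and root-mean-square image displacement in the CV metric, and
#' flags convergence once the RMS displacement has stayed below `tol` for
#' `consecutive` iterations.
#'
#' @param history list of `string_path` objects (or N x d matrices), length
#'   >= 2, all with the same image count.
#' @param metric optional [cv_metric()].
#' @param tol convergence tolerance on RMS displacement; default 1% of the
#'   mean inter-image spacing of the final path.
#' @param consecutive number of consecutive sub-tolerance iterations
#'   required.
#' @return data frame with `iteration`, `max_disp`, `rms_disp`, and a
#'   `converged_at` attribute (NA if never converged).
#' @export
string_convergence <- function(history, metric = NULL, tol = NULL,
                               consecutive = 5L) {
  if (length(history) < 2L) stop("need at least 2 iterations of history")
  mats <- lapply(history, function(p)
    if (inherits(p, "string_path")) p$images else as.matrix(p))
  nimg <- vapply(mats, nrow, integer(1))
  if (length(unique(nimg)) != 1L) stop("image counts differ across history")
  last <- mats[[length(mats)]]
  if (is.null(tol)) {
    spacing <- mean(sqrt(rowSums((last[-1L, , drop = FALSE] -
                                  last[-nrow(last), , drop = FALSE])^2)))
    tol <- 0.01 * spacing
  }
  disp <- t(vapply(seq_len(length(mats) - 1L), function(i) {
    D <- apply_metric(mats[[i + 1L]] - mats[[i]], metric)
    dd <- sqrt(rowSums(D^2))
    c(max(dd), sqrt(mean(dd^2)))
  }, numeric(2)))
  out <- data.frame(iteration = seq_len(nrow(disp)),
                    max_disp = disp[, 1], rms_disp = disp[, 2])
  below <- out$rms_disp < tol
  conv <- NA_integer_
  run <- 0L
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= consecutive) { conv <- i; break }
  }
  attr(out, "converged_at") <- conv
  attr(out, "tol") <- tol
  out
}
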