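#' Tube-restricted Voronoi assignment of samples to path images
#'
#' Builds the Voronoi cell of each image: every sample is labeled with the
#' nearest image center in the CV metric (ties broken toward the lower image
#' index), and samples farther than the tube cutoff `r_c` from every center
#' are excluded (label `NA`).  The cutoff sets the thickness of the
#' transition tube the analysis is localized to.
#'
#' @param samples a [sample_set()] or an n x d coordinate matrix.
#' @param centers a [string_path()] or N x d matrix of image centers.
#' @param metric optional [cv_metric()] scales.
#' @param r_c tube cutoff (> 0; `Inf` keeps every sample).
#' @return list of class `tube_voronoi` with `label` (integer or NA per
#'   sample), `dist` (distance to the assigned center), `r_c`, `n_excluded`.
#' @export
assign_voronoi <- function(samples, centers, metric = NULL, r_c = Inf) {
  X <- if (inherits(samples, "sample_set")) samples$coords else as.matrix(samples)
  if (nrow(X) == 0L) stop("empty sample set")
  C <- if (inherits(centers, "string_path")) centers$images else as.matrix(centers)
  stopifnot(r_c > 0)
  d2 <- cross_dist2(X, C, metric)
  # which.min breaks ties toward the lower index
  lab <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(d2[cbind(seq_len(nrow(X)), lab)])
  lab[dmin > r_c] <- NA_integer_
  structure(list(label = lab, dist = dmin, r_c = r_c,
                 n_excluded = sum(is.na(lab)), n_centers = nrow(C)),
            class = "tube_voronoi")
}

#' Boltzmann-weighted centers of Voronoi cells
#'
#' The weighted mean of the samples in each cell, using the sample weights
#' (e.g. from reweighting a biased ensemble so cell means are Boltzmann
#' averages).  Empty cells are returned as `NA` rows and flagged -- they are
#' never silently interpolated here; [run_phsm()] applies its documented
#' neighbor-midpoint policy before reparametrizing.
#'
#' @param samples a [sample_set()] or n x d matrix.
#' @param assignment a `tube_voronoi` from [assign_voronoi()].
#' @param weights optional nonnegative sample weights (default uniform).
#' @return list with `centers` (N x d, NA rows for empty cells) and
#'   `empty` (logical per cell).
#' @export
weighted_centers <- function(samples, assignment, weights = NULL) {
  X <- if (inherits(samples, "sample_set")) samples$coords else as.matrix(samples)
  lab <- assignment$label
  stopifnot(length(lab) == nrow(X))
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (length(weights) != nrow(X) || any(weights < 0))
    stop("weights must be nonnegative, one per sample")
  N <- assignment$n_centers
  keep <- !is.na(lab) & weights > 0
  if (!any(keep)) stop("all Voronoi cells are empty")
  grp <- lab[keep]
  wsum_part <- rowsum(weights[keep], grp)
  num_part <- rowsum(X[keep, , drop = FALSE] * weights[keep], grp)
  idx <- as.integer(rownames(wsum_part))
  centers <- matrix(NA_real_, N, ncol(X))
  centers[idx, ] <- num_part / as.numeric(wsum_part)
  empty <- rep(TRUE, N)
  empty[idx] <- FALSE
  colnames(centers) <- colnames(X)
  list(centers = centers, empty = empty)
}

# Neighbor-midpoint fill-in for empty cells (keeps the image count fixed).
fill_empty_cells <- function(centers, empty, cyclic, fallback) {
  if (!any(empty)) return(centers)
  N <- nrow(centers)
  for (i in which(empty)) {
    prev <- if (i > 1L) i - 1L else if (cyclic) N else NA_integer_
    nxt <- if (i < N) i + 1L else if (cyclic) 1L else NA_integer_
    cand <- c(prev, nxt)
    cand <- cand[!is.na(cand) & !empty[cand]]
    centers[i, ] <- if (length(cand)) colMeans(centers[cand, , drop = FALSE])
                    else fallback[i, ]
  }
  centers
}

#' Post-hoc string method: principal curve from a weighted sample set
#'
#' Extracts an approximate minimum free-energy path from existing (typically
#' umbrella-biased, reweighted) samples by iterating three steps until the
#' image centers converge: (i) tube-restricted Voronoi assignment of the
#' samples to the current images, (ii) Boltzmann-weighted cell centers, and
#' (iii) equidistant reparametrization along a Bezier curve through those
#' centers.  At the fixed point the weighted mean of each Voronoi cell lies
#' on (near) the curve: a principal curve of the weighted ensemble.
#'
#' Samples are re-assigned against the moving centers every iteration (an
#' excluded sample may re-enter as the tube moves).  Empty cells inherit the
#' midpoint of their neighbors' centers before reparametrization.  An open
#' path connects two given points, so its endpoints stay pinned at the
#' initial path's endpoints; a cyclic path is fully free.
#'
#' @param samples a [sample_set()] or n x d matrix.
#' @param weights optional sample weights (default uniform).
#' @param initial_path a [string_path()].
#' @param metric optional [cv_metric()].
#' @param r_c tube cutoff; default 3x the median nearest-neighbor spacing of
#'   the initial images.
#' @param max_iter iteration cap.
#' @param tol convergence threshold on the maximum image displacement per
#'   iteration (metric units); default 1e-3 x the mean inter-image spacing.
#' @param interp curve family for step (iii): `"bezier"` (default) or the
#'   interpolating `"spline"` fallback of [bezier_reparametrize()], which
#'   avoids the contraction a high-degree Bezier applies to strongly curved
#'   (especially closed) paths.
#' @return a [string_path()] with attributes `diagnostics` (per-iteration
#'   data frame: max displacement, excluded fraction), `converged`,
#'   `self_consistency` (RMS distance of final cell means from the final
#'   images).
#' @export
run_phsm <- function(samples, weights = NULL, initial_path, metric = NULL,
                     r_c = NULL, max_iter = 100L, tol = NULL,
                     interp = c("bezier", "spline")) {
  interp <- match.arg(interp)
  stopifnot(inherits(initial_path, "string_path"))
  X <- if (inherits(samples, "sample_set")) samples$coords else as.matrix(samples)
  N <- nrow(initial_path$images)
  cyclic <- initial_path$cyclic
  imgs <- initial_path$images
  spacing <- mean(sqrt(rowSums((imgs[-1L, , drop = FALSE] -
                                imgs[-N, , drop = FALSE])^2)))
  if (is.null(r_c)) {
    nn <- apply(as.matrix(stats::dist(apply_metric(imgs, metric))), 1,
                function(r) min(r[r > 0]))
    r_c <- 3 * stats::median(nn)
  }
  if (is.null(tol)) tol <- 1e-3 * spacing
  diag_rows <- vector("list", max_iter)
  converged <- FALSE
  disp_hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    asg <- assign_voronoi(X, imgs, metric = metric, r_c = r_c)
    if (all(is.na(asg$label)))
      stop("no samples fall inside the tube (r_c = ", format(r_c),
           "); widen r_c or improve the initial path")
    wc <- weighted_centers(X, asg, weights)
    centers <- fill_empty_cells(wc$centers, wc$empty, cyclic, imgs)
    if (!cyclic) {
      # an open path connects two GIVEN points: its endpoints stay pinned
      centers[1L, ] <- initial_path$images[1L, ]
      centers[N, ] <- initial_path$images[N, ]
    }
    new_imgs <- bezier_reparametrize(centers, N, cyclic = cyclic,
                                     interp = interp)$images
    if (!cyclic) {
      new_imgs[1L, ] <- centers[1L, ]; new_imgs[N, ] <- centers[N, ]
    }
    disp <- max(sqrt(rowSums(apply_metric(new_imgs - imgs, metric)^2)))
    diag_rows[[it]] <- data.frame(
      iteration = it, max_disp = disp,
      excluded_fraction = asg$n_excluded / nrow(X),
      empty_cells = sum(wc$empty))
    imgs <- new_imgs
    disp_hist <- c(disp_hist, disp)
    if (disp < tol) { converged <- TRUE; break }
    if (length(disp_hist) >= 10L &&
        all(diff(utils::tail(disp_hist, 10L)) >= 0)) {
      if (disp < 0.02 * spacing) {
        # plateau at the discrete-reassignment noise floor: the centers jitter
        # by single cell-membership flips; accept as converged
        converged <- TRUE
        break
      }
      warning("image displacement non-decreasing for 10 iterations; ",
              "returning partial result")
      break
    }
  }
  out <- string_path(imgs, cyclic = cyclic,
                     names = colnames(initial_path$images),
                     scales = initial_path$scales)
  final_asg <- assign_voronoi(X, imgs, metric = metric, r_c = r_c)
  final_wc <- weighted_centers(X, final_asg, weights)
  ok <- !final_wc$empty
  resid <- sqrt(mean(rowSums(apply_metric(
    final_wc$centers[ok, , drop = FALSE] - imgs[ok, , drop = FALSE],
    metric)^2)))
  attr(out, "diagnostics") <- do.call(rbind, diag_rows[!vapply(diag_rows, is.null, logical(1))])
  attr(out, "converged") <- converged
  attr(out, "self_consistency") <- resid
  attr(out, "r_c") <- r_c
  attr(out, "interp") <- interp
  out
}

#' Representative samples nearest each path image
#'
#' For each image center, returns the index of the sample minimizing the
#' metric distance to it (ties to the earliest sample) -- the
#' closest-conformation reconstruction used to turn a converged string into
#' a concrete trajectory.
#'
#' @param samples a [sample_set()] or n x d matrix.
#' @param path a [string_path()] or N x d matrix.
#' @param metric optional [cv_metric()].
#' @return integer vector of sample indices, one per image.
#' @export
nearest_sample_path <- function(samples, path, metric = NULL) {
  X <- if (inherits(samples, "sample_set")) samples$coords else as.matrix(samples)
  if (nrow(X) == 0L) stop("empty sample set")
  C <- if (inherits(path, "string_path")) path$images else as.matrix(path)
  d2 <- cross_dist2(C, X, metric)
  apply(d2, 1, which.min)   # which.min ties to the first (earliest) sample
}
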