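#' String method with swarms of trajectories
#'
#' Iteratively refines a transition pathway toward the minimum free-energy
#' path.  Each iteration: (1) multiple copies per image are equilibrated
#' under a harmonic restraint at the image center; (2) the copies are
#' released and propagate freely for a short swarm; (3) each image center is
#' moved to the mean swarm endpoint (the drift estimate); (4) the path is
#' reparametrized to equidistant images along a Bezier curve (shared with
#' the post-hoc string method).  Open strings keep both endpoints pinned;
#' cyclic strings are fully free.  A path lying along an exact free-energy
#' valley is a fixed point of the update in the zero-noise limit.
#'
#' @param path initial [string_path()].
#' @param surface a [potential_surface()].
#' @param copies_per_image number of swarm copies per image (>= 1).
#' @param restrain_steps equilibration steps under the image restraint.
#' @param swarm_steps free-propagation steps per swarm.
#' @param k_restrain restraint force constant.
#' @param iterations number of restrain/release/update cycles.
#' @param config a [brownian_config()]; its `steps`/`stride` fields are
#'   ignored (the cycle structure sets the durations), its seed drives all
#'   noise.
#' @param average_last the returned path is the reparametrized mean of the
#'   final `average_last` iterations (>= 1), averaging out the Monte-Carlo
#'   noise of the drift estimates around the converged string.
#' @return the final [string_path()] with attributes `history` (list of
#'   image matrices per iteration) and `convergence` (see
#'   [string_convergence()]).
#' @export
run_smwst <- function(path, surface, copies_per_image = 8L,
                      restrain_steps = 50L, swarm_steps = 20L,
                      k_restrain = 100, iterations = 30L, config,
                      average_last = 1L) {
  stopifnot(inherits(path, "string_path"),
            inherits(config, "brownian_config"), copies_per_image >= 1)
  N <- nrow(path$images)
  d <- ncol(path$images)
  Dvec <- rep_len(config$diffusion, d)
  cyclic <- path$cyclic
  centers <- path$images
  history <- vector("list", iterations + 1L)
  history[[1L]] <- centers
  with_seed(config$seed, {
    for (it in seq_len(iterations)) {
      # one walker per (image, copy); restrained equilibration then release
      C <- centers[rep(seq_len(N), each = copies_per_image), , drop = FALSE]
      X <- C
      res <- tryCatch(
        em_run(X, surface, restrain_steps, config$timestep, Dvec,
               config$beta, config$noise_scale, config$guard,
               centers = C, k = k_restrain, label = "restrained copy",
               metropolis = isTRUE(config$metropolis)),
        error = function(e) stop("iteration ", it, ": ", conditionMessage(e)))
      res <- tryCatch(
        em_run(res$X, surface, swarm_steps, config$timestep, Dvec,
               config$beta, config$noise_scale, config$guard,
               label = "swarm copy",
               metropolis = isTRUE(config$metropolis)),
        error = function(e) stop("iteration ", it, ": ", conditionMessage(e)))
      drift <- rowsum(res$X, rep(seq_len(N), each = copies_per_image)) /
        copies_per_image
      if (!cyclic) {
        drift[1L, ] <- centers[1L, ]
        drift[N, ] <- centers[N, ]
      }
      centers <- bezier_reparametrize(drift, N, cyclic = cyclic)$images
      if (!cyclic) { centers[1L, ] <- drift[1L, ]; centers[N, ] <- drift[N, ] }
      history[[it + 1L]] <- centers
    }
  })
  average_last <- min(as.integer(average_last), iterations)
  if (average_last > 1L) {
    # each stored iteration is already arc-equidistant, so the image-wise
    # mean needs no further reparametrization (which would re-smooth it)
    keep <- history[(iterations + 2L - average_last):(iterations + 1L)]
    centers <- Reduce(`+`, keep) / length(keep)
  }
  out <- string_path(centers, cyclic = cyclic,
                     names = colnames(path$images), scales = path$scales)
  attr(out, "history") <- history
  attr(out, "convergence") <- string_convergence(history)
  out
}
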