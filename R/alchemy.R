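#' Bidirectional nonequilibrium work sets
#'
#' Forward and reverse work samples from fast-switching alchemical
#' transformations, with the inverse temperature at which they were
#' generated.  Reverse works are reported on the reverse process (so the
#' Crooks relation reads P_f(W) / P_r(-W) = exp(beta (W - dG))).
#'
#' @param forward,reverse numeric work values (energy units); both non-empty
#'   and finite.
#' @param beta inverse temperature.
#' @return object of class `work_set`.
#' @export
work_set <- function(forward, reverse, beta = 1) {
  forward <- as.numeric(forward); reverse <- as.numeric(reverse)
  if (length(forward) < 1L || length(reverse) < 1L)
    stop("both forward and reverse work sets must be non-empty")
  if (any(!is.finite(forward)) || any(!is.finite(reverse)))
    stop("work values must be finite")
  stopifnot(beta > 0)
  structure(list(forward = forward, reverse = reverse, beta = beta),
            class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf("<work_set> %d forward (mean %.3f), %d reverse (mean %.3f), beta = %g\n",
              length(x$forward), mean(x$forward),
              length(x$reverse), mean(x$reverse), x$beta))
  invisible(x)
}

#' Accumulate nonequilibrium work from dH/dlambda series
#'
#' Fast-growth thermodynamic integration: W = sum_steps (dH/dlambda)_step *
#' (delta lambda)_step, with the coupling parameter varied at every step.
#'
#' @param dhdl dH/dlambda value reported at each step.
#' @param lambda coupling-parameter schedule, same length, monotone from 0 to
#'   1 (or 1 to 0 for a reverse transformation); the increment applied with
#'   step i is `lambda[i] - lambda[i - 1]` (first step from `lambda[1] - 0`
#'   for a forward schedule, `lambda[1] - 1` for a reverse one).
#' @return total work W (energy units).
#' @export
accumulate_work <- function(dhdl, lambda) {
  dhdl <- as.numeric(dhdl); lambda <- as.numeric(lambda)
  if (length(dhdl) != length(lambda))
    stop("dhdl and lambda schedules must have equal length")
  dl <- diff(lambda)
  forwardish <- lambda[length(lambda)] >= lambda[1]
  if (length(dl) && !(all(dl >= 0) || all(dl <= 0)))
    stop("lambda schedule must be monotone")
  start <- if (forwardish) 0 else 1
  dlam <- c(lambda[1] - start, dl)
  sum(dhdl * dlam)
}

# Fermi-function ingredients of the Bennett acceptance ratio at a trial dG.
bar_fermi <- function(ws, dG) {
  b <- ws$beta
  M <- log(length(ws$forward) / length(ws$reverse))
  list(ff = stats::plogis(-(M + b * ws$forward - b * dG)),
       fr = stats::plogis(-(-M + b * ws$reverse + b * dG)))
}

#' Bennett acceptance ratio estimate
#'
#' Solves the BAR self-consistency equation
#' sum_F f(M + beta W_F - beta dG) = sum_R f(-M + beta W_R + beta dG),
#' f the Fermi function and M = ln(n_F / n_R), by bracketed root finding
#' (tolerance 1e-10 energy units).  The analytic standard error uses the
#' Fermi-function variance expression
#' var(beta dG) = [<f^2>/<f>^2 - 1]/n_F + [<f^2>/<f>^2 - 1]/n_R
#' evaluated at the solution.
#'
#' @param works a [work_set()].
#' @return list with `dG`, `se` (analytic standard error), and `overlap`
#'   (mean Fermi weight; near 0 indicates non-overlapping work
#'   distributions, which triggers a warning).
#' @export
bar_estimate <- function(works) {
  stopifnot(inherits(works, "work_set"))
  if (length(works$forward) < 2L || length(works$reverse) < 2L)
    stop("BAR requires at least 2 work values in each direction")
  fobj <- function(dG) {
    fw <- bar_fermi(works, dG)
    sum(fw$ff) - sum(fw$fr)
  }
  lo <- min(-works$reverse, works$forward) - 1
  hi <- max(-works$reverse, works$forward) + 1
  # fobj is monotone increasing in dG; expand the bracket if needed
  for (i in 1:60) {
    if (fobj(lo) <= 0 && fobj(hi) >= 0) break
    span <- hi - lo; lo <- lo - span; hi <- hi + span
  }
  if (fobj(lo) > 0 || fobj(hi) < 0)
    stop("BAR root could not be bracketed; work distributions may be pathological")
  dG <- stats::uniroot(fobj, c(lo, hi), tol = 1e-10)$root
  fw <- bar_fermi(works, dG)
  nf <- length(works$forward); nr <- length(works$reverse)
  var_b <- (mean(fw$ff^2) / mean(fw$ff)^2 - 1) / nf +
           (mean(fw$fr^2) / mean(fw$fr)^2 - 1) / nr
  overlap <- min(mean(fw$ff), mean(fw$fr))
  if (overlap < 1e-4)
    warning("forward and reverse work distributions barely overlap; ",
            "BAR estimate is unreliable (mean Fermi weight ",
            format(overlap), ")")
  list(dG = dG, se = sqrt(max(var_b, 0)) / works$beta, overlap = overlap)
}

#' Crooks--Gaussian intersection estimate
#'
#' Fits Gaussians to the forward works and to the negated reverse works and
#' takes dG as their intersection point: the midpoint of the means for equal
#' variances, otherwise the root of the quadratic intersection equation
#' lying between the two means (if no root lies between them, the root
#' nearest their midpoint is used and flagged).  The error is the standard
#' deviation of the estimate over `n_boot` resamples with replacement, drawn
#' independently for each direction.
#'
#' @param works a [work_set()].
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return list with `dG`, `se`, `flagged` (TRUE if the fallback root was
#'   used), and the fitted `mean_f`, `mean_r`, `sd_f`, `sd_r`.
#' @export
cgi_estimate <- function(works, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(works, "work_set"))
  if (length(works$forward) < 2L || length(works$reverse) < 2L)
    stop("CGI requires at least 2 work values in each direction")
  point <- cgi_intersect(works$forward, -works$reverse)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      f <- sample(works$forward, replace = TRUE)
      r <- sample(works$reverse, replace = TRUE)
      cgi_intersect(f, -r)$dG
    }, numeric(1))
  })
  list(dG = point$dG, se = stats::sd(boots), flagged = point$flagged,
       mean_f = point$m1, mean_r = point$m2,
       sd_f = point$s1, sd_r = point$s2)
}

# Intersection of N(m1, s1) and N(m2, s2) densities; x1 = forward works,
# x2 = negated reverse works.
cgi_intersect <- function(x1, x2) {
  m1 <- mean(x1); m2 <- mean(x2)
  s1 <- stats::sd(x1); s2 <- stats::sd(x2)
  s1 <- max(s1, 1e-12); s2 <- max(s2, 1e-12)
  flagged <- FALSE
  if (abs(s1 - s2) < 1e-9 * max(s1, s2)) {
    dG <- (m1 + m2) / 2
  } else {
    a <- 1 / s2^2 - 1 / s1^2
    b <- 2 * (m1 / s1^2 - m2 / s2^2)
    cc <- m2^2 / s2^2 - m1^2 / s1^2 + 2 * log(s2 / s1)
    disc <- b^2 - 4 * a * cc
    if (disc < 0) {
      dG <- (m1 + m2) / 2; flagged <- TRUE
    } else {
      roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
      lohi <- range(m1, m2)
      between <- roots[roots >= lohi[1] & roots <= lohi[2]]
      if (length(between)) dG <- between[1]
      else { dG <- roots[which.min(abs(roots - (m1 + m2) / 2))]; flagged <- TRUE }
    }
  }
  list(dG = dG, flagged = flagged, m1 = m1, m2 = m2, s1 = s1, s2 = s2)
}

#' Thermodynamic-cycle assembly of relative free energies
#'
#' Combines per-state alchemical free-energy differences of a mutation
#' (wild-type to mutant) over the four corners of a transport cycle --
#' outward-facing apo (OF_a), outward-facing bound (OF_b), inward-facing
#' bound (IF_b), inward-facing apo (IF_a) -- into relative binding and
#' conformational free energies, with errors propagated in quadrature.
#'
#' @param states named list with entries `OF_a`, `OF_b`, `IF_b`, `IF_a`,
#'   each a list(dG, se).
#' @return data frame of the four assembled quantities:
#'   ddG_binding_IF = dG(IF_b) - dG(IF_a), ddG_binding_OF = dG(OF_b) -
#'   dG(OF_a), ddG_conf_apo = dG(OF_a) - dG(IF_a), ddG_conf_bound =
#'   dG(OF_b) - dG(IF_b).  These satisfy the cycle-closure identity
#'   ddG_binding_OF - ddG_binding_IF = ddG_conf_bound - ddG_conf_apo.
#' @export
cycle_ddg <- function(states) {
  need <- c("OF_a", "OF_b", "IF_b", "IF_a")
  if (!all(need %in% names(states)))
    stop("missing state(s): ", paste(setdiff(need, names(states)), collapse = ", "))
  g <- function(s) states[[s]]$dG
  e <- function(s) { se <- states[[s]]$se; if (is.null(se)) 0 else se }
  q <- function(a, b) sqrt(e(a)^2 + e(b)^2)
  data.frame(
    quantity = c("ddG_binding_IF", "ddG_binding_OF",
                 "ddG_conf_apo", "ddG_conf_bound"),
    value = c(g("IF_b") - g("IF_a"), g("OF_b") - g("OF_a"),
              g("OF_a") - g("IF_a"), g("OF_b") - g("IF_b")),
    se = c(q("IF_b", "IF_a"), q("OF_b", "OF_a"),
           q("OF_a", "IF_a"), q("OF_b", "IF_b")))
}
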