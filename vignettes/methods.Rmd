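---
title: "Free energies along transition pathways: the methods behind pathpmf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free energies along transition pathways: the methods behind pathpmf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathpmf)
```

# The problem

Large conformational transitions — the motivating case is the
alternating-access cycle of a membrane transporter, where two helix bundles
rock between inward-facing (IF) and outward-facing (OF) states with and
without bound substrate — are far too slow for brute-force simulation. The
practical strategy is to (i) describe the motion with a handful of
collective variables (CVs), (ii) force sampling along a pathway through CV
space with biased simulations, and (iii) undo the bias statistically to
recover the free-energy landscape, with honest error bars. `pathpmf`
implements that full chain and, because every stage can silently fail, pairs
it with analytic toy systems on which every stage has a known answer.

# Collective variables

**Orientation quaternions.** The optimal rigid-body rotation superimposing a
coordinate group on a reference is a unit quaternion
$Q = (q_0, \mathbf{q})$, computed here by the standard 4×4 key-matrix
eigenvalue method after centroid removal (`best_fit_quaternion()`). Since
$Q$ and $-Q$ are the same rotation, all quaternions are canonicalized to the
hemisphere $q_0 \ge 0$; this makes Euclidean operations on quaternion
components (PCA, path metrics) well defined, and every consumer is invariant
under sign flips of its arguments. The separation of two orientations is the
geodesic $\Omega(P, Q) = \arccos |P \cdot Q| \in [0, \pi/2]$, the form used
by production biasing codes; a harmonic orientation restraint is
$U = \tfrac12 k\, \Omega(Q, Q_c)^2$ (`orientation_restraint()`). Its
gradient is taken on the normalized inner product so it is tangent to the
unit sphere and vanishes smoothly at $\Omega = 0$; the $\Omega/\sin\Omega$
prefactor is series-expanded below $10^{-6}$ and the inner product clamped
$10^{-12}$ away from $\pm 1$ to keep the arccos derivative finite. For small
$\Omega$, $\Omega^2 \approx |P - Q|^2$ — the regime in which quaternion
components may be treated as ordinary Euclidean CVs. Note the agreement is
fourth order: the relative gap is $\Omega^2/12$, about $10^{-5}$ at
$\Omega = 0.01$.

**Other CVs.** `delta_rmsd()` (difference of two best-fit RMSDs, a signed
progress variable between two reference structures), `substrate_z()` (height
of a substrate atom above an anchor-group centroid, with an a-posteriori
offset calibration against the protein centroid), `interhelical_angle()`
(angle between dominant principal axes of two helices, each axis oriented by
its N→C end-to-end projection — without that orientation step the angle is
ambiguous between $\alpha$ and $180^\circ - \alpha$), and
`quaternion_pca()` (principal components of quaternion vector parts, the
"QPC" coordinates used to visualize global conformational changes).

# The toy engine

All sampling machinery runs over a pluggable propagator: overdamped Langevin
(Euler–Maruyama) dynamics in CV space,
$d\zeta = -\beta D \nabla U\, dt + \sqrt{2 D}\, dW$, in reduced units
($k_BT = 1$). Three analytic surfaces are built in (`preset_surface()`):

* `double_well_1d`: $U = b (x^2 - 1)^2$, barrier exactly $b$;
* `curved_valley_2d`: a semicircular valley $\tfrac12 k_r (r - R)^2 +
  \tfrac{h}{2}(1 - \cos 2\phi)$ — the valley curve is known exactly, so path
  methods can be graded geometrically;
* `cyclic_channels_2d`: a circular valley whose angular potential
  $V(\phi) = h - h\cos 2\phi - \tfrac{2B}{3}\sin^3\phi$ has two equal basins
  connected by two channels with barriers $2h \mp 2B/3$: stationary points
  sit exactly on the coordinate axes and the planted inter-channel barrier
  gap is exactly $4B/3$. Defaults $h = 2.75$, $B = 2.625$ put the barriers
  at 3.75 and 7.25 with gap 3.5, echoing the motif of a substrate-lowered
  transition barrier in a transport cycle; the numbers themselves are
  fixture parameters, not claims about any molecule.

Two numerical choices matter. First, the plain Euler–Maruyama chain samples
a distribution with $O(\Delta t)$ bias (for a harmonic mode of stiffness
$k$, the variance is inflated by roughly $k \beta D \Delta t / 2$); analyses
that compare against analytic Boltzmann answers therefore set
`metropolis = TRUE` in `brownian_config()`, which accept/rejects each
proposal (MALA) and makes the stationary distribution exactly
$e^{-\beta U}$ at any timestep. Second, all randomness flows from explicit
seeds, restored on exit, so every sampler is bit-reproducible.

`analytic_pmf()` is the oracle: direct quadrature of $e^{-\beta U}$ over the
orthogonal coordinate (Cartesian, or $r\,dr$ in polar form for the circular
surfaces), with a Richardson-style self-check at doubled resolution.
`make_crooks_work_samples()` draws the unique equal-variance Gaussian pair
satisfying the Crooks relation — forward $\sim N(\Delta G + \beta\sigma^2/2,
\sigma^2)$, reverse $\sim N(-\Delta G + \beta\sigma^2/2, \sigma^2)$ — the
fixture for the work estimators.

# Sampling drivers

**BEUS** (`run_beus()`): one replica per umbrella window; neighboring
windows periodically attempt to swap *biases* with Metropolis probability
$\min(1, e^{-\Delta})$,
$\Delta = \beta[(U_i(\zeta_j) + U_j(\zeta_i)) - (U_i(\zeta_i) +
U_j(\zeta_j))]$. Swapping biases rather than coordinates keeps each
replica's trajectory continuous, which is what the autocorrelation analysis
wants. Attempts alternate even/odd neighbor pairs each epoch (a standard
non-conflicting schedule; the attempt frequency is a run parameter), and
cyclic ladders exchange across the seam. With the exchange interval set to
infinity the driver reduces exactly to independent umbrella sampling.
`beus_accounting()` does the retained-sample and block bookkeeping; with 150
replicas of 50 ns, 10 ns discarded, 5 ps sampling and 10 ns blocks it yields
1,200,000 configurations in 600 blocks.

**SMwST** (`run_smwst()`): per iteration each image's swarm copies are
equilibrated under a harmonic restraint at the image center, released for a
short free swarm, and the image center moves to the mean swarm endpoint (the
drift estimate — plain endpoint mean, the standard choice); the string is
then reparametrized to equal arc length. Open strings pin both endpoints;
cyclic strings are free. Swarms must be short enough that the drift is in
the linear-response regime: long swarms let copies slide along the path into
the basins and bias the string. Because each iteration's update carries
Monte-Carlo noise of order $\sigma_{\text{swarm}}/\sqrt{n_{\text{copies}}}$
(halved by quadrupling copies), the returned path averages the last
`average_last` iterations — the averaged images are already equidistant, so
no further smoothing is applied to them.

# The post-hoc string method

`run_phsm()` extracts an approximate minimum free-energy path (a principal
curve) from an existing weighted sample set, without any new simulation.
Each iteration: (i) a Voronoi cell per image under a diagonal-weighted
Euclidean metric, samples farther than a tube cutoff $r_c$ from every
center excluded (re-evaluated each iteration, so samples re-enter as the
tube moves); (ii) weighted (Boltzmann) cell means; (iii) $N$ equidistant
points along a curve through the means. Ties in the assignment go to the
lower image index (determinism); empty cells inherit their neighbors'
midpoint so the image count never changes; an open path connects two given
endpoints, which stay pinned. Default $r_c$ is 3× the median
nearest-neighbor image spacing — right for refining a reasonable path; a
deliberately bad initialization (a chord a full unit away from the valley)
needs a wider tube, which the validation runs set explicitly. Convergence is
declared when the maximum image displacement falls below $10^{-3}$× the
mean image spacing, or when displacements plateau below 2% of the spacing
(the noise floor of discrete cell-membership flips).

Step (iii) follows the literal reading in which the cell means are the
*control points* of a single global Bézier curve (de Casteljau evaluated,
arc length by dense chord accumulation). A Bézier does not interpolate its
interior controls: it contracts curved polygons by roughly
$|f''| t(1-t) / 2N$ per pass — about 0.026 at $N = 48$ on a unit
semicircle, and 4–5× worse on a closed circle, where the curve must also
carry a seam. The converged PHSM path therefore sits slightly inside a
curved valley (within 0.03 at $N = 32$ on the semicircular test, inside the
0.05 tube the validation demands). For strongly curved or cyclic paths the
documented `interp = "spline"` fallback replaces the Bézier with an
interpolating (periodic) cubic spline, which is exact on a circle; it is off
by default and flagged in the result's metadata. `nearest_sample_path()`
turns a converged string back into concrete sampled conformations.

# Reweighting

With $N$ windows of bias $U_i$ and $T_i$ samples each, the perturbed free
energies $F_i$ solve the self-consistent (WHAM) system
$$e^{-\beta F_i} = \sum_t w^t e^{-\beta U_i(\zeta^t)}, \qquad
  w^t = \Big[\sum_j T_j e^{\beta F_j - \beta U_j(\zeta^t)}\Big]^{-1},$$
anchored at $F_1 = 0$ (the additive gauge is checked to leave weights and
PMF shapes untouched). `wham_solve()` first minimizes the equivalent convex
likelihood by BFGS with an analytic gradient — plain fixed-point sweeps
stall on the slow collective modes of long or cyclic ladders and can
spuriously report convergence — then verifies the fixed point by
self-consistent sweeps to the stated tolerance. Both the direct and the
alternating weights/free-energies routes are exposed and agree. All
exponentials are handled through common scale shifts, so 100+-window
problems do not underflow. Per-sample weights come from the same denominator
(`sample_weights()`); re-solving under nonuniform observation weights
(`obs_weights`, warm-started from the full-data solution) is what the block
bootstrap uses.

**Bayesian estimation.** `gibbs_reweight()` samples the posterior of
$(\{w^t\}, \{f_i = T_i e^{\beta F_i}\})$ by conjugate Gamma conditionals:
$f_i \mid w \sim \Gamma(T_i, \sum_t w^t e^{-\beta U_i(\zeta^t)})$ and
$w^t \mid f \sim \Gamma(1, \sum_i f_i e^{-\beta U_i(\zeta^t)})$, weights
renormalized each sweep (flat improper priors). The conditional means
reproduce the WHAM equations, which is the guard that this reading of the
scheme is right: posterior means agree with WHAM within posterior spread on
the toys, the spread shrinks as $n^{-1/2}$, and any single draw is a usable
reweighting. The chain starts from the maximum-likelihood weights by
default; from flat weights the burn-in would have to match the WHAM
iteration count, which for cyclic ladders is thousands of sweeps.

**Projection and the stiff-spring correction.** `project_pmf()` estimates
$G(\xi) = -\beta^{-1}\ln \sum_t w^t K(\xi - \xi^t)$ for any per-sample
projection $\xi$, with top-hat (1D/2D) or Gaussian (1D, Silverman bandwidth)
kernels; bins supported by fewer raw samples than an occupancy floor are
masked, never extrapolated, because the estimator is only meaningful where
sampling of $\xi$ has converged. Along a path sampled with stiff springs of
force constant $k$, the PMF follows from the perturbed free energies by the
second-order expansion
$$G(s) = F(s) + \frac{F'(s)^2}{2k} - \frac{F''(s)}{2\beta k} + O(k^{-2}),$$
with second-order central differences (wrapped for cyclic paths, one-sided
at open endpoints). On the exactly solvable Gaussian case — $G = \tfrac12
\kappa s^2$ convolved with the spring gives $F$ with stiffness $\kappa_{\rm
eff} = \kappa k/(\kappa + k)$ — the correction recovers $\kappa$ to within
$(\kappa/k)^2$, under 1% for $k \ge 100\kappa$, and its magnitude scales as
$1/k$. The per-image correction is reported so users can verify it is small
against the statistical error, the a-posteriori validity check for the
approximation. `state_free_energies()` then tabulates state-to-state
$\Delta G$ and barrier heights with errors in quadrature (zero by
construction for identical indices).

# Uncertainty

`autocorrelation_time()` integrates the ACF to its first negative estimate
(a robust default cutoff); computed on continuous replica trajectories it
upper-bounds the per-image times. `statistical_inefficiency()` is
$g = 1 + 2\tau/\tau_{\rm lag}$, and `path_average()` reports per-image
means with errors inflated by $\sqrt{g}$ (the $\sigma^2 g/N$ contract).
`block_bootstrap()` resamples contiguous per-replica blocks — classical
multinomial resampling or the Bayesian variant with flat-Dirichlet block
weights (the default; the two agree on iid data) — and blocks never span
replica boundaries. One-sample blocks demonstrably underestimate the error
of correlated series; blocks much longer than $\tau$ match the
inefficiency-corrected analytic variance on AR(1) fixtures.

# Nonequilibrium alchemy

`accumulate_work()` sums $(\partial H/\partial\lambda)\,\Delta\lambda$ per
step (rectangle rule, matching a coupling parameter varied every step).
`bar_estimate()` solves the Bennett acceptance-ratio self-consistency by
bracketed root finding (tolerance $10^{-10}$) with the Fermi-function
variance expression as the analytic error; it is exact in the reversible
limit and antisymmetric under swapping directions. `cgi_estimate()` fits
Gaussians to the forward and negated-reverse works and intersects them —
the midpoint of the means at equal variance, otherwise the quadratic root
between the means (a fallback to the root nearest the midpoint is flagged) —
with an independent-resampling bootstrap error. The two estimators agree
within combined errors on Crooks-consistent fixtures across
$\Delta G \in [-5, 5]$, $\sigma \in [0.5, 4]$, and CGI reduces to BAR as
$\sigma \to 0$. `cycle_ddg()` assembles per-state mutation free energies
into relative binding and conformational $\Delta\Delta G$s over the four
corners of the IF/OF × apo/bound cycle; the closure identity
$\Delta\Delta G_{\rm bind}^{\rm OF} - \Delta\Delta G_{\rm bind}^{\rm IF} =
\Delta\Delta G_{\rm conf}^{\rm bound} - \Delta\Delta G_{\rm conf}^{\rm apo}$
holds algebraically.

# The end-to-end benchmark

`run_cyclic_pipeline()` chains everything on `cyclic_channels_2d`: a closed
32-image BEUS ladder ($k = 100$, Metropolis-adjusted, 80,000 steps per
replica at $\Delta t = 10^{-3}$ by default — about 3,000 retained samples
per window after discarding the first quarter), Gibbs reweighting, an
unweighted PHSM extraction of the cyclic path (umbrella windows already
cover the cycle uniformly, and unweighted cell means track pathway geometry
without the basin-collapse that a 7 $k_BT$ free-energy contrast imposes on
weighted means — the same estimator choice used for path averages under
stiff restraints), the stiff-spring-corrected $G(s)$, and a state/barrier
table. Errors come from a Bayesian block bootstrap (10 blocks per replica,
flat-Dirichlet weights, WHAM re-solved per replicate from the warm start).
The headline check: the estimated inter-channel barrier difference must
bracket the planted 3.5 within its bootstrap error; across seeds the
estimate lands within $\pm 0.2$ with reported errors of about 0.1.

# What the toys do and do not show

The toy systems exercise every statistical property the estimators rely on —
biased sampling, exchange, reweighting consistency, autocorrelation, work
fluctuations — under exactly known answers. They do not emulate the hard
parts of real molecular data: CV spaces here are 1–2 dimensional with a
clean separation between path and orthogonal degrees of freedom; real CV
sets (20 quaternions, $Z_P$, ΔRMSD) are high-dimensional, with hidden slow
modes that no reweighting can repair, position-dependent anisotropic
diffusion (the propagator here uses per-dimension constants), and force
fields whose own accuracy is outside statistics. Passing this suite
validates the machinery, not any biological conclusion.

# Problem sizes

The validation suite samples at the scale where the closed forms bite:
$10^4$ samples per window for WHAM/Gibbs recovery, $10^5$ samples for PMF
projections, path extraction and work estimators, $10^5$ trials for
acceptance rates, and 80,000-step replicas for the cyclic benchmark —
sizes chosen so statistical bands are a few percent of the planted signals.
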