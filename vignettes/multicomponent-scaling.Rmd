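---
title: "Scaling multi-component structure-factor models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaling multi-component structure-factor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcsf)
```

## The model

Measured diffraction intensities reflect everything in the unit cell, not
just the atoms a crystallographer has placed. Bulk solvent, disordered
ligands, semi-ordered lipid or loop regions all scatter. `mcsf` models the
total structure factor as

$$F_{\mathrm{model}}(\mathbf{s}) \;=\; k_{\mathrm{overall}}(s)\,\Big(
  k_0 F_0(\mathbf{s}) \;+\; \sum_{n=1}^{N} k_n(s)\, F_n(\mathbf{s}) \Big),$$

where $F_0$ is the (absolute-scale) atomic contribution, $F_1 \dots F_N$
are structure factors of additional scattering components — here analytic
smeared spheres, Gaussian point atoms, binary grid masks, or anything
supplied externally — and the $k_n$ are unknown non-negative scale factors.
When every component shares one form factor the $k_n$ can be read as
occupancies. Scales are treated as constant within each resolution shell;
shells are cut uniformly in $\ln d$ (thin enough that the assumption holds,
populous enough that the per-shell fit is determined — sparse
low-resolution shells are merged into their larger-$d$ neighbour). The
smoothness of $k_n(s)$ across shells is an empirical observation about
good fits, not an enforced constraint.

Fitting compares $|F_{\mathrm{model}}|$ (or its square) with observed
amplitudes $|F_{\mathrm{obs}}|$ per shell. Because the model intensity
$|\sum_n k_n F_n|^2 = \sum_{n,m} k_n k_m v_{nm}$ couples components through
the real cross-terms $v_{nm} = \mathrm{Re}(F_n \overline{F_m})$, the
intensity residual is a quartic polynomial in the scales.

## The four searches

* **Algorithm 1 (sequential)** adds one component at a time, fitting each
  new scale by 1-D minimization of the amplitude residual with earlier
  scales frozen. Cheap and greedy; errors in early scales propagate, and
  with correlated components its residual cannot beat a simultaneous
  search. Used here mainly to seed the other algorithms.
* **Algorithm 2 (simultaneous quartic least squares)** minimizes the
  intensity residual over all scales with L-BFGS-B using the analytic
  gradient; the `"2h"` variant follows with a damped Newton polish using
  the analytic Hessian. It needs starting values within roughly an order
  of magnitude of the answer.
* **Algorithm 3 (two-step analytic)** substitutes products
  $u_{nm} = k_n k_m$, solves the resulting linear normal equations over
  all $(N+1)(N+2)/2$ products, then recovers the individual scales by
  linear least squares on $\lambda_n = \ln k_n$ over the positive products.
  It needs no initial values but the large system is badly conditioned for
  more than a handful of components (the implementation monitors condition
  numbers and falls back to a truncated pseudo-inverse with a warning).
* **Algorithm 4 (iterative phased search)** approximates each reflection's
  phase by the current model phase, turning the fit into a linear
  $(N{+}1)$-dimensional solve per iteration; a few dozen iterations
  typically converge. It is the default: nearly as accurate as algorithm 2
  with far less work, and with error-free phases it is exact in one solve.

## What the driver adds

`fit_driver()` iterates per-shell solves until the largest relative
parameter change falls below `tol` (default `1e-4`). Points where the
implementation had to make choices the description above leaves open:

* **Absolute scales, not data division.** An earlier implementation held
  $k_0 = 1$ and divided the observations by a frozen per-shell overall
  scale before each component solve. That alternation is unstable: in
  low-resolution shells an underestimated overall scale inflates the
  component scales, which shrinks the amplitude-ratio overall scale
  further — a feedback that diverged on error-free data. The driver
  therefore solves all scales in absolute terms and only *reports*
  `k_overall`/`k_n` in the requested parameterization.
* **Pinned atomic scale.** With `k0 = "fixed"` (default) the atomic
  coefficient is held fixed during every inner solve and refreshed by an
  exact 1-D cubic-root coordinate-descent step afterwards. Leaving it free
  adds a compensating direction that created genuine local minima in
  roughly 1 in 10 order-of-magnitude-perturbed starts; pinning removed
  every such failure in our closed-loop tests.
* **Initialization.** The atomic scale is anchored on the two
  highest-resolution shells, where smeared bulk-like components have died
  off ($e^{-Bs^2/4}$ with $B = 50$ Å$^2$ is below 0.2 beyond
  $s \approx 0.36$ Å$^{-1}$), then one sequential pass seeds the component
  scales. A supplied starting point takes precedence; if a fit from a
  supplied start fails to converge, the driver retries from its own
  initialization and keeps whichever solution fits the data better.
* **Negative scales** are permitted within an inner solve but clipped to
  zero between outer passes (occupancy semantics; persistent
  negative/positive pairs of correlated components can otherwise overfit
  noise with arbitrarily large cancelling scales). `clip = FALSE` disables
  this.
* **Termination.** Outer iteration stops on the parameter tolerance, on a
  machine-level plateau of the R factor (three consecutive improvements
  below $10^{-10}(1+R)$ — ordinary convergence in the presence of noise),
  or on three consecutive *significant* (relative $10^{-3}$) R increases,
  which flags divergence and restores the best iterate.
* **Ill-conditioning.** All linear solves monitor the condition number;
  above $10^{12}$ a truncated pseudo-inverse is used and a warning is
  recorded in the run log. Components that are unidentifiable in a shell
  then stay at the minimum-norm solution instead of running away.

## The synthetic world

`synthetic_crystal()` builds the self-contained test systems used
throughout:

* **`"regions"`** — a P1 cube (default edge 42.4 Å, giving ~10⁴ unique
  reflections at $d_{\min} = 2.5$ Å) with a protein mimic of 500
  single-Gaussian atoms (weight 6, B = 15 Å², a compact ball occupying 25%
  of the cell) plus 7 sphere components: one dominant solvent-like sphere
  (radius ≈ cell/3) and six pocket-sized spheres (radius 2.3–3.6 Å,
  matching regions of 50–190 Å³), all smeared with B = 50 Å². True scales
  are uniform in [0, 1]. This mirrors a bulk-solvent mask with one large
  and several tiny isolated regions; the dominant component matters — with
  seven uniformly small spheres the landscape loses its anchor and
  order-of-magnitude-perturbed starts occasionally stray.
* **`"packed"`** — a 46 Å cube whose solvent region is saturated with
  non-overlapping spheres of radius 3–10 Å under the minimum-image
  convention, occupancies log-uniform in [0.1, 100]. Saturation is
  declared after 150 consecutive rejected placements; this pair
  (cell edge, rejection budget) was calibrated once so that a typical seed
  yields 30–50 spheres (median 38 across seeds) and then frozen. An
  unlimited rejection budget would keep gap-filling with the smallest
  spheres towards ~150.

What the generator does *not* emulate: space-group symmetry (everything is
P1), element form factors (single-Gaussian atoms), measurement sigmas,
systematic errors, or incompleteness. A green closed-loop test therefore
establishes that the *scale searches* recover their parameters under the
stated error models — not that any particular real crystal will behave as
nicely.

Error models follow the published protocol: coordinate errors are
isotropic Gaussian displacements rescaled so the realized RMSD hits the
target exactly (the unperturbed model generates the data, the perturbed
model supplies $F_0$ during the fit); data errors are zero-mean Gaussian
amplitude noise with the sigma calibrated by bisection so the R factor
between noisy and exact amplitudes hits the target to $10^{-4}$, with
negative amplitudes clipped to zero *before* the calibration is evaluated.

## Benchmarks and aggregation

`run_benchmark()` repeats seeded trials: draw true scales, simulate
error-free amplitudes, apply the scenario's perturbation, start each
algorithm from the truth multiplied by random factors in [0.1, 10], fit,
and score. Because the synthetic truth is shell-constant while the fit is
per-shell, each component's recovered scale is pooled across shells by a
weighted median with information weights $\sum_s v_{nn,s}^2$: shells where
the component scatters strongly dominate, and the median ignores the
occasional wild estimate from a shell where the component is
unidentifiable. Each trial's headline error is the *pooled* relative error
of the scale vector, $\sum_n |\hat k_n - k_n| / \sum_n k_n$, summarized
over trials by mean and standard deviation. Per-component versus pooled
normalization was an open choice; the per-component mean was rejected
because it diverges whenever a uniform-[0,1] truth lands near zero (a
true scale of $9\times10^{-5}$ with an ordinary absolute error of 0.03
contributes a relative error of 377 on its own), which bounded error
curves cannot tolerate. The strict per-component maximum is still used
for the error-free recovery claim, where it is well defined.

Outer solver tolerances are matched to what is being measured: $10^{-8}$
for error-free recovery claims at the $10^{-6}$ level, $10^{-5}$ for the
percent-level error scenarios.

## Numerical choices worth knowing

* Sphere transform $\Phi(x) = 3(\sin x - x\cos x)/x^3$ switches to its
  series $1 - x^2/10 + x^4/280$ below $x = 10^{-2}$ to avoid cancellation.
* The L-BFGS-B stage optimizes in units of `k_init/10`; its natural
  first-step length would otherwise project starts onto the $k = 0$ box
  corner, which is an exact stationary saddle of the quartic (the gradient
  vanishes identically there) and traps the search.
* L-BFGS-B's line searches bottom out several digits above the
  representable minimum; algorithm 2 therefore ends with a short
  Gauss–Newton finisher (which uses first-derivative information only, so
  the distinction between the plain and Hessian-assisted variants is
  preserved). Similarly, once a fit explains the data to $R < 10^{-4}$
  the driver finishes with a few *unpinned* passes of the same per-shell
  search, because the pinned coordinate-descent iteration converges only
  linearly in its last digits; the polish is kept only if $R$ does not
  degrade.
* The Newton polish caps step length at $1 + \max|k|$ per iteration so
  near-null Hessian directions cannot carry the iterate through flat
  regions, and requires strict residual decrease in its line search.
* Mask transforms use the unnormalized inverse FFT (convention
  $e^{+2\pi i\,\mathbf{h}\cdot\mathbf{x}}$) scaled by
  $V_{\mathrm{cell}}/N_{\mathrm{grid}}$, and require
  $d_{\min} \ge 2\times$ the largest grid spacing.
* Friedel half-set convention: keep $(h,k,l)$ with $h>0$, or $h=0,k>0$,
  or $h=k=0,l>0$. No symmetry expansion, no systematic absences.
* The product-recovery step of algorithm 3 solves the
  $\ln u_{nm} = \lambda_n + \lambda_m$ system by least squares directly
  rather than through a printed closed form, sidestepping its
  normalization ambiguity; components with no positive product estimate
  are set to 0 with a warning.

## Known limitations

* The overall scale is per-shell isotropic; the anisotropic overall scale
  of full-featured refinement pipelines is out of scope.
* Masks are accepted as given grids; constructing solvent masks from
  atomic coordinates is out of scope.
* Unweighted residuals only — supplied sigmas are carried but unused.
* Algorithm 3 is included for completeness; beyond a handful of components
  its normal system is rank-deficient at realistic shell sizes and the
  implementation degrades (deliberately, with warnings) to a pseudo-inverse.
* The high-resolution anchoring of the atomic scale assumes the non-atomic
  components fade at high resolution (true for smeared masks and spheres,
  not necessarily for arbitrary external components); supply `k_init` when
  that assumption fails.
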