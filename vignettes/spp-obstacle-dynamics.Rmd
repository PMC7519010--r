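---
title: "Self-propelled particles among tethered obstacles: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-propelled particles among tethered obstacles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spobs)
```

## The system

`spobs` studies collective motion of self-propelled particles (SPPs) —
cells, bacteria, sperm, animals — moving through a *deformable elastic
environment*. The environment is modelled as $N$ obstacle beads, each
tethered to a fixed anchor point by a Hookean spring (stiffness $\kappa$,
friction $\eta$), mimicking a fibrous matrix whose components can be pushed
aside and relax back. The $M$ SPPs move at unit speed along their body
orientation, align with neighbours within radius $r_A$ at frequency $\nu$
(Vicsek-type alignment with rotational noise $d_s$), repel each other
through a short-ranged even potential $\psi$, and interact with obstacles
through an even potential $\phi$ of range $r_I$ — repulsive or attractive
depending on the sign of its amplitude. Everything is nondimensionalised to
the unit torus, with the domain crossing time as time unit. The overdamped
dynamics are integrated with the Euler–Maruyama scheme (`ibm_run()`).

The central scientific point the package reproduces: *an elastic
environment induces SPP aggregation even without any direct SPP–SPP
attraction, and does so regardless of whether obstacles repel or attract
the particles*.

## The macroscopic model

In the stiff-spring regime, measured by the small parameter
$\gamma = \eta/\kappa$ (spring relaxation time over crossing time) with
rescaled obstacle noise $\delta = d_o\gamma$, the obstacle density
$\rho_f$ becomes a *functional of the SPP density* $\rho_g$. With
$\bar\rho_g = \phi * \rho_g$, the closures implemented in
`rho_f_order1()`, `rho_f_noise()`, `rho_f_order2()` are

$$\rho_f = 1 + \frac{\gamma}{\eta}\partial_x^2\bar\rho_g, \qquad
\rho_f = 1 - \frac{\gamma}{\delta\eta}\left[\bar\rho_g -
M_{2\delta}*\bar\rho_g\right], \qquad
\rho_f^{(2)} = \rho_f - \frac{\gamma^2}{\eta}\,
\partial_t\partial_x^2\bar\rho_g ,$$

where $M_\delta$ is the unit-mass wrapped Gaussian of variance $\delta$.
The memory term shifts obstacle-density minima backwards relative to the
SPP motion — obstacles remember where the particles were. In 2D the same
expansion can be organised as the Jacobian determinant of the anchor map
$Y(x) = x + \frac{\gamma}{\eta}\nabla\bar\rho_g$
(`jacobian_det_density()`), whose quadratic part is the Hessian-determinant
term computed by `nonlinear_term()`.

The 1D SPP density then obeys the nonlocal conservation law (all particles
aligned rightward, transport speed $c_1$)

$$\partial_t\rho_g + c_1\partial_x\rho_g =
\frac{1}{\zeta}\partial_x\!\left(\mu\rho_g\partial_x\rho_g +
\rho_g\partial_x\bar\rho_f\right),$$

with $\mu = \int\psi$ the self-repulsion mass. Substituting the
leading-order closure turns it into a gradient flow
(`gradient_flow_rhs()`, `interaction_energy()`) driven by the
internal energy $\frac{\mu}{2}\rho^2$ and the *obstacle-induced interaction
kernel* $W = \phi' * \phi'$. `macro_kernel()` builds $W$ by discrete
self-convolution; the structure is universal and biphasic:
$W'(0^+) = 2\varphi(0)^2 > 0$ (short-range attraction, independent of the
sign of $\phi$ — it enters squared) and $W' < 0$ on $(r_I, 2r_I)$
(longer-range repulsion). For the exponential force profile the closed form
`macro_kernel_exponential_wprime()` places the sign change exactly at
$2r_I$ and serves as the convolution oracle.

## Linear stability and pattern size

Perturbations $e^{ikx+\alpha t}$ of the uniform state grow at the rate
(`dispersion()`)

$$\alpha(k) = -\,\frac{ikc_1}{D(k)} + \frac{\rho_0}{\zeta}k^2\,
\frac{\frac{\gamma}{\eta\delta}\bigl(1-e^{-\delta k^2}\bigr)\hat\phi_k^2
- \mu}{D(k)}, \qquad
D(k) = 1 + \gamma^2\tfrac{\rho_0}{\eta\zeta}k^2\hat\phi_k^2 .$$

Obstacle noise only ever stabilises; the memory denominator $D$ rescales
rates without changing their sign. For the compact quadratic kernel the
gain $(k\hat\phi_k)^2$ is maximised exactly at $k = \pi/r_I$, so on the
torus the fastest-growing integer mode is $l_{\max} \approx 1/(2r_I)$ and
the expected pattern size is $P = 1/l_{\max}$ (`predicted_pattern_size()`).
With $\mu$ exactly zero the maximiser of $\Re\alpha \propto k^4\hat\phi_k^2$
would instead sit at $r_Ik \approx 4.49$ (the first minimum of
$\sin(u)/u$); finite self-repulsion damps that lobe, which is why the
$1/(2r_I)$ rule needs $\mu > 0$.

`simulate_linearized()` is the package's independent check: it integrates
the linearized PDE in real space and fits the log-amplitude slope and phase
drift, without touching the dispersion algebra. At the parameter scales
used here the two agree to better than $10^{-3}$ relative.

## Numerical choices

* **Spectral derivatives and convolutions.** All fields live on uniform
  periodic grids; derivatives and kernel convolutions are Fourier
  multipliers ($\hat\phi_k$ evaluated in closed form for the quadratic
  family). The Nyquist mode is zeroed in odd derivatives. This makes the
  mean of every $\rho_f$ closure exactly 1 and mass conservation exact at
  the DC component.
* **Time stepping.** Explicit RK4 on the flux form. The step is chosen each
  step from the linear rate bound (self-repulsion diffusion
  $+\,$obstacle-induced growth$\,+$ advection, evaluated at the current
  $\max\rho$), with safety factor 0.8 on a stability radius of 2.5. A mild
  exponential filter $e^{-36(|k|/k_{\max})^{36}}$ is applied each step; it
  touches only the top ~15% of modes and controls aliasing at steep cluster
  edges.
* **Vacuum and validity.** In strongly unstable regimes the density
  develops near-vacuum stretches; a spectral scheme then undershoots
  slightly below zero (about 1% of the peak density in the travelling-
  cluster regime). Runs are flagged (`undershoot` attribute) but not
  clipped, and the undershoot does not shrink with resolution — it is a
  property of the discretisation near vacuum, not an error to be resolved
  away. Similarly, $\rho_f < 0$ is reported with a warning and a validity
  flag: negativity marks the physical limit of the stiff-spring expansion
  (where predictions stop agreeing with the particle model), not a solver
  failure. Interaction radii below about $0.13$ in the pattern-scan family
  sit in that breakdown regime and lead to finite-time collapse.
* **Kernel self-convolution.** $W = \phi'*\phi'$ uses trapezoid-weighted
  discrete convolution; $\phi'$ jumps at 0, and at lag 0 the integrand is
  continuous with value $-\varphi(0)^2$ while the sampled product is 0, so
  that node gets a single-point correction (without it the short-range
  limit ratio measures 0.5 instead of 2). $W'$ is formed by central
  differences away from 0; the two one-sided limits at 0 are reported
  separately because $W'$ genuinely jumps there. The exponential kernel is
  truncated at $10\,r_I$ (neglected tail $\sim e^{-10}$).
* **Particle model.** Cell-list neighbour search (cell edge at least the
  largest interaction radius, minimum-image displacements) with a
  brute-force $O(NM)$ path kept as the oracle; the two agree to $10^{-13}$.
  The orientation dynamics on the circle are integrated as the angle
  equation $d\theta = \nu\sin(\bar\theta-\theta)dt + \sqrt{2d_s}\,dW$,
  which preserves $|\alpha| = 1$ exactly; where the mean flux vanishes the
  alignment drift is set to zero for that step (the symmetric choice for
  the undefined mean direction). The sum defining the mean flux includes
  the particle itself; the self-repulsion sum excludes it. Default step
  $\min(0.1\gamma, 10^{-3})$ — a tenth of the fastest (spring) time scale.
  The 1D model drops the orientation equation entirely (all particles move
  rightward) and runs in a compiled inner loop that is bitwise-identical to
  the generic stepper.

## Study conditions and generator defaults

The synthetic initial conditions define the simulated experiments:

* `perturbed_uniform_density()`: i.i.d. uniform node noise of relative
  amplitude $10^{-2}$, smoothed by one mollifier pass (variance
  $10^{-4}$), mean re-centred exactly. The amplitude is not stated in the
  reference experiments; $10^{-2}$ excites all modes while keeping the
  early evolution linear.
* `gaussian_bump_density()`: wrapped Gaussian, sd 0.05 domain lengths
  (width unstated in the reference; 0.05 gives an order-one localised
  aggregate well inside the domain).
* Continuum runs use 512 nodes for the travelling-cluster experiment and
  256 for the pattern-size scan (the patterns there have at most ~7 peaks);
  particle comparisons use $N = M = 100$ with equally spaced anchors, the
  self-repulsion kernel of width $r_R = 0.02$ and mass $\mu$.
* The pattern-size comparison uses $r_I \in \{0.14, 0.15, 0.16\}$: verified
  unstable with positive obstacle density throughout. The 2D presets
  (`moving_clusters`, `trails`, `travelling_bands`) bind the reference
  parameter sets at $N = M = 5000$; the test suite exercises a scaled
  $N = M = 500$, $T = 5$ variant, which reproduces the qualitative
  signatures (global alignment, clustering) but not the full pattern
  morphology.

What passing tests show — and what they do not: the particle model is
validated against the continuum model and the dispersion relation under
matched, idealised conditions (uniform anchors, quadratic kernels, moderate
densities). Real fibrous environments have anisotropic, heterogeneous
anchoring and finite-size obstacles; none of that is represented here.

## A worked example

```{r example, eval = FALSE}
mp <- macro_preset("fig8", r_I = 0.15)
predicted_pattern_size(mp)        # unstable, l_max = 4, P = 0.25
rc <- run_comparison("fig8", r_I = 0.15, seed = 1, T = 30)
rc$macro$n_peaks                  # 4
rc$ibm$n_peaks                    # 4
```

## Known limitations

* The 2D/3D continuum equations (coupled density–orientation transport)
  are not solved; 2D physics is available only through the particle model,
  and the 1D theory cannot distinguish clusters from bands or describe
  trails.
* The stiff-spring closure loses validity where it predicts $\rho_f < 0$;
  the package reports this but offers no well-posed replacement closure.
* The transport coefficients $c_1, c_2$ of the hydrodynamic limit are
  inputs (the reference experiments use $c_1 = 1$); their defining
  integrals are not evaluated here, and $c_2$ never enters the 1D system.
* Tether springs are linear and obstacle–obstacle interactions are absent,
  by model design.
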