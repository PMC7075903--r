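---
title: "Active elasticity of confluent cell monolayers: models, estimators and fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active elasticity of confluent cell monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activesheet)
```

## The model

Confluent epithelial monolayers on a substrate show swirl-like velocity
correlations extending over ten or more cell sizes. `activesheet` implements
the dense-active-matter picture of this phenomenon: cells are self-propelled
agents with overdamped dynamics,

$$\zeta \dot{\mathbf r}_i = \zeta v_0 \hat{\mathbf n}_i
  - \nabla_{\mathbf r_i} V,$$

where $\zeta$ is the cell–substrate friction, $v_0$ the active crawling
speed, and $\hat{\mathbf n}_i = (\cos\theta_i, \sin\theta_i)$ a polarity
direction that diffuses rotationally,
$\dot\theta_i = \eta_i$ with
$\langle\eta_i(t)\eta_j(t')\rangle = \delta_{ij}\,\delta(t-t')/\tau$.
Two interaction energies are provided:

* **soft disks** — one-sided harmonic springs,
  $V = \sum_{i<j}\tfrac{k}{2}(\sigma_i+\sigma_j-r_{ij})^2$ for overlapping
  pairs, simulated at packing fraction $\phi = \sum_i \pi\sigma_i^2/L^2 = 1$
  (overlap areas double-counted) with 30% radius polydispersity to emulate
  cell-size heterogeneity; an optional piecewise-linear attractive tail of
  relative range $\varepsilon = 0.15$ is available for experiment-matched
  runs;
* **self-propelled Voronoi (SPV)** — each cell is the Voronoi tile of its
  center and
  $V_i = \tfrac{K}{2}(A_i - A_0)^2 + \tfrac{\Gamma}{2}(P_i - P_0)^2$, with
  the dimensionless shape factor $\bar p_0 = P_0/\sqrt{A_0}$ controlling the
  solid–fluid transition (solid at 3.6, transition near 3.812).

Units follow the convention $k = \zeta = \bar\sigma = 1$ for the disk model,
so times are in units of $\zeta/k$ and lengths in mean radii.

## Linear response and the correlation length

Below the structural relaxation time the system fluctuates inside an energy
minimum, and the dynamics linearizes over the normal modes
$\boldsymbol\xi^\nu$ (eigenvalues $\lambda_\nu$) of the Hessian. Each mode
is an overdamped degree of freedom driven by exponentially correlated
(Ornstein–Uhlenbeck) noise, giving the mode energies

$$E_\nu = \frac{\zeta v_0^2 \tau}{4\,(1+\lambda_\nu\tau/\zeta)},$$

(equipartition at $T_{\rm eff} = \zeta v_0^2\tau/2$ as $\tau \to 0$, and a
$1/\lambda_\nu$ divergence of the soft-mode occupation at large $\tau$), and
the mode-resolved velocity correlation

$$\langle|\mathbf v(\mathbf q)|^2\rangle =
  \sum_\nu \frac{v_0^2}{2(1+\lambda_\nu\tau/\zeta)}
  \,|\boldsymbol\xi_\nu(\mathbf q)|^2 .$$

Coarse-graining to continuum elasticity (bulk modulus $B$, shear modulus
$\mu$) turns this into a two-Lorentzian spectrum

$$\langle|\mathbf v(\mathbf q)|^2\rangle = \frac{N v_0^2}{2}\left[
  \frac{1}{1+\xi_L^2 q^2} + \frac{1}{1+\xi_T^2 q^2}\right],
  \qquad \xi_L^2 = \frac{(B+\mu)\tau}{\zeta},\quad
  \xi_T^2 = \frac{\mu\tau}{\zeta},$$

with real-space counterpart
$C_{vv}(r) = \frac{a^2v_0^2}{4\pi}[K_0(r/\xi_L)/\xi_L^2 +
K_0(r/\xi_T)/\xi_T^2]$ and mean-square speed obtained by integrating the
spectrum up to the microscopic cutoff $q_m = 2\pi/a$. The correlation length
grows as $\sqrt{\tau}$ — persistence, not speed, sets the swirl size.

```{r lengths}
correlation_lengths(B = 1.684, mu = 0.510, tau = 2.5)
```

## Two time-scale conventions, made explicit

The angular noise $\langle\eta\eta\rangle = \delta(t-t')/\tau$ makes the
*polarity autocorrelation* decay as $\exp(-t/2\tau)$ (the angle variance
after time $t$ is $t/\tau$), while the linear-response formulas above are
derived for a projected noise correlator
$\tfrac12\zeta^2v_0^2\,e^{-|t-t'|/\tau}$, i.e. for an orientation
correlation time equal to $\tau$. Both statements appear side by side in the
source formulation; they differ by a factor 2 in the meaning of $\tau$. The
package keeps them cleanly separated:

* the **simulators** implement the angular noise literally (increment
  variance $\mathrm{d}t/\tau$); a test verifies the measured
  $\exp(-t/2\tau)$ law;
* the **theory and mode formulas** take $\tau$ to be the orientation
  correlation time (the OU correlator above).

To compare a simulation with drive persistence $\tau_d$ against the theory,
pass $\tau = 2\tau_d$ to the prediction functions (equivalently, run the
simulator at $\tau_d = \tau/2$). The acceptance comparisons do exactly this,
and the agreement of the mode sum with measured spectra to a few per cent
confirms the accounting.

## Elastic moduli: four estimators and why they disagree

`estimate_moduli()` quotes moduli in *per-particle units* (physical modulus
times area per particle) — the units in which the dynamical-matrix branch
slopes are read off. Four routes are available:

1. **`method = "dq"`, `tangent = "printed"`** (default). Assemble the
   per-contact blocks $-k\,\hat n\hat n^T + |f|\,\hat t\hat t^T$, Fourier
   transform to $D(\mathbf q)$, radially average the longitudinal and
   transverse eigenvalue branches and fit their slopes against $q^2$ through
   the origin up to $q = 1.5$. This is the published recipe for the
   reference packing, and it reproduces the reference bulk modulus
   ($B \approx 1.68$ at $N = 3183$) to about 1%.
2. **`tangent = "dimensional"`** replaces $|f|$ with $f/r$, which is the
   exact second derivative of the pair energy (verified against finite
   differences to $10^{-10}$); `assemble_hessian()` always uses this form.
3. **`method = "greens"`** measures the branches of the *inverse* Hessian,
   $\lambda_b(q) = 1/(N\,\mathbf e_b^H H^+ \mathbf e_b)$, via sparse
   Cholesky solves. Unlike the plane-wave quadratic form of $D(q)$, this
   harmonic-mean weighting includes the non-affine relaxation and converges
   to the true wave moduli at low $q$.
4. **`method = "strain"`** imposes small affine strains, re-minimizes, and
   differentiates the relaxed energy — the direct definition of the static
   moduli.

On a perfect crystal all four agree (the package tests this at 2%). On a
deeply jammed disordered packing they genuinely differ: the plane-wave
$D(q)$ branch overestimates the transverse slope because plane waves are not
eigenmodes of a disordered solid, the Green's-function branch lies below the
static modulus at accessible $q$ because quasi-localized soft modes deplete
it, and the pre-stress convention ($|f|$ vs $f/r$) shifts the transverse
branch by roughly the mean contact distance. For the reference packing the
four routes give transverse values spanning 0.4–0.85; the package reports
the default-pipeline value and exposes the alternatives rather than
averaging over conventions. The longitudinal slope is far more robust
(within a few per cent across routes and seeds).

```{r moduli, eval = FALSE}
cfg <- generate_packing(3183, packing_fraction = 1, polydispersity = 0.3,
                        seed = 1)
estimate_moduli(cfg)                        # default: printed D(q) pipeline
estimate_moduli(cfg, method = "greens")     # non-affine wave moduli
estimate_moduli(cfg, method = "strain")     # static stress-strain moduli
```

## Numerical choices

* **Minimization** uses FIRE (overdamped descent with adaptive inertia) with
  a monotone-energy safeguard; the default residual target is
  $\max_i|F_i| < 10^{-8}\,k\bar\sigma$. Plain gradient descent reaches the
  same minima but not within a practical iteration budget at $N = 3183$.
* **Integration** is first-order with $\delta t = 0.01$; the stationary
  velocity variance of a mode carries an $O(\lambda\delta t)$ discretization
  bias, a few per cent for the stiffest modes.
* **Small periodic boxes** (below three interaction ranges) switch from cell
  lists to explicit image sums, so confluent two-particle boxes are handled
  exactly; self-image separations are constant and contribute energy but no
  force.
* **Tessellation** is built per cell by half-plane clipping against
  bisectors in order of distance, with an early exit once no remaining
  candidate can cut the tile. Every tile vertex is the circumcenter of its
  generating triple, which makes the SPV forces exact analytic gradients
  through the circumcenter derivatives (verified against finite differences
  to $10^{-10}$). Exact cocircular degeneracies during dynamics are resolved
  by a deterministic $10^{-10}$-scale jitter. In open mode, tiles are
  clipped to the convex hull of the centers, hull cells are flagged as
  boundary, the line tension $\lambda$ multiplies the hull perimeter, and
  forces fall back to central finite differences (the closure construction
  is a package choice; periodic mode is the reference-tested default).
* **Wavevector grids** contain all box-commensurate vectors in a half plane
  ($\mathbf q$ and $-\mathbf q$ are redundant); radial averages use bins of
  width $2\pi/L$ labelled by the mean $|q|$ of their members.
* **Quadrature**: the temporal autocorrelation integrates the per-mode OU
  velocity correlation over both branches up to $q_m$, splitting the
  integral at the removable $\lambda\tau/\zeta = 1$ point, where the
  integrand's limit is evaluated analytically.
* **Spectrum fits** minimize count-weighted squared log-residuals, because
  the spectrum spans more than a decade and log residuals equalize leverage;
  the high-$q$ tail beyond $\pi/(2h)$ (grid spacing $h$) is excluded by
  default.

## The synthetic-field generator

`generate_field()` draws statistically independent frames of a Gaussian
random vector field on a PIV-like grid (54 × 40 nodes at 16 micron spacing
by default, matching time-lapse microscopy of corneal epithelial monolayers
at 10× magnification), with longitudinal/transverse Fourier amplitudes
following the two-Lorentzian spectrum, and rescales each frame to a
requested root-mean-square speed (about 12 micron/h in the experiments).
Frames are temporally independent: the generator validates the *spatial*
pipeline (spectrum estimation and the $\xi_T$ fit); temporal estimators are
exercised against simulator output and closed-form theory instead. Real PIV
fields differ in ways the generator does not emulate — non-Gaussian tails,
temporal persistence, measurement noise, and the unexplained high-$q$
behaviour seen in experiments — so passing the synthetic round trip shows
estimator correctness, not experimental realism.

## The fitting pipeline

With the moduli ratio fixed at $(\mu+B)/\mu = 4.3$ (the soft-disk value,
overridable), the mean-square-normalized spectrum has a single shape
parameter, $\xi_T$:

```{r fit}
flds <- generate_field(nx = 54, ny = 40, spacing = 16,
                       xi_L = sqrt(4.3) * 100, xi_T = 100,
                       v_rms = 12, n_frames = 120, seed = 7)
spec <- measure_vq(flds, normalization = "mean_square")
fit <- fit_xi_transverse(spec, moduli_ratio = 4.3, n_cells = 54 * 40)
fit
```

The $q \to 0$ amplitude implies $v_0/\bar v$; for confluent monolayers this
ratio is large (around 10), meaning most self-propulsion is absorbed by
elastic deformation. `fit_temporal()` then searches along the constraint
$\mu\tau/\zeta = \xi_T^2$ for the persistence time that best reproduces a
normalized velocity autocorrelation, and `map_to_model_params()` converts
$(\mu/\zeta, \tau, v_0)$ into simulation parameters via
$k/\zeta = \mu/\sigma^2$, $\Gamma/\zeta = \mu/\langle A\rangle$,
$K/\zeta = \mu/\langle A\rangle^2$. The constraint uses the
$\xi_T^2 = \mu\tau/\zeta$ form throughout (an alternative printed form with
$\tau$ in the denominator is dimensionally inconsistent).
`reference_monolayer_params()` stores the adopted corneal-monolayer
operating point, including the manually rounded $k/\zeta = 55\,h^{-1}$
(the raw map from $\mu/(\sigma^2\zeta) = 60.5\,h^{-1}$ would give 60.5).

## Scales used by the shipped checks

The packaged tests run the physics at desk scale, chosen so each comparison
resolves the effect it checks: moduli at the reference $N = 3183$ over 3
seeds; mode-sum versus simulation at $N = 1000$ with runs of 2,500 (τ = 20)
and 10,000 (τ = 200) time units — the long-persistence run needs a
stationarity transient of about 2,500 time units before velocity statistics
settle; the glassy-trend and speed-collapse sweeps at $N = 500$; parameter
recovery on 54 × 40 grids over 10 seeds. Residual simulation-vs-theory
deviations at the few-per-cent level are real physics (anharmonicity at
large persistence amplitudes plus integrator bias), not sampling noise.

## Known limitations

* Substrate friction is the only dissipation channel; cell–cell ("wet")
  dissipation and alignment interactions are out of scope.
* The division/extrusion variant uses the simplest steady-state scheme
  (rate $\mathrm{d}t/\tau_{\rm div}$ per cell, daughters at a
  $0.1\bar\sigma$ offset, extrusion of the most compressed cell above the
  population target); division-algorithm internals beyond this are not
  modelled.
* Normal modes are computed for the disk model only; the SPV energy is
  simulated but not mode-analysed.
* The transverse elastic modulus of deeply jammed packings is
  convention-sensitive (see the moduli section); quantitative downstream
  uses should state which estimator they rely on.
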