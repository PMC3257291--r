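---
title: "Stochastic control analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic control analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochctrl)
```

## The problem

Genetically identical cells display phenotypic variability because gene
expression and other cellular processes are intrinsically stochastic. An
experimenter who can perturb reaction rates — promoter activation,
transcription, translation, degradation — often wants to move one statistical
property of a molecular species while pinning another: reduce the noise level
of a protein without shifting its mean, shift the mean without touching the
noise, or reshape the amplitude and period of a noisy oscillation.

`stochctrl` answers the question *which parameters, perturbed in which
direction and ratio, achieve a requested change* for any reaction network
modeled as a continuous-time Markov jump process (or a Langevin system with
explicit additive noise). It does so at the level of the linear noise
approximation (LNA), where every stationary second-moment property is an
explicit function of the steady state, so that exact parametric sensitivities
can be computed instead of estimated from stochastic simulation.

## Model and statistics

For a network with stoichiometry matrix $N$ (dynamic species $\times$
reactions) and rate vector $v(x, p)$, the macroscopic steady state $x^*$
solves $N v(x^*, p) = 0$. Conserved combinations (e.g. total promoter copies)
make $N$ rank-deficient; we factor $N = L N_R$ with $N_R$ of full row rank
over an *independent* subset of species and work in that reduced space.

Under the LNA the stationary covariance $C$ of the independent species solves
the Lyapunov (fluctuation–dissipation) equation
$$A C + C A^\top + D = 0, \qquad
  A = N_R \frac{\partial v}{\partial x} L, \qquad
  D = N_R\,\mathrm{diag}(v^*)\,N_R^\top,$$
with $A$ the reduced Jacobian and $D$ the diffusion matrix ($D$ is taken from
the model instead for Langevin networks). Derived statistics are the noise
levels $\eta_{ij} = C_{ij}/(x_i^* x_j^*)$ (squared coefficient of variation on
the diagonal) and the lagged autocovariance $R(\tau) = e^{A\tau} C$, reported
as the normalized same-species autocorrelation
$A_{ii}(\tau) = R_{ii}(\tau)/C_{ii}$.

### Control coefficients

The scaled control coefficient (CC) of a stationary property $Y$ with respect
to a parameter $p$ is the log–log sensitivity $(p/Y)\,\partial Y/\partial p$ —
the relative change in $Y$ per relative change in $p$. Mean CCs follow the
classical concentration-control expression
$\mathrm{d}x^*/\mathrm{d}p = -L (N_R J L)^{-1} N_R\, \partial v/\partial p$.
Covariance CCs come from differentiating the Lyapunov equation: for each
parameter, $\mathrm{d}C/\mathrm{d}p$ solves a second Lyapunov equation whose
inhomogeneity $\delta A\, C + C\, \delta A^\top + \delta D$ collects both the
explicit parameter dependence and the implicit dependence through the shifted
steady state. Noise-level CCs follow by the quotient rule, and autocorrelation
CCs integrate the variational system
$\mathrm{d}(\delta R)/\mathrm{d}\tau = A\,\delta R + \delta A\, R$ in closed
form through the exponential of the block matrix
$\left[\begin{smallmatrix} A & 0 \\ \delta A & A\end{smallmatrix}\right]$.

Every analytic CC route is cross-checked in the test suite against a fully
independent brute-force oracle (`finite_difference_ccs()`) that re-runs the
entire pipeline at log-perturbed parameters.

Because a uniform rescaling of all rate constants only rescales time, the
scaled CCs of means and noise levels over the rate parameters sum to zero
(the summation theorems), and the autocorrelation CCs sum to
$\tau\, A'(\tau)/A(\tau)$. Two caveats the package makes explicit:

* *Shape parameters* (the Hill constant and coefficient of a feedback term)
  do not scale rates linearly and are excluded from the summation set; each
  network carries its `rate_parameters`.
* For Langevin networks with a *constant* diffusion matrix, $D$ does not
  scale with the rates, so $C \mapsto C/\alpha$ and the noise-level CCs sum
  to $-1$ instead of $0$. The test suite asserts exactly that.

### Control vectors and orthogonal control

The control vector of a variable over a chosen parameter subset is its vector
of scaled CCs; the inner product with a relative perturbation
$\delta p / p$ gives the first-order relative response. To change a *moved*
variable while holding a *fixed* one, the moved vector $G_m$ is projected onto
the hyperplane perpendicular to the fixed vector $G_f$:
$$u \propto \pm\left(G_m - (G_m\!\cdot\!\hat G_f)\,\hat G_f\right), \qquad
  \varepsilon = |\sin\theta|, \qquad S = \lVert G_m\rVert\,\varepsilon,$$
with $\theta$ the angle between the two vectors. The efficiency
$\varepsilon$ is the fraction of $G_m$ living in the admissible space: it is
the unique trigonometric choice with the right limits (anti-parallel vectors
give 0, perpendicular ones give 1 and the maximal strength
$S = \lVert G_m \rVert$). The same direction falls out of the minimum-norm
Lagrange construction solved by `generalized_design()` (pseudoinverse of the
stacked control vectors), and the equivalence is asserted numerically on
random instances. Anti-parallel vectors — exactly what Poissonian species
produce, since $\eta = 1/x^*$ ties the noise vector to the negated mean
vector — are reported as an "orthogonal control impossible" outcome with
$S = 0$ rather than an error.

Numerically, $\varepsilon$ and $\theta$ are computed from the orthogonal
decomposition itself (`atan2` of perpendicular and parallel components), not
from `acos` of a normalized inner product: near the (anti-)parallel limit the
`acos` route loses half the significant digits and turns a structurally zero
efficiency into $\sim\!10^{-8}$.

### Constraint tolerance

When the fixed variable is allowed to move by up to `tol` per unit
perturbation, the admissible perpendicular plane thickens into a cone of
half-angle $\theta_d = \arcsin(\min(1, \mathrm{tol}/\lVert G_f\rVert))$. With
$\alpha = |\pi/2 - \theta|$ the moved vector's angle to the plane, the relaxed
efficiency is $1$ if $\alpha \le \theta_d$ and $\cos(\alpha - \theta_d)$
otherwise, with the direction rotated toward the plane by the excess angle.
`tol = 0` reduces exactly to the strict design, $\varepsilon_{tol}$ is
non-decreasing in `tol`, and the whole space becomes admissible once
`tol` $\ge \lVert G_f\rVert$; boundary ties ($\alpha = \theta_d$) resolve to
$\varepsilon_{tol} = 1$. This cone geometry is this package's reconstruction
of the verbal "expanded perpendicular space" idea; the monotonicity and limit
properties above are what the tests pin down.

### Iterative noise reduction

`iterate_noise_reduction()` applies the orthogonal direction in small
multiplicative steps, $p \leftarrow p\,(1 + \lambda \hat u)$, recomputing the
CCs after each step — a first-order Euler march along the constraint
manifold in log-parameter space (multiplicative updates keep parameters
positive for $\lambda < 1/\lVert\hat u\rVert_\infty$). Per step the held mean
drifts only at $O(\lambda^2)$; the test suite verifies the quadratic
per-step order on the two-state promoter by a Richardson check (halving
$\lambda$ cuts the one-step drift about fourfold).

One structural fact worth knowing: for a linear chain whose end product is
controlled through the chain constants $k_1..k_4$, the stationary end-product
mean depends on them only through $k_1/k_4$, so the constraint manifold is
*exactly* log-affine, the orthogonal direction satisfies $u_1 = u_4$, and the
march holds the mean to solver precision at any $\lambda$ — the drift you see
on that fixture is $\sim 10^{-11}$, not $O(\lambda^2)$.

### Oscillation control

For an underdamped system the normalized autocorrelation is a damped
oscillation; its first trough ($\tau_1$) and following peak ($\tau_2$) anchor
the amplitude, and the steepest descending flank in $(0, \tau_1)$ plus the
steepest ascending flank in $(\tau_1, \tau_2)$ anchor the period. A
parameter scores for *amplitude* control when its scaled CCs at
$\tau_1, \tau_2$ share a sign (in relative terms a same-sign pair inflates
both extremes, because the trough itself is negative). It scores for
*period* control when its flank sensitivities have opposite signs — a pure
stretch of the lag axis, $A(\tau) \mapsto A(\tau/(1+s))$, raises the
descending flank and lowers the ascending one. The period sign test uses the
log-parameter sensitivity $\partial A/\partial \ln p$ rather than the fully
scaled CC: dividing by $A(\tau)$, which itself changes sign between the two
flanks, would make the opposite-sign rule depend on which side of a zero
crossing an anchor happens to fall. Scaled CCs at lags where
$|A(\tau)| \le 10^{-6}$ are flagged and reported unscaled only.

## Numerical choices

* **Steady state**: damped Newton with positivity-preserving line search on
  the independent species (tolerance $10^{-10}$ relative on
  $\lVert N_R v\rVert$), falling back to `deSolve` relaxation with
  geometrically growing horizons, then Newton again. Conservation totals are
  honored exactly by construction.
* **Lyapunov solves**: direct dense Kronecker linear solve; the networks this
  package targets have at most dozens of species, where this is simpler than
  and as accurate as Schur-based methods. Residuals are checked to
  $10^{-10}\lVert D\rVert$ and covariance eigenvalues below
  $-10^{-9}$ (relative) are errors rather than clipped.
* **Matrix exponentials**: `Matrix::expm` (scaling-and-squaring Padé). The
  block-triangular exponentials used for autocorrelation sensitivities are
  exactly the case where cheaper eigendecomposition-based routines fail: the
  block matrix duplicates every eigenvalue of $A$ and is maximally
  non-normal. The matrix-ODE route (`deSolve`) is kept as an independent
  cross-check and the two agree to $10^{-8}$ in the tests.
* **Second derivatives of rates**: $\partial A/\partial p$ and
  $\partial A/\partial x$ are central finite differences (relative step
  $10^{-6}$) of the *analytic* first derivatives, keeping the symbolic layer
  of the expression grammar first-order only.
* **Expression grammar**: `+ - * / ^`, parentheses, numeric literals,
  declared identifiers and a built-in `hill(x, K, h)`; anything else is a
  schema error. Restricting the grammar keeps symbolic differentiation total
  and lets the SSA compile rate laws into fast closures.
* **SSA**: Gillespie's direct method, exact, no tau-leaping — fixtures are
  small and exactness is the point of the verification layer. Stationary
  estimators resample the step function on a uniform grid (refined so the
  smallest requested lag spans at least 4 grid cells) and use batch-means
  standard errors with 32 equal-time batches and 20% burn-in by default.
* **Overconstrained detection**: a generalized design is declared
  overconstrained when the least-squares residual exceeds
  $10^{-8}\lVert \text{targets}\rVert$ (overridable).

## The fixtures: what they emulate and what they do not

All numeric defaults below are this package's own documented choices.

* `birth_death(k_s = 2, k_d = 0.4)` — the minimal synthesis–degradation
  process. Its stationary law is Poisson, which makes it the analytic
  worked example: mean $k_s/k_d$, noise $k_d/k_s$, mean CCs $(+1, -1)$, noise
  CCs $(-1, +1)$, orthogonal control impossible.
* `two_state_promoter(0.1, 0.9, 10, 1, 5, 0.1)` — telegraph promoter with
  transcription, translation and first-order decays; one conservation
  relation (promoter copies). Defaults give a slow, mostly-off promoter
  (10% active), bursty mRNA and protein mean 50 — a regime where noise
  control genuinely conflicts with mean control and translation dominates
  the best two-parameter schemes.
* `linear_pathway(variant)` — three-metabolite chain fed through an enzyme.
  Variant A (fixed enzyme, no feedback) is an open first-order mass-action
  network: product-form Poisson stationary law, diagonal covariance, zero
  orthogonal-control efficiency — the structural negative control. B adds
  end-product Hill inhibition, C replaces the enzyme with a birth–death
  species (extrinsic noise), BC does both; each breaks product form and
  makes the efficiency strictly positive.
* `feedback_oscillator()` — a three-species negative-feedback ring (kinase →
  p53-like → inhibitor ⊣ kinase) driven by constant additive Gaussian noise.
  Defaults put the steady state at the Hill midpoint ($A = P53 = M = 20$)
  with a complex eigenvalue pair of quality $|\mathrm{Im}|/|\mathrm{Re}|
  \approx 4.5$, giving a clear sub-zero trough and positive peak in the P53
  autocorrelation. A ring is used rather than a two-species loop because a
  negative 2-cycle with first-order decays cannot exceed quality
  $\sim\!1$ — not enough structure for trough/peak anchor detection. The
  constructor rejects parameterizations whose eigenvalues are purely real.

What passing tests on these fixtures shows: the analytic machinery (steady
states, covariances, sensitivities, designs) is internally consistent, agrees
with brute-force recomputation, and reproduces every closed-form and
structural result available for linear networks. What it does not show: that
the LNA is adequate for any particular *nonlinear* real system at low copy
number — the approximation linearizes rates about the macroscopic state, and
its validity there must be checked case by case, e.g. with the package's own
SSA layer. The fixtures also idealize reality: single-promoter copy, no cell
cycle, no extrinsic noise beyond the explicit enzyme species, and the
oscillator is a structural stand-in rather than a fitted damage-response
model.

## Problem sizes used in the tests

Unit and property tests run entirely on the fixtures above (1–5 species).
Stochastic verification uses single trajectories of $4\times10^5$ to
$7\times10^5$ reaction events (birth–death and promoter), which put the
batch-means standard errors of means and noise levels near 1–2% — tight
enough for three-standard-error agreement checks against the LNA without
replicate averaging. Random-instance property checks (product form,
projection/minimum-norm equivalence, summation theorems) use 20–100 draws
under fixed seeds.

## Known limitations

* Frequency-domain (power-spectral-density) control coefficients are not
  implemented; the autocorrelation route avoids matrix inversions and serves
  the same dynamical-control purposes.
* CCs are infinitesimal sensitivities. Finite perturbations (10-fold rate
  changes, promoter mutations) can and do reorder control schemes; the
  iterative march is the package's tool for extending designs to finite
  amplitudes, and it assumes the sensitivity landscape stays smooth along
  the path.
* Only same-species normalized autocorrelations receive scaled CCs;
  cross-correlation sensitivities are available unscaled.
* SBML import is not implemented; models enter through the native
  structured-text schema or programmatic constructors.
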