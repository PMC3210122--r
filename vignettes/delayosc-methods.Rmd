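---
title: "Reduction theories for delay-induced neural oscillations: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduction theories for delay-induced neural oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delayosc)
```

## The model

`delayosc` studies networks of *delay-induced* oscillators of the
cortico-thalamic (neural mass) type. Each node describes the mean firing
rate deviation $u_i(t)$ of a local cortical area whose activity is fed
back through the thalamus with a transmission delay $\tau$:

$$
\ddot u_i = -2\gamma\dot u_i - \gamma^2(1 - a)\,u_i
  + \gamma^2\!\left[b\,u_i(t-\tau) + p_2 u_i^2 + p_3 u_i^3\right]
  + \gamma^2\!\sum_j \epsilon^u_{ij}(u_j - u_i)
  + \gamma\!\sum_j \epsilon^v_{ij}(v_j - v_i),
$$

with $v = \dot u$. The damping rate $\gamma$ (1/s) sets the intrinsic
time scale, $a$ is the instantaneous cortico-cortical gain, and $b$ the
delayed cortico-thalamic feedback gain — the control parameter: on the
branch traced by the package, $b < 0$ (negative feedback) and the rest
state $u \equiv 0$ undergoes a Hopf bifurcation as $b$ decreases through
a critical value $b_c(a)$. The quadratic and cubic coefficients
$p_2, p_3$ are the local curvature of the neuronal firing-rate
nonlinearity; throughout the package $p_2 = 0$ (which removes all
second-order center-manifold corrections from the cubic-order reduction)
and $p_3 = -1$ (saturating, so the bifurcation is supercritical and the
attractor globally bounded). Coupling is pairwise, symmetric and
*diffusive* — proportional to state differences, vanishing identically on
the synchronized manifold — through two channels: the state itself
($\epsilon^u$) and its derivative ($\epsilon^v$). Coupling delays are not
modeled: the intrinsic loop delay dominates.

Because the delayed term makes the phase space a function segment
$u([t-\tau, t])$, each oscillator is infinite-dimensional; the package's
purpose is to reduce this to tractable low-dimensional descriptions and
to quantify how far those descriptions can be trusted.

### Packaged working points

The parameter file `inst/extdata/param_sets.yaml` fixes $\gamma = 10$/s,
$\tau = 0.3$ s and three named points in the $(a, b)$ plane, expressed
through the bifurcation offset $\mu = b_c - b$:

| point | $a$ | $\mu$ | role |
|---|---|---|---|
| A | 0.6 | 0.03 | just above onset (0.88 Hz): small nearly sinusoidal cycle; reference point for all reduction validity checks |
| B | $-1.4$ | 0.03 | same offset (same amplitude) but ~45% faster; partner of A for amplitude death |
| C | 0.6 | 7.0 | far above onset: strongly anharmonic waveform; working point for multimodal locking |

These numbers are the package's own calibration of the three regimes the
methods address: A must sit where the asymptotic reductions hold to a few
percent (at this delay that means a ~3% relative offset); B must differ
from A in frequency by enough that diffusive coupling can quench the
pair (with both gains in $[0, 1]$ the projected coupling at these
parameters is too reactive for death, hence the inhibition-dominated
$a_B = -1.4$); and C must lie deep in the nonlinear regime while still
owning a stable simple periodic orbit. At C the subleading pair of
characteristic roots (the second delay branch, frequency ratio close to
5 at this point) is only weakly damped, and the cycle, its phase
sensitivity, and consequently the phase coupling function all carry
strong 5th-harmonic structure — the origin of five-fold multimodal
locking.

## Linear stability

The exponential ansatz gives the transcendental characteristic function
$$\Delta(\lambda) = \lambda^2 + 2\gamma\lambda + \gamma^2(1-a)
  - \gamma^2 b e^{-\lambda\tau}.$$
`find_hopf()` eliminates $b$ through the imaginary part of
$\Delta(i\omega) = 0$ and brackets the real part on the first branch
$\omega\tau \in (0, \pi)$, then polishes $(\omega_c, b_c)$ by a
two-variable Newton iteration to residual $10^{-12}$; transversality is
verified from $d\lambda/db = \gamma^2 e^{-i\omega\tau}/\Delta'(i\omega)$,
and the destabilizing direction of $b$ is recorded rather than assumed.
`hopf_curve()` continues the branch in $a$; `leading_roots()` locates all
characteristic roots above a floor by Newton iteration from a grid of
seeds (40 × 40 over $\mathrm{Re} \in [\text{floor}, \gamma]$,
$\mathrm{Im} \in [0, 3\pi/\tau]$, deduplication radius $10^{-8}$) and is
cross-checked in the tests by an argument-principle winding count.

```{r hopf}
sets <- load_param_sets()
find_hopf(sets$A)
```

## Direct simulation

`dde_integrate()` implements the method of steps with the classical RK4
scheme. Design choices, made for reproducibility rather than raw
adaptivity:

* the step divides the delay exactly ($dt = \tau/m$, $m \ge 20$, default
  40), so the derivative discontinuities radiating from $t = 0$ always
  land on grid points and every Hermite interpolation interval is
  internally smooth;
* delayed values at half steps come from cubic Hermite interpolation of
  an already completed step (values plus stored derivatives), keeping the
  observed order at 4 — verified against the exact piecewise-polynomial
  solution of a scalar linear delay equation, with the subtlety that the
  derivative at the history/solution junction is one-sided and the lag
  interpolant must use the matching side;
* no adaptive stepping, no event location; an overflow guard aborts at
  $|u| > 10^6$ with the blow-up time;
* default initial history is the constant $0.01$ (any history in the
  basin serves; converged-cycle segments can be supplied exactly via
  `cycle_history()`).

`find_limit_cycle()` defines the phase origin as the upward $u = 0$
crossing, refines crossing times on the dense interpolant, and reports
period (mean crossing interval), amplitude ($\max|u|$), and a quiescent
flag — amplitude death is a result, not an error. Because $p_2 = 0$
makes the model odd-symmetric, even Fourier harmonics of the cycle vanish
identically; the package therefore uses the 3rd harmonic (first overtone
actually present) when it needs a waveform-complexity measure.

## Center-manifold reduction

Near the Hopf point the segment space splits along the eigenfunctions
$\phi(\theta) = q e^{i\omega_c\theta}$, $q = (1, i\omega_c)^T$, paired
with dual eigenfunctions $\psi(s) = p e^{-i\omega_c s}$,
$p = (2\gamma + i\omega_c, 1)$, under Hale's bilinear form; the
closed-form normalization is $D = \Delta'(i\omega_c)$, so the projection
of a forcing $F$ in the $\dot v$ equation onto the critical mode is
simply $F/D$ (`build_center_basis()`, verified against high-resolution
quadrature of the bilinear form). Treating the offset $\nu = b - b_c$ as
a third, frozen variable of the extended system, the cubic-order planar
equation for the complex amplitude $z_j$ ($u_j \approx z_j + \bar z_j$)
is assembled in `amplitude_equation()`; rotating-frame averaging
(`cgl_reduce()`) gives the network Stuart–Landau / complex
Ginzburg–Landau form

$$
\dot z_j = (\mu^g_j + i\omega_j^{\rm eff}) z_j + c\, z_j |z_j|^2
 + \sum_k (K^u_{jk} + K^v_{jk})(z_k - z_j),
$$

with $\mu^g_j = \nu_j\gamma^2\,\mathrm{Re}\,E_j$,
$E_j = e^{-i\omega_j\tau}/D_j$, $c = 3\gamma^2 p_3 / D$, and projected
couplings $K^u = \gamma^2\epsilon^u/D$, $K^v = i\omega\gamma\epsilon^v/D$.
Three consequences used throughout:

* **supercriticality**: $\mathrm{Re}\,c < 0$ across the explored gain
  range, so a circular cycle of radius
  $|z|_\infty = \sqrt{\mu^g/|\mathrm{Re}\,c|}$ branches off;
* **phase sensitivity**: with shear $\beta = \mathrm{Im}\,c /
  \mathrm{Re}\,c$, the asymptotic phase of the normal form is
  $\Theta(z) = \arg z - \beta\ln(|z|/R)$, so an impulse with projection
  $d$ shifts the phase by $\mathrm{Im}[(1-i\beta)\,d\,e^{-i\theta'}]/R$ —
  a pure sinusoid whose amplitude grows as $1/\sqrt{\mu}$
  (`analytic_Z()`);
* **coupling functions**: averaging the projected diffusive coupling
  gives $\Gamma(\varphi) = \mathrm{Im}[\kappa(e^{i\varphi}-1)]$ with
  $\kappa_u = \gamma^2(1-i\beta)/D$ and $\kappa_v = i\omega\gamma
  (1-i\beta)/D$ (`analytic_gamma()`).

A structural remark: in this model **both** coupling channels carry an
odd (phase-difference-driving) component — the derivative channel would
be exactly even only if $\omega_c\tau$ were a multiple of $\pi$, which
the traced branch never attains. The pair experiments therefore use the
$u$ channel where the classic single-stable-state locking is wanted, and
the $v$ channel where its strong odd 5th harmonic at C produces
multimodal locking.

For a coupled pair the rest state can restabilize (amplitude death).
`death_eigenvalues()` computes both the exact eigenvalues of the
4-dimensional real linearization of the unaveraged amplitude equations
(counter-rotating terms included) and the second-order perturbative
values obtained by projecting the frequency/growth mismatch onto the
left/right eigenvectors of the coupling block; the death threshold is
bisected on the exact maximal real part.

## Phase reduction

Far from onset the center-manifold route fails but the oscillator still
has a stable cycle, and weak coupling can be reduced to phases alone.
`prc_direct()` measures the phase sensitivity by the direct method: seed
the integrator with an exact converged-cycle history, add a small impulse
to the *current* value of one component (history untouched; an impulse in
$v$ is what a delta force in the second-order equation produces, so that
is the component the coupling convolution needs), integrate a
relaxation window, and read the asymptotic shift of the crossing times
against an identically seeded unperturbed run. Defaults: impulse
$10^{-3}$ of the cycle amplitude, 64 phases near onset and 128 at C
(higher harmonic content), 30–40 relaxation periods; linearity and
window-independence are tested, not assumed.

`gamma_convolution()` forms
$\Gamma(\varphi) = \frac{1}{2\pi}\int Z(\theta)\,[s(\theta+\varphi) -
s(\theta)]\,d\theta$ by the trapezoid rule on the uniform grid
(spectrally accurate for these smooth periodic integrands), with
$s = \gamma^2 u$ or $\gamma v$ per unit coupling intensity. The
antisymmetric part is oriented so that the phase difference
$\varphi = \theta_{\rm partner} - \theta_{\rm self}$ of a symmetric pair
obeys $\dot\varphi = \Delta\omega + \epsilon\Gamma_a(\varphi)$;
`locking_analysis()` then finds all roots by sign-change bracketing plus
bisection, classifies stability by the slope, and assigns basins bounded
by the unstable roots. `critical_coupling()` is the closed formula
$\epsilon_c = |\Delta\omega| / \max(\mp\Gamma_a)$.

## The experiments

* **Critical coupling** (`exp_critical_coupling()`): equal-amplitude
  pairs with prescribed mismatch are built by inverting the Hopf
  relations at fixed offset (`match_pair()`). The phase-formula column is
  evaluated at the pair's *measured* uncoupled frequency mismatch: the
  inverse construction controls critical frequencies, while the realized
  orbital frequencies also carry offset- and amplitude-induced shifts
  that differ slightly between partners (~17% here); the phase
  description is a statement about realized frequencies. Lock detection
  fits the drift rate of crossing-time phase differences (tolerance
  $2\pi\times10^{-3}$ per rotation) over windows long enough to resolve
  the slow beating near threshold.
* **Amplitude death** (`exp_amplitude_death()`): the A–B pair under a
  u-channel sweep. The simulated onset is bisected on the *sign of the
  asymptotic decay rate* of the amplitude envelope rather than on a
  fixed amplitude cutoff, because the decay rate vanishes at threshold
  and any finite-time cutoff biases the onset upward.
* **Multimodal locking** (`exp_multimodal()`): two identical C
  oscillators, v-channel, $\epsilon = 0.02$; initial conditions are
  time-shifted history segments of the same converged cycle, giving an
  exact uniform grid of initial phase differences. Final differences are
  clustered by circular gaps and matched to the predicted basins (a run
  seeded exactly on an unstable point has no predicted basin and is
  excluded from the agreement score).
* **Population** (`exp_population()`): an all-to-all, u-channel coupled
  ensemble with uniform gain/offset spreads around A, coupling
  normalized by $n$. The spreads (half-widths 0.05 in $a$, 0.01 in
  $\mu$) realize the narrowly-distributed-frequency regime the phase
  reduction assumes; with much broader spreads the coupling needed for
  synchronization is strong enough that amplitude-mediated frequency
  pulling (large shear here) makes the full ensemble synchronize before
  a phase-only model does. Phases are extracted from crossing times, the
  order parameter is the modulus of the mean phasor, and the reduced
  phase model is co-simulated with the measured $\Gamma$ (Fourier form,
  mean-field evaluation) and the measured uncoupled frequencies.
  `exp_population_death()` is the broad-spread quenching variant.

Problem sizes in the shipped tests and acceptance script (64–128 PRC
phases, 20 initial phase differences, $n = 50$ ensembles, 150–700 s
horizons) were chosen as the smallest that leave each estimate's
numerical noise well inside the tolerance it is compared against.

## What the synthetic conditions do and do not show

All inputs are generated from the model itself; there is no external
data. Passing tests demonstrate internal consistency of the three levels
of description (delay equation, amplitude equations, phase equations)
within their asymptotic regimes — near onset, weak coupling, narrow
frequency spread — and the existence of the three headline phenomena in
this model class. They do not validate the neural interpretation of the
parameters, the behavior under noise (not modeled), coupling delays
(excluded by design), or regimes beyond the first Hopf branch
(higher-frequency delay modes are only traced as spectra, and parameter
regions with chaotic attractors are flagged by the period-consistency
check rather than analyzed).

## Known limitations

* The analytic reduction path requires $p_2 = 0$; a nonzero quadratic
  coefficient is rejected explicitly rather than silently approximated.
* The direct PRC assumes a stable simple cycle; mixed-mode or chaotic
  attractors (large offsets between C and the second-branch takeover)
  are outside its contract.
* The perturbative death eigenvalues are second order in the mismatch
  and degrade when $|K|$ is small compared with $|\delta|$; the exact
  4-D eigensolve is always reported alongside.
* Amplitude equations carry their truncation error (a few percent in
  thresholds at these offsets); the package treats the full delay
  simulation as ground truth everywhere.
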