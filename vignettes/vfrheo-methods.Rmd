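---
title: "A fibril-scale visco-hyperelastic model of vocal-fold tissue mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fibril-scale visco-hyperelastic model of vocal-fold tissue mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfrheo)
```

## The model

The vocal-fold load-bearing layers — the lamina propria (a loose collagen
network in a gel-like ground substance) and the vocalis muscle (myofibril
bundles sheathed by collagen fibrils) — are treated as incompressible
fibre-reinforced composites. The microstructure is idealised as the
periodic repetition of a representative elementary volume (REV): four
fibril bundles connected at a central node, embedded in an isotropic
neo-Hookean matrix. Each bundle family is described by histological
descriptors: fibril diameter $d_0$, sinusoidal waviness (amplitude $R_0$,
period $H_0$, about ten periods per chord so $\ell_0 = 10\,H_0$), volume
fraction $\Phi$, and a mean orientation given by a polar angle $\theta_0$
from the longitudinal axis $e_z$ and an azimuth $\varphi_0$ from $e_x$.
The four directors are the images of one generating vector under sign
flips of its $x$ and $y$ components, which realises orthotropic symmetry
about $e_z$.

Two derived geometric quantities drive the elasticity:

* the tortuosity $\xi_0$, the arc length of one sinusoid period divided by
  $H_0$ (computed by adaptive quadrature; it equals the classical
  complete-elliptic-integral expression), and
* the apparent folded modulus
  $E_{eq}^0 = E_f \langle\cos\beta_0\rangle / (\langle\cos^2\beta_0\rangle
  + 16 v^2/d_0^2)$ with $v^2 = R_0^2/2$, the effective small-strain
  stiffness of a wavy fibril before it straightens.

**Kinematics.** Bundles convect affinely with the macroscopic deformation
gradient $F$: chord stretch $\lambda_i = \|F E_i\|$, log-strain
$\varepsilon_i = \ln\lambda_i$, direction $e_i = F E_i/\lambda_i$, rate
$\dot\varepsilon_i = e_i \cdot L \cdot e_i$ with $L$ the velocity
gradient. Unconnected neighbour nodes move affinely too; contact along
$e_q$ activates once the gap $\delta_q$ drops below a critical distance
$\delta_c$.

**Fibril force.** Each fibril carries a non-linear Zener (standard linear
solid) force $t_i = t_i^e + t_i^{ve}$. The neutral branch $t_i^e$ is
hyperelastic with a tangent that transitions smoothly from $E_{eq}^0$
(bending-dominated unfolding) to $E_f$ (taut stretching) around
$\varepsilon_i = \ln\xi_0$, a transition smoothed by the parameter
$\alpha$; in compression only the linear folded term is kept. The viscous
branch obeys a Maxwell evolution
$\dot t_i^{ve} + (E/\eta)\, t_i^{ve} = (\pi E d_0^2/4)\dot\varepsilon_i$
whose viscosity $\eta$ is a Carreau function of the *dashpot* strain rate
$\dot\varepsilon_i - 4\dot t_i^{ve}/(\pi E d_0^2)$: Newtonian plateau
$\eta_0$ below the transition rate $\dot\varepsilon_0$, power-law thinning
with index $n \in [0,1]$ above it.

**Steric interaction.** Active contacts carry a repulsive force
$R_q = R_q^e + R_q^{ve}$ with $R_q^e = -\beta|\ln(\delta_q/\delta_c)|^\kappa$
and a Maxwell–Carreau viscous part with parameters
$(E', \eta_0', \dot\varepsilon_0', n)$. The viscous steric force evolves
only while the contact is active and is reset to zero when contact is
lost: the dashpot force has no carrier without contact.

**Upscaling.** The macroscopic Cauchy stress is
$\sigma = -p\,\delta + \sigma_m + \sigma_f + \sigma_s$ with
$\sigma_m = \mu(1-\Phi)\,F F^T$ and
$$\sigma_f = \frac{\Phi}{(\pi d_0^2/4)\,\xi_0}\sum_{i=1}^4 t_i \lambda_i\,
 e_i \otimes e_i,\qquad
\sigma_s = \frac{\Phi}{(\pi d_0^2/4)\,\xi_0}\sum_{q=1}^5
 \frac{R_q}{\delta_q^*}\, e_q \otimes e_q,$$
where $\delta_q^* = \delta_q/\ell_0$; the vocalis sums two family terms.
The network prefactor is read as force per fibril cross-section, weighted
by volume fraction and tortuosity: this is the only reading with stress
units, and it yields the dilute-limit modulus $\Phi E/\xi_0$ times the
orientation factor. The factor-of-4 convention (cross-section
$\pi d_0^2/4$ rather than $\pi d_0^2$) rescales all fibril stresses
uniformly and therefore trades off exactly against the fitted moduli.

## Conventions the geometry does not pin down

Two aspects of the REV are not derivable from the histological inputs and
are fixed here as documented package conventions:

* **Steric neighbour set.** Candidate neighbours are the non-zero lattice
  vectors $\ell_0(E_i \pm E_j)$, $i \neq j$ (the network tiles space by
  translations along the bundle chords); the five smallest distinct
  distances are retained with a lexicographic tie-break
  (`buildNeighbors()`).
* **Neighbour rest distances.** The raw lattice distances are incompatible
  with the fitted contact distances: for the lamina propria samples one
  candidate rests far *inside* $\delta_c$ (which would put GPa-scale
  contact stresses into the undeformed state), while for the vocalis all
  candidates rest tens of $\delta_c$ away (contact would never engage,
  contradicting the central role of steric repulsion in transverse
  compression). A power-law barrier with $\kappa = 3$ and the fitted
  $\beta$ produces tissue-scale stresses only for penetrations of a few
  per cent of $\delta_c$, i.e. the rest gaps must be of the order of
  $\delta_c$ itself. `revGeometry()` therefore rescales the neighbour
  distances so that the nearest neighbour rests at
  $(1 + h)\,\delta_c$ with clearance $h = 0.05$ (directions and distance
  ratios preserved). With this near-contact packing the first contact
  engages at about 5% approach strain: transverse compression to a Hencky
  strain of $-0.2$ drives it well into contact, simple shear and the
  lateral contractions of moderate tension do not. $h$ is a geometry
  convention fixed once, not a fitting dial.

Other resolved ambiguities, chosen on dimensional or physical grounds:
the bracket of the neutral fibril force is grouped so that its tangent
runs from $E_{eq}^0$ to $E_f$ (the only grouping consistent with the
bending-to-stretching role of $\alpha$); the steric Maxwell drive uses
the prefactor $\pi E' d_0^2/4$ (dimensional consistency with the Carreau
argument), with $d_0$ the collagen-family diameter; contact activates on
approach ($\delta_q \le \delta_c$); the tissue-level steric channel uses
the collagen-row interaction constants where tables list per-family
values; the $\langle\cdot\rangle$ averages in $E_{eq}^0$ apply to
$\cos\beta_0$ and $\cos^2\beta_0$ separately.

## Loading programs and numerics

Drivers construct exactly unimodular kinematics:

* `runOscillatoryShear()`: $\gamma_{zx} = \gamma_0\sin(2\pi f t)$ with
  $F = \delta + \gamma\, e_z \otimes e_x$ (only the symmetric
  $\sigma_{zx}$ is reported, so the transpose convention is
  observationally irrelevant);
* `runCyclicShear()` and `runCyclicUniaxial()`: triangular strain paths at
  constant rate magnitude. In uniaxial modes the two lateral stretches are
  solved per step so both lateral normal stresses vanish (anisotropy makes
  them differ in general): a secant iteration on the log-ratio of the
  lateral stretches with a bracketed fallback, to a residual below
  $10^{-9}\max(\mu, 1\,\mathrm{Pa})$. The pressure follows from the
  traction-free condition ($\sigma_{yy} = 0$ in shear).

Internal forces advance by backward Euler: each step solves the scalar
implicit residual per element by damped Newton started from a linearised
predictor, with a deterministic expanding-bracket bisection fallback, to
$|r| \le 10^{-12}(\pi E d_0^2/4)\max(|\dot\varepsilon|,
\dot\varepsilon_0)$; failing steps are halved recursively (at most 20
times). Backward Euler is L-stable, which matters because the thinned
viscosity can make the local relaxation time much shorter than the step.
The price is first-order accuracy: at the default 200 steps per
oscillation cycle the steady-cycle first-harmonic moduli are converged to
better than 0.1%, while the raw stress *peak* during the start-up
transient still moves by about 0.5% under step halving; peak-level
statements should be made on steady cycles (where halving moves the peak
by under 0.05%) or at higher `stepsPerCycle`. Cyclic drivers default to
400 steps per triangular cycle.

All simulations start from the virgin state (zero internal forces), and
each loading mode starts fresh — no internal state is carried between
tension, compression and shear programs. Oscillatory runs stop at the
first cycle whose loop area changes by less than 0.5% (`detectSteady`),
with a guard that classifies all-zero-area (purely elastic) runs as
steady from cycle 1; moduli are extracted from the last simulated cycle
by first-harmonic Fourier projection, because start-up transients
contaminate early cycles.

## Parameters

| group | symbol | unit | meaning |
|---|---|---|---|
| histology | $\theta_0, \varphi_0$ | deg | bundle orientation (polar from $e_z$, azimuth from $e_x$) |
| | $H_0, R_0, d_0$ | m | waviness period, amplitude, fibril diameter |
| | $\Phi$ (or $\Phi_c, \Phi_m$) | – | fibril volume fraction(s) |
| hyperelastic | $E_f$ | Pa | fibril Young modulus |
| | $\mu$ | Pa | matrix shear modulus |
| | $\alpha$ | – | bending-to-stretching transition sharpness |
| | $\beta, \kappa, \delta_c$ | N, –, m | steric barrier stiffness, exponent, contact distance |
| viscoelastic | $E, \eta_0, \dot\varepsilon_0, n$ | Pa, Pa s, 1/s, – | bundle Maxwell spring, plateau viscosity, Carreau transition rate, thinning index |
| | $E', \eta_0', \dot\varepsilon_0'$ | Pa, Pa s, 1/s | steric Maxwell analogues (sharing $n$) |

Configuration files (YAML, micrometres/MPa, converted to SI at parse
time) ship as presets for six reference samples: `CSAOS` and `CLAOS`
(vocal-fold cover calibrated against small- and large-amplitude
oscillatory shear), `LP1`/`LP2` (lamina propria) and `V1`/`V2` (vocalis)
calibrated against multi-axial cyclic data. The vocalis presets carry two
families sharing the bundle viscoelastic parameters. Derived relaxation
times $\eta_0/E$ are 0.42 s (`CSAOS`), 0.27 s (`CLAOS`) and about 10 s
(`LP1`), with similar steric times $\eta_0'/E'$.

## Synthetic data and calibration

`makeSynthetic()` generates seeded pseudo-experimental datasets by
running the reference protocols — a SAOS sweep at $\gamma_0 = 0.01$ over
1–250 Hz, LAOS at 75 Hz with $\gamma_0 \in \{0.05, 0.1, 0.2, 0.5\}$, and
triangular cycles to $\varepsilon_{zz} = 0.1$, $\varepsilon_{xx} = -0.2$
or $\gamma_{zx} = 0.6$ at $10^{-3}\,\mathrm{s}^{-1}$ — and applying
multiplicative log-normal noise $\exp(\sigma Z)$ to the observables.
The generator emulates clean protocol geometry with stationary
multiplicative noise; it does not emulate inter-donor variability,
preconditioning/accommodation history, instrument compliance or drift, so
recovery results bound identification error under idealised conditions
only. Each dataset stores its own discretisation so that fits re-simulate
on the identical grid.

`fitModel()` performs bounded Levenberg–Marquardt least squares with
corridor constraints on the histological and hyperelastic parameters
(`parameterBounds()`), log-scaled positive parameters, SAOS residuals on
log-moduli (the moduli span decades), per-dataset RMS scaling, and seeded
Latin-hypercube multi-start. `profileParameter()` re-fits along a grid of
one parameter and flags flat profiles; a single-rate cyclic test cannot
pin the thinning index $n$ (any $n$ is compensated by $\eta_0$ and
$\dot\varepsilon_0$), reproducing the practice of fixing $n$ from the
oscillatory data.

## What the model does and does not reproduce

The test suite and acceptance script compute, among others:

* tortuosities from the $(R_0, H_0)$ pairs matching the tabulated
  histology-derived values to $\pm 0.01$;
* the quasi-static limit: cyclic tension at $10^{-9}\,\mathrm{s}^{-1}$
  collapses onto the neutral hyperelastic curve to well under 0.5% of the
  peak stress;
* tension hysteresis with positive residual strain on the first LP cycle,
  and the steric ablation contract — switching $\sigma_s$ off collapses
  the transverse-compression stress for both tissue types;
* intracycle strain stiffening (J-shaped loops) at $\gamma_0 = 0.5$ and
  stress levels growing with frequency in the Pipkin grid;
* agreement of simulated small-strain moduli with an independent
  linearised standard-linear-solid closed form to better than 1%.

A reproducible limitation surfaces at the SAOS operating point
($\gamma_0 = 0.01$) of the cover parameter set: there the fibril Zener
element is provably in its linear regime. The dashpot strain rate is
bounded by $\varepsilon_{el}/\tau_0 \approx 5\times10^{-4}\,
\mathrm{s}^{-1}$, below the Carreau transition rate
$\dot\varepsilon_0 = 2.1\times10^{-3}\,\mathrm{s}^{-1}$ (and the implicit
Maxwell residual is single-rooted for elastic strains below
$\sim 1.2\times10^{-3}$, while SAOS fibril strains are
$\sim 2\times10^{-4}$), so no thinning activates and the response is a
single-relaxation-time standard linear solid with $\tau = \eta_0/E =
0.42$ s. Consequences, all quantified by the acceptance suite: the
$G' = G''$ crossover falls near 0.35 Hz rather than in the reported
50–100 Hz window; the loss factor above 100 Hz is $\sim 0.02$ rather than
$\sim 0.73$; $G''$ decreases with frequency above $1/(2\pi\tau)$; and the
thinning parameters $(\dot\varepsilon_0, n)$ are unidentifiable from
clean SAOS data (their imprint is a $\lesssim 2\%$ constant viscosity
shift, degenerate with $\eta_0$). At LAOS and finite-strain cyclic
amplitudes the element is strongly non-linear and the documented
hysteresis, thinning and stiffening phenomenology appears — though the
relaxation proceeds in intracycle bursts, so low-amplitude loops carry
~12% cubic-harmonic content and the loop area is not perfectly monotone
in frequency at the smallest LAOS amplitude. Reproducing the reported
high-frequency oscillatory behaviour with these parameter values would
require a thinning argument of macroscopic-rate magnitude (for example
the local shear rate of the matrix around a bundle) instead of the
bundle-axial dashpot rate; exploring such a variant is future work, and
the constitutive laws implemented here are exactly the published forms.

Other known limitations: no damage or accommodation kinetics
(Mullins-type softening is out of scope, so repeated cycles stabilise
after the first), no poroelastic fluid transport, no inertia
(quasi-static stress balance at prescribed kinematics), and exactly four
discrete bundle directors rather than an orientation distribution.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` favour throughput: SAOS sweeps
use about 30 frequencies at 200 steps per cycle with steady-cycle
detection; oracle comparisons refine to 1500–2000 steps per cycle at a
handful of sub-hertz frequencies; cyclic runs use one cycle at 120–400
steps; calibration checks fit 4–6 frequency points. A full-resolution
study would simply raise `stepsPerCycle`, `nCycles` and the grid
densities; all observables shown here are converged at the stated levels
(halving checks are part of the suite).
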