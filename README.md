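# vfrheo

Micro-mechanical simulation of the finite-strain, rate-dependent mechanics
of human vocal-fold tissues.

The vocal-fold load-bearing layers — the *lamina propria* (a wavy collagen
network in a gel-like matrix) and the *vocalis* muscle (myofibril bundles
sheathed by collagen) — are soft, strongly anisotropic and markedly
viscoelastic: they sustain tension, compression and shear at finite
strains and oscillate at phonation frequencies from tens of hertz to the
kilohertz range. `vfrheo` implements a fibril-scale visco-hyperelastic
model of these tissues and the full battery of loading programs used to
probe them.

## The model in brief

The tissue is a periodic network of four fibril-bundle directors
$E_i$ in an incompressible neo-Hookean matrix. Bundles convect affinely
($\lambda_i = \lVert F E_i\rVert$, $\varepsilon_i = \ln\lambda_i$) and each
fibril carries a non-linear Zener force $t_i = t_i^e + t_i^{ve}$:

* a hyperelastic branch whose tangent stiffness runs from the folded
  apparent modulus $E_{eq}^0$ (set by the sinusoidal waviness $R_0, H_0$
  and diameter $d_0$) to the fibril modulus $E_f$ as the fibril
  straightens past its tortuosity $\xi_0$;
* a Maxwell branch
  $\dot t_i^{ve} + (E/\eta)t_i^{ve} = \tfrac{\pi E d_0^2}{4}\dot\varepsilon_i$
  with a Carreau shear-thinning viscosity
  $\eta = \eta_0\left[1 + (\dot\varepsilon^{v}/\dot\varepsilon_0)^2\right]^{(n-1)/2}$
  evaluated on the dashpot rate $\dot\varepsilon^{v}$.

Bundle–bundle steric repulsion activates below a critical node distance
$\delta_c$ with an elastic barrier
$R_q^e = -\beta\,|\ln(\delta_q/\delta_c)|^{\kappa}$ plus a Maxwell–Carreau
viscous part. The macroscopic Cauchy stress assembles as

$$\sigma = -p\,\delta + \mu(1-\Phi)FF^T
  + \frac{\Phi}{(\pi d_0^2/4)\xi_0}\sum_{i=1}^{4} t_i\lambda_i\, e_i\!\otimes e_i
  + \frac{\Phi}{(\pi d_0^2/4)\xi_0}\sum_{q=1}^{5} \frac{R_q}{\delta_q^*}\, e_q\!\otimes e_q,$$

with the pressure $p$ fixed by traction-free boundary conditions.
Drivers integrate the internal forces by implicit backward Euler through
small/large-amplitude oscillatory shear (SAOS/LAOS), cyclic tension,
transverse compression and longitudinal shear; post-processing yields
$G'$, $G''$, loss factor $\zeta^\star$, dynamic viscosity $\mu'$,
Lissajous/Pipkin diagrams and hysteresis metrics; bounded least squares
identifies the histo-mechanical parameters from rheometric data.

Six calibrated parameter presets ship with the package (`CSAOS`, `CLAOS`,
`LP1`, `LP2`, `V1`, `V2`). See the methods vignette
(`vignettes/vfrheo-methods.Rmd`) for assumptions, numerical choices and
known limitations — including a documented analysis of which reported
observables the published parameter values can and cannot reproduce.

## Worked example

```r
library(vfrheo)

m <- loadPreset("LP1")
m
#> <tissue_model> sample LP1
#>   kind:       lamina_propria
#>   families:  collagen (phi total 0.46)
#>     collagen   d0 0.4 um, xi0 1.128, Ef 847 MPa, Eeq0 604 kPa
#>   matrix:     mu 200 Pa
#>   bundle ve:  E 1.47 MPa, eta0 14.2 MPa s, edot0 0.0005 /s, n 0.27 (tau 9.66 s)
#>   steric:     beta 0.0002 N, kappa 3, delta_c 66 um, E' 0.99 MPa, eta0' 8.3 MPa s
#>   directors:  theta0 16 deg, phi0 83 deg, ell0 420 um

# one load/unload tension cycle along the anterior-posterior axis,
# Hencky strain 0.1 at 1e-3 /s
tr <- runCyclicUniaxial(m, axis = "z", epsTarget = 0.1, rate = 1e-3, nCycles = 1)
round(cycleMetrics(tr, 1), 4)
#>       loop_area     peak_stress residual_strain
#>       1467.0183     158721.6433          0.0032
```

The loop area (Pa) is the energy dissipated per unit volume over the
cycle, the peak stress is the maximum $|\sigma_{zz}|$ on loading, and the
residual strain is where the unloading branch crosses zero stress — the
inelastic strain left after one cycle.

```r
# SAOS sweep of the average vocal-fold cover at gamma0 = 0.01
sw <- saosSweep(loadPreset("CSAOS"), c(1, 10, 75, 250))
sw
#>     f G_storage G_loss loss_factor dyn_viscosity cycles
#> 1   1      1134  431.8      0.3809       68.7294      4
#> 2  10      1297   67.5      0.0521        1.0751      2
#> 3  75      1304   26.2      0.0201        0.0557      2
#> 4 250      1304   21.7      0.0167        0.0138      2
```

`G_storage`/`G_loss` are the first-harmonic moduli (Pa) of the steady
cycle, `loss_factor` their ratio $G''/G'$, and `dyn_viscosity`
$G''/2\pi f$ (Pa s). A steric-ablation experiment is one call away:
`runCyclicUniaxial(disableSteric(m), "x", -0.2, 1e-3)` versus the same
run on `m` isolates the bundle-contact contribution to transverse
compression.

A thin command-line front end lives at `inst/cli/vfrheo`
(`simulate-saos`, `simulate-laos`, `simulate-cyclic`, `make-synthetic`,
`calibrate`).

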