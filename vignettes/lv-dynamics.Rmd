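---
title: "A three-degree-of-freedom dynamic model of the left ventricle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-degree-of-freedom dynamic model of the left ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvdyn)
```

## The model

`lvdyn` simulates the beating left ventricle (LV) as a thick-walled,
axisymmetric, truncated prolate-spheroidal shell whose deformation is
restricted to a three-parameter family of volume-preserving mappings, and
couples it to a lumped-parameter circulation.  The aim is a model rich
enough to predict wall stress and strain fields, pressure-volume loops and
work budgets, yet cheap enough that a full cardiac cycle integrates in
seconds.

### Geometry and kinematics

Prolate spheroidal coordinates $(\mu, \nu, \phi)$ with interfocal
half-distance $a$ place the wall between two confocal spheroids,
$\mu_{in0} \le \mu_0 \le \mu_{out0}$, truncated at the base
$\nu_0 = \nu_{up}$.  Deformation is described by three time-dependent
parameters:

* $a_1$ (cm) — elongation, through $a = a_0 + a_1$;
* $a_2$ (cm) — circumferential contraction/expansion of the wall;
* $a_3$ (rad) — torsion growing from base to apex as
  $\phi = \phi_0 + a_3(\cos\nu_0 - \cos\nu_{up})$.

Myocardium is incompressible, so the radial coordinate of each material
point follows implicitly from the requirement that every coordinate shell
conserves its volume.  This yields a cubic in $\cosh\mu$ per point, solved
by a safeguarded Newton iteration on the branch continuous with the
reference state ($\mu = \mu_0$ when $a_1 = a_2 = 0$).  The deformation
gradient then has $\det \mathbf{F} = 1$ by construction; the test suite
asserts this to $10^{-8}$ on the quadrature grid and checks $\mathbf{F}$
against central differences of the mapped Cartesian positions.

Strain sensitivities $\partial\mathbf{E}/\partial a_i$ drive the weak-form
equilibrium.  For $a_3$ the derivative is analytic (only one component of
$\mathbf{F}$ depends on $a_3$, linearly); for $a_1, a_2$ we use scaled
central differences of the strain through the implicit mapping, validated
in the tests against fourth-order differences and an energy-gradient
oracle at $10^{-6}$ relative accuracy.  A fully symbolic derivation is
possible but error-prone, and adds no accuracy at the tolerances used.

### Fibers

Muscle fibers lie in surfaces of constant $\mu_0$ and wind helically with
a wrapping parameter $\omega(\mu_0)$ fixed by the equatorial helix angle,
which varies linearly across the wall from $+85^\circ$ (endocardium) to
$-65^\circ$ (epicardium), the classical transmural profile.  The local
fiber frame $(s, n, f)$ rotates fiber-frame tensors into prolate
components.  Fiber stretch is computed both as an arc-length ratio of the
helical curve and as $\sqrt{\mathbf{f}_0^{\mathsf T}\mathbf{C}\,
\mathbf{f}_0}$; the two routes agree to $10^{-6}$ everywhere and the
equality is asserted for randomized states.  Sarcomere length is
$L_s = \lambda_f L_{s0}$ with $L_{s0} = 1.82\ \mu$m at the reference
shape, which is taken near end systole; during diastole sarcomeres
stretch onto the descending limb of the length-tension curve.

### Constitutive model

Total second Piola-Kirchhoff stress:
$\mathbf{S} = -p_M \mathbf{C}^{-1} + \mathbf{S}_f + \mathbf{S}_e +
\mathbf{S}_v$.  The reaction term does no work under the
volume-preserving family and is omitted from the equilibrium equations.

* **Active fiber stress.**  $\sigma_{ff} = A(t)\,G(L_s)\,
  (F_0 + k_{av}\,\dot\varepsilon_f)(1 + k\,\varepsilon_{f,ed})$, uniaxial
  along the fiber; $A(t) = [\sin(\pi t/T_a)]^d$ with
  $d = 1/(1 + k'\varepsilon_{f,ed})$, so higher end-diastolic strain both
  (optionally, $k$) scales force and ($k'$) broadens activation.  With the
  default $k = 0$ the force scaling is disabled while $k' = 1$ still
  shapes the activation.  Defaults: $F_0 = 300$ kPa, $k_{av} = 0.5$
  kPa s, $L_{smax} = 2.23\ \mu$m, $L_{sw} = 0.2\ \mu$m, $T_a = 0.4$ s,
  $T_c = 1$ s.  End-diastolic strain is snapshotted per material point at
  the start of each activation (the model's end diastole); no clamp is
  applied to negative $\sigma_{ff}$ by default.
* **Passive elasticity.**  Transversely isotropic Fung-type energy
  $\Psi = \tfrac12 c_1 (e^W - 1)$ with
  $W = b_{ff}E_{ff}^2 + b_{xx}(E_{ss}^2 + E_{nn}^2 + 2E_{sn}^2) +
  b_{fx}\,2(E_{fs}^2 + E_{fn}^2)$; defaults $c_1 = 1$ kPa,
  $(b_{ff}, b_{xx}, b_{fx}) = (5, 3, 7)$.  The stress is the exact energy
  gradient (asserted numerically).
* **Viscosity.**  Kelvin-Voigt matrix viscosity, the pull-back of the
  fluid form: $\mathbf{S}_v = k_{vm}\mathbf{C}^{-1}\dot{\mathbf{C}}
  \mathbf{C}^{-1}$, $k_{vm} = 0.025$ kPa s; a push-forward oracle checks
  the simple-shear limit.

### Equilibrium and circulation

Virtual work of the three generalized coordinates reduces equilibrium to
$\mathbf{M}(\mathbf{a}, t)\,\dot{\mathbf{a}} + \mathbf{g}(\mathbf{a}, t) =
\mathbf{b}(\mathbf{a})\,p$, where $\mathbf{M}$ collects the rate-linear
stresses (viscosity, force-velocity), $\mathbf{g}$ the rate-independent
ones, and $\mathbf{b}$ the boundary work of the cavity pressure per unit
pressure.  The internal integral uses 2-D Simpson quadrature on a regular
$9 \times 11$ mesh over $(\mu_0, \nu_0)$; refinement to $17 \times 21$
moves converged stroke work by less than $0.1\%$.

The external work has an endocardial lateral term (a line integral over
$\nu_0$, 41 Simpson nodes) and a basal term.  The basal boundary
condition of a truncated shell is genuinely ambiguous in a reduced model;
we model it as the cavity pressure acting on the flat basal disk of the
cavity through the axial motion of the basal endocardial edge.  With this
choice $\mathbf{b}$ equals $\partial V/\partial \mathbf{a}$ *identically*
(the lateral sweep plus the disk sweep is exactly the rate of change of
the cavity volume), so external power equals $p\,dV/dt$ and the
work-balance closure between net internal work and stroke work is exact
up to integration error for every basal angle, including
$\nu_{up} = \pi/2$ where the basal plane cannot move.  Torsion does no
boundary work.

The circulation is a four-node circuit: constant pulmonary source
pressure, atrial compliance, LV, aortic impedance + compliance, systemic
drain.  Valves are smooth sigmoidal resistances in the transvalvular
pressure difference, switching between a closed value $R_{cc}$ and the
open values.  $R_{cc} = 10$ kPa s/cm$^3$ and sigmoid steepness
$\beta = 50$/kPa are model choices (with $\beta = 50$ the open valve
behaves like a diode with a forward drop of $\approx 0.2$ kPa at
physiological flows); stroke work moves by only a few percent when
$\beta$ is varied tenfold, and the defaults are fixed once in
`lv_circulation()`.  The aortic valve law and the pressure divider at the
aortic root are mutually dependent and are resolved simultaneously inside
the per-stage solve.

### Time integration

The coupled system is a differential-algebraic system: five differential
states $(a_1, a_2, a_3, P_A, P_{AO})$ plus the algebraic cavity pressure
$p$.  Because $\mathbf{M}$, $\mathbf{g}$, $\mathbf{b}$ do not depend on
the rates, each stage reduces to a *scalar* monotone equation for $p$
(flow balance with $\dot{\mathbf{a}} = \mathbf{M}^{-1}(\mathbf{b}p -
\mathbf{g})$ substituted), solved by warm-started Newton/secant iteration
to a residual of $10^{-10}$ cm$^3$/s, with a bracketed fallback.  Time
stepping is two-stage second-order Runge-Kutta (Heun); the observed
convergence order in the tests is $\ge 1.8$.

The wall mechanics is stiff: linearizing
$\dot{\mathbf{a}} = \mathbf{M}^{-1}(\mathbf{b}p - \mathbf{g})$ gives
relaxation rates up to a few $10^3$/s during systole (exponential
passive stiffness against the viscosity).  The baseline step
$5\times10^{-4}$ s therefore sits near the explicit stability bound, and
two safeguards adapt the step deterministically: (i) the classical
valve-transition trigger — refine to $5\times10^{-5}$ s when a valve
sigmoid argument is within $5/\beta$ of switching *and* slewing faster
than 1 kPa/s (the slew condition prevents permanent refinement during
diastasis, where the open-valve gradient rests inside the band); (ii) an
embedded-error control that redoes a step at half size when the stage
disagreement $\tfrac{dt}{2}\lVert f_2 - f_1\rVert$ exceeds a scaled
tolerance ($2\times10^{-3}$).  Steps land exactly on activation and cycle
boundaries, so the activation kink never falls inside a step.  Halving
the baseline step changes converged per-cycle works by $< 0.05\%$.
All runs are deterministic: identical configurations produce bit-identical
output.

### Work accounting

At every accepted step the instantaneous powers are evaluated from the
converged stage solution and integrated per cycle by the trapezoidal
rule: fiber power $\int \mathbf{S}_f : \dot{\mathbf{E}}\,dV_0$ (reported
with the sign that makes contracting fibers do positive work), viscous
dissipation (always $\le 0$), net elastic power (vanishing over a closed
cycle, asserted $< 0.2\%$ of stroke work), boundary work, and stroke
power $p\,dV/dt$.  Work is reported in joules using
1 kPa cm$^3$ = 1 mJ.  Because $\mathbf{b} = \partial V/\partial
\mathbf{a}$ exactly, the identity "net internal work = stroke work" holds
to round-off at every basal angle; it is asserted at $10^{-4}\%$ for the
equatorially-truncated shapes and $5\%$ for the default shapes.

## Study conditions and problem sizes

The default experiment integrates 12 cardiac cycles for each of three
reference shapes with identical cavity (59.8714 cm$^3$) and wall
(158.112 cm$^3$) volumes — spherical, normal and ellipsoidal — from
common initial conditions $a_i = 0$, $P_A = 1.5$ kPa, $P_{AO} = 10$ kPa
(chosen once, near the periodic state; the transient decays within 4-5
cycles and reported averages use cycles 6-12).  The energy-closure
experiment rebuilds each shape with $\nu_{up} = \pi/2$ at unchanged
volumes via monotone root finds on the truncated-spheroid closed form.
Quadrature sizes are the defaults above.  These are also the problem
sizes exercised by the test suite and the acceptance script.

```{r shape-presets}
do.call(rbind, lapply(names(lv_shape_presets()), function(nm) {
  g <- lv_geometry(nm)
  data.frame(shape = nm, a0 = g$a0, mu_in0 = g$mu_in0, mu_out0 = g$mu_out0,
             cavity = cavity_volume(g), wall = wall_volume(g))
}))
```

## Degenerate inputs and numerical choices

* The mapping solve fails loudly ("deformation too extreme") when the
  implicit cubic has no root with $\mu > 0$; the simulator halves its
  step before giving up.
* Exactly circumferential fibers (zero equatorial angle) make the
  wrapping parameter infinite; the code takes the circular-fiber limit.
  The default $9$-node transmural grid does not contain the zero
  crossing.
* The strain-energy exponent is capped ($W > 250$ aborts with a
  diagnostic) to catch runaway strains before floating-point overflow.
* The static inflation solver is Newton with step halving on a
  finite-difference Jacobian, with a damped pseudo-time fallback that
  integrates the viscous dynamics to rest.

## What the model does not represent

Only the LV is modeled: no right ventricle, pericardium, atrial
contraction ("atrial kick"), or inertia.  The shape family is
axisymmetric, so regional wall-motion abnormalities are out of reach.
The activation is prescribed, not electrophysiological, and the fiber
architecture has a single transmurally linear helix-angle law without
sheet structure.  The basal boundary treatment is a reduced-order
idealization; we chose the variant with exact work closure, which means
the small basal-closure discrepancy characteristic of cruder basal
approximations is absent here by construction.  Passive parameters are
taken from the literature defaults rather than fitted to a specific
subject; simulated EDV, pressures and ejection fraction land in the
normal human range, but individual hearts differ.
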