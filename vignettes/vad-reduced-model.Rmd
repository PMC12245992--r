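---
title: "A reduced-order model of maternal soft-tissue loading in vacuum-assisted delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of maternal soft-tissue loading in vacuum-assisted delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vadsim)
```

## The problem

Vacuum-assisted delivery (VAD) applies traction to the fetal head through a
suction cup during uterine contractions. The technique is associated with
pelvic floor trauma — levator ani avulsion, perineal tears, obstetric anal
sphincter injuries — and clinicians lack quantitative guidance on how
contraction duration, rest intervals between pulls, and the number of pulls
affect the load on maternal tissues. `vadsim` provides a desk-scale,
fully testable model of this question: finite-strain constitutive models of
the pelvic floor muscle (PFM) and perineal structures, a
displacement-controlled pull/rest traction protocol, and a reduced-order
geometric model of the two hiatal openings the head must pass (the levator
hiatus and, more caudally, the urogenital hiatus). The package is built for
*orderings and mechanisms*, not absolute organ-level stresses: a full 3D
finite-element contact model would be needed for the latter, and no such
meshes are shipped here.

## Constitutive models

### Transversely isotropic hyperelasticity (PFM)

The pelvic floor muscle is modeled with a transversely isotropic strain
energy split into isotropic matrix, fiber and volumetric parts,
$U = U_m + U_f + U_J$, with

$$U_m = c\,\{e^{b(\bar I_1 - 3)} - 1\}, \qquad
  U_{f} = A\,\{e^{a(\bar\lambda_f - 1)^2} - 1\}
        + \theta\,T_0^M\!\left[(\bar\lambda_f - 1)
        - \tfrac{4}{3}(\bar\lambda_f - 1)^3\right], \qquad
  U_J = \tfrac{1}{D}(J - 1)^2 .$$

Here $\bar I_1$ is the first invariant of the isochoric right Cauchy–Green
tensor, $\bar\lambda_f$ the isochoric fiber stretch, $J = \det F$, and the
active fiber term (activation $\theta \in [0,1]$, peak tension $T_0^M$) is
written in closed form as the antiderivative of the activation envelope
$-4(\bar\lambda_f-1)^2 + 1$. Defaults are the pelvic-floor values
$c = 0.0185$ MPa, $b = 1.1730$, $A = 0.0280$ MPa, $a = 0.6215$, with
$\theta = 0$ throughout — passive tissue, a reasonable approximation for
the majority of vaginal births; the active branch is implemented and
unit-tested but inert by default, and $T_0^M$ (no established value for
this tissue in this setting) defaults to a placeholder 0.682 MPa that has
no effect while $\theta = 0$.

Two constants required by the implementation have no canonical value:

* **Volumetric stiffness.** $D$ is a penalty constant; we default to
  $1/D = 10$ MPa, roughly 200× the matrix shear modulus $2cb \approx
  0.043$ MPa, i.e. near-incompressible without being numerically stiff.
  It is configurable per material.
* **Stress measure.** All reported stresses are Cauchy ("true") stresses;
  "maximum principal stress" on a ring in the uniaxial reduction below is
  the hoop Cauchy stress.

Cauchy stresses are obtained analytically from the standard isochoric
push-forward ($\sigma = \frac{2}{J}W_1\,\mathrm{dev}\,\bar b +
\frac{1}{J}W_\lambda \bar\lambda_f\,\mathrm{dev}(m \otimes m) +
\frac{2}{D}(J-1)I$) and verified, state by state, against central-difference
differentiation of the energy (`numerical_stress_oracle()`, truncation
$O(h^2)$): the test suite requires agreement to a relative $10^{-5}$ on
seeded random isochoric deformations. In the incompressible uniaxial
convenience mode the pressure is eliminated by the lateral traction-free
condition rather than by a mixed formulation — there is no mesh in this
package, so analytic enforcement is exact.

Companion models: perineal body and bulbospongiosus are linear elastic
($E = 23.8$ kPa, $\nu = 0.49$); the external anal sphincter is Neo-Hookean
($c_{10} = 0.1$ MPa); the fetal head is linear elastic ($E = 1.1$ MPa,
$\nu = 0.25$). A linear law "at hiatal stretch 3" is of course a strong
simplification; we keep the one-dimensional engineering convention
$\sigma = E(\lambda - 1)$ for ring segments, mirroring the simplicity of
the tissue assignment itself rather than inventing a finite-strain
extension the assignment never specified.

### Generalized-Maxwell viscoelasticity

The PFM response is time dependent. We attach two sets of Maxwell branches
— matrix: $(B, \tau) = (1.5, 20\,\mathrm{s}), (0.7, 400\,\mathrm{s}),
(0.5, 5000\,\mathrm{s})$; fiber: $(1.2, 0.9\,\mathrm{s}),
(0.5, 250\,\mathrm{s}), (0.3, 3500\,\mathrm{s})$ — each shadowing its own
isochoric stress contribution. The reduced relaxation function is

$$g(t) = 1 + \sum_\alpha B_\alpha e^{-t/\tau_\alpha},$$

so the instantaneous stiffness is $(1 + \sum B)$ times the equilibrium
(long-term) stiffness: 3.7× for the matrix set, 3.0× for the fiber set.
The alternative normalization (instantaneous = 1, equilibrium reduced)
is rejected because branch ratios above 1 are incompatible with it.

The published source for these parameters prints only the free-energy form
of the dissipative potential, not the evolution law, so the integrator is
a design decision: we use the conventional stress-like internal-variable
recurrence with exponential integration,

$$H_\alpha^{n+1} = e^{-\Delta t/\tau_\alpha} H_\alpha^{n}
  + B_\alpha\, e^{-\Delta t/(2\tau_\alpha)}\, \Delta \bar S,$$

second-order accurate via the midpoint factor and exact for
piecewise-constant stress rates, with total stress = equilibrium stress
$+\sum_\alpha H_\alpha$. The suite verifies the recurrence against the
closed form $g(t)\bar S$ branch by branch (1% band), checks relaxation
completeness after $5\tau_{\max}$, and checks that halving the time step
changes a full simulation's stress trace by well under 0.5% in sup-norm.
Default steps: 1 s during maneuver phases, 60 s during the 3 h engagement
ramp — the exponential integrator is unconditionally stable, so the coarse
engagement step costs accuracy only in the slowly varying ramp where it is
negligible.

## The traction protocol

A protocol is: 3 h of engagement (prolonged labor; the head settles into
the pelvic floor), then $n$ pulls. Timing values follow cardiotocographic
ranges: contractions of 60 or 90 s, rests of 60 or 180 s, 2–4 pulls,
100 mm total cup descent; the full crossing gives the canonical
12-scenario grid. Three protocol details are underdetermined and fixed
here as package design decisions: the descent is split **equally** across
pulls; each pull is a **linear** ramp (constant descent rate); and **no
rest follows the final pull**. The engagement phase holds the cup at zero
displacement — its descent is absorbed into the canal model's pre-stretch
ramp, because the cup is only placed once engagement is complete.

## The reduced canal model

The 3D anatomy is reduced to two material rings crossed by an axisymmetric
quasi-rigid head profile (default: a sphere of radius 47.5 mm, an
order-of-magnitude term-head radius; the head's 1.1 MPa modulus is several
hundred times the tissue moduli, which justifies rigidity for ring
kinematics — head compliance is exercised separately by the calibration
module). A ring of undeformed circumference $C_0$ at axial station $z$ is
kinematically distended by the head section crossing its plane:

$$\lambda(d) = \max\!\left(1, \frac{2\pi\,\rho(z - d)}{C_0}\right),$$

purely geometric and identical across material configurations. During
engagement each ring ramps linearly from $\lambda = 1$ to a pre-stretch
$\lambda_{\mathrm{eng}} = 1.3$ (so that viscoelastic history exists before
the first pull); during the maneuver the stretch is the kinematic value
floored at $\lambda_{\mathrm{eng}}$ — the engaged head holds the
pre-distension open, which also keeps the stretch history continuous at
the engagement/maneuver boundary.

Each ring carries a one-dimensional incompressible uniaxial (hoop) stress
state: the levator ring uses the muscle model with both viscoelastic
branch sets (fiber direction circumferential — hoop loading is the
dominant hiatal mode), the urogenital ring the linear elastic perineal
law. This is a deliberate 1D reduction of "maximum principal stress along
a path".

**Default anatomy is calibrated, not predicted.** Ring circumferences are
set to $2\pi R / 2.09$ and $2\pi R / 3.01$ and stationed at 69.91 mm and
79.51 mm so that the kinematic peak stretches and their descents equal the
reference values for levator and urogenital hiatus by construction. What
the model then *predicts* is everything downstream: stress histories,
relaxation, and cross-scenario orderings.

**Cup force.** The axial traction is a membrane projection,
$F_y = \sum_{\text{rings}} \sigma_1 A \sin\alpha$, with $\alpha$ the local
slope angle of the head profile at the ring plane and $A$ a configured
effective area per ring (defaults 150 and 100 mm²; newton values scale
with these areas and are not comparable to full 3D contact resultants —
only orderings are claimed). Only the head's *leading face* contributes:
once the equator has passed a ring plane, the hoop tension's axial
component acts along the descent rather than against it, so the ring stops
resisting.

## Synthetic data

The generators stand in for undeposited geometry and experimental curves:

* `default_anatomy()` — deterministic, anchor-calibrated (above).
* `perturbed_cohort(n, cv, seed)` — independent mean-1 lognormal factors
  on head radius and ring circumferences. Each factor carries
  $\mathrm{CV} = cv/\sqrt 2$ so that the *derived peak stretch*
  (proportional to a ratio of two independent factors) has cohort CV
  $\approx cv$: the dial controls the variability of the quantity a
  sensitivity study actually varies. Factors are drawn per anatomy and
  ring; generation is a pure function of $(n, cv, \mathrm{seed})$ and
  leaves the global RNG stream untouched.
* `synthetic_compression_curve()` — forward Hertz forces on a deflection
  grid spanning $(0, 5]$ mm with independent multiplicative Gaussian noise
  $(1 + cv\,z_i)$; the real neonatal curves exist only as published
  figures, so a multiplicative, positivity-respecting noise model is
  assumed.

What the generators do **not** emulate: real hiatal rings are neither
circular nor planar, the head is not axisymmetric and rotates (flexion,
internal rotation) during descent, and tissue properties vary spatially.
Passing tests therefore demonstrate correctness of the mechanics and the
claimed orderings *within this idealization*, not clinical validity on
real anatomies.

## Head-modulus calibration

The forward plate-compression model is two-sided Hertz contact on an
elastic sphere ($F = \tfrac43 E^* \sqrt R\, (\delta/2)^{3/2}$,
$E^* = E/(1-\nu^2)$, default $R = 45$ mm — the order of a term head's
biparietal half-axis), adequate for exercising the calibration loop though
not a substitute for a meshed skull. Only $E$ is optimized; $\nu$ stays at
0.25. Because the model is exactly linear in $E$, the least-squares
minimizer is closed-form (computed via `lm` without intercept), and the
round-trip identity — generate at $E$, recover $E$ — is exact to numerical
precision on noiseless curves; at 2% multiplicative noise the seeded
recovery error and the 100-replicate RMSE both stay under 2%.

## Numerical choices and degenerate inputs

* Non-positive $\det F$ and non-unit fiber directions are rejected at
  state construction; the uniaxial convenience mode refuses non-uniaxial
  deformations rather than silently projecting.
* A head too small to distend a ring yields a valid run with
  $\lambda \equiv 1$ plus a warning; a zero-descent protocol with unit
  pre-stretch yields identically zero stress.
* A rest phase starting from zero stress reports `NA` relaxation rather
  than dividing by zero.
* Rest-phase relaxation percent is defined as
  $100(\sigma_{\mathrm{start}} - \sigma_{\mathrm{end}}) /
  \sigma_{\mathrm{start}}$ over the rest window; cross-scenario percent
  decrease as $100(\mathrm{peak}_A - \mathrm{peak}_B)/\mathrm{peak}_A$.
* Elastic stress-vs-displacement profiles are evaluated exactly through
  the ring kinematics (they depend on displacement only); viscoelastic
  profiles are interpolated from the simulated time series and are
  protocol-dependent, as they should be.
* Problem sizes: the default sweep simulates 12 scenarios at 1 s maneuver
  resolution and 60 s engagement resolution (≈360–1100 samples per
  scenario); the anchor sweep scans displacement at 0.01 mm. These sizes
  keep every quantity stable to well inside the tested tolerances
  (halving the step moves stress traces by < 0.01%).

## What the model reproduces, and one thing it does not

With default conditions the package reproduces the qualitative findings
that motivated it, each computed by the test suite and the acceptance
script: shorter contraction/rest timing raises peak PFM stress at every
pull count; at 60 s/60 s timing peak PFM stress decreases monotonically
from 2 to 4 pulls (the computed 2→4 decrease, 8.8%, is close to the
full-3D reference of 8.4%); stress relaxes strictly during every rest
(second-rest relaxation 23.3% in the 90/180/3 scenario vs 19.2% in the 3D
reference); and the elastic urogenital ring's stress–displacement curve is
bit-identical across all 12 scenarios.

Peak **cup force**, however, is *not* monotone in pull count here: the
3-pull scenario peaks above the 2-pull one (≈214 N vs ≈196 N with default
areas), although 2 > 4 holds. The cause is structural. With equal descent
increments, the 3-pull scenario's second pull (33.3→66.7 mm) happens to
cover the entire steep stretch rise (contact starts near 33 mm, stretch
peaks at 69.91 mm) in one uninterrupted 60 s ramp, so at the
force-critical displacements (~55 mm, where the slope projection
$\sin\alpha$ is still large) it carries more short-time overstress than
the 2-pull scenario, whose rest at 50 mm wipes the 20 s branch. The peak
*stress* ordering survives because stress peaks at the stretch maximum,
where $\sin\alpha \to 0$ removes the geometry weighting. A related
boundary effect inverts the stress ordering marginally at 60/180 timing
(2 vs 3 pulls, 1% apart); the pull-count analysis in the reference work
was performed at 60/60 timing only, and that is where the package asserts
it. We report the force non-monotonicity as a genuine limitation of the
ring reduction rather than adjusting geometry or protocol to mask it.

## Limitations

No 3D discretization, contact mechanics, cup suction model, head rotation
or flexion-point geometry; absolute stresses and forces are not
comparable to full-model values (the reduced peak PFM stresses are ~7 MPa
against ~0.8 MPa in 3D, since a thin ring concentrates what a muscle
sheet distributes); one head shape and one anatomy by default. The
package's claims are the mechanisms and orderings its tests compute.
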