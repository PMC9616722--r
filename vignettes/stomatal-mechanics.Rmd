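---
title: "Turgor-driven guard-cell mechanics and AFM stiffness mapping with stomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turgor-driven guard-cell mechanics and AFM stiffness mapping with stomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Stomatal pores open because the two guard cells surrounding them inflate
under turgor pressure and flex apart. `stomech` models the guard-cell pair
as two hollow, deformed tori whose plan-view outlines are ellipses: the pore
outline (semi-axes `pore_length/2` by `pore_width/2`) and the complex
outline (semi-axes `stoma_length/2` by `pore_width/2 + gc_width`). Each
cell's midline is the half-ellipse lying pointwise midway between the two,
and the tube cross-section at sweep angle $\theta$ is an ellipse with
in-plane semi-axis $|c(\theta)-p(\theta)|/2$ (the half-gap between the two
outlines) and out-of-plane semi-axis `gc_width/2`. This construction places
the ventral wall seam exactly on the pore ellipse and the dorsal extreme on
the complex outline, so the undeformed model reproduces the four measured
dimensions identically; a circular cross-section of fixed diameter cannot do
this (its inward offset misses the pore ellipse and develops cusps when the
tube radius exceeds the midline's minimum curvature radius, which happens
for ordinary stomatal dimensions). The in-plane map
$(\theta, s) \mapsto ((a_p + s\,\Delta a)\cos\theta,\ (b_p + s\,\Delta b)\sin\theta)$
has a strictly negative Jacobian for every valid geometry, so the sweep can
never self-intersect.

The wall, of thickness 0.1 µm, is meshed with 8-node hexahedra
(`n_midline` × `n_circum` × `n_thickness` per cell; desk default 24 × 16 × 1,
about 830 elements for the pair). The two cells share their end
cross-sections, which lie in the mid-plane of the complex; the polar walls
are annular slabs of thickness 0.3 µm straddling those shared
cross-sections. Every polar node is fixed in space, which clamps the tube
ends — the model's representation of the pole anchoring. Because each lumen
must form a closed pressure surface, a fan of triangular facets caps the
tube ends; those facets act only on fixed nodes, so they close the surface
without adding compliance. Each element carries a unit fiber direction: the
cross-section hoop tangent, orthogonalized against the local midline
tangent, standing for the circumferential cellulose microfibril
orientation.

## Constitutive law

The wall is a transversely isotropic Veronda–Westmann solid in uncoupled
(isochoric–volumetric) form. With $\tilde I_1$, $\tilde I_2$ the isochoric
invariants of the distortional left Cauchy–Green tensor and
$\tilde\lambda$ the distortional fiber stretch:

$$W = C_1\!\left(e^{C_2(\tilde I_1 - 3)} - 1\right)
    - \tfrac{C_1 C_2}{2}(\tilde I_2 - 3)
    + W_f(\tilde\lambda) + \tfrac{K}{2}(\ln J)^2 .$$

$C_1$ (MPa) scales the stress–strain curve, $C_2$ (dimensionless) sets its
nonlinearity, and for small strains the matrix Young's modulus is
$E = 3\,C_1 C_2$. The single fiber parameter $C_5$ (MPa) enters through a
tension-only quadratic fiber energy, $W_f'(\tilde\lambda) =
C_5\langle\tilde\lambda - 1\rangle$: the one-parameter law consistent with
reducing the fiber family to a single stiffness value, inactive in
compression. The volumetric penalty uses $K = 10^4$ MPa (10 GPa), making
the wall nearly incompressible (effective Poisson ratio ≈ 0.5); any $U(J)$
with $U''(1) = K$ would serve equally at these volume changes. The fiber
stress is the deviatoric dyad term
$\sigma_f = (\tilde\lambda/J)\,W_f'\,\mathrm{dev}(\tilde a \otimes \tilde a)$,
keeping the fiber contribution purely deviatoric as the uncoupled split
requires.

## Finite-element solution

The solver is total-Lagrangian with trilinear hexahedra, 2×2×2 Gauss
quadrature, and a mean-dilatation treatment of the volumetric term: the
penalty acts on the element-average dilatation $\bar J$ rather than
pointwise, the standard remedy for volumetric locking at $K/E \sim 10^2$ to
$10^3$. The internal force is the exact gradient of the discrete energy
(mean-dilatation term included), which the tests verify against central
finite differences of the total potential at $10^{-6}$ relative tolerance.
Turgor acts as a follower pressure on the deformed lumen surfaces
(bilinear-quad and flat-triangle facets); on a closed surface the resultant
vanishes identically, which is also tested. The tangent matrix is assembled
by central finite differences at element/facet level (step $10^{-6}$ µm) —
an accepted alternative to the analytic tangent given that the residual,
not the tangent, determines the converged solution. Element-level checks
include rigid-rotation covariance of the nodal forces on a skewed curved
element; this test exists because an isoparametric-gradient transposition
error produces forces that are the exact gradient of a *wrong* energy and
therefore passes every energy-consistency check while breaking frame
indifference.

Newton iteration converges on the relative residual (default $10^{-6}$ of
the external force norm) with damped steps that back off only on element
inversion or gross divergence; transient residual growth under follower
loads is otherwise tolerated. The load program is adaptive: steps that
converge in fewer than half the iteration budget grow by 1.25× (capped at
`dP_max` = 0.5 MPa), failed steps halve down to `dP_min`, below which the
solve aborts carrying its accepted states. The initial step is 0.025 MPa
(0.5 % of the 5 MPa ramp) because the pressure–aperture curve is steepest
at low turgor and the first accepted state doubles as the low-turgor
comparison point between genotypes.

Validation targets are the Laplace solutions: a pressurized thin sphere
(mean von Mises within a few percent of $pR/2t$) and a capped cylinder
(mid-span hoop stress within a few percent of $pR/t$), both meshed as
closed hex shells (cubed-sphere mapping avoids polar degeneracy; the
sphere's six rigid modes are pinned by per-component constraints on its
axis nodes).

## Observables

The pore outline is the deformed ventral seam of each cell — the wall edge
facing the pore — joined into a closed polygon and projected onto the leaf
plane. Aperture is the outline's maximum transverse width; pore area its
shoelace polygon area; both are emitted since either may be the quantity of
interest. Complex length/width are the bounding-box extents of the deformed
outer wall surface, and aspect ratio their quotient. Field outputs are the
element-averaged effective (von Mises) Cauchy stress
$\sqrt{\tfrac32\,\mathrm{dev}\,\sigma : \mathrm{dev}\,\sigma}$ and effective
Lagrange strain $\sqrt{\tfrac32 E':E'}$ with
$E' = E - \tfrac{\mathrm{tr}E}{3}I$, written per load step to VTU for
rendering.

# Parameter choices

Fitted per-genotype material values are not redistributed with the
package, so it ships reconstruction defaults, clearly labelled and
overridable through the YAML/JSON config:

* **Geometry** (shared across genotypes, as complex length does not differ
  between the lines): stoma length 24 µm, pore 12 × 2.4 µm, guard-cell
  width 6 µm — ordinary Arabidopsis dimensions for a nearly closed stoma.
* **$C_2 = 5$, $E_{control} = 3 C_1 C_2 = 48$ MPa.** Two constraints pin
  this range. First, the response regime: with $E \lesssim 15$ MPa the
  dimensionless load $pR/tE$ passes unity below 0.5 MPa, the stoma is fully
  inflated almost immediately and the aperture then drifts back down —
  whereas the observed pressure–aperture relation develops progressively
  over the whole 0–5 MPa turgor range. Second, admissibility: the
  near-incompressibility requirement $K \ge 100\,E$ with the fixed
  $K = 10$ GPa caps $E$ at 100 MPa, and the ×2 stiffness sensitivity
  variant must stay below that cap, giving $E_{control} \le 50$ MPa.
* **Genotype split**: arad1 and ARAD1-OE scale $C_1$ by $\pm\sqrt{1.8}$
  about control, so the arad1 : ARAD1-OE matrix-modulus ratio equals the
  model-predicted 1.8-fold change exactly while control sits at the
  geometric mean.
* **$C_5 = 3000$ MPa.** Cellulose microfibrils are orders of magnitude
  stiffer than the pectin matrix; at this value the hoop fibers are close
  to inextensible, which is what makes pressurization lengthen and bow the
  cells apart (monotone opening) instead of ballooning the cross-section.
  Conveniently, this is also the regime in which halving or doubling $C_5$
  barely moves the response — the reported insensitivity to fiber stiffness
  is a saturation effect.

Model apertures at 5 MPa (≈ 7–8 µm) exceed measured open apertures:
the model has no epidermal confinement, no cuticular ledge, and
reconstruction rather than fitted wall parameters, so its absolute opening
is expected to overshoot. All cross-genotype claims are therefore
comparative (orderings, fold changes), not absolute.

On incompressibility: wall membrane stress at 5 MPa turgor is
$O(pR/t) \approx 10^2$ MPa by statics, independent of wall stiffness, so the
element dilatation reaches $|J - 1| = \sigma_m/K \approx 0.01$–0.03 at
$K = 10$ GPa. The material is near-incompressible in the meaningful sense
(volume changes of a few percent at hundreds of MPa), but a 1 % dilatation
bound is at the edge of what this load case permits; the measured maximum
is reported by the acceptance script as `max_abs_J_minus_1`.

# The AFM pipeline and its synthetic instrument

The processing chain converts raw force maps — grids of force–distance
curves — into apparent-modulus maps: volt-to-force conversion via the
calibrated deflection sensitivity and cantilever stiffness
($F = V \cdot s \cdot k_c$), straight-line baseline/tilt subtraction over
the pre-contact window, contact detection at 5× the baseline noise,
indentation as piezo travel minus cantilever bending
($\delta = (z - z_c) - F/k_c$), and a least-squares fit of the pyramidal
Hertz model

$$F = \frac{\tan\alpha}{\sqrt 2}\,\frac{E_a}{1-\nu^2}\,\delta^2$$

over the 10–100 nm depth window, with the contact point jointly refined as
a depth offset. Three numerical choices matter for soft samples, where the
threshold crossing sits hundreds of nm past the true contact and the
depth-window forces can drop below the noise floor. The baseline window is
validated by fitting its head half and testing the *mean* tail deviation
from the extrapolation (a contact ramp shifts the mean systematically even
when it hides below the point noise); the contact offset is estimated in
closed form from the deep, high-force part of the curve, where
$\sqrt F$ is linear in depth and the intercept locates the contact to
about a nanometre; and once the contact is pinned, the pipeline re-fits
the baseline over the full pre-contact stretch and re-derives the
indentation, so the fit window sees data on the correct depth scale.
Without these steps the fitted moduli of compliant pixels are biased low
by tens of percent rather than merely noisy. The face half-angle α (default 20°) and ν (default 0.5)
are configuration: the instrument's nominal "5 nm diameter" tip specifies
a radius, not an angle, and the fitted ν is not recoverable, so both are
exposed rather than hard-coded. Retraction segments are never analyzed.
Failures at any stage mask the pixel; masking stringency (fit RMS bound,
minimum in-window points) can only grow the masked set.

The synthetic generator replaces the instrument: it runs the same physics
forward — pyramidal Hertz force, cantilever bending coupling
$z = z_0 + \delta + F/k_c$, optional baseline tilt, additive Gaussian
deflection noise scaled to the 250 nN setpoint, approach terminated at the
setpoint — on a stoma-shaped modulus field (elliptical guard-cell annulus
over a pavement background). The generator and the fitting code implement
the Hertz expression independently; they share only the documented unit
constant (1 MPa = 10⁻³ nN/nm²), so round-trip recovery tests are
meaningful. Every curve is a pure function of (config, seed), with
per-pixel seeds derived from the map seed, and the TSV + JSON container
serializes bit-identically. What the generator does not emulate: surface
topography, adhesion, substrate (finite-thickness) effects, and 1/f drift
— so pipeline recovery on synthetic maps demonstrates correctness of the
inversion chain, not robustness to every artifact of real leaf surfaces.

# Problem sizes and numerical settings

Desk-scale defaults: 24 × 16 × 1 elements per guard cell (≈ 830 hexahedra,
≈ 5,000 free degrees of freedom; the ~18,000-element scale is available via
`mesh_resolution`), full 0–5 MPa ramps in ~40 adaptive steps, 16 × 16
synthetic force maps (the instrument's 128 × 128 via config). One genotype
ramp solves in about a minute on one core. Property tests that compare two
solver paths (initial-step halving, mesh refinement) run the ramp to
1.5 MPa — the quasi-static path-independence and convergence they check are
not load-level-specific, and this keeps the default test run fast.
Degenerate inputs are rejected loudly: non-positive Jacobians abort mesh
generation with the offending element, element inversion during a solve
names the element and step, and a ramp that cannot converge above the
minimum step signals a condition carrying all accepted states.

# Known limitations

* Trilinear hexahedra with one element through the thickness underrepresent
  bending; mean dilatation addresses volumetric locking but not transverse
  shear stiffness, so thin-shell bending boundary layers are stiffer than
  converged shell theory. Membrane-dominated quantities (the benchmark
  stresses, aperture trends) are accurate; local bending fields near the
  polar clamps are qualitative.
* No self-contact between ventral walls, no epidermal back-pressure, no
  osmotic coupling, no closing hysteresis: the model describes quasi-static
  inflation of an isolated pair.
* The cross-section height is assumed equal to `gc_width` (no independent
  depth measurement); flagged for sensitivity analysis rather than exposed
  as a fitted parameter.
* Solid (not shell) elements are used throughout since the wall thickness
  is meshed explicitly; at paper-scale resolution this matches the
  ~18,000-element description.
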