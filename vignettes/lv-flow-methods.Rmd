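---
title: "Left-ventricular 4D flow analysis: models, phantoms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left-ventricular 4D flow analysis: models, phantoms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lvflow` post-processes time-resolved, three-directional velocity fields of
the left ventricle (LV) — the data produced by 4D flow MRI after eddy-current
and aliasing correction, segmentation and landmark tracking, all of which are
upstream of this package. Its inputs are a velocity field and a binary LV
mask on a common voxel grid, frame times over one cardiac cycle, anatomical
landmarks per frame (apex, mitral and aortic annulus rings,
papillary-muscle tips and bases), and the subject's haematocrit. From these
it computes four families of quantities:

* **intraventricular energetics** — kinetic energy
  $KE = \sum_{\mathrm{voxels}} \tfrac12 \rho V_{\mathrm{vox}} |v|^2$ and the
  bulk viscous energy-loss rate
  $\dot{EL} = \sum 2\mu (S\!:\!S)\, V_{\mathrm{vox}}$, with $S$ the
  strain-rate tensor, both volume-normalized (KE~V~, EL~V~) and reported
  globally and per region;
* **hemodynamic forces (HDF)** — the volume integral of the intraventricular
  pressure gradient $b = -\rho(\partial_t v + (v\cdot\nabla)v) +
  \nabla\cdot(2\mu S)$, projected on anatomical axes, with per-phase RMS
  values, the transversal-to-longitudinal ratio R~RMS~ and the
  early-diastolic filling impulse;
* **flow components** — pathline subdivision of the end-diastolic blood pool
  into direct flow (DF), retained inflow (RI), delayed ejection (DE) and
  residual volume (RV), as percentages of end-diastolic volume (EDV);
* **cardiac phases** — systole/diastole boundary at aortic valve closure and
  E-/A-wave windows from the transvalvular flow curves.

Because no acquisition accompanies the package, every operator is exercised
on synthetic fields with known answers: analytic flows with closed-form
energetics and forces, and a contracting-ellipsoid LV phantom.

## Data model and units

Geometry is kept in millimetres, time in seconds, velocity in m/s and all
derived quantities in SI (J, W, N, Pa); unit conversion happens only at the
I/O boundary, where on-disk units are declared in a JSON sidecar. Voxel
centres sit at `origin + orientation %*% ((index - 1) * spacing)`; the
`orientation` matrix plays the role of NIfTI direction cosines. Velocity
*components are stored along the grid axes* (phase-contrast acquisitions
encode velocity along image axes) and are mapped to world vectors through
`orientation`. This convention makes a rotation of the dataset a pure
metadata operation: the voxel arrays are untouched, so every scalar output is
invariant under rotation to floating-point roundoff — a property the test
suite asserts at 1e-6. Time is cyclic with the RR interval, as in
retrospectively gated acquisitions; the first frame is end-diastole.

The reference interchange format is a single-file R-native bundle
(`rds_bundle`); per-frame NIfTI volumes and legacy-ASCII VTK structured
points are supported for interoperability with imaging and rendering tools.

## Blood rheology

Blood is treated as an incompressible fluid with density 1025 kg/m^3 and a
shear-thinning, haematocrit-dependent viscosity. The constitutive law is a
Carreau–Yasuda model
$$\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
  \left[1 + (\lambda\dot\gamma)^a\right]^{(n-1)/a},$$
with whole-blood constants at the reference haematocrit 0.45
($\mu_0 = 56$ mPa s, $\mu_\infty = 3.45$ mPa s, $\lambda = 3.313$ s,
$n = 0.3568$, $a = 2$) taken from the standard blood-rheology literature,
and both asymptotic viscosities scaled with haematocrit by a
Krieger–Dougherty-type factor $((1-hct)/(1-hct_{\mathrm{ref}}))^{-2.5}$,
which is monotone increasing in haematocrit. These constants are a modelling
choice of this package, fully overridable through `rheology_params()`; a
Newtonian model (default 3.5 mPa s) backs all analytic verification work.
The shear rate is $\dot\gamma = \sqrt{2\,S\!:\!S}$, which reduces to $|k|$
for the simple shear $v_x = k y$ — conventions differing by $\sqrt2$ exist,
so the normalization is stated explicitly.

## Discrete operators

Spatial derivatives are masked finite differences: central in the mask
interior, one-sided at the mask boundary with a 3-point second-order stencil
where two aligned in-mask neighbours exist, first-order otherwise. Central
and 3-point one-sided stencils are exact on quadratics, which is what makes
the Poiseuille dissipation and pressure-gradient oracles attainable at 5% on
a 1 mm grid; voxels with no in-mask neighbour along an axis are flagged
low-confidence rather than rejected. Near-wall voxels are kept (with their
one-sided stencils) rather than eroded.

The temporal derivative in the pressure gradient is a cyclic three-point
difference on the (possibly non-uniform) frame times, gated per voxel on
mask membership in the neighbouring frames, falling back to one-sided
differences where a voxel enters or leaves the mask. The viscous term is
implemented as the full variable-viscosity divergence $\nabla\cdot(2\mu S)$;
it reduces exactly to $\mu\nabla^2 v$ for uniform viscosity and contributes
little at 4D-flow resolution, and can be disabled to mimic inertia-only
implementations.

Phase integrals (EL per phase, per-phase RMS, the filling impulse) use
trapezoidal integration on a piecewise-linear, cyclically closed curve, so
sub-frame endpoints (aortic valve closure, force zero crossings) are handled
by linear interpolation — necessary because 20–30 frames per cycle is coarse.
EL~V~ per phase is normalized by the *phase-mean* volume; the
per-frame-normalized-then-integrated variant is available behind a
configuration switch, since with time-resolved normalization the two
readings differ and the choice must be explicit. Peaks are located as the
largest sample inside the phase window, with an optional three-point
parabolic refinement.

## Anatomical frame and regions

The basal–apical axis is the unit vector from the mitral-annulus centroid to
the apex; the septal–lateral axis is the aortic-centroid direction
orthogonalized against it (the LVOT plane) and signed toward the lateral
wall; the inferior–anterior axis completes the right-handed triad. Clinical
practice derives these from 2D long-axis views; this package works directly
in 3D world coordinates, an equivalent reformulation. Regional analysis cuts
the chamber with two planes perpendicular to the long axis through the mean
papillary-muscle tip and base positions: basal (mitral plane to PM tips),
mid (tips to bases), apical (below the bases). The cut planes follow the
landmarks frame by frame by default; a fixed-at-end-diastole option exists
because published descriptions leave this open. Valve "planes" are discs
fitted to the annulus point rings (centroid, best-fit normal, radius = mean
point distance); transvalvular flow integrates the normal velocity over
equal-area quadrature points with mask-aware trilinear interpolation.

## Pathline tracing and flow components

Pathlines are integrated with classical RK4, trilinear in space and linear
in (cyclic) time, with sub-steps bounded at half a voxel per step at the
current maximal in-mask speed. Interpolation near the wall is
mask-weight-normalized — out-of-mask corners get zero weight — so near-wall
particles are carried at interior-like velocities instead of being
artificially slowed; velocity outside the mask is zero. A particle is
truncated only when it leaves the 1-voxel-dilated mask, a tolerance that
absorbs the staircase boundary of a moving voxelized wall. Valve crossings
are detected as segment–disc intersections against the frame-interpolated
discs, with a small hysteresis band so that seeds lying exactly on the
annulus plane are classified by their genuine departure direction rather
than by roundoff.

Classification seeds one pathline per in-mask voxel centre at end-diastole,
traces backward through diastole (mitral-disc crossing = "entered") and
forward through systole (aortic-disc crossing = "leaves"), yielding
DF (entered and leaves), RI (entered only), DE (leaves only) and RV
(neither: blood resident for at least two cycles, realized with one cycle of
data through the backward/forward construction). Truncated seeds are
reported as unclassified, with a quality warning above 10%. Fractions,
counts and per-seed labels are returned; fractions plus unclassified close
to 100% exactly.

## The synthetic module

Four analytic fields (uniform, rigid rotation, Poiseuille, uniform
acceleration) carry their closed forms as machine-checkable truth:
rigid rotation has zero strain rate, Poiseuille has axial pressure gradient
$-4\mu v_{\max}/R^2$ and bulk dissipation $2\pi\mu v_{\max}^2 L$, a uniform
ramp $a$ has $b = -\rho a$ everywhere. These truths are themselves verified
against brute-force numerical differentiation in the tests before being used
as oracles.

The LV phantom is a half-ellipsoid (apex fixed, base plane fixed, short axis
contracting as $\sqrt{V(t)}$) whose volume follows a half-cosine ejection
over a prescribed systolic fraction and a biphasic E/A filling with
prescribed peak-flow ratio (merged single-peak filling available). Default
conditions: EDV 150 mL, EF 0.60, 70 bpm, systolic fraction 0.35, E/A = 2,
grid 32 x 32 x 48 at 2.5 mm, 30 frames — matching clinical 4D-flow voxel
sizes (2.0–2.8 mm) and frame counts (20–30), with cohort-scale EDV/EF knobs.
The interior velocity is built from a Stokes streamfunction about the active
orifice axis (aortic in ejection, mitral in filling): a flat-top jet whose
slice flux equals the volume change beyond each short-axis plane, fed by the
streamfunction's radial far field, which at the wall reproduces the mean
wall-following motion; the jet axis bends smoothly from the (offset) orifice
onto the long axis. Two properties of this construction matter downstream:
the flux through the annulus disc matches $\mp dV/dt$ (the transvalvular
oracle), and the field is divergence-free, so Lagrangian transport is
volume-consistent and the pathline bookkeeping identities
(DF+DE $\approx$ EF, DF+RI $\approx$ inflow/EDV) hold by construction rather
than by tuning. The jet fills 75% of the annulus radius — a
vena-contracta-like margin sized so that the trilinearly smeared jet stays
inside the measurement disc at clinical voxel sizes. A consequence of the
quasi-steady construction worth knowing: the phantom's KE_V peaks slightly
*before* the transmitral flow peak, because the chamber-normalized inflow
rate $\dot V/V$ leads $\dot V$; peak-timing tests therefore compare against
a finely time-sampled phantom rather than the flow-peak time. Optional components: seedable isotropic Gaussian velocity noise (the
simplest surrogate for velocity-encoding noise), and a transverse sloshing
term with a parabolic envelope vanishing at the wall, used as a
disorganized-flow surrogate when constructing reduced-EF phantom groups.

What the phantom does *not* emulate: MR signal formation, partial-volume and
background-phase errors, valve leaflet motion, trabeculation, and genuinely
chaotic intracavitary flow. Passing phantom tests therefore demonstrates the
correctness and stability of the *operators*, not clinical accuracy on
patient data.

## Numerical tolerances and degenerate inputs

Closed-form checks run at 1–5% at the stated grid resolutions, with
refinement tests asserting that errors halve when spacing halves; phantom
parameter recovery runs at 2 EF points, 5% stroke-volume agreement and half
a frame for valve closure, reflecting what a 2.5 mm / 30-frame acquisition
can resolve. Degenerate inputs fail loudly: empty masks, collinear
landmarks, papillary planes out of order, missing frames in a series, zero
volumes, a zero basal–apical RMS (undefined R~RMS~), and a basal–apical
force with no diastolic zero crossing (undefined impulse, flagged rather
than fabricated).

## Design choices made where the field leaves them open

* The HDF sign convention reports the volume integral of the pressure
  gradient (positive basal–apical toward the apex); the action–reaction
  reading is a global sign flip, exposed as `hdf_convention =
  "wall_on_blood"`.
* R~RMS~ combines the two transversal components as the root of their summed
  squared RMS values, divided by the basal–apical RMS, computed per phase
  (whole-cycle RMS values are reported alongside).
* Problem sizes in the tests and acceptance script (default phantom at
  32 x 32 x 48 x 30; smaller 26 x 26 x 40 x 20 phantoms for invariance
  batteries; 10-phantom robustness batches) were chosen as the smallest
  sizes representative of clinical resolution at which the stated
  tolerances are meaningful.
* Group comparisons are deliberately descriptive (mean, SD, percent
  difference); inferential statistics on synthetic cohorts would be
  meaningless.

## Known limitations

The filling impulse integrates the basal–apical force only up to its first
zero crossing after valve closure; when that component oscillates near zero
early in diastole (transverse disturbances, velocity noise), the endpoint —
and hence the impulse magnitude — is sensitive, which is a property of the
index itself rather than of this implementation. Group contrasts built on it
are therefore assessed as orderings, never magnitudes.

Bulk dissipation excludes boundary-layer losses below voxel scale, so EL is
a lower bound on true viscous loss. The phantom's wall-normal velocity match
is exact only in the slice-averaged sense, which leaves a few percent of
seeds unclassified in component analysis. Pressure is never reconstructed —
only its gradient and the volume-integrated force, which is all the reported
quantities require.
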