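---
title: "Computing global LV hemodynamic forces from 4D flow velocity fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing global LV hemodynamic forces from 4D flow velocity fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvforce)
```

## The physical model

Time-resolved phase-contrast MRI (4D flow) measures all three velocity
components of intracavitary blood on a voxel grid across the cardiac cycle.
Treating blood as an incompressible Newtonian fluid, the pressure-gradient
field inside the left ventricle (LV) follows from the Navier-Stokes momentum
balance with body forces excluded:

$$\nabla p \;=\; -\rho\,\frac{\partial \mathbf v}{\partial t}
  \;-\;\rho\,(\mathbf v\cdot\nabla)\,\mathbf v
  \;+\;\mu\,\nabla^2 \mathbf v,$$

with blood density $\rho = 1060\ \mathrm{kg/m^3}$ and dynamic viscosity
$\mu = 0.004\ \mathrm{N\,s/m^2}$ (package defaults, overridable in the
sidecar). Integrating $\nabla p$ over the segmented LV volume at each cardiac
frame gives a single 3-vector per frame,

$$\mathbf F(t) \;=\; \int_{LV(t)} \nabla p \; dV
  \;=\; \oint_{\partial LV(t)} p\,\hat{\mathbf n}\; dS,$$

which by the divergence theorem (outward normal) is the net pressure force
the blood exerts on its surroundings — the *global hemodynamic force* on the
myocardial wall. The sign convention is fixed by that identity; the package
never needs an absolute pressure level because only $\nabla p$ enters.
During diastolic filling the myocardium decelerates the inflowing blood and
the reaction force on the wall points toward the apex; in a healthy,
elongated LV it is therefore expected to align with the apex-base axis,
whereas dilated, more spherical ventricles redirect part of it transversely.

`hemoforce()` is the per-subject entry point; it returns a classed object
with `print()`, `summary()`, `coef()`, `plot()` and `as.data.frame()`
methods.

## Discretization

Spatial derivatives are second-order central differences restricted to
in-mask neighbors, degrading to first-order one-sided stencils at the cavity
boundary; a voxel with no in-mask neighbor along some axis is marked invalid
and excluded from the integral rather than zero-filled — zero-filling biases
exactly the boundary shell that dominates the surface integral. The
Laplacian requires both neighbors per axis and contributes nothing where
they are missing; at 3 mm resolution the viscous term is orders of magnitude
below the transient term, and the one-sided bias it would otherwise pick up
exceeds its value. It can be disabled altogether
(`hf_config(include_viscous = FALSE)`) for sensitivity analyses.

The frame axis is cyclic (retrospective gating: the last frame precedes the
first), so $\partial\mathbf v/\partial t$ is a cyclic central difference
using each frame's own mask, falling back to one-sided when the voxel leaves
the mask in an adjacent frame. The Eulerian terms are integrated over the
instantaneous mask; no wall-motion (moving-boundary) correction of the
material derivative is applied, which is a known limitation shared with the
standard in vivo processing of such data. An optional one-voxel mask erosion
(`erode_mask = TRUE`) excludes partially filled border voxels; the default
integrates all valid in-mask voxels.

On an oscillating-ball phantom with spatially uniform
$v_x = A\sin(2\pi t/T)$ the discrete solver reproduces the closed form
$F_x = -\rho A(2\pi/T)\cos(2\pi t/T)V$ up to the cyclic-difference factor
$\sin(\omega\Delta t)/(\omega\Delta t)$ (second order in $\Delta t$) and the
voxelization error of the ball volume (approximately second order in $h$);
both are verified in the test suite, as is the equality of
$\int\nabla p\,dV$ with an independently quadratured surface integral
$\oint p\hat{\mathbf n}\,dS$.

## Preprocessing

Two corrections precede the physics, in fixed order.

**Temporal velocity unwrapping.** Velocities beyond the encoding limit VENC
alias by multiples of $2\cdot\mathrm{VENC}$. Starting from the frame of
minimal global mean speed, each voxel/component series is walked cyclically
and shifted by the wrap integer in $\{-2,\dots,2\}$ that minimizes the jump
to the already-corrected neighbor; true speeds are assumed below
$2\cdot\mathrm{VENC}$ and true frame-to-frame jumps below VENC (at
VENC = 1 m/s more than two wraps is implausible in the ventricle). This is a
deliberately temporal, per-voxel scheme — multi-dimensional spatial
unwrapping is out of scope.

**Background-offset removal.** Eddy currents leave a slowly varying,
time-constant offset in each velocity component. A polynomial of total
degree 4 (35 terms) in physical coordinates is fitted by weighted least
squares to the *time-averaged* velocity, then subtracted from every frame.
The weights form a soft static-tissue mask,
$w = \exp[-(\sigma_{speed}/s)^2]$ with $\sigma_{speed}$ the temporal
standard deviation of the voxel speed and scale $s = 0.05$ m/s
(`hf_config(sd_scale = )`). The published corrections this emulates name a
weighted soft mask without specifying the weighting rule; this Gaussian-in-SD
form is this package's stand-in and is documented as such. A consequence of
the soft mask is that slowly moving blood retains a little weight, so on a
perfectly artifact-free dataset the background stage is not the exact
identity: it removes a spurious offset well below $10^{-3}$ m/s, which is
negligible against the noise floor (the test suite pins this bound).
Unwrapping runs first because wraps corrupt the temporal mean the fit uses.

## Anatomy, phases, and metrics

The long axis $\hat e_{long}$ runs from the mitral-valve (MV) center to the
apex. The three-chamber (LAx) plane is spanned by $\hat e_{long}$ and the
MV-to-aortic-valve direction orthogonalized against it; that in-plane
transverse direction, signed to point from the anteroseptal (aortic) side
toward the inferolateral wall (an `rv_direction` landmark overrides the
sign when supplied), is $\hat e_{sax1}$, and $\hat e_{sax2}$ completes the
right-handed triad. The basal short-axis projection is the fixed
$(\hat e_{sax1}, \hat e_{sax2})$ plane rather than a per-frame anatomical
slice: the force is one global vector, so only the plane's orientation
matters, and a fixed orthogonal plane makes the two projections exactly
complementary. The reference origin is the mask center of mass at the first
E-wave frame (the convention adopted for "early diastole").

Cardiac phases are detected from speed traces trilinearly interpolated at
the MV and AoV landmarks. Systole ends where the AoV trace falls below its
onset threshold; the E-wave runs from the onset of the MV-speed rise —
first frame above `onset_frac` (default 0.05) of the baseline-corrected wave
peak, walked back to the preceding local minimum — to the local minimum
after the E peak; the A-wave is found the same way around the second
diastolic peak and ends at end-diastole; diastasis is the gap. The four
windows partition the cycle; a fused single-peak inflow yields an empty
A-wave plus a warning, and flat traces are an error. The 5% onset fraction
turns the verbal "onset of the increase" into a numeric rule robust to
noise; detection is invariant to rescaling of the traces, and traces are
lightly smoothed (3-point mean) before thresholding.

Per filling wave the package reports the **SAx-max/LAx-max ratio**
$\max|F_{sax1}| / \max|F_{long}|$ over the wave's frames (absolute signed
projections: per-wave extrema, direction-agnostic) and the **time-averaged
SAx-plane force** $\mathrm{mean}\sqrt{F_{sax1}^2+F_{sax2}^2}$. The ratio
uses only the anteroseptal-inferolateral component, mirroring how the two
metrics are defined as distinct quantities; note that the ratio's *name*
puts SAx in the numerator and the package follows the name (a transverse
force excess must increase it), resolving a word-order ambiguity in how the
quotient is sometimes phrased. Loop orientation in the LAx plane is the
sign of the shoelace area of the $(F_{long}, F_{sax1})$ trajectory
(indeterminate below $10^{-6}\ \mathrm{N^2}$), and the E-wave peak lag is
the time from the MV-speed peak to the $|\mathbf F|$ peak within the
E-window. EDV is taken from the mask (maximum volume over the cycle), the
only geometry the pipeline holds; the sphericity index enters as an external
covariate because its image-based measurement is out of scope.

## The synthetic LV phantom

No measured datasets ship with the package; a self-validating phantom
generator defines the study conditions instead.

Geometry is a prolate ellipsoid whose semi-axes follow from the prescribed
EDV and sphericity index ($SI$ = basal diameter / long-axis length), with a
volume waveform EDV → ESV (from the ejection fraction) → partial E-wave
refill (70% of stroke volume by default) → diastasis → A-wave completion,
anchored at the basal plane so the apex does the moving. The end-diastolic
scale is calibrated so the voxelized mask volume matches the prescribed EDV
to within two voxel volumes. A 30-frame segmentation series on a finer
(1.5 mm) grid emulates the morphological time base and exercises the
nearest-neighbor mask resampling; velocity data use 40 frames over a
1000 ms cycle on a 3 mm grid, with VENC 1 m/s — the acquisition regime of
clinical 4D flow.

The velocity field is a spatially uniform bulk component $u(t)$, apodized by
a cosine rolloff that vanishes just inside the cavity boundary, plus
confined MV inflow jets (E and A lobes) and an AoV outflow jet that drive
the valve-plane speed traces. For such a field the convective volume
integral is the integral of the gradient of a compactly supported function
and cancels, so the global force is dominated by the transient term,
$\mathbf F \approx -\rho\, d/dt \int \mathbf v\, dV$ — the *momentum
oracle*, an independent route to $\mathbf F$ that is stored as ground truth
with every phantom and guards the pressure-gradient path against sign and
unit errors (the two agree within a few percent RMS; the interior of the
bulk field is divergence-free, the rolloff shell carries the divergence
that sources the net momentum change, as the open mitral/aortic orifices do
in vivo). The long-axis velocity lobes rise slowly and fall quickly, so the
deceleration force peak trails the inflow velocity peak by one to two
frames (25-50 ms), and the LAx force loop runs counter-clockwise — both
features of measured healthy ventricles.

Per-wave amplitudes of the long-axis and transverse bulk components are
tuned by construction: two fixed-point iterations rescale them until the
force metrics *computed by the package's own pipeline on the noiseless
field* (with the phase windows it detects) match the prescribed targets.
This makes the generator's targets meaningful through the full measurement
chain while the momentum oracle remains the independent check. Acquisition
artifacts are then injected: Gaussian velocity noise (SD 0.02 m/s),
a random degree-4 background polynomial (RMS 0.02 m/s), and VENC aliasing.
The DCM presets use an E-jet of 1.25 m/s so genuine wraps occur and the
unwrapping stage does real work.

Cohort presets (`healthy`, `dcm`, `dcm_normal_diastolic`) draw per-subject
targets from truncated normal distributions whose means and SDs encode the
published group summaries the phantom emulates (force-direction ratios,
short-axis force levels, EDV, EF, SI); the sphericity index is coupled to
the standardized E-ratio with coefficient 0.3, which reproduces a pooled
two-group ratio-SI regression of weak-to-moderate strength. Cohort
generation is a pure function of (preset, n, seed).

What the phantom does **not** emulate: intraventricular vortex dynamics,
trabeculation and papillary muscles, valve leaflets, turbulence, k-space /
SENSE reconstruction effects, partial-volume and displacement artifacts,
segmentation error, and through-plane motion of the basal plane. Passing
the recovery tests therefore shows that the estimator chain is unbiased and
correctly scaled under controlled conditions — not that it reproduces every
property of measured ventricles.

## Statistics

Group comparisons use unpaired t-tests, pooled-variance student by default
(the era-typical clinical choice; Welch by `variant = "welch"`), accepting
raw samples or summary statistics (mean, SD, n). Significance is $\alpha =
0.05$ with no multiple-testing correction, deliberately mirroring the
analysis this package operationalizes. The force-ratio vs sphericity
regression pools both groups (n = 20), consistent with a relation assessed
across the clinical spectrum. The test suite checks the p-values against a
direct numerical integration of the t density and calibrates the test's
type-I error under the null (empirical size 0.03-0.07 over 500 seeded
replicates at reduced n).

## Problem sizes and runtime choices

The validation suite uses the oscillating-ball oracle at $16^3$-$64^3$
voxels and 10-80 frames; phantom cohorts of 10 + 10 + 5 subjects at 3 mm /
40 frames (grids of roughly $27\times27\times41$ voxels, chosen so one
subject generates and analyzes in seconds on a single core); and 500
metric-level replicates for the null calibration. These sizes keep the full
pipeline exercised end to end — generation, artifact injection,
preprocessing, physics, detection, metrics, statistics — at desk scale.

## Known limitations

* The Eulerian integral over the instantaneous mask omits the moving-wall
  contribution to the material derivative.
* The viscous term is underestimated at 3 mm resolution and near the
  boundary (no one-sided Laplacian).
* The background soft mask is a documented stand-in for an unspecified
  published weighting; its scale is a configuration knob.
* Border voxels are integrated unless `erode_mask = TRUE`; with 3 mm voxels
  their contribution is small but not zero.
* The basal SAx projection uses one fixed orthogonal plane per subject, not
  a manually chosen per-subject slice orientation.
* Landmarks are inputs: no automatic valve or apex detection.
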