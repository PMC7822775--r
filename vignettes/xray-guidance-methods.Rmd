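---
title: "Projection geometry, registration and tracking for X-ray guidance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection geometry, registration and tracking for X-ray guidance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrnav)
```

# Scope

`xrnav` implements the computational core of an X-ray navigation system for
transcatheter interventions: the projective geometry of a C-arm fluoroscopy
system, 3D reconstruction of working points from biplane views, rigid
cross-modal registration of tomographic (MRI/CT) marker sets onto the X-ray
world, template-matching tracking with 2D and 3D motion compensation,
character recognition of the geometry panel burned into live video frames,
closed-form bounds on the overlay error introduced by display rounding, and
a synthetic phantom/frame simulator that provides exact ground truth for all
of the above. Rendering, GUI and video-capture hardware are out of scope;
the package operates on frames, meshes, point lists and geometry records.

# Coordinate systems and the projection model

The world coordinate system (WCS) has its origin at the iso-center — the
point all gantry rotations pivot about — with x toward patient-left,
y anterior, z cranial. Image coordinates are 0-based pixels with the origin
at the upper-left corner and rows growing downward.

A C-arm acquisition is a pinhole camera. For gantry angles $(\alpha,\beta)$
(primary LAO$+$/RAO$-$, secondary CRAN$+$/CAUD$-$), table position
$t = (t_x, t_y, t_z)$ mm, source-image distance $SID$, source-to-patient
distance $SPD$ and detector field diagonal $FD$, the projection is the
$3\times4$ homogeneous matrix

$$
P = \begin{bmatrix} f & 0 & n_u/2 \\ 0 & f & n_v/2 \\ 0 & 0 & 1 \end{bmatrix}
\left[\, A \;\middle|\; \begin{matrix}-t_x\\-t_y\\ SPD + t_z\end{matrix}\,\right],
\qquad f = \frac{SID}{\mathrm{pitch}},\quad
\mathrm{pitch} = \frac{FD}{\sqrt{n_u^2+n_v^2}},
$$

where the rows of $A$ are the in-plane detector axes and the view axis,
obtained by rotating the zero-angle camera frame (u = patient-left,
v = caudal, view = anterior) by $R_{PA}(\alpha) R_{SA}(\beta)$ — the primary
rotation about the head-foot axis composed with the secondary rotation about
the patient left-right axis, in that order. The table translation acts in
the rotated camera frame, which is what makes a pure horizontal table move
produce a pure image shift at every angulation.

Sign conventions in this construction are fixed by three testable
properties rather than by any printed matrix, whose raw signs are
convention-dependent (a common published form maps the iso-center to
$(-n_u/2, +n_v/2)$ with negative depth):

* the iso-center at zero table projects to the image center
  $(n_u/2, n_v/2)$ for every angulation and SID;
* image rows grow downward (the v row carries the flip);
* the magnification of an infinitesimal object at the iso-center is
  $SID/SPD$.

These are the only behaviors downstream results depend on, and each is a
unit test. Depth is positive from the source toward the detector, so
points behind the focal spot are detectable and flagged non-projectable.
For square images the focal length reduces to the familiar
$\sqrt{2}\, n_u\, SID / FD$. Non-square detectors use the image diagonal,
covered by a unit test.

$SPD$ is a per-C-arm vendor constant that is not displayed or exported by
the system; the shipped defaults (810 mm frontal, 765 mm lateral) are
configuration values in `default_carm_configs()` and every API takes SPD
explicitly. The table-axis mapping (displayed long/lat/vert to camera axes)
is likewise configurable; the default maps axes 1 and 2 perpendicular to
the zero-angle view axis and axis 3 along it.

# Biplane reconstruction

A point marked in two views is reconstructed by back-projecting each pixel
to a ray from its focal spot and returning the midpoint of the common
perpendicular of the two rays — algebraically the least-squares point for
two lines, and the natural closed form under the epipolar-constraint
framing. The closest-approach distance between the rays (`gap_mm`) is
returned as an epipolar consistency diagnostic: zero for exact
correspondences, growing with marking error. Geometry pairs whose view
axes are separated by less than 15° (configurable) are rejected as
degenerate; this conditioning guard is a design choice, as is the 15°
default — triangulation error grows quickly as views approach parallel,
which a property test verifies by simulation. `epipolar_line()` projects a
ray from one view into the other, clipped to the image bounds, for
interactive correspondence checking.

# Rigid registration

Tomographic marker positions are registered to their XR-reconstructed
counterparts with a paired-point rigid least-squares fit
$\min_T \sum_i \lVert T p_i^{\mathrm{tomo}} - p_i^{\mathrm{XR}} \rVert^2$,
solved by the SVD (Kabsch) construction with determinant correction so the
result is always a proper rotation — no scaling, no reflection, no outlier
rejection, matching the rigid-only scope of the workflow. Horn's quaternion
method reaches the same optimum and serves as the independent oracle in the
tests. Accuracy is reported as
$\mathrm{RMSE} = \sqrt{\tfrac1n \sum_i \lVert T p^{\mathrm{tomo}}_i -
p^{\mathrm{XR}}_i \rVert^2}$. Fits require at least three non-collinear
pairs; pairing is by label, so point order is irrelevant.

# Template tracking and motion compensation

Tracking uses zero-normalized cross-correlation (mean-subtracted NCC): the
score is exactly invariant to affine intensity changes of the frame, which
unnormalized variants are not. The search scans every placement of the
template inside the window; ties break toward the smallest $(v, u)$.
Parabolic sub-pixel refinement exists but is off by default — the shipped
behavior is integer-pixel argmax, and all tolerances below account for the
resulting half-pixel quantization. Search windows default to 3× the
template size re-centered on the last position (temporal coherence); the
template itself is never updated, since drift correction is not part of the
modeled workflow — re-initialization is a user action.

2D motion compensation shifts the model overlay by the tracked structure's
displacement from its reference position. 3D tracking matches a catheter-tip
template in both biplane views, triangulates per frame, and subtracts the
3D motion vector of a reference structure tracked the same way in both
views (one structure, triangulated — not per-plane vectors fused), yielding
the tip trajectory inside the static 3D model. Biplane frames are paired
nearest-in-index; capture skew between the two video chains is not modeled.

# Panel character recognition

In live operation the imaging geometry exists only as numbers burned into
the 1280×1024 video frame next to the fixed 1000×1000 image region. Each
analyzed cell is binarized at the midpoint of its own intensity range —
removing all luminance/contrast (gain/offset) dependence exactly — and
classified to the glyph (digits, signs, blank) minimizing the Frobenius
norm of the binary difference matrix. A scalar Frobenius norm of the cell
itself would collide between glyphs of equal on-pixel count; the
nearest-template reading is the only one that uniquely identifies every
character, and an exhaustive pairwise test keeps the shipped font's
confusion matrix diagonal. A best distance above 10% of the cell area, or
two glyphs within numerical tolerance of each other, clears the confidence
flag instead of guessing — inverted-polarity input is rejected this way,
never misread.

Angulation signs come from the orientation words: the distinguishing letter
of each pair (L/R for LAO/RAO, second letter R/A for CRAN/CAUD) is
classified against exactly those two glyph candidates; degree-sign cells
distinguish angle fields from table fields. The shipped layout is
synthetic — vendor panel coordinates and fonts are not redistributable — and
displays every field simultaneously: 19 character cells per C-arm
(3 primary + 2 secondary + 3×3 table + 3 SID + 2 FD) plus the discriminator
cells. Vendor panels that alternate table and angulation values in a shared
area (13 analyzed positions) are supported through the same layout file
mechanism (`read_panel_layout()`), with per-field validity flags carrying
the "not currently displayed" case.

`to_carm_geometry()` turns an integer reading into a metric geometry:
cm become mm, and the displayed FD maps to an exact pixel pitch through a
per-C-arm override table (the analog of taking `ImagerPixelSpacing` from
DICOM per FD setting), which eliminates the FD rounding error entirely.
The shipped override tables are synthetic stand-ins chosen so that each
true diagonal rounds to its displayed value.

# Rounding-error bounds

Displayed values are rounded to whole centimetres and degrees, so two
frames with identical displayed geometry can differ by up to 1 cm of table
travel or 1° of angulation. The worst-case overlay displacement is
evaluated at maximal magnification (maximal SID):

* table: $\epsilon_t = \dfrac{10\,\mathrm{mm}}{SPD}\cdot SID_{\max}$ —
  14.8 mm for the frontal C-arm (SPD 810, SID 1200) and 16.99 mm for the
  lateral (SPD 765, SID 1300);
* angulation: $\epsilon_a = \sqrt{b^2 + L^2 - 2bL\cos\theta}$ with
  $L = SID_{\max} - SPD$, $b = L\sin(90°)/\sin(90°-\theta)$, $\theta = 1°$ —
  6.8 mm frontal. Algebraically this law-of-cosines form collapses to
  $L\tan\theta$, which the tests exploit as an independent construction.

For the lateral C-arm the same closed form gives 9.34 mm. A value of
9.4 mm has circulated for this configuration, but no single SPD consistent
with the 16.99 mm table bound reproduces it; the package reports the
computed value and documents the discrepancy rather than matching it.
Simultaneous rounding of several parameters can accumulate and is
deliberately not modeled. The SID rounding error only perturbs
magnification and produces no displacement, so it has no bound here.

# The phantom simulator

The simulator emulates the accuracy experiment such a system is validated
with: a phantom of glass spheres of 6, 10 and 20 mm diameter (optionally a
glass tube) imaged by a biplane system. Projections are analytic — each
pixel's ray is intersected with every sphere/cylinder in closed form and
intensities follow exponential attenuation of the path length — which is
exact and fast, and the projected sphere centers are emitted as ground
truth (checked in tests against an independent ray/detector-plane oracle
rather than the package's own projection path). Live frames are composed
from the image region plus a panel rendered from the display-rounded
reading (rounding half away from zero — vendor behavior is unknown, so the
rule is centralized in one function), followed by a per-frame gain/offset
to emulate capture-dependent intensity variations.

`sample_marker_sets()` emulates manual marker identification: tomographic
coordinates are sphere centers mapped through a seeded random rigid scanner
pose plus isotropic Gaussian noise, 2D points are exact projections plus
pixel noise. Noise magnitudes are specified as the standard deviation of
the error-vector magnitude (per-axis $\sigma/\sqrt{d}$): a scalar "0.5 mm
isotropic resolution" quoted for an MRI acquisition describes the size of
the 3D localization uncertainty, not a per-axis deviate. Under this
convention the expected 6-marker registration RMSE at $\sigma = 0.5$ mm is
$\approx \sigma\sqrt{2/3} \approx 0.41$ mm, consistent with the
few-tenths-of-a-millimetre accuracy reported for real phantom experiments;
the per-axis reading would predict $\approx 0.71$ mm and is inconsistent
with those results.

What passing simulator-based tests does *not* show: robustness to scatter,
detector blur, spectral effects, deformable anatomy, or vendor fonts and
panel layouts other than the synthetic one — real deployments must
calibrate a layout file and the per-C-arm constants.

# Numerical choices and problem sizes

* All distances are mm internally; degrees at API boundaries.
* Exact round-trips (project→triangulate, DICOM, VTK) are asserted at
  1e-6 mm / stated storage precision; oracle equivalences at 1e-9.
* Tracking tolerances derive from the half-pixel quantization of
  integer-pixel NCC mapped to iso-center scale,
  $0.5\cdot \mathrm{pitch}\cdot SPD/SID$ per view axis, combined in
  quadrature; motion-compensation closure is asserted within 1.5× that.
* Test problem sizes are chosen for exactness-per-second: 200–220 px
  detectors for rendered tracking sequences (50 frames), full 1280×1024
  frames for panel recognition (500 frames), 100 seeds for the
  registration Monte Carlo, ≥1000 cases for the projection oracle.
* The registration experiment of the accuracy study uses the biplane
  LAO 0°/LAO 90° configuration with SID 1200/1300 mm, table
  (−640, −70, 60) mm, 6 markers — the first row of the study's geometry
  table — and reports the median RMSE over seeds.

# Known limitations

Rigid-only registration (no deformation), fixed templates (no drift
correction), two-view reconstruction only, no automatic 2D correspondence,
minimal DICOM support (uncompressed explicit-VR little-endian with the
X-ray Angiographic / RT table tag set), legacy VTK POLYDATA only. The
rounding-error bounds are worst-case along the centerline; error grows
with distance from the iso-center and can accumulate across parameters.
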